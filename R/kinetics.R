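#' Influx rate constant Ki of the irreversible two-tissue model
#'
#' Ki = K1 * k3 / (k2 + k3), the net rate of irreversible tracer uptake from
#' plasma into tissue. With no trapping pathway (k2 = k3 = 0) Ki is defined
#' as 0, with a warning.
#'
#' @param K1 plasma-to-tissue delivery, mL/ccm/min (or a length-3 vector
#'   \code{c(K1, k2, k3)})
#' @param k2 tissue-to-plasma clearance, 1/min
#' @param k3 trapping rate into the specific compartment, 1/min
#' @return Ki in mL/ccm/min
#' @examples
#' compute_ki(0.849, 0.645, 0.750)  # 0.4565
#' @export
compute_ki <- function(K1, k2 = NULL, k3 = NULL) {
  if (is.null(k2) && length(K1) >= 3) {
    k2 <- K1[[2]]; k3 <- K1[[3]]; K1 <- K1[[1]]
  }
  if (any(c(K1, k2, k3) < 0)) stop("rate constants must be non-negative")
  if (k2 + k3 == 0) {
    warning("k2 + k3 = 0: no trapping pathway, Ki defined as 0")
    return(0)
  }
  K1 * k3 / (k2 + k3)
}

# exponential kernel of the 2TC impulse response: list(alpha=rates, phi=coefs)
# C_T(t) = sum_i phi_i * int_0^t exp(-alpha_i (t-s)) Cp(s) ds
.tc_kernel <- function(K1, k2, k3, k4 = 0) {
  if (any(c(K1, k2, k3, k4) < 0)) stop("rate constants must be non-negative")
  if (k4 == 0) {
    beta <- k2 + k3
    if (beta == 0) return(list(alpha = 0, phi = K1))
    ki <- K1 * k3 / beta
    return(list(alpha = c(0, beta), phi = c(ki, K1 - ki)))
  }
  s <- k2 + k3 + k4
  disc <- s^2 - 4 * k2 * k4
  if (disc < 1e-20) {        # repeated root: nudge off the degeneracy
    k4 <- k4 * (1 + 1e-8) + 1e-12
    s <- k2 + k3 + k4
    disc <- s^2 - 4 * k2 * k4
  }
  r <- sqrt(disc)
  a1 <- (s - r) / 2; a2 <- (s + r) / 2
  list(alpha = c(a1, a2),
       phi = c(K1 * (k3 + k4 - a1) / (a2 - a1),
               K1 * (a2 - k3 - k4) / (a2 - a1)))
}

# exact convolution of exp(-alpha t) with a piecewise-linear curve,
# evaluated recursively at the knots (t, y): returns G(t_j) for all knots
.conv_exp_pl <- function(t, y, alpha) {
  n <- length(t)
  G <- numeric(n)
  dt <- diff(t)
  y0 <- y[-n]; slope <- diff(y) / dt
  if (alpha == 0) {
    seg <- y0 * dt + slope * dt^2 / 2
    return(cumsum(c(0, seg)))
  }
  em <- exp(-alpha * dt)
  one_m <- -expm1(-alpha * dt)          # 1 - exp(-alpha dt), stable
  seg <- y0 * one_m / alpha + slope * (dt / alpha - one_m / alpha^2)
  for (j in seq_len(n - 1L)) G[j + 1L] <- G[j] * em[j] + seg[j]
  G
}

#' Forward-solve the two-tissue-compartment model
#'
#' Solves \deqn{dC_1/dt = K_1 Cp - (k_2 + k_3) C_1 + k_4 C_2, \quad
#'   dC_2/dt = k_3 C_1 - k_4 C_2} with zero initial conditions and returns
#' the total tissue activity \eqn{C_T = C_1 + C_2}. The solution is the
#' convolution of Cp with a sum of exponentials and is computed exactly for
#' the piecewise-linear input-function contract (closed-form segment
#' integrals with a recursive update), so accuracy is limited only by the
#' input function's sampling, not by an ODE step size. The irreversible
#' configuration (k4 = 0) reduces the kernel to
#' \eqn{K_i + (K_1 - K_i) e^{-(k_2+k_3) t}}.
#'
#' @param kp named or positional vector \code{c(K1, k2, k3)} or
#'   \code{c(K1, k2, k3, k4)}; units mL/ccm/min for K1, 1/min otherwise
#' @param input_fn an [input_function()]
#' @param times evaluation times, minutes, sorted non-decreasing
#' @return tissue activity C_T at \code{times}, kBq/cc
#' @export
solve_2tc <- function(kp, input_fn, times) {
  kp <- unname(unlist(kp))
  K1 <- kp[1]; k2 <- kp[2]; k3 <- kp[3]
  k4 <- if (length(kp) >= 4) kp[4] else 0
  if (is.unsorted(times)) stop("times must be sorted")
  if (any(times < 0)) stop("times must be >= 0")
  if (K1 == 0) return(numeric(length(times)))
  kern <- .tc_kernel(K1, k2, k3, k4)
  knots <- sort(unique(c(0, input_fn$time[input_fn$time <= max(times)], times)))
  knots <- knots[knots >= 0]
  cpk <- if_eval(input_fn, knots)
  ct <- numeric(length(knots))
  for (i in seq_along(kern$alpha))
    ct <- ct + kern$phi[i] * .conv_exp_pl(knots, cpk, kern$alpha[i])
  ct[match(times, knots)]
}

# frame-averaged model TAC: mean of C_T over each frame interval,
# by trapezoid on a fine sub-grid (step <= max_step, >= 20 intervals/frame)
.model_frame_avg <- function(kp, input_fn, schedule, vB = 0,
                             max_step = 0.02) {
  nfr <- nrow(schedule)
  grids <- vector("list", nfr)
  for (i in seq_len(nfr)) {
    npt <- max(21L, ceiling((schedule$end[i] - schedule$start[i]) / max_step) + 1L)
    grids[[i]] <- seq(schedule$start[i], schedule$end[i], length.out = npt)
  }
  allt <- sort(unique(unlist(grids)))
  ct <- solve_2tc(kp, input_fn, allt)
  if (vB > 0) ct <- (1 - vB) * ct + vB * if_eval(input_fn, allt)
  vapply(seq_len(nfr), function(i) {
    g <- grids[[i]]
    v <- ct[match(g, allt)]
    sum(diff(g) * (v[-length(v)] + v[-1]) / 2) / (g[length(g)] - g[1])
  }, numeric(1))
}

.as_region_tac <- function(tac, region = NULL) {
  if (inherits(tac, "tac_set")) {
    if (is.null(region)) {
      if (ncol(tac$activity) != 1L)
        stop("tac_set has several regions; supply 'region'")
      region <- colnames(tac$activity)[1]
    }
    return(region_tac(tac, region))
  }
  if (!all(c("start", "end", "activity") %in% names(tac)))
    stop("TAC must be a tac_set or a data frame with start, end, activity")
  if (!"mid" %in% names(tac)) tac$mid <- (tac$start + tac$end) / 2
  tac
}

#' Fit the two-tissue-compartment model to a regional TAC
#'
#' Weighted nonlinear least squares of the frame-averaged model against the
#' observed frame activities, over frames whose midpoints fall inside the
#' fit window. The irreversible configuration (default) estimates K1, k2,
#' k3 with k4 fixed at 0 and reports the influx constant Ki = K1*k3/(k2+k3);
#' \code{k4 = "free"} fits the reversible 4-parameter model for model
#' comparison via AIC.
#'
#' The optimiser is bounded Levenberg-Marquardt (all rates in
#' [\code{lower}, \code{upper}]) restarted from \code{n_starts} points on a
#' log-spaced grid; the solution with the lowest weighted residual sum of
#' squares wins, ties broken by the lower k3.
#'
#' @param tac a [tac_set()] plus \code{region}, or a data frame with columns
#'   \code{start}, \code{end}, \code{activity} (from [region_tac()])
#' @param input_fn an [input_function()]
#' @param region region name when \code{tac} is a \code{tac_set}
#' @param window_end end of the fit window, minutes (default 30: late-phase
#'   metabolite data are unreliable, so quantification uses 0-30 min)
#' @param weights \code{"frame_duration"} (w proportional to frame length,
#'   default) or \code{"uniform"}
#' @param k4 \code{"fixed"} (irreversible, k4 = 0) or \code{"free"}
#' @param vB fractional blood volume; 0 (default) omits the blood term,
#'   otherwise the model is (1-vB)*C_T + vB*Cp
#' @param n_starts number of multi-start initial points
#' @param lower,upper box constraints on each rate constant (1/min)
#' @return an object of class \code{tcfit}; see [coef.tcfit()],
#'   [predict.tcfit()], [plot.tcfit()]
#' @export
fit_2tc <- function(tac, input_fn, region = NULL, window_end = 30,
                    weights = c("frame_duration", "uniform"),
                    k4 = c("fixed", "free"), vB = 0,
                    n_starts = 5, lower = 0, upper = 10) {
  tac <- .as_region_tac(tac, region)
  weights <- match.arg(weights)
  k4 <- match.arg(k4)
  use <- tac$mid <= window_end + 1e-9
  if (sum(use) < (if (k4 == "free") 5L else 4L))
    stop("too few frames inside the fit window")
  sch <- tac[use, c("start", "end", "mid")]
  obs <- tac$activity[use]
  w <- if (weights == "frame_duration") (sch$end - sch$start) else rep(1, nrow(sch))
  w <- w / mean(w)
  sw <- sqrt(w)
  npar <- if (k4 == "free") 4L else 3L

  if (max(abs(obs)) == 0) {
    params <- c(K1 = 0, k2 = 0, k3 = 0, k4 = 0)
    return(structure(list(params = params, ki = 0, wrss = 0,
                          se = rep(NA_real_, npar), window_end = window_end,
                          weights_label = weights, n_frames = nrow(sch),
                          fitted = obs * 0, residuals = obs * 0,
                          observed = obs, schedule = sch,
                          input_fn = input_fn, degenerate = TRUE,
                          reversible = (k4 == "free"), vB = vB,
                          aic = NA_real_, converged = TRUE),
                     class = "tcfit"))
  }

  resid_fn <- function(p) {
    kp <- if (npar == 4L) p else c(p, 0)
    sw * (.model_frame_avg(kp, input_fn, sch, vB = vB) - obs)
  }
  grid <- 10^seq(-1.3, 0.6, length.out = n_starts)
  best <- NULL; best_dev <- Inf; best_par <- NULL
  lo <- rep(max(lower, 0), npar); hi <- rep(upper, npar)
  if (npar == 4L) lo[4] <- 0
  for (g in grid) {
    start <- rep(g, npar)
    if (npar == 4L) start[4] <- min(g / 10, 0.05)
    f <- try(minpack.lm::nls.lm(
      par = pmin(pmax(start, lo + 1e-6), hi), fn = resid_fn,
      lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12,
                                           ptol = 1e-12)), silent = TRUE)
    if (inherits(f, "try-error")) next
    better <- f$deviance < best_dev * (1 - 1e-10) ||
      (abs(f$deviance - best_dev) <= best_dev * 1e-10 &&
         !is.null(best_par) && f$par[3] < best_par[3])
    if (is.null(best) || better) {
      best <- f; best_dev <- f$deviance; best_par <- f$par
    }
  }
  if (is.null(best)) stop("2TC fit failed to converge from all starts")
  p <- best$par
  params <- if (npar == 4L) c(K1 = p[1], k2 = p[2], k3 = p[3], k4 = p[4])
            else c(K1 = p[1], k2 = p[2], k3 = p[3], k4 = 0)
  ki <- if (params["k2"] + params["k3"] > 0)
    unname(params["K1"] * params["k3"] / (params["k2"] + params["k3"])) else 0
  fitted <- .model_frame_avg(if (npar == 4L) p else c(p, 0),
                             input_fn, sch, vB = vB)
  se <- tryCatch({
    s <- summary(best)
    as.numeric(s$coefficients[, "Std. Error"])
  }, error = function(e) rep(NA_real_, npar))
  n <- nrow(sch)
  aic <- n * log(best$deviance / n) + 2 * (npar + 1)
  structure(list(params = params, ki = ki, wrss = best$deviance, se = se,
                 window_end = window_end, weights_label = weights,
                 n_frames = n, fitted = fitted, residuals = obs - fitted,
                 observed = obs, schedule = sch, input_fn = input_fn,
                 degenerate = FALSE, reversible = (npar == 4L), vB = vB,
                 aic = aic, converged = best$info %in% 1:4),
            class = "tcfit")
}

#' @export
print.tcfit <- function(x, ...) {
  cat(if (x$reversible) "Reversible" else "Irreversible",
      "2TC fit,", x$n_frames, "frames, window 0 -",
      x$window_end, "min\n")
  p <- x$params
  cat(sprintf("  K1 = %.4f mL/ccm/min, k2 = %.4f, k3 = %.4f, k4 = %.4f /min\n",
              p["K1"], p["k2"], p["k3"], p["k4"]))
  cat(sprintf("  Ki = %.4f mL/ccm/min, WRSS = %.5g\n", x$ki, x$wrss))
  if (x$degenerate) cat("  (degenerate fit: zero TAC)\n")
  invisible(x)
}

#' @export
summary.tcfit <- function(object, ...) {
  print(object)
  nm <- names(object$params)[seq_along(object$se)]
  se <- object$se
  cat("  standard errors:",
      paste(sprintf("%s %.4g", nm, se), collapse = ", "), "\n")
  cat(sprintf("  AIC = %.2f, weights = %s, converged = %s\n",
              object$aic, object$weights_label, object$converged))
  invisible(object)
}

#' Extract rate constants from a 2TC fit
#' @param object a \code{tcfit}
#' @param ... unused
#' @return named vector \code{K1, k2, k3, k4, Ki}
#' @export
coef.tcfit <- function(object, ...) c(object$params, Ki = object$ki)

#' Predict tissue activity from a fitted 2TC model
#' @param object a \code{tcfit}
#' @param newdata a numeric vector of times (instantaneous curve), a
#'   \code{frame_schedule} (frame averages), or NULL for the fitted frames
#' @param ... unused
#' @return predicted tissue activity, kBq/cc
#' @export
predict.tcfit <- function(object, newdata = NULL, ...) {
  kp <- object$params
  if (is.null(newdata)) return(object$fitted)
  if (is.numeric(newdata)) {
    ct <- solve_2tc(kp, object$input_fn, newdata)
    if (object$vB > 0)
      ct <- (1 - object$vB) * ct + object$vB * if_eval(object$input_fn, newdata)
    return(ct)
  }
  .model_frame_avg(kp, object$input_fn, newdata, vB = object$vB)
}

#' @export
residuals.tcfit <- function(object, ...) object$residuals

#' @export
fitted.tcfit <- function(object, ...) object$fitted

#' Plot a 2TC fit: observed frame activities and the model curve
#' @param x a \code{tcfit}
#' @param ... passed to \code{plot}
#' @export
plot.tcfit <- function(x, ...) {
  tt <- seq(0, max(x$schedule$end), length.out = 200)
  graphics::plot(x$schedule$mid, x$observed, xlab = "time (min)",
                 ylab = "activity (kBq/cc)", ...)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Compare irreversible and reversible 2TC fits by AIC
#'
#' @param fit_irreversible,fit_reversible \code{tcfit} objects for the same
#'   TAC
#' @return data frame with WRSS, number of parameters, AIC and delta-AIC;
#'   attribute \code{"preferred"} names the lower-AIC model
#' @export
compare_tcfits <- function(fit_irreversible, fit_reversible) {
  d <- data.frame(
    model = c("irreversible (k4=0)", "reversible (k4 free)"),
    npar = c(3, 4),
    wrss = c(fit_irreversible$wrss, fit_reversible$wrss),
    aic = c(fit_irreversible$aic, fit_reversible$aic)
  )
  d$delta_aic <- d$aic - min(d$aic)
  attr(d, "preferred") <- d$model[which.min(d$aic)]
  d
}

#' Patlak graphical analysis for irreversible tracers
#'
#' Regresses the normalized tissue ratio y(t) = C_T(t)/Cp(t) on the
#' normalized time x(t) = \eqn{\int_0^t Cp ds / Cp(t)}, using frame
#' midpoints inside [t_star, window_end]. Beyond the equilibration time
#' t* the plot is linear and its slope estimates the influx constant Ki.
#'
#' @inheritParams fit_2tc
#' @param t_star equilibration time, minutes (default 10: transients with
#'   k2+k3 of order 1/min have decayed long before)
#' @param window_end last usable frame midpoint, minutes (default 30)
#' @return object of class \code{patlak_fit}: slope (Ki estimate,
#'   mL/ccm/min), intercept (mL/cc), r_squared, points used
#' @export
patlak <- function(tac, input_fn, region = NULL, t_star = 10,
                   window_end = 30) {
  tac <- .as_region_tac(tac, region)
  mid <- tac$mid
  cp <- if_eval(input_fn, mid)
  use <- mid >= t_star - 1e-9 & mid <= window_end + 1e-9 & cp > 0
  if (sum(use) < 2L)
    stop("need at least 2 frames with midpoint in [t_star, window_end] and Cp > 0")
  xs <- if_cumint(input_fn, mid[use]) / cp[use]
  ys <- tac$activity[use] / cp[use]
  fit <- stats::lm(ys ~ xs)
  tss <- sum((ys - mean(ys))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  r2 <- min(max(r2, 0), 1)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, t_star = t_star,
                 n_points = sum(use),
                 points = data.frame(time = mid[use], x = xs, y = ys)),
            class = "patlak_fit")
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf(
    "Patlak analysis (t* = %g min, %d points): slope %.4f mL/ccm/min, intercept %.4f, R^2 %.4f\n",
    x$t_star, x$n_points, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
coef.patlak_fit <- function(object, ...)
  c(slope = object$slope, intercept = object$intercept)

#' @export
plot.patlak_fit <- function(x, ...) {
  graphics::plot(x$points$x, x$points$y,
                 xlab = "normalized time (min)", ylab = "C_T / Cp", ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Tissue-to-plasma activity ratio over time
#'
#' Diagnostic for irreversibility: for an irreversibly trapped tracer the
#' ratio of tissue activity to metabolite-corrected plasma keeps rising
#' through the scan; for a reversible tracer it plateaus.
#'
#' @inheritParams fit_2tc
#' @return data frame \code{time}, \code{ratio}; frames with Cp = 0 are
#'   skipped with a warning
#' @export
tissue_plasma_ratio <- function(tac, input_fn, region = NULL) {
  tac <- .as_region_tac(tac, region)
  cp <- if_eval(input_fn, tac$mid)
  bad <- cp <= 0
  if (any(bad))
    warning(sum(bad), " frame(s) skipped: Cp = 0 at midpoint")
  data.frame(time = tac$mid[!bad], ratio = tac$activity[!bad] / cp[!bad])
}

#' Correlate 2TC Ki with Patlak slope across fits
#'
#' @param fits_2tc list of \code{tcfit} objects, or numeric Ki values
#' @param fits_patlak list of \code{patlak_fit} objects, or numeric slopes
#' @return object of class \code{ki_correlation}: Pearson r and the
#'   least-squares line of Patlak slope against 2TC Ki
#' @export
correlate_ki <- function(fits_2tc, fits_patlak) {
  ki <- if (is.numeric(fits_2tc)) fits_2tc
        else vapply(fits_2tc, function(f) f$ki, numeric(1))
  sl <- if (is.numeric(fits_patlak)) fits_patlak
        else vapply(fits_patlak, function(f) f$slope, numeric(1))
  if (length(ki) != length(sl)) stop("paired lists differ in length")
  if (length(ki) < 3L) stop("need at least 3 pairs")
  line <- stats::lm(sl ~ ki)
  structure(list(r = stats::cor(ki, sl),
                 slope = unname(stats::coef(line)[2]),
                 intercept = unname(stats::coef(line)[1]),
                 n = length(ki), ki_2tc = ki, ki_patlak = sl),
            class = "ki_correlation")
}

#' @export
print.ki_correlation <- function(x, ...) {
  cat(sprintf(
    "Ki correlation over %d fits: r = %.4f; Patlak = %.3f * Ki(2TC) + %.4f\n",
    x$n, x$r, x$slope, x$intercept))
  invisible(x)
}
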