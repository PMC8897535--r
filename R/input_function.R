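#' Metabolite-corrected arterial input function
#'
#' The input function Cp(t) drives every kinetic fit. Its interpolation
#' contract is fixed: piecewise-linear between samples, 0 before the first
#' sample, and mono-exponential extrapolation beyond the last sample (rate
#' taken from the final two samples; held constant if they do not decline).
#'
#' @param time sample times, minutes, strictly increasing
#' @param cp metabolite-corrected plasma activity, kBq/cc, non-negative
#' @return an object of class \code{input_function}
#' @export
input_function <- function(time, cp) {
  time <- as.numeric(time); cp <- as.numeric(cp)
  if (length(time) != length(cp)) stop("time and cp differ in length")
  if (length(time) < 1L) stop("empty input function")
  if (is.unsorted(time, strictly = TRUE))
    stop("input function times must be strictly increasing")
  if (any(!is.finite(cp)) || any(cp < 0))
    stop("Cp must be finite and non-negative")
  n <- length(time)
  tail_rate <- 0
  if (n >= 2L && cp[n] > 0 && cp[n - 1L] > cp[n])
    tail_rate <- log(cp[n - 1L] / cp[n]) / (time[n] - time[n - 1L])
  structure(list(time = time, cp = cp, tail_rate = tail_rate),
            class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat("Input function: ", length(x$time), " samples, ",
      format(min(x$time)), "-", format(max(x$time)), " min, peak ",
      format(max(x$cp), digits = 4), " kBq/cc\n", sep = "")
  invisible(x)
}

#' Evaluate an input function
#'
#' @param x an \code{input_function}
#' @param t times (minutes), any order
#' @return Cp(t) under the interpolation contract
#' @export
if_eval <- function(x, t) {
  n <- length(x$time)
  out <- numeric(length(t))
  inside <- t >= x$time[1] & t <= x$time[n]
  if (any(inside))
    out[inside] <- stats::approx(x$time, x$cp, xout = t[inside],
                                 rule = 1)$y
  beyond <- t > x$time[n]
  if (any(beyond))
    out[beyond] <- x$cp[n] * exp(-x$tail_rate * (t[beyond] - x$time[n]))
  out
}

#' Cumulative integral of an input function from time zero
#'
#' Exact for the piecewise-linear contract (trapezoid on segments, analytic
#' exponential tail beyond the last sample, zero before the first).
#'
#' @param x an \code{input_function}
#' @param t upper limits, minutes, each >= 0
#' @return the integrals \eqn{\int_0^t Cp(s) ds}
#' @export
if_cumint <- function(x, t) {
  tt <- x$time; cp <- x$cp; n <- length(tt)
  # cumulative integral at the sample knots
  knot_int <- c(0, cumsum(diff(tt) * (cp[-n] + cp[-1]) / 2))
  vapply(t, function(ti) {
    if (ti <= tt[1]) return(0)
    if (ti <= tt[n]) {
      j <- findInterval(ti, tt)
      v <- if_eval(x, ti)
      return(knot_int[j] + (ti - tt[j]) * (cp[j] + v) / 2)
    }
    tail <- if (x$tail_rate > 0)
      cp[n] * (1 - exp(-x$tail_rate * (ti - tt[n]))) / x$tail_rate
    else cp[n] * (ti - tt[n])
    knot_int[n] + tail
  }, numeric(1))
}

# -- blood curve merging -----------------------------------------------------

#' Merge continuous and discrete blood data into one plasma curve
#'
#' The continuous whole-blood curve from the automated sampling system covers
#' the first minutes at high time resolution; discrete samples provide plasma
#' activity later. The continuous segment is scaled to plasma units by a
#' single constant plasma-to-whole-blood ratio, by default estimated at the
#' earliest discrete sample that falls inside the continuous time range.
#' The scaled continuous curve is kept over its entire span (it is the
#' higher-resolution measurement); discrete samples inside that span inform
#' the ratio and the junction consistency check, and samples after it extend
#' the curve.
#'
#' @param blood a [blood_data()]
#' @param plasma_to_wb_ratio plasma/whole-blood activity ratio applied to the
#'   continuous segment; \code{NULL} (default) estimates it from the earliest
#'   overlapping discrete sample
#' @param junction_tol relative discontinuity at the junction above which a
#'   warning is emitted (default 0.05)
#' @return data frame \code{time}, \code{value}: total plasma activity curve
#' @export
merge_blood_curves <- function(blood, plasma_to_wb_ratio = NULL,
                               junction_tol = 0.05) {
  cont <- blood$continuous; disc <- blood$discrete
  if (!nrow(cont)) stop("continuous blood series is empty")
  disc <- disc[is.finite(disc$value), , drop = FALSE]   # pf-only samples carry no activity
  if (!nrow(disc)) stop("no discrete plasma samples to merge")
  t_end <- max(cont$time)
  ov <- which(disc$time >= min(cont$time) & disc$time <= t_end)
  if (is.null(plasma_to_wb_ratio)) {
    if (!length(ov)) {
      plasma_to_wb_ratio <- 1
      warning("no discrete sample overlaps the continuous curve; ",
              "plasma-to-whole-blood ratio defaults to 1")
    } else {
      i <- ov[1]
      wb_at <- stats::approx(cont$time, cont$value, xout = disc$time[i])$y
      if (!is.finite(wb_at) || wb_at <= 0)
        stop("cannot estimate plasma-to-whole-blood ratio: ",
             "continuous curve non-positive at the overlap sample")
      plasma_to_wb_ratio <- disc$value[i] / wb_at
    }
  }
  # junction consistency: scaled continuous vs overlapping discrete samples
  if (length(ov)) {
    at_ov <- stats::approx(cont$time, cont$value, xout = disc$time[ov])$y *
      plasma_to_wb_ratio
    ref <- pmax(abs(disc$value[ov]), .Machine$double.eps)
    mis <- max(abs(at_ov - disc$value[ov]) / ref)
    if (mis > junction_tol)
      warning(sprintf(
        "scaled continuous curve and overlapping discrete sample(s) disagree by %.1f%%",
        100 * mis))
  }
  out <- rbind(
    data.frame(time = cont$time, value = cont$value * plasma_to_wb_ratio),
    data.frame(time = disc$time[disc$time > t_end],
               value = disc$value[disc$time > t_end])
  )
  out <- out[order(out$time), ]
  rownames(out) <- NULL
  attr(out, "plasma_to_wb_ratio") <- plasma_to_wb_ratio
  out
}

# -- parent fraction ---------------------------------------------------------

.hill_pf <- function(t, floor, t50, h) {
  pf <- floor + (1 - floor) / (1 + (t / t50)^h)
  pmin(pmax(pf, 0), 1)
}

#' Fit a Hill model to plasma parent-fraction samples
#'
#' Models the fraction of plasma radioactivity attributable to unchanged
#' radioligand as \deqn{pf(t) = floor + (1 - floor) / (1 + (t/t50)^h)}
#' which equals 1 at t = 0 and decreases monotonically towards \code{floor}.
#' Fitted by least squares with box constraints (floor in [0,1], t50 and h
#' positive).
#'
#' @param time sample times, minutes, in [0, 60]
#' @param fraction parent fractions in [0, 1]
#' @param t_max samples beyond this time are ignored (default 30 min;
#'   late-phase parent-fraction measurements are unreliable)
#' @return an object of class \code{pf_fit} with elements \code{params}
#'   (floor, t50, h), \code{residuals}, \code{time_range}
#' @export
fit_parent_fraction <- function(time, fraction, t_max = 30) {
  keep <- !is.na(fraction) & time <= t_max + 1e-9
  time <- time[keep]; fraction <- fraction[keep]
  if (length(time) < 3L) stop("need at least 3 parent-fraction samples")
  if (length(unique(time)) == 1L) stop("all sample times identical")
  if (any(fraction < 0 | fraction > 1)) stop("fractions must lie in [0,1]")
  if (diff(range(fraction)) < 1e-12) {
    # constant data: degenerate but well-defined model
    params <- c(floor = fraction[1], t50 = 1, h = 1)
    fit <- structure(list(params = params, residuals = fraction * 0,
                          time_range = range(time), constant = TRUE),
                     class = "pf_fit")
    return(fit)
  }
  resid_fn <- function(p) .hill_pf(time, p[1], p[2], p[3]) - fraction
  starts <- list(c(0.05, 10, 2), c(0.0, 5, 1), c(0.2, 20, 3))
  best <- NULL
  for (s in starts) {
    f <- try(minpack.lm::nls.lm(
      par = s, fn = resid_fn,
      lower = c(0, 1e-3, 1e-2), upper = c(1, 1e3, 50),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best)) stop("parent-fraction fit failed from all starts")
  params <- c(floor = best$par[1], t50 = best$par[2], h = best$par[3])
  structure(list(params = params, residuals = resid_fn(best$par),
                 time_range = range(time), constant = FALSE,
                 deviance = best$deviance),
            class = "pf_fit")
}

#' @export
print.pf_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Parent-fraction Hill fit: floor %.4f, t50 %.3f min, h %.3f (pf(30) = %.3f)\n",
    p["floor"], p["t50"], p["h"], predict(x, 30)))
  invisible(x)
}

#' @export
predict.pf_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) seq(0, 30, by = 1)
       else if (is.list(newdata)) newdata$time else newdata
  if (any(t < 0)) stop("parent fraction undefined for negative times")
  p <- object$params
  .hill_pf(t, p["floor"], p["t50"], p["h"])
}

#' Apply metabolite correction to a plasma activity curve
#'
#' Multiplies total plasma activity by the modelled parent fraction,
#' pointwise, yielding the metabolite-corrected input function
#' Cp(t) = plasma(t) x pf(t). The product is evaluated on the plasma
#' curve's sample times plus a refinement grid (default step 0.1 min), so
#' the smooth curvature of the parent-fraction model between sparse late
#' plasma samples is carried into the input function rather than being
#' linearised away.
#'
#' @param plasma data frame \code{time}, \code{value} (total plasma
#'   activity), e.g. from [merge_blood_curves()]
#' @param pf_model a \code{pf_fit}, or a single number in [0,1] for a
#'   constant parent fraction
#' @param refine_step spacing of the refinement grid, minutes; NULL
#'   evaluates at the plasma sample times only
#' @return an [input_function()]
#' @export
metabolite_correct <- function(plasma, pf_model, refine_step = 0.1) {
  if (!all(c("time", "value") %in% names(plasma)))
    stop("plasma curve needs columns 'time' and 'value'")
  if (any(plasma$time < -1e-9))
    stop("plasma curve extends before injection; parent-fraction model ",
         "is undefined there")
  tt <- plasma$time
  if (!is.null(refine_step)) {
    tt <- sort(unique(c(tt, seq(min(tt), max(tt), by = refine_step))))
  }
  val <- stats::approx(plasma$time, plasma$value, xout = tt)$y
  pf <- if (is.numeric(pf_model) && length(pf_model) == 1L) {
    if (pf_model < 0 || pf_model > 1) stop("constant parent fraction outside [0,1]")
    rep(pf_model, length(tt))
  } else {
    predict(pf_model, pmax(tt, 0))
  }
  input_function(tt, val * pf)
}

# -- plasma free fraction ----------------------------------------------------

#' Plasma free fraction by ultrafiltration with membrane-binding correction
#'
#' Computes fp = (Cfree/Ctotal) / (control Cfree/Ctotal). The control
#' (protein-free buffer) ratio corrects for binding of the radioligand to
#' the ultrafiltration membrane. Duplicate determinations are averaged
#' before ratios are formed; fp is clipped to [0,1].
#'
#' @param plasma_free,plasma_total ultrafiltrate and total plasma counts
#'   (vectors of duplicate determinations allowed)
#' @param control_free,control_total the same for the buffer control
#' @return an object of class \code{free_fraction}: list with \code{fp},
#'   \code{protein_binding_pct}, the averaged counts and the control ratio
#' @export
plasma_free_fraction <- function(plasma_free, plasma_total,
                                 control_free, control_total) {
  vals <- list(plasma_free = plasma_free, plasma_total = plasma_total,
               control_free = control_free, control_total = control_total)
  for (nm in names(vals))
    if (any(!is.finite(vals[[nm]])) || any(vals[[nm]] <= 0))
      stop(nm, " counts must be positive")
  m <- vapply(vals, mean, numeric(1))
  control_ratio <- m["control_free"] / m["control_total"]
  if (control_ratio <= 0) stop("control ratio must be positive")
  fp <- (m["plasma_free"] / m["plasma_total"]) / control_ratio
  fp <- min(max(fp, 0), 1)
  structure(list(Cfree = unname(m["plasma_free"]),
                 Ctotal = unname(m["plasma_total"]),
                 control_ratio = unname(control_ratio),
                 fp = unname(fp),
                 protein_binding_pct = unname((1 - fp) * 100)),
            class = "free_fraction")
}

#' @export
print.free_fraction <- function(x, ...) {
  cat(sprintf("Plasma free fraction fp = %.4f (protein binding %.1f%%)\n",
              x$fp, x$protein_binding_pct))
  invisible(x)
}
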