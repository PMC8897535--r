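#' Target occupancy from baseline and pretreatment influx constants
#'
#' Occupancy (%) = 100 * (Ki_baseline - Ki_pretreatment) / Ki_baseline.
#' Values are never clipped: measurement noise can push an occupancy
#' slightly above 100% or below 0%, and those values must survive into the
#' dose-response fit.
#'
#' @param ki_baseline,ki_pretreatment influx constants (mL/ccm/min) at the
#'   baseline and drug-pretreatment scans; vectors are paired elementwise
#'   (e.g. one value per region)
#' @return occupancy in percent
#' @examples
#' occupancy_from_ki(0.450, 0.027)  # 94.0
#' @export
occupancy_from_ki <- function(ki_baseline, ki_pretreatment) {
  if (any(!is.finite(ki_baseline)) || any(!is.finite(ki_pretreatment)))
    stop("Ki values must be finite")
  if (any(ki_baseline <= 0))
    stop("occupancy undefined: baseline Ki must be positive")
  100 * (ki_baseline - ki_pretreatment) / ki_baseline
}

#' Average occupancy across regions
#'
#' Unweighted arithmetic mean of the per-region occupancies of one scan
#' pair; the averaged value is what enters the dose-response analysis.
#'
#' @param per_region occupancies in percent, one per region
#' @return mean occupancy in percent
#' @export
average_occupancy <- function(per_region) {
  if (!length(per_region)) stop("no regional occupancies to average")
  mean(per_region)
}

#' Average plasma drug concentration (Cave)
#'
#' Mean of the drug concentrations measured just before tracer injection
#' and at 30 min (defaults -1 and 30 min, matched within a +/-2 min
#' tolerance). If either sample is missing or below the detection limit the
#' result is NA with attribute \code{excluded = TRUE}, so the scan pair can
#' be dropped from the Emax fit rather than entered with a zeroed value.
#'
#' @param series a [conc_series()]
#' @param at the two nominal sampling times, minutes
#' @param tol matching tolerance, minutes
#' @return Cave in ng/mL, or NA flagged \code{excluded}
#' @export
cave <- function(series, at = c(-1, 30), tol = 2) {
  vals <- numeric(length(at))
  for (i in seq_along(at)) {
    j <- which(abs(series$time - at[i]) <= tol)
    if (!length(j)) {
      warning("no sample within ", tol, " min of t = ", at[i],
              "; Cave excluded")
      return(structure(NA_real_, excluded = TRUE))
    }
    j <- j[which.min(abs(series$time[j] - at[i]))]
    if (series$below_lod[j] || is.na(series$conc[j])) {
      warning("sample at t = ", series$time[j],
              " min below detection limit; Cave excluded")
      return(structure(NA_real_, excluded = TRUE))
    }
    vals[i] <- series$conc[j]
  }
  structure(mean(vals), excluded = FALSE)
}

.emax_sse <- function(ec50, conc, occ, emax) {
  sum((occ - emax * conc / (ec50 + conc))^2)
}

#' Fit the Emax concentration-occupancy model
#'
#' Unweighted least squares of \deqn{Occ = E_{max} \cdot C / (EC_{50} + C)}
#' over EC50, with Emax fixed at 100% by default (full occupancy
#' attainable). The 1-D objective is minimised on the log-EC50 scale over
#' [1e-6, 1e6] ng/mL; use [ec50_grid_scan()] for an independent brute-force
#' check of the minimiser. Setting \code{emax = NULL} frees Emax as a
#' second parameter.
#'
#' @param conc plasma drug concentrations C, ng/mL (NA pairs are dropped)
#' @param occupancy occupancies in percent (may exceed 100 or be negative)
#' @param emax fixed maximal occupancy in percent (default 100), or NULL to
#'   estimate it
#' @return object of class \code{emax_fit} with elements \code{ec50},
#'   \code{emax}, \code{emax_fixed}, \code{sse}, \code{data}
#' @export
fit_emax <- function(conc, occupancy, emax = 100) {
  keep <- !is.na(conc) & !is.na(occupancy)
  conc <- as.numeric(conc[keep]); occupancy <- as.numeric(occupancy[keep])
  if (length(conc) < 2L) stop("need at least 2 (concentration, occupancy) pairs")
  if (any(conc <= 0)) stop("concentrations must be positive")
  if (all(occupancy <= 0)) stop("all occupancies non-positive: no dose response to fit")
  if (is.null(emax)) {
    resid_fn <- function(p) occupancy - p[2] * conc / (exp(p[1]) + conc)
    f <- minpack.lm::nls.lm(par = c(log(stats::median(conc)), 100),
                            fn = resid_fn,
                            lower = c(log(1e-6), 1e-3),
                            upper = c(log(1e6), 500),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
    ec50 <- exp(f$par[1]); emax_hat <- f$par[2]
    sse <- f$deviance
    fixed <- FALSE
  } else {
    opt <- stats::optimize(function(l) .emax_sse(exp(l), conc, occupancy, emax),
                           interval = log(c(1e-6, 1e6)), tol = 1e-12)
    ec50 <- exp(opt$minimum); emax_hat <- emax
    sse <- opt$objective
    fixed <- TRUE
  }
  fitted <- emax_hat * conc / (ec50 + conc)
  structure(list(ec50 = ec50, emax = emax_hat, emax_fixed = fixed,
                 sse = sse, fitted = fitted,
                 residuals = occupancy - fitted,
                 data = data.frame(conc = conc, occupancy = occupancy)),
            class = "emax_fit")
}

#' @export
print.emax_fit <- function(x, ...) {
  cat(sprintf("Emax occupancy model: EC50 = %.4g ng/mL, Emax = %.4g%%%s, n = %d\n",
              x$ec50, x$emax, if (x$emax_fixed) " (fixed)" else "",
              nrow(x$data)))
  invisible(x)
}

#' @export
summary.emax_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  SSE = %.4f; residual range [%.2f, %.2f]%%\n",
              object$sse, min(object$residuals), max(object$residuals)))
  invisible(object)
}

#' @export
coef.emax_fit <- function(object, ...)
  c(EC50 = object$ec50, Emax = object$emax)

#' Predicted occupancy at given concentrations
#' @param object an \code{emax_fit}
#' @param newdata concentrations in ng/mL (vector or list/data frame with
#'   element \code{conc}); NULL returns fitted values
#' @param ... unused
#' @return occupancy in percent
#' @export
predict.emax_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  conc <- if (is.list(newdata)) newdata$conc else newdata
  object$emax * conc / (object$ec50 + conc)
}

#' @export
residuals.emax_fit <- function(object, ...) object$residuals

#' @export
plot.emax_fit <- function(x, ...) {
  cc <- exp(seq(log(min(x$data$conc) / 3), log(max(x$data$conc) * 3),
                length.out = 200))
  graphics::plot(x$data$conc, x$data$occupancy, log = "x",
                 xlab = "plasma concentration (ng/mL)",
                 ylab = "occupancy (%)", ...)
  graphics::lines(cc, predict(x, cc))
  invisible(x)
}

#' Brute-force log-grid scan of the Emax SSE surface
#'
#' Evaluates the sum of squared residuals of the fixed-Emax model on a
#' logarithmic EC50 grid. Serves as an independent check that the
#' optimiser's EC50 is the global minimiser.
#'
#' @inheritParams fit_emax
#' @param grid EC50 grid, ng/mL (default 10001 points log-spaced over
#'   [1e-2, 1e3])
#' @return list with \code{ec50} (best grid point), \code{sse} (its SSE),
#'   \code{grid}, \code{sse_grid}
#' @export
ec50_grid_scan <- function(conc, occupancy, emax = 100,
                           grid = 10^seq(-2, 3, length.out = 10001)) {
  keep <- !is.na(conc) & !is.na(occupancy)
  conc <- conc[keep]; occupancy <- occupancy[keep]
  sse <- vapply(grid, .emax_sse, numeric(1), conc = conc,
                occ = occupancy, emax = emax)
  i <- which.min(sse)
  list(ec50 = grid[i], sse = sse[i], grid = grid, sse_grid = sse)
}
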