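#' Percent injected dose in a region of interest
#'
#' %ID = activity concentration (Bq/cc) x ROI volume (cc) / injected dose
#' (Bq) x 100, with all activities decay-corrected to injection time.
#'
#' @param activity_conc activity concentration, Bq/cc
#' @param roi_volume region volume, cc
#' @param injected injected dose, Bq
#' @return percent injected dose
#' @examples
#' percent_injected_dose(1000, 70, 1e6)  # 7 %ID
#' @export
percent_injected_dose <- function(activity_conc, roi_volume, injected) {
  if (any(injected <= 0)) stop("injected dose must be positive")
  if (any(roi_volume <= 0)) stop("ROI volume must be positive")
  activity_conc * roi_volume / injected * 100
}

#' Organ time-activity curve in percent injected dose
#'
#' @param organ organ name
#' @param time minutes post-injection, increasing
#' @param pct_id decay-corrected percent injected dose per time point,
#'   in [0, 100]
#' @return data frame of class \code{organ_tac}
#' @export
organ_tac <- function(organ, time, pct_id) {
  if (length(time) != length(pct_id)) stop("time and pct_id differ in length")
  if (is.unsorted(time, strictly = TRUE)) stop("times must be increasing")
  if (any(pct_id < 0 | pct_id > 100)) stop("%ID must lie in [0, 100]")
  d <- data.frame(organ = organ, time = as.numeric(time),
                  pct_id = as.numeric(pct_id))
  class(d) <- c("organ_tac", "data.frame")
  d
}

#' Residence time of an organ
#'
#' The time-integrated decay-weighted fractional activity
#' \deqn{\tau = \int_0^\infty \frac{\%ID(t)}{100} e^{-\lambda t} dt}
#' with \eqn{\lambda = \ln 2 / T_{1/2}}. Observed %ID values (which are
#' decay-corrected) are treated as piecewise-linear between the measured
#' times; each segment's decay-weighted integral is computed analytically
#' (so a constant curve yields the exact closed form at any sampling), and
#' an analytic tail assumes no further biological clearance after the last
#' sample (physical decay only). Before the first sample the fractional
#' uptake is held at its first observed value. Result in hours (MBq.h per
#' MBq injected).
#'
#' @param organ an [organ_tac()], or a data frame with \code{time} (min)
#'   and \code{pct_id} columns
#' @param half_life physical half-life in minutes (default 20.364, C-11)
#' @return residence time tau in hours
#' @examples
#' # whole body pinned at 100 %ID: decay-only bound, 0.4897 h for C-11
#' wb <- organ_tac("whole body", c(0, 30, 100), c(100, 100, 100))
#' residence_time(wb)
#' @export
residence_time <- function(organ, half_life = 20.364) {
  if (!all(c("time", "pct_id") %in% names(organ)))
    stop("organ TAC needs columns 'time' and 'pct_id'")
  if (half_life <= 0) stop("half-life must be positive")
  t <- organ$time; a <- organ$pct_id / 100
  if (length(t) < 2L) stop("need at least 2 time points")
  if (any(a < 0)) stop("%ID must be non-negative")
  lambda <- log(2) / half_life              # per minute
  n <- length(t)
  dt <- diff(t)
  a0 <- a[-n]; slope <- diff(a) / dt
  em <- exp(-lambda * dt)
  one_m <- -expm1(-lambda * dt)
  # int_{t0}^{t1} (a0 + b(u - t0)) e^{-lambda u} du, exact per segment
  seg <- exp(-lambda * t[-n]) *
    (a0 * one_m / lambda + slope * (one_m / lambda - dt * em) / lambda)
  # leading segment [0, t1]: fractional uptake held at the first observation
  lead <- if (t[1] > 0) a[1] * (1 - exp(-lambda * t[1])) / lambda else 0
  tail <- a[n] * exp(-lambda * t[n]) / lambda
  (lead + sum(seg) + tail) / 60
}

#' Residence times for a set of organ TACs
#'
#' Applies [residence_time()] per organ and, when a whole-body curve is
#' present, assigns the unaccounted remainder
#' tau_remainder = max(0, tau_wholebody - sum of organ taus).
#'
#' @param organs list of [organ_tac()] objects, or a long data frame with
#'   columns \code{organ}, \code{time}, \code{pct_id}
#' @param half_life physical half-life, minutes
#' @param wholebody name of the whole-body curve used for the remainder
#'   rule (set NULL to skip)
#' @return named numeric vector of residence times, hours
#' @export
residence_times <- function(organs, half_life = 20.364,
                            wholebody = "whole body") {
  if (is.data.frame(organs))
    organs <- split(organs, organs$organ)
  taus <- vapply(organs, residence_time, numeric(1), half_life = half_life)
  names(taus) <- vapply(organs, function(o) as.character(o$organ[1]),
                        character(1))
  if (!is.null(wholebody) && wholebody %in% names(taus)) {
    others <- taus[names(taus) != wholebody]
    rem <- max(0, taus[[wholebody]] - sum(others))
    taus <- c(others, remainder = rem)
  }
  taus
}

#' Read an S-value table
#'
#' CSV with organ names in the first row and first column; cell (T, S) is
#' the absorbed dose in target T per unit time-integrated activity in
#' source S, in uSv/(MBq.h).
#'
#' @param path file path
#' @return numeric matrix, rows = targets, columns = sources
#' @export
read_s_table <- function(path) {
  d <- .read_delim(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0))
    stop("S-values must be finite and non-negative")
  m
}

#' Read a tissue-weighting-factor table
#'
#' CSV with columns \code{organ,weight}; the weights must sum to 1.
#'
#' @param path file path
#' @return named numeric vector of weights
#' @export
read_weights_table <- function(path) {
  d <- .read_delim(path)
  for (col in c("organ", "weight"))
    if (!col %in% names(d)) stop("weights table missing column '", col, "'")
  stats::setNames(as.numeric(d$weight), d$organ)
}

#' Organ absorbed doses from residence times and an S-value table
#'
#' MIRD formalism: \eqn{D_T = \sum_S \tau_S \cdot S(T \leftarrow S)}.
#'
#' @param taus named residence times, hours (MBq.h/MBq)
#' @param s_table matrix from [read_s_table()] (rows targets, columns
#'   sources)
#' @return named vector of absorbed doses, uSv/MBq
#' @export
absorbed_dose <- function(taus, s_table) {
  missing_src <- setdiff(names(taus), colnames(s_table))
  if (length(missing_src))
    stop("source organ(s) absent from S-value table: ",
         paste(missing_src, collapse = ", "))
  drop(s_table[, names(taus), drop = FALSE] %*% taus)[rownames(s_table)]
}

#' Effective dose from organ doses and tissue weighting factors
#'
#' ED = sum of w_T * D_T over the weighted target organs; the weights must
#' sum to 1 (within 1e-6) and every weighted organ must have a dose.
#'
#' @param doses named absorbed doses, uSv/MBq
#' @param weights named tissue weighting factors summing to 1
#' @return effective dose, uSv/MBq
#' @export
effective_dose <- function(doses, weights) {
  if (abs(sum(weights) - 1) > 1e-6)
    stop("tissue weighting factors must sum to 1 (got ",
         format(sum(weights)), ")")
  missing_t <- setdiff(names(weights), names(doses))
  if (length(missing_t))
    stop("no dose available for weighted organ(s): ",
         paste(missing_t, collapse = ", "))
  sum(weights * doses[names(weights)])
}

#' Full dosimetry chain from organ %ID curves
#'
#' Convenience wrapper: residence times (with remainder rule), absorbed
#' doses, effective dose.
#'
#' @inheritParams residence_times
#' @param s_table S-value matrix
#' @param weights tissue weighting factors
#' @return object of class \code{dose_result}: list with \code{taus},
#'   \code{doses}, \code{effective_dose}
#' @export
dose_chain <- function(organs, s_table, weights, half_life = 20.364,
                       wholebody = "whole body") {
  taus <- residence_times(organs, half_life = half_life,
                          wholebody = wholebody)
  taus <- taus[names(taus) %in% colnames(s_table) | names(taus) != "remainder"]
  doses <- absorbed_dose(taus, s_table)
  structure(list(taus = taus, doses = doses,
                 effective_dose = effective_dose(doses, weights)),
            class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat("Organ absorbed doses (uSv/MBq):\n")
  print(round(x$doses, 3))
  cat(sprintf("Effective dose: %.3f uSv/MBq\n", x$effective_dose))
  invisible(x)
}
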