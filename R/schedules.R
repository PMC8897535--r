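#' Construct a PET frame schedule
#'
#' A frame schedule is the sequence of reconstruction frames of a dynamic PET
#' acquisition, stored as a data frame with columns \code{start}, \code{end}
#' and \code{mid} (all minutes post-injection). Frames must be sorted and
#' non-overlapping; the built-in presets are contiguous.
#'
#' Two presets reproduce common dynamic brain protocols on an HRRT:
#' \describe{
#'   \item{\code{"brain63"}}{33 frames: 10 s x 9, 15 s x 2, 20 s x 3,
#'     30 s x 4, 1 min x 4, 3 min x 4, 6 min x 7; total 63 min.}
#'   \item{\code{"brain123"}}{34 frames: 20 s x 9, 1 min x 3, 3 min x 5,
#'     6 min x 17; total 123 min.}
#' }
#'
#' @param x either a preset name (\code{"brain63"}, \code{"brain123"}) or a
#'   numeric vector of frame durations in minutes
#' @param name optional label stored as attribute \code{"name"}
#' @return a \code{frame_schedule}: data frame with columns
#'   \code{start}, \code{end}, \code{mid} (minutes)
#' @examples
#' sch <- frame_schedule("brain63")
#' sum(sch$end - sch$start)  # 63
#' @export
frame_schedule <- function(x, name = NULL) {
  if (is.character(x) && length(x) == 1L) {
    durs_sec <- switch(x,
      brain63  = c(rep(10, 9), rep(15, 2), rep(20, 3), rep(30, 4),
                   rep(60, 4), rep(180, 4), rep(360, 7)),
      brain123 = c(rep(20, 9), rep(60, 3), rep(180, 5), rep(360, 17)),
      stop("unknown frame schedule preset: ", x)
    )
    durs <- durs_sec / 60
    if (is.null(name)) name <- x
  } else {
    durs <- as.numeric(x)
    if (any(!is.finite(durs)) || any(durs <= 0))
      stop("frame durations must be finite and positive")
  }
  end <- cumsum(durs)
  start <- c(0, end[-length(end)])
  sch <- data.frame(start = start, end = end, mid = (start + end) / 2)
  class(sch) <- c("frame_schedule", "data.frame")
  attr(sch, "name") <- name
  validate_schedule(sch)
}

#' Build a frame schedule from explicit start/end times
#'
#' @param start,end frame boundaries in minutes post-injection
#' @param name optional label
#' @return a validated \code{frame_schedule}
#' @export
frame_schedule_from_times <- function(start, end, name = NULL) {
  if (length(start) != length(end)) stop("start and end differ in length")
  sch <- data.frame(start = as.numeric(start), end = as.numeric(end),
                    mid = (as.numeric(start) + as.numeric(end)) / 2)
  class(sch) <- c("frame_schedule", "data.frame")
  attr(sch, "name") <- name
  validate_schedule(sch)
}

#' Validate a frame schedule
#'
#' Checks that frames are finite, each \code{end > start >= 0}, sorted by
#' start, and mutually non-overlapping. Returns the schedule unchanged when
#' valid; signals an error naming the first offending frame otherwise.
#'
#' @param schedule a \code{frame_schedule} or a data frame with columns
#'   \code{start} and \code{end}
#' @return the validated schedule (invisibly identical input)
#' @export
validate_schedule <- function(schedule) {
  if (!all(c("start", "end") %in% names(schedule)))
    stop("schedule needs columns 'start' and 'end'")
  s <- schedule$start; e <- schedule$end
  if (length(s) == 0L) stop("schedule has no frames")
  if (any(!is.finite(s)) || any(!is.finite(e)))
    stop("non-finite frame boundary at frame ",
         which(!is.finite(s) | !is.finite(e))[1])
  bad <- which(e <= s | s < 0)
  if (length(bad))
    stop("invalid frame (need end > start >= 0) at frame ", bad[1])
  if (is.unsorted(s, strictly = TRUE))
    stop("frames not sorted by start time at frame ",
         which(diff(s) <= 0)[1] + 1L)
  ov <- which(s[-1] < e[-length(e)] - 1e-9)
  if (length(ov))
    stop("overlapping frames at frame ", ov[1] + 1L)
  schedule
}

frame_durations <- function(schedule) schedule$end - schedule$start
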