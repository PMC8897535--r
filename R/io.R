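#' Regional time-activity curves for one dynamic scan
#'
#' Container pairing a frame schedule with one activity column per brain
#' region, in kBq/cc decay-corrected to injection time.
#'
#' @param schedule a \code{frame_schedule}
#' @param activity numeric matrix, frames x regions, with region names as
#'   column names (kBq/cc)
#' @param scan_id scan identifier
#' @param condition \code{"baseline"} or \code{"pretreatment"}
#' @param injected_mbq injected radioactivity in MBq (must be > 0 if given)
#' @return an object of class \code{tac_set}
#' @export
tac_set <- function(schedule, activity, scan_id = "scan",
                    condition = c("baseline", "pretreatment"),
                    injected_mbq = NA_real_) {
  schedule <- validate_schedule(schedule)
  condition <- match.arg(condition)
  activity <- as.matrix(activity)
  if (nrow(activity) != nrow(schedule))
    stop("activity has ", nrow(activity), " rows but schedule has ",
         nrow(schedule), " frames")
  if (is.null(colnames(activity)) || anyDuplicated(colnames(activity)))
    stop("activity columns must carry unique region names")
  if (any(!is.finite(activity)))
    stop("non-finite activity values")
  if (!is.na(injected_mbq) && injected_mbq <= 0)
    stop("injected activity must be positive")
  structure(list(schedule = schedule, activity = activity,
                 scan_id = scan_id, condition = condition,
                 injected_mbq = injected_mbq),
            class = "tac_set")
}

#' @export
print.tac_set <- function(x, ...) {
  cat("Dynamic PET TAC set '", x$scan_id, "' (", x$condition, ")\n", sep = "")
  cat("  frames:", nrow(x$schedule), " spanning",
      format(max(x$schedule$end)), "min\n")
  cat("  regions:", paste(colnames(x$activity), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one region's TAC as a data frame
#'
#' @param x a \code{tac_set}
#' @param region region name
#' @return data frame with columns start, end, mid, activity
#' @export
region_tac <- function(x, region) {
  if (!region %in% colnames(x$activity))
    stop("no region '", region, "' in TAC set")
  cbind(as.data.frame(x$schedule[c("start", "end", "mid")]),
        activity = x$activity[, region])
}

# -- TAC tables -------------------------------------------------------------

.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Read a regional TAC table
#'
#' Expects a comma- or tab-separated file with header columns
#' \code{frame_start}, \code{frame_end} (minutes) and one column per region
#' (kBq/cc, decay-corrected to injection).
#'
#' @param path file path
#' @param scan_id,condition,injected_mbq scan metadata (see [tac_set()])
#' @return a \code{tac_set}
#' @export
read_tac_table <- function(path, scan_id = basename(path),
                           condition = "baseline",
                           injected_mbq = NA_real_) {
  d <- .read_delim(path)
  for (col in c("frame_start", "frame_end"))
    if (!col %in% names(d)) stop("TAC table missing column '", col, "'")
  regions <- setdiff(names(d), c("frame_start", "frame_end"))
  if (!length(regions)) stop("TAC table has no region columns")
  sch <- frame_schedule_from_times(d$frame_start, d$frame_end)
  act <- as.matrix(d[regions])
  tac_set(sch, act, scan_id = scan_id, condition = condition,
          injected_mbq = injected_mbq)
}

#' Write a regional TAC table
#'
#' Inverse of [read_tac_table()]; values are written with 15 significant
#' digits so a write/read round trip is value-identical well beyond 12
#' significant digits.
#'
#' @param x a \code{tac_set}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_tac_table <- function(x, path) {
  d <- data.frame(frame_start = x$schedule$start,
                  frame_end = x$schedule$end, check.names = FALSE)
  d <- cbind(d, as.data.frame(x$activity))
  .write_delim(d, path)
}

.write_delim <- function(d, path) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], function(v) {
    out <- formatC(v, digits = 15, format = "g")
    out[is.na(v)] <- ""
    out
  })
  utils::write.table(d, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- blood tables -----------------------------------------------------------

#' Arterial blood data container
#'
#' Holds the continuous early whole-blood curve from an automated blood
#' sampling system and the discrete plasma samples with parent fractions.
#'
#' @param continuous data frame \code{time} (min), \code{value} (kBq/cc
#'   whole blood)
#' @param discrete data frame \code{time} (min), \code{value} (kBq/cc
#'   plasma; NA for samples drawn only for radiometabolite analysis),
#'   \code{parent_fraction} in [0,1] or NA when not measured
#' @return an object of class \code{blood_data}
#' @export
blood_data <- function(continuous, discrete) {
  continuous <- as.data.frame(continuous)
  discrete <- as.data.frame(discrete)
  for (nm in c("time", "value")) {
    if (!nm %in% names(continuous)) stop("continuous series missing '", nm, "'")
    if (!nm %in% names(discrete)) stop("discrete series missing '", nm, "'")
  }
  if (!"parent_fraction" %in% names(discrete))
    discrete$parent_fraction <- NA_real_
  if (nrow(continuous) && is.unsorted(continuous$time, strictly = TRUE))
    stop("continuous times must be strictly increasing")
  if (nrow(discrete) && is.unsorted(discrete$time, strictly = TRUE))
    stop("discrete times must be strictly increasing")
  pf <- discrete$parent_fraction
  if (any(!is.na(pf) & (pf < 0 | pf > 1)))
    stop("parent fraction outside [0,1]")
  structure(list(continuous = continuous, discrete = discrete),
            class = "blood_data")
}

#' Read a blood table
#'
#' Single-file layout with columns \code{time,value,kind,parent_fraction}
#' where \code{kind} is \code{continuous_wb} or \code{discrete_plasma}.
#' Missing parent fractions stay missing (never coerced to 0).
#'
#' @param path file path
#' @return a \code{blood_data}
#' @export
read_blood_table <- function(path) {
  d <- .read_delim(path)
  for (col in c("time", "value", "kind"))
    if (!col %in% names(d)) stop("blood table missing column '", col, "'")
  if (!"parent_fraction" %in% names(d)) d$parent_fraction <- NA_real_
  bad <- setdiff(unique(d$kind), c("continuous_wb", "discrete_plasma"))
  if (length(bad)) stop("unknown blood series kind: ", bad[1])
  blood_data(
    continuous = d[d$kind == "continuous_wb", c("time", "value")],
    discrete = d[d$kind == "discrete_plasma",
                 c("time", "value", "parent_fraction")]
  )
}

#' Write a blood table
#' @param x a \code{blood_data}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_blood_table <- function(x, path) {
  d <- rbind(
    data.frame(time = x$continuous$time, value = x$continuous$value,
               kind = "continuous_wb", parent_fraction = NA_real_),
    data.frame(time = x$discrete$time, value = x$discrete$value,
               kind = "discrete_plasma",
               parent_fraction = x$discrete$parent_fraction)
  )
  .write_delim(d, path)
}

# -- drug concentration series ----------------------------------------------

#' Plasma drug-concentration series
#'
#' @param time minutes relative to radioligand injection (may be negative)
#' @param conc ng/mL; NA allowed only where \code{below_lod} is TRUE
#' @param below_lod logical flag per sample (below limit of detection)
#' @return an object of class \code{conc_series} (data frame)
#' @export
conc_series <- function(time, conc, below_lod = rep(FALSE, length(time))) {
  if (length(conc) != length(time) || length(below_lod) != length(time))
    stop("time, conc and below_lod differ in length")
  if (any(!below_lod & (is.na(conc) | conc < 0)))
    stop("concentrations must be >= 0 unless flagged below the detection limit")
  d <- data.frame(time = as.numeric(time), conc = as.numeric(conc),
                  below_lod = as.logical(below_lod))
  d <- d[order(d$time), ]
  rownames(d) <- NULL
  class(d) <- c("conc_series", "data.frame")
  d
}

#' Read / write a drug concentration table
#'
#' Columns \code{time_min,conc_ng_per_ml,below_lod}; an empty concentration
#' with \code{below_lod=TRUE} marks a sample below the detection limit.
#'
#' @param path file path
#' @return a \code{conc_series}
#' @export
read_conc_table <- function(path) {
  d <- .read_delim(path)
  for (col in c("time_min", "conc_ng_per_ml"))
    if (!col %in% names(d)) stop("concentration table missing column '", col, "'")
  lod <- if ("below_lod" %in% names(d))
    as.logical(d$below_lod) else rep(FALSE, nrow(d))
  lod[is.na(lod)] <- FALSE
  conc_series(d$time_min, d$conc_ng_per_ml, lod)
}

#' @rdname read_conc_table
#' @param x a \code{conc_series}
#' @export
write_conc_table <- function(x, path) {
  .write_delim(data.frame(time_min = x$time, conc_ng_per_ml = x$conc,
                          below_lod = x$below_lod), path)
}

# -- occupancy/concentration study table ------------------------------------

#' Read a study occupancy-concentration table
#'
#' Layout \code{animal,dose_mg_per_kg,cave_ng_per_ml,occupancy_pct,method}:
#' one row per scan pair and occupancy method, with the average plasma
#' concentration (Cave) left empty for samples below the detection limit.
#'
#' @param path file path
#' @return data frame with those columns
#' @export
read_occ_conc_table <- function(path) {
  d <- .read_delim(path)
  need <- c("animal", "cave_ng_per_ml", "occupancy_pct", "method")
  for (col in need)
    if (!col %in% names(d)) stop("occupancy table missing column '", col, "'")
  d
}

#' Path to a packaged example data file
#' @param file file name under the package's \code{extdata} directory;
#'   omit to list available files
#' @return full path (or vector of file names)
#' @export
petocc_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "petocc")))
  p <- system.file("extdata", file, package = "petocc")
  if (p == "") stop("no packaged file '", file, "'")
  p
}
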