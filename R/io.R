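#' Construct a subject record
#'
#' Bundles one subject-night: the 30-s epoch grid (activity count,
#' SpO2 coverage, reference PSG stage or `NA`), the RR series, the
#' lights-off time, and provenance metadata. All channels share the
#' same epoch grid with epoch 0 starting at t = 0.
#'
#' @param subject Subject id string.
#' @param epochs Data frame with columns `epoch`, `t_start_s`,
#'   `activity_count`, `spo2_coverage_s`, `psg_stage`.
#' @param rr An [rr_series()].
#' @param lights_off_s Lights-off time in seconds from record start.
#' @param seed Optional generating seed (provenance).
#' @return List of class `subject_record`.
#' @export
subject_record <- function(subject, epochs, rr, lights_off_s = 0, seed = NA_integer_) {
  need <- c("epoch", "t_start_s", "activity_count", "spo2_coverage_s", "psg_stage")
  miss <- setdiff(need, names(epochs))
  if (length(miss)) stop("epochs is missing column(s): ", paste(miss, collapse = ", "))
  if (any(epochs$activity_count < 0, na.rm = TRUE)) {
    stop("activity counts must be non-negative (row ",
         which(epochs$activity_count < 0)[1], ")")
  }
  if (epochs$t_start_s[1] != 0) stop("epoch 0 must start at t = 0")
  stopifnot(inherits(rr, "rr_series"))
  if (rr$beat_time_s[1] > max(epochs$t_start_s) + EPOCH_SEC ||
      max(rr$beat_time_s) < 0) {
    stop("epochs and RR series have disjoint time bases")
  }
  structure(list(subject = as.character(subject), epochs = epochs, rr = rr,
                 lights_off_s = lights_off_s, seed = seed),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record %s> %d epochs, %d beats, lights off at %.0f s\n",
              x$subject, nrow(x$epochs), length(x$rr$rr_ms), x$lights_off_s))
  invisible(x)
}

#' Write / read a subject record as a CSV pair
#'
#' `write_subject_record()` writes `<stem>_epochs.csv` (columns
#' subject, epoch, t_start_s, activity_count, spo2_coverage_s,
#' psg_stage, lights_off_s, seed) and `<stem>_rr.csv` (subject,
#' beat_time_s, rr_ms). `read_subject_record()` reads the pair back;
#' the round trip is identity. Malformed rows (negative counts,
#' non-monotone beat times) raise errors naming the offending row.
#'
#' @param rec A [subject_record()].
#' @param stem Path stem (without the `_epochs.csv` / `_rr.csv` suffix).
#' @return `write_subject_record()` returns the two paths invisibly;
#'   `read_subject_record()` returns a [subject_record()].
#' @export
write_subject_record <- function(rec, stem) {
  stopifnot(inherits(rec, "subject_record"))
  ep <- cbind(subject = rec$subject, rec$epochs,
              lights_off_s = rec$lights_off_s, seed = rec$seed)
  rrd <- data.frame(subject = rec$subject,
                    beat_time_s = rec$rr$beat_time_s, rr_ms = rec$rr$rr_ms)
  p1 <- paste0(stem, "_epochs.csv"); p2 <- paste0(stem, "_rr.csv")
  utils::write.csv(ep, p1, row.names = FALSE)
  utils::write.csv(rrd, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_subject_record
#' @export
read_subject_record <- function(stem) {
  p1 <- paste0(stem, "_epochs.csv"); p2 <- paste0(stem, "_rr.csv")
  ep <- utils::read.csv(p1, stringsAsFactors = FALSE)
  rrd <- utils::read.csv(p2, stringsAsFactors = FALSE)
  need <- c("subject", "epoch", "t_start_s", "activity_count",
            "spo2_coverage_s", "psg_stage")
  miss <- setdiff(need, names(ep))
  if (length(miss)) {
    stop(p1, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(c("beat_time_s", "rr_ms") %in% names(rrd))) {
    stop(p2, " is missing required column(s)")
  }
  bad <- which(ep$activity_count < 0)
  if (length(bad)) stop(p1, ": negative activity count at row ", bad[1])
  nonmono <- which(diff(rrd$beat_time_s) <= 0)
  if (length(nonmono)) stop(p2, ": beat times not strictly increasing at row ",
                            nonmono[1] + 1L)
  subject_record(
    subject = ep$subject[1],
    epochs = ep[, c("epoch", "t_start_s", "activity_count",
                    "spo2_coverage_s", "psg_stage")],
    rr = rr_series(rrd$beat_time_s, rrd$rr_ms),
    lights_off_s = if ("lights_off_s" %in% names(ep)) ep$lights_off_s[1] else 0,
    seed = if ("seed" %in% names(ep)) ep$seed[1] else NA_integer_
  )
}

#' Write a cohort to a directory
#'
#' One CSV pair per subject under `dir`, stems equal to subject ids.
#'
#' @param records List of [subject_record()]s.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of stems.
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stems <- vapply(records, function(r) file.path(dir, r$subject), character(1))
  for (i in seq_along(records)) write_subject_record(records[[i]], stems[i])
  invisible(stems)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  files <- list.files(dir, pattern = "_epochs\\.csv$", full.names = TRUE)
  stems <- sub("_epochs\\.csv$", "", files)
  lapply(sort(stems), read_subject_record)
}
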