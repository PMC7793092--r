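#' Detect record bounds from SpO2 coverage
#'
#' When a recording's true start and end are unspecified, the SpO2
#' channel serves as a surrogate: the record is bounded by the first
#' and last 5-min blocks that contain at least 30 s of SpO2 samples.
#' Blocks are consecutive, non-overlapping 10-epoch spans counted from
#' the start of the recording.
#'
#' @param spo2_coverage Per-epoch SpO2 coverage in seconds (0–30).
#' @return List of class `record_bounds` with `start_s`, `end_s`
#'   (epoch-aligned, half-open `[start, end)`), and the corresponding
#'   0-based epoch indices `start_epoch`, `end_epoch`.
#' @export
detect_record_bounds <- function(spo2_coverage) {
  if (any(spo2_coverage < 0 | spo2_coverage > EPOCH_SEC)) {
    stop("spo2 coverage must be within [0, 30] seconds per epoch")
  }
  n <- length(spo2_coverage)
  n_blocks <- floor(n / 10)
  if (n_blocks < 1) stop("record shorter than one 5-min block")
  block_cov <- vapply(seq_len(n_blocks), function(b) {
    sum(spo2_coverage[((b - 1) * 10 + 1):(b * 10)])
  }, numeric(1))
  ok <- which(block_cov >= 30)
  if (!length(ok)) stop("no 5-min block contains >= 30 s of SpO2 coverage")
  start_epoch <- (min(ok) - 1L) * 10L
  end_epoch <- max(ok) * 10L            # exclusive
  structure(list(start_s = start_epoch * EPOCH_SEC,
                 end_s = end_epoch * EPOCH_SEC,
                 start_epoch = start_epoch, end_epoch = end_epoch),
            class = "record_bounds")
}

#' Derive sleep parameters from a hypnogram
#'
#' Computes the standard per-record sleep parameters within the
#' detected record bounds:
#' * SPT (sleep period time) — total recording time, `end - start`, min;
#' * TST — total time scored as sleep, min;
#' * SE — sleep efficiency, `(TST / SPT) * 100`, %;
#' * SOL — time from lights off to sleep onset, min, where onset is the
#'   start of the first sliding 10-min (20-epoch) span with at least
#'   50% of epochs scored as sleep;
#' * WASO — cumulative wake after sleep onset, min;
#' * REM / NREM — minutes in each stage (`REM + NREM = TST`).
#'
#' If no qualifying onset span exists, SOL and WASO are `NA` and the
#' result carries `no_onset = TRUE`.
#'
#' @param hyp A [hypnogram()] or stage label vector covering the record
#'   from epoch 0 (binary `sleep`/`wake` labels are accepted; REM and
#'   NREM minutes are then `NA`). Only epochs within `bounds`
#'   contribute.
#' @param lights_off Lights-off time in seconds from record start;
#'   defaults to the bounds start.
#' @param bounds A [detect_record_bounds()] result, or `NULL` to use
#'   the full hypnogram.
#' @param onset_rule `"sliding"` (default; earliest qualifying 20-epoch
#'   span at any epoch offset) or `"fixed"` (spans tiled from lights
#'   off).
#' @return One-row data frame: SPT, TST, SE, SOL, WASO, REM, NREM
#'   (minutes except SE in %), plus `no_onset`.
#' @export
derive_parameters <- function(hyp, lights_off = NULL, bounds = NULL,
                              onset_rule = c("sliding", "fixed")) {
  onset_rule <- match.arg(onset_rule)
  raw <- unclass(hyp)
  binary <- all(raw %in% c("sleep", "wake") | is.na(raw))
  labels <- if (binary) raw else collapse_stages(raw, "three")
  n <- length(labels)
  if (is.null(bounds)) {
    bounds <- structure(list(start_s = 0, end_s = n * EPOCH_SEC,
                             start_epoch = 0L, end_epoch = n),
                        class = "record_bounds")
  }
  if (bounds$end_epoch > n) stop("hypnogram does not cover the record bounds")
  if (is.null(lights_off)) lights_off <- bounds$start_s
  if (lights_off < bounds$start_s || lights_off >= bounds$end_s) {
    stop("lights_off must lie within the record bounds")
  }
  idx <- (bounds$start_epoch + 1L):bounds$end_epoch   # 1-based epochs in bounds
  lab <- labels[idx]
  sleep <- lab %in% c("NREM", "REM", "sleep")
  spt <- (bounds$end_s - bounds$start_s) / 60
  tst <- 0.5 * sum(sleep)
  se <- 100 * tst / spt
  # binary scorers carry no stage information
  rem <- if (binary) NA_real_ else 0.5 * sum(lab == "REM")
  nrem <- if (binary) NA_real_ else 0.5 * sum(lab == "NREM")

  lights_epoch <- floor(lights_off / EPOCH_SEC) - bounds$start_epoch + 1L
  onset_local <- find_sleep_onset(sleep, lights_epoch, onset_rule)
  if (is.na(onset_local)) {
    sol <- NA_real_
    waso <- NA_real_
    no_onset <- TRUE
  } else {
    onset_s <- (bounds$start_epoch + onset_local - 1L) * EPOCH_SEC
    sol <- (onset_s - lights_off) / 60
    # WASO counts wake from the first sleep epoch at/after onset, so
    # residual wake inside the qualifying span is latency, not WASO.
    first_sleep <- onset_local + which(sleep[onset_local:length(sleep)])[1] - 1L
    waso <- 0.5 * sum(!sleep[first_sleep:length(sleep)])
    no_onset <- FALSE
  }
  data.frame(SPT = spt, TST = tst, SE = se, SOL = sol, WASO = waso,
             REM = rem, NREM = nrem, no_onset = no_onset)
}

# First epoch (1-based, within bounds) of the earliest 10-min span with
# >= 10 of its 20 epochs scored as sleep, searching from `from`.
find_sleep_onset <- function(sleep, from, onset_rule = "sliding") {
  n <- length(sleep)
  span <- 20L
  if (n - from + 1L < span) return(NA_integer_)
  starts <- if (onset_rule == "sliding") from:(n - span + 1L)
            else seq(from, n - span + 1L, by = span)
  cs <- cumsum(c(0L, sleep))
  for (s in starts) {
    if (cs[s + span] - cs[s] >= 10L) return(s)
  }
  NA_integer_
}

#' Sleep parameters for every subject under one or more scorers
#'
#' @param records List of [subject_record()]s.
#' @param hypnograms Named list (scorer -> named list by subject of
#'   stage-label vectors).
#' @param use_bounds Detect bounds from each record's SpO2 channel
#'   (default `TRUE`).
#' @return Data frame with columns subject, scorer, SPT, TST, SE, SOL,
#'   WASO, REM, NREM.
#' @export
cohort_sleep_parameters <- function(records, hypnograms, use_bounds = TRUE) {
  rows <- list()
  for (rec in records) {
    bounds <- if (use_bounds) detect_record_bounds(rec$epochs$spo2_coverage_s)
              else NULL
    lo <- rec$lights_off_s
    if (!is.null(bounds) && (lo < bounds$start_s || lo >= bounds$end_s)) {
      lo <- bounds$start_s
    }
    for (scorer in names(hypnograms)) {
      h <- hypnograms[[scorer]][[rec$subject]]
      if (is.null(h)) next
      p <- derive_parameters(h, lights_off = lo, bounds = bounds)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject = rec$subject, scorer = scorer),
        p[, c("SPT", "TST", "SE", "SOL", "WASO", "REM", "NREM")])
    }
  }
  do.call(rbind, rows)
}
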