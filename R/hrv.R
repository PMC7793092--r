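#' Names of the 17 HRV metrics
#'
#' Nine time-domain and eight frequency-domain metric names, in the
#' canonical column order used throughout the package.
#'
#' @return Character vector of length 17.
#' @export
hrv_metric_names <- function() {
  c("MeanRR", "SDRR", "MeanHR", "MinHR", "MaxHR", "RMSSD", "PNN50",
    "HRVti", "TINN",
    "VLFPeak", "LFPeak", "HFPeak", "VLFPower", "LFPower", "HFPower",
    "LF_HF", "StressIndex")
}

#' All 17 HRV metrics for one RR window
#'
#' @inheritParams hrv_time_domain
#' @param ... Passed to [hrv_freq_domain()].
#' @return Named numeric vector of length 17.
#' @export
hrv_window_features <- function(w, mean_hr_mode = "per_beat", ...) {
  c(hrv_time_domain(w, mean_hr_mode = mean_hr_mode),
    hrv_freq_domain(w, ...),
    StressIndex = stress_index(w))[hrv_metric_names()]
}

#' Per-epoch HRV feature time series
#'
#' Evaluates the 17 HRV metrics once per 30-s epoch over a window of
#' the chosen length. With trailing alignment (the default) the window
#' for epoch `n` (0-based) ends at the epoch's end, `(n + 1) * 30` s;
#' with centered alignment it is centered on the epoch's midpoint.
#' Windows clipped at the record start are computed on the available
#' data and flagged in the `truncated` column, not dropped.
#'
#' @param rr An [rr_series()] on the record time base (t = 0 at epoch 0).
#' @param n_epochs Number of 30-s epochs to score.
#' @param window_len Window length in seconds: 30, 180 or 300.
#' @param align `"trailing"` (default) or `"centered"`.
#' @param mean_hr_mode Passed to [hrv_time_domain()].
#' @return Data frame with `epoch` (0-based), `truncated`, and the 17
#'   metric columns of [hrv_metric_names()].
#' @export
hrv_per_epoch <- function(rr, n_epochs, window_len = 300,
                          align = c("trailing", "centered"),
                          mean_hr_mode = "per_beat") {
  align <- match.arg(align)
  stopifnot(inherits(rr, "rr_series"))
  if (!window_len %in% c(30, 180, 300)) {
    stop("window_len must be one of 30, 180, 300 seconds")
  }
  record_end <- n_epochs * EPOCH_SEC
  if (rr$beat_time_s[1] > record_end || max(rr$beat_time_s) < 0) {
    stop("RR series and epoch grid have disjoint time bases")
  }
  feats <- matrix(NA_real_, n_epochs, 17,
                  dimnames = list(NULL, hrv_metric_names()))
  trunc <- logical(n_epochs)
  for (e in seq_len(n_epochs)) {
    t_end <- if (align == "trailing") e * EPOCH_SEC else
      (e - 0.5) * EPOCH_SEC + window_len / 2
    w <- slice_rr(rr, t_end, window_len)
    trunc[e] <- w$truncated
    if (w$n >= 2) feats[e, ] <- hrv_window_features(w, mean_hr_mode = mean_hr_mode)
  }
  data.frame(epoch = seq_len(n_epochs) - 1L, truncated = trunc, feats)
}

#' HRV features for every record of a cohort
#'
#' @param records List of [subject_record()]s.
#' @param window_len,align,mean_hr_mode Passed to [hrv_per_epoch()].
#' @return Named list (by subject id) of [hrv_per_epoch()] data frames.
#' @export
cohort_hrv <- function(records, window_len = 300, align = "trailing",
                       mean_hr_mode = "per_beat") {
  out <- lapply(records, function(rec) {
    hrv_per_epoch(rec$rr, nrow(rec$epochs), window_len = window_len,
                  align = align, mean_hr_mode = mean_hr_mode)
  })
  names(out) <- vapply(records, `[[`, character(1), "subject")
  out
}
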