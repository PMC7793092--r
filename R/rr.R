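#' RR-interval series
#'
#' The substrate for all HRV metrics: beat occurrence times (seconds
#' from record start, strictly increasing) paired with the RR interval
#' (ms) ending at each beat, i.e. interval `i` spans
#' `(beat_time[i] - rr_ms[i]/1000, beat_time[i]]`. Intervals outside the
#' physiological guard band 200–3000 ms are flagged (attribute
#' `guard_flags`), not rejected.
#'
#' @param beat_time_s Numeric vector of beat times in seconds.
#' @param rr_ms Numeric vector of RR intervals in ms, same length.
#' @return Object of class `rr_series`: a list with `beat_time_s` and
#'   `rr_ms`.
#' @export
rr_series <- function(beat_time_s, rr_ms) {
  if (length(beat_time_s) != length(rr_ms)) {
    stop("beat_time_s and rr_ms must have equal length")
  }
  if (any(rr_ms <= 0)) stop("RR intervals must be positive")
  if (length(beat_time_s) > 1 && any(diff(beat_time_s) <= 0)) {
    stop("beat times must be strictly increasing")
  }
  flags <- which(rr_ms < 200 | rr_ms > 3000)
  structure(list(beat_time_s = as.numeric(beat_time_s),
                 rr_ms = as.numeric(rr_ms)),
            class = "rr_series", guard_flags = flags)
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats over %.1f s, mean RR %.0f ms\n",
              length(x$rr_ms), max(x$beat_time_s) - min(x$beat_time_s) +
                x$rr_ms[1] / 1000, mean(x$rr_ms)))
  invisible(x)
}

#' Slice a trailing RR window
#'
#' Returns the intervals whose terminating beats fall in the half-open
#' window `(t_end - window_len, t_end]`. Windows clipped at the record
#' start are returned with `truncated = TRUE` and computed on whatever
#' data is available; a window before the first beat is the empty
#' sentinel (`n = 0`).
#'
#' @param rr An [rr_series()].
#' @param t_end Window end time (s), normally an epoch boundary.
#' @param window_len Window length in seconds (30, 180 or 300 in the
#'   standard configurations; any positive value is accepted).
#' @return Object of class `rr_window`: list with `beat_time_s`,
#'   `rr_ms`, `n`, `t_end`, `window_len`, `truncated`.
#' @export
slice_rr <- function(rr, t_end, window_len) {
  stopifnot(inherits(rr, "rr_series"))
  if (window_len <= 0) stop("window_len must be positive")
  t0 <- t_end - window_len
  keep <- rr$beat_time_s > t0 & rr$beat_time_s <= t_end
  record_start <- rr$beat_time_s[1] - rr$rr_ms[1] / 1000
  structure(list(beat_time_s = rr$beat_time_s[keep],
                 rr_ms = rr$rr_ms[keep],
                 n = sum(keep),
                 t_end = t_end, window_len = window_len,
                 truncated = t0 < record_start - 1e-9),
            class = "rr_window")
}

#' Artifact fraction of an RR series
#'
#' Fraction (as a percentage) of intervals deviating by more than 20%
#' from an 11-beat running median — a simple, documented beat-artifact
#' detector. Records at or above 5% are conventionally excluded from
#' training and evaluation.
#'
#' @param rr An [rr_series()].
#' @param threshold Relative deviation flagged as artifact (default 0.2).
#' @return Percentage in `[0, 100]`, or `NA` for series with fewer than
#'   3 intervals.
#' @export
artifact_fraction <- function(rr, threshold = 0.2) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$rr_ms
  if (length(x) < 3) return(NA_real_)
  med <- stats::runmed(x, k = min(11L, length(x) - (1 - length(x) %% 2)),
                       endrule = "median")
  100 * mean(abs(x - med) / med > threshold)
}

#' Is a record excluded by the artifact rule?
#'
#' @param rr An [rr_series()].
#' @param max_percent Exclusion bound (default 5).
#' @return Logical; `NA` when the fraction is undefined.
#' @export
artifact_excluded <- function(rr, max_percent = 5) {
  af <- artifact_fraction(rr)
  if (is.na(af)) return(NA)
  af >= max_percent
}
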