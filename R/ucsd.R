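#' UCSD scorer configuration
#'
#' Loads the weighted-window scorer configuration: seven coefficients
#' for the minutes at lags -4 ... +2 around the scored minute, the
#' sleep/wake decision threshold, and the count mode the weights were
#' calibrated for. Defaults come from the versioned YAML shipped with
#' the package (`inst/extdata/ucsd_default.yaml`); any field can be
#' overridden.
#'
#' @param weights Numeric vector of exactly 7 coefficients
#'   (lags -4 ... +2), or `NULL` for the file defaults.
#' @param threshold Positive decision bound (weighted sum below it
#'   scores sleep), or `NULL` for the file default.
#' @param count_mode One of `"PIM"`, `"ZCM"`, `"TAT"`.
#' @param path Optional path to an alternative YAML config.
#' @return List of class `ucsd_config`.
#' @export
ucsd_config <- function(weights = NULL, threshold = NULL,
                        count_mode = NULL, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ucsd_default.yaml", package = "hypnoscore")
  }
  cfg <- yaml::read_yaml(path)
  if (!is.null(weights)) cfg$weights <- weights
  if (!is.null(threshold)) cfg$threshold <- threshold
  if (!is.null(count_mode)) cfg$count_mode <- count_mode
  cfg$weights <- as.numeric(cfg$weights)
  if (length(cfg$weights) != 7) {
    stop("UCSD config needs exactly 7 weights (minutes -4 ... +2)")
  }
  if (cfg$threshold <= 0) stop("UCSD threshold must be positive")
  if (!cfg$count_mode %in% c("PIM", "ZCM", "TAT")) {
    stop("count_mode must be PIM, ZCM or TAT")
  }
  structure(cfg, class = "ucsd_config")
}

#' Aggregate 30-s counts to per-minute counts
#'
#' Pairwise sums of consecutive 30-s epochs. An odd trailing epoch is
#' not emitted as a minute: it is carried on the result as attribute
#' `trailing_half` with a warning.
#'
#' @param counts_30s Non-negative numeric vector of per-epoch counts.
#' @return Numeric vector of per-minute counts.
#' @export
counts_to_minutes <- function(counts_30s) {
  n <- length(counts_30s)
  if (n %% 2 == 1) {
    warning("odd number of 30-s epochs; last epoch carried as a half-minute")
    half <- counts_30s[n]
    counts_30s <- counts_30s[-n]
    n <- n - 1L
  } else half <- NULL
  out <- if (n > 0) {
    counts_30s[seq(1, n, by = 2)] + counts_30s[seq(2, n, by = 2)]
  } else numeric(0)
  attr(out, "trailing_half") <- half
  out
}

#' Score per-minute activity with the UCSD weighted window
#'
#' For each minute `t`, `D(t) = sum(w_k * A(t + k))` over lags
#' `k = -4 ... +2`; the minute is sleep when `D(t) < threshold`. The
#' four leading and two trailing minutes are zero-padded (which biases
#' the edges toward sleep; edge minutes are flagged in the `edge`
#' attribute). Each minute's label is duplicated to its two 30-s
#' epochs.
#'
#' @param counts_per_min Per-minute activity counts.
#' @param cfg A [ucsd_config()].
#' @return Character vector of `"sleep"`/`"wake"`, one per 30-s epoch
#'   (length `2 * length(counts_per_min)`), with attributes `D`
#'   (per-minute score) and `edge` (logical per-minute edge flag).
#' @export
ucsd_score <- function(counts_per_min, cfg = ucsd_config()) {
  stopifnot(inherits(cfg, "ucsd_config"))
  n <- length(counts_per_min)
  if (n < 1) stop("no minutes to score")
  padded <- c(rep(0, 4), counts_per_min, rep(0, 2))
  d <- vapply(seq_len(n), function(t) {
    sum(cfg$weights * padded[(t - 4):(t + 2) + 4])
  }, numeric(1))
  lab_min <- ifelse(d < cfg$threshold, "sleep", "wake")
  out <- rep(lab_min, each = 2)
  attr(out, "D") <- d
  attr(out, "edge") <- seq_len(n) <= 4 | seq_len(n) > n - 2
  out
}

#' Score a 30-s count series with the UCSD algorithm
#'
#' Convenience wrapper: aggregates to minutes, scores, expands back to
#' the 30-s grid, and replicates the final minute's label over an odd
#' trailing epoch so the output always matches the input length.
#'
#' @param counts_30s Per-epoch (30-s) activity counts.
#' @param cfg A [ucsd_config()].
#' @return Character vector of `"sleep"`/`"wake"`, one per input epoch.
#' @export
ucsd_score_epochs <- function(counts_30s, cfg = ucsd_config()) {
  n <- length(counts_30s)
  cpm <- suppressWarnings(counts_to_minutes(counts_30s))
  labels <- ucsd_score(cpm, cfg)
  if (length(labels) < n) labels <- c(labels, rep(labels[length(labels)],
                                                  n - length(labels)))
  as.vector(labels[seq_len(n)])
}
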