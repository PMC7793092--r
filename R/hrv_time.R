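#' Time-domain HRV metrics for one RR window
#'
#' Computes the nine time-domain metrics: MeanRR, SDRR, MeanHR, MinHR,
#' MaxHR (min/max over a 5-beat moving average), RMSSD, PNN50 (count of
#' successive differences > 50 ms divided by the total number of
#' intervals), the HRV triangular index (total count over modal bin
#' count, 1/128-s histogram bins) and TINN (baseline width of a
#' least-squares triangular fit to the same histogram).
#'
#' Windows with fewer than 2 intervals return all-`NA`. With fewer
#' than 5 intervals MinHR and MaxHR fall back to MeanHR (flagged via
#' attribute `short_hr`).
#'
#' @param w An [slice_rr()] window (or any list with `rr_ms`).
#' @param mean_hr_mode `"per_beat"` (mean of per-beat 60000/RR, the
#'   convention of standard HRV software) or `"from_mean_rr"`
#'   (60000/MeanRR).
#' @param bin_width_s Histogram bin width for HRVti/TINN (default 1/128 s).
#' @return Named numeric vector of the nine metrics.
#' @export
hrv_time_domain <- function(w, mean_hr_mode = c("per_beat", "from_mean_rr"),
                            bin_width_s = 1 / 128) {
  mean_hr_mode <- match.arg(mean_hr_mode)
  rr <- w$rr_ms
  out <- c(MeanRR = NA_real_, SDRR = NA_real_, MeanHR = NA_real_,
           MinHR = NA_real_, MaxHR = NA_real_, RMSSD = NA_real_,
           PNN50 = NA_real_, HRVti = NA_real_, TINN = NA_real_)
  n <- length(rr)
  if (n < 2) return(out)
  out["MeanRR"] <- mean(rr)
  out["SDRR"] <- stats::sd(rr)
  out["MeanHR"] <- if (mean_hr_mode == "per_beat") mean(60000 / rr) else 60000 / mean(rr)
  short_hr <- n < 5
  if (short_hr) {
    out["MinHR"] <- out["MaxHR"] <- out["MeanHR"]
  } else {
    ma <- stats::filter(rr, rep(1 / 5, 5), sides = 2)
    ma <- ma[!is.na(ma)]
    out["MinHR"] <- min(60000 / ma)
    out["MaxHR"] <- max(60000 / ma)
  }
  d <- diff(rr)
  out["RMSSD"] <- sqrt(mean(d^2))
  out["PNN50"] <- 100 * sum(abs(d) > 50) / n
  h <- rr_histogram(rr, bin_width_s * 1000)
  out["HRVti"] <- n / max(h$counts)
  out["TINN"] <- tinn_width(h)
  attr(out, "short_hr") <- short_hr
  out
}

# Histogram of RR intervals (ms) on bins aligned to multiples of bw_ms.
rr_histogram <- function(rr, bw_ms) {
  k <- floor(rr / bw_ms)
  rng <- range(k)
  counts <- tabulate(k - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  mids <- (rng[1]:rng[2] + 0.5) * bw_ms
  list(counts = counts, mids = mids, bw = bw_ms)
}

# TINN: baseline width (ms) of the best least-squares triangular
# interpolation of the RR histogram. The apex is pinned at the modal
# bin (position and height); the left base N and right base M are
# searched over bin midpoints; left and right errors are separable so
# each side is minimized independently. Degenerate histograms (mode at
# an edge with no room on one side, or a single bin) fall back to the
# span of non-empty bins.
tinn_width <- function(h) {
  counts <- h$counts
  mids <- h$mids
  B <- length(counts)
  if (B < 2) return(0)
  p <- which.max(counts)
  y <- counts[p]
  xm <- mids[p]
  best_side <- function(side_idx, base_candidates) {
    # side_idx: bins strictly on one side of the mode
    best <- NULL
    best_err <- Inf
    for (b in base_candidates) {
      tri <- y * (mids[side_idx] - b) / (xm - b)
      tri[tri < 0] <- 0
      tri[tri > y] <- y
      err <- sum((counts[side_idx] - tri)^2)
      if (err < best_err - 1e-12) {
        best_err <- err
        best <- b
      }
    }
    best
  }
  left_idx <- seq_len(p - 1L)
  right_idx <- if (p < B) seq(p + 1L, B) else integer(0)
  n_base <- if (length(left_idx)) {
    best_side(left_idx, mids[left_idx] - h$bw)
  } else xm - h$bw
  m_base <- if (length(right_idx)) {
    best_side(right_idx, mids[right_idx] + h$bw)
  } else xm + h$bw
  if (is.null(n_base) || is.null(m_base)) {
    ne <- which(counts > 0)
    return(mids[max(ne)] - mids[min(ne)])
  }
  m_base - n_base
}

#' Square root of the Baevsky stress index
#'
#' `SI = AMo / (2 * Mo * MxDMn)` on the 50-ms RR histogram, where `Mo`
#' is the modal interval (s), `AMo` the modal bin's share of intervals
#' (%), and `MxDMn` the interval range (s); this function returns
#' `sqrt(SI)`. Bins are centered on multiples of 50 ms, so `Mo` is a
#' round multiple of 0.05 s.
#'
#' @param w An [slice_rr()] window.
#' @return `sqrt(SI)`, or `NA` for windows with fewer than 2 intervals
#'   or zero range (constant RR — the index is undefined).
#' @export
stress_index <- function(w) {
  rr <- w$rr_ms
  if (length(rr) < 2) return(NA_real_)
  mxdmn <- (max(rr) - min(rr)) / 1000
  if (mxdmn <= 0) return(NA_real_)
  k <- round(rr / 50)           # bin centers at multiples of 50 ms
  tab <- tabulate(k - min(k) + 1L)
  mo <- (which.max(tab) + min(k) - 1L) * 50 / 1000
  amo <- 100 * max(tab) / length(rr)
  sqrt(amo / (2 * mo * mxdmn))
}
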