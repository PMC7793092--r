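#' Welch power spectral density
#'
#' One-sided Welch PSD estimate: the series is split into segments of
#' `seg_len` samples with 50% overlap, each segment is demeaned,
#' Hann-windowed and Fourier-transformed, and the scaled periodograms
#' are averaged. Density units are `x-unit^2 / Hz`.
#'
#' @param x Numeric series sampled at `fs` Hz.
#' @param fs Sampling frequency (Hz).
#' @param seg_len Segment length in samples; defaults to the full
#'   series (a single segment).
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_len = length(x)) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  if (seg_len < 8) stop("series too short for a PSD estimate")
  step <- max(1L, floor(seg_len / 2))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))  # Hann
  scale <- 1 / (fs * sum(w^2))
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2 * scale
    half <- sp[seq_len(nf)]
    # one-sided: double everything except DC (and Nyquist when present)
    half[2:(nf - 1L)] <- 2 * half[2:(nf - 1L)]
    if (seg_len %% 2 == 1) half[nf] <- 2 * half[nf]
    acc <- acc + half
  }
  list(freq = (seq_len(nf) - 1) * fs / seg_len, psd = acc / length(starts))
}

# Integrate a PSD over [lo, hi] by the trapezoid rule, interpolating
# the density at the exact band edges so adjacent bands tile the axis.
band_power <- function(freq, psd, lo, hi) {
  if (hi <= freq[1] || lo >= freq[length(freq)]) return(0)
  lo <- max(lo, freq[1]); hi <- min(hi, freq[length(freq)])
  inner <- freq > lo & freq < hi
  f <- c(lo, freq[inner], hi)
  p <- c(stats::approx(freq, psd, lo)$y, psd[inner], stats::approx(freq, psd, hi)$y)
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

band_peak <- function(freq, psd, lo, hi) {
  i <- which(freq >= lo & freq <= hi)
  if (!length(i)) return(NA_real_)
  freq[i[which.max(psd[i])]]
}

#' Frequency-domain HRV metrics for one RR window
#'
#' The RR tachogram (interval value at its terminating beat time) is
#' interpolated to an even 4-Hz grid by cubic spline, linearly
#' detrended, and its Welch PSD computed (150-s Hann segments with 50%
#' overlap when the window holds at least 240 s of samples, a single
#' segment otherwise). Band powers are trapezoid integrals of the
#' density over VLF (0–0.04 Hz), LF (0.04–0.15 Hz) and HF
#' (0.15–0.4 Hz); band peaks are the frequency of maximum density
#' within each band.
#'
#' VLF fields are `NA` when the window spans less than 50 s (two
#' periods of the upper VLF edge). `LF_HF` is `NA` when HF power is
#' zero. Windows with fewer than 4 intervals return all-`NA`.
#'
#' @param w An [slice_rr()] window.
#' @param resample_hz Tachogram resampling rate (default 4 Hz).
#' @param bands Named list of band edges in Hz.
#' @return Named numeric vector: VLFPeak, LFPeak, HFPeak, VLFPower,
#'   LFPower, HFPower, LF_HF.
#' @export
hrv_freq_domain <- function(w, resample_hz = 4,
                            bands = list(vlf = c(0, 0.04),
                                         lf = c(0.04, 0.15),
                                         hf = c(0.15, 0.4))) {
  out <- c(VLFPeak = NA_real_, LFPeak = NA_real_, HFPeak = NA_real_,
           VLFPower = NA_real_, LFPower = NA_real_, HFPower = NA_real_,
           LF_HF = NA_real_)
  if (is.null(w$rr_ms) || length(w$rr_ms) < 4) return(out)
  tt <- w$beat_time_s
  span <- tt[length(tt)] - tt[1]
  if (span < 8) return(out)
  grid <- seq(tt[1], tt[length(tt)], by = 1 / resample_hz)
  y <- stats::splinefun(tt, w$rr_ms, method = "fmm")(grid)
  # linear detrend
  fit <- stats::lm.fit(cbind(1, grid), y)
  y <- fit$residuals
  seg_len <- if (span >= 240) 150 * resample_hz else length(y)
  ps <- welch_psd(y, resample_hz, seg_len = seg_len)
  for (b in names(bands)) {
    key <- toupper(b)
    out[paste0(key, "Power")] <- band_power(ps$freq, ps$psd, bands[[b]][1], bands[[b]][2])
    out[paste0(key, "Peak")] <- band_peak(ps$freq, ps$psd, bands[[b]][1], bands[[b]][2])
  }
  if (span < 50) out[c("VLFPeak", "VLFPower")] <- NA_real_
  if (!is.na(out["HFPower"]) && out["HFPower"] > 0) {
    out["LF_HF"] <- out["LFPower"] / out["HFPower"]
  }
  out
}
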