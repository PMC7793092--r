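# Independent naive-loop oracles and small fixture builders shared by
# the test files. The oracles deliberately use plain loops and direct
# formula transcription, never the package's vectorized code paths.

# -- fixture builders ----------------------------------------------------

# RR series with given intervals (ms), beats starting at rr[1]/1000 s.
make_rr <- function(rr_ms) {
  rr_series(cumsum(rr_ms) / 1000, rr_ms)
}

# Sinusoidally modulated RR series: rr(t) = base + amp * sin(2*pi*f*t).
make_sine_rr <- function(total_s, base_ms = 1000, amp_ms = 0, freq_hz = 0.25) {
  t <- 0; times <- c(); rrs <- c()
  while (t < total_s) {
    rr <- base_ms + amp_ms * sin(2 * pi * freq_hz * t)
    t <- t + rr / 1000
    times <- c(times, t); rrs <- c(rrs, rr)
  }
  rr_series(times, rrs)
}

random_window <- function(n = 300, seed = 1) {
  withr::with_seed(seed, {
    rr <- 1000 + cumsum(rnorm(n, 0, 12))
    rr <- pmin(pmax(rr, 500), 1800)
    w <- slice_rr(make_rr(rr), sum(rr) / 1000, 30)  # take everything
    list(beat_time_s = cumsum(rr) / 1000, rr_ms = rr, n = n)
  })
}

# -- time-domain oracle --------------------------------------------------

oracle_time_domain <- function(rr) {
  n <- length(rr)
  mean_rr <- sum(rr) / n
  sdrr <- sqrt(sum((rr - mean_rr)^2) / (n - 1))
  mean_hr <- sum(60000 / rr) / n
  # 5-beat moving average, then HR
  if (n >= 5) {
    ma <- sapply(3:(n - 2), function(i) mean(rr[(i - 2):(i + 2)]))
    min_hr <- min(60000 / ma); max_hr <- max(60000 / ma)
  } else {
    min_hr <- max_hr <- mean_hr
  }
  d <- rr[-1] - rr[-n]
  rmssd <- sqrt(sum(d^2) / (n - 1))
  pnn50 <- 100 * sum(abs(d) > 50) / n
  # histogram with 1/128-s bins aligned at multiples of the bin width
  bw <- 1000 / 128
  k <- floor(rr / bw)
  counts <- sapply(min(k):max(k), function(b) sum(k == b))
  mids <- (min(k):max(k) + 0.5) * bw
  hrvti <- n / max(counts)
  tinn <- oracle_tinn(counts, mids, bw)
  c(MeanRR = mean_rr, SDRR = sdrr, MeanHR = mean_hr, MinHR = min_hr,
    MaxHR = max_hr, RMSSD = rmssd, PNN50 = pnn50, HRVti = hrvti, TINN = tinn)
}

# Exhaustive joint search over (N, M) base pairs for the triangular fit
# (apex pinned at the first modal bin), scoring the FULL histogram for
# every pair — independent of the separable minimization in the package.
oracle_tinn <- function(counts, mids, bw) {
  p <- which.max(counts)
  y <- counts[p]; xm <- mids[p]
  n_cand <- if (p > 1) mids[1:(p - 1)] - bw else xm - bw
  m_cand <- if (p < length(counts)) mids[(p + 1):length(counts)] + bw else xm + bw
  best <- Inf; best_nm <- c(NA, NA)
  for (N in n_cand) for (M in m_cand) {
    tri <- ifelse(mids <= N | mids >= M, 0,
                  ifelse(mids <= xm, y * (mids - N) / (xm - N),
                         y * (M - mids) / (M - xm)))
    err <- sum((counts - tri)^2)
    if (err < best - 1e-12) { best <- err; best_nm <- c(N, M) }
  }
  best_nm[2] - best_nm[1]
}

oracle_stress_index <- function(rr) {
  mxdmn <- (max(rr) - min(rr)) / 1000
  if (mxdmn <= 0) return(NA_real_)
  k <- round(rr / 50)
  tab <- sapply(min(k):max(k), function(b) sum(k == b))
  mo <- (min(k):max(k))[which.max(tab)] * 50 / 1000
  amo <- 100 * max(tab) / length(rr)
  sqrt(amo / (2 * mo * mxdmn))
}

# -- frequency-domain oracle --------------------------------------------

# Direct re-derivation of the per-window spectral metrics: cubic-spline
# resampling, explicit least-squares detrend, explicit Hann segments,
# and a direct DFT sum (no fft), with explicit trapezoid band
# integration. Shares only the interpolation primitive with the
# package path.
oracle_freq_domain <- function(beat_time_s, rr_ms, fs = 4) {
  grid <- seq(beat_time_s[1], beat_time_s[length(beat_time_s)], by = 1 / fs)
  y <- stats::splinefun(beat_time_s, rr_ms, method = "fmm")(grid)
  n <- length(y)
  sx <- sum(grid); sxx <- sum(grid^2); sy <- sum(y); sxy <- sum(grid * y)
  beta <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  alpha <- (sy - beta * sx) / n
  y <- y - alpha - beta * grid
  span <- grid[n] - grid[1]
  seg <- if (span >= 240) 150 * fs else n
  step <- max(1, floor(seg / 2))
  starts <- seq(1, n - seg + 1, by = step)
  h <- 0.5 - 0.5 * cos(2 * pi * (0:(seg - 1)) / (seg - 1))
  nf <- floor(seg / 2) + 1
  freq <- (0:(nf - 1)) * fs / seg
  acc <- numeric(nf)
  for (s in starts) {
    x <- y[s:(s + seg - 1)]
    x <- (x - mean(x)) * h
    for (k in 0:(nf - 1)) {
      re <- sum(x * cos(-2 * pi * k * (0:(seg - 1)) / seg))
      im <- sum(x * sin(-2 * pi * k * (0:(seg - 1)) / seg))
      p <- (re^2 + im^2) / (fs * sum(h^2))
      if (k > 0 && (k < nf - 1 || seg %% 2 == 1)) p <- 2 * p
      acc[k + 1] <- acc[k + 1] + p
    }
  }
  psd <- acc / length(starts)
  bp <- function(lo, hi) {
    lo <- max(lo, freq[1]); hi <- min(hi, freq[nf])
    inner <- which(freq > lo & freq < hi)
    f <- c(lo, freq[inner], hi)
    p <- c(approx(freq, psd, lo)$y, psd[inner], approx(freq, psd, hi)$y)
    s <- 0
    for (j in 2:length(f)) s <- s + (f[j] - f[j - 1]) * (p[j] + p[j - 1]) / 2
    s
  }
  pk <- function(lo, hi) {
    i <- which(freq >= lo & freq <= hi)
    freq[i[which.max(psd[i])]]
  }
  out <- c(VLFPeak = pk(0, 0.04), LFPeak = pk(0.04, 0.15),
           HFPeak = pk(0.15, 0.4), VLFPower = bp(0, 0.04),
           LFPower = bp(0.04, 0.15), HFPower = bp(0.15, 0.4))
  out["LF_HF"] <- if (out[["HFPower"]] > 0) out[["LFPower"]] / out[["HFPower"]]
                  else NA_real_
  if (span < 50) out[c("VLFPeak", "VLFPower")] <- NA_real_
  out
}

# -- agreement / comparison oracles -------------------------------------

oracle_kappa <- function(tp, tn, fp, fn) {
  n <- tp + tn + fp + fn
  po <- (tp + tn) / n
  pe <- ((tp + fn) / n) * ((tp + fp) / n) + ((tn + fp) / n) * ((tn + fn) / n)
  100 * (po - pe) / (1 - pe)
}

oracle_bland_altman <- function(ref, est) {
  d <- ref - est
  n <- length(d)
  bias <- sum(d) / n
  sdd <- sqrt(sum((d - bias)^2) / (n - 1))
  se <- sdd / sqrt(n)
  tstat <- bias / se
  m <- (ref + est) / 2
  mx <- mean(m)
  beta <- sum((m - mx) * (d - bias)) / sum((m - mx)^2)
  alpha <- bias - beta * mx
  resid <- d - alpha - beta * m
  s2 <- sum(resid^2) / (n - 2)
  se_b <- sqrt(s2 / sum((m - mx)^2))
  list(bias = bias,
       loa = c(bias - 1.96 * sdd, bias + 1.96 * sdd),
       t_p = 2 * pt(-abs(tstat), n - 1),
       slope = beta,
       slope_p = 2 * pt(-abs(beta / se_b), n - 2),
       mae = mean(abs(d)))
}

# -- misc ----------------------------------------------------------------

# Tiny cohort parameters for fast structural tests.
tiny_params <- function(n_subjects = 2, n_epochs = 60, seed = 42) {
  sim_params(n_subjects = n_subjects, n_epochs = n_epochs, seed = seed)
}
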