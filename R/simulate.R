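#' Simulation parameters for synthetic subject-nights
#'
#' Bundles everything needed to generate a seeded synthetic cohort:
#' a first-order Markov model over the five PSG stages at the 30-s
#' epoch grid, stage-conditioned activity-count distributions
#' (emulating PIM-mode counts: high-mean overdispersed bursts in wake,
#' mostly-zero with rare bursts in sleep), and stage-conditioned
#' cardiac parameters driving RR-interval generation (mean HR, white
#' jitter, LF and HF sinusoidal modulation, respiratory frequency).
#'
#' Defaults encode the physiological contrasts the classifier relies
#' on: heart rate and HRV fall from wake through the NREM stages and
#' rise again in REM, and the LF/HF ratio is elevated in REM relative
#' to NREM.
#'
#' @param n_subjects Number of subject-nights in a cohort.
#' @param n_epochs Epochs per record (default 960 = 8 h).
#' @param transition 5x5 row-stochastic matrix over `W,N1,N2,N3,REM`.
#' @param activity Data frame with rows `W,N1,N2,N3,REM` and columns
#'   `p_active` (probability an epoch carries any movement), `mean`
#'   (negative-binomial mean count when active) and `size` (dispersion).
#' @param cardiac Data frame with rows `W,N1,N2,N3,REM` and columns
#'   `hr_bpm`, `sdnn_ms` (white jitter SD), `lf_amp_ms` (0.1-Hz
#'   modulation amplitude), `hf_amp_ms` (respiratory modulation
#'   amplitude) and `resp_hz`.
#' @param spo2_dropout Fraction of the record that may be lost to
#'   leading/trailing SpO2 dropout (each edge draws up to this share).
#' @param lights_off_epoch 0-based epoch index of lights off.
#' @param seed Master integer seed.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_subjects = 20,
                       n_epochs = 960,
                       transition = default_transition(),
                       activity = default_activity(),
                       cardiac = default_cardiac(),
                       spo2_dropout = 0.02,
                       lights_off_epoch = 0,
                       seed = 1L) {
  p <- structure(list(
    n_subjects = as.integer(n_subjects), n_epochs = as.integer(n_epochs),
    transition = transition, activity = activity, cardiac = cardiac,
    spo2_dropout = spo2_dropout,
    lights_off_epoch = as.integer(lights_off_epoch), seed = as.integer(seed)
  ), class = "sim_params")
  validate_sim_params(p)
  p
}

#' @rdname sim_params
#' @export
default_transition <- function() {
  m <- matrix(c(
    # W      N1     N2     N3     REM
    0.880, 0.090, 0.020, 0.005, 0.005,   # W
    0.150, 0.500, 0.330, 0.010, 0.010,   # N1
    0.030, 0.040, 0.850, 0.050, 0.030,   # N2
    0.010, 0.005, 0.100, 0.880, 0.005,   # N3
    0.060, 0.020, 0.040, 0.005, 0.875),  # REM
    nrow = 5, byrow = TRUE, dimnames = list(STAGES5, STAGES5))
  m
}

#' @rdname sim_params
#' @export
default_activity <- function() {
  data.frame(
    row.names = STAGES5,
    p_active = c(0.95, 0.15, 0.05, 0.02, 0.05),
    mean     = c(1500, 150, 120, 100, 120),
    size     = c(2, 1, 1, 1, 1)
  )
}

#' @rdname sim_params
#' @export
default_cardiac <- function() {
  data.frame(
    row.names = STAGES5,
    hr_bpm    = c(75, 64, 60, 56, 68),
    sdnn_ms   = c(25, 15, 12, 10, 18),
    lf_amp_ms = c(20, 12, 10, 8, 35),
    hf_amp_ms = c(10, 20, 25, 28, 10),
    resp_hz   = c(0.25, 0.25, 0.25, 0.25, 0.27)
  )
}

#' Cohort preset with the REM signature only in LF/HF
#'
#' A variant of the default simulation in which REM is
#' indistinguishable from NREM in both movement (identical activity
#' parameters) and mean heart rate, leaving the elevated-LF /
#' suppressed-HF cardiac modulation as the only REM marker. A
#' count-only classifier has no REM information on such a cohort, so
#' it isolates the contribution of the HRV channels to stage scoring.
#'
#' @param n_subjects,n_epochs,seed As in [sim_params()].
#' @return A [sim_params()] object.
#' @export
planted_lfhf_params <- function(n_subjects = 12, n_epochs = 480, seed = 1L) {
  act <- default_activity()
  act["REM", ] <- act["N2", ]
  card <- default_cardiac()
  card$hr_bpm <- rep(62, 5)
  card$sdnn_ms <- rep(12, 5)
  card$lf_amp_ms <- c(8, 8, 8, 8, 35)
  card$hf_amp_ms <- c(25, 25, 25, 25, 10)
  card$resp_hz <- rep(0.25, 5)
  sim_params(n_subjects = n_subjects, n_epochs = n_epochs,
             activity = act, cardiac = card, seed = seed)
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$n_subjects < 1L) stop("n_subjects must be >= 1")
  if (p$n_epochs < 1L) stop("n_epochs must be >= 1")
  tm <- p$transition
  if (!is.matrix(tm) || !identical(dim(tm), c(5L, 5L))) {
    stop("transition must be a 5x5 matrix over ", paste(STAGES5, collapse = ","))
  }
  if (any(tm < 0)) stop("transition probabilities must be non-negative")
  if (any(abs(rowSums(tm) - 1) > 1e-9)) {
    stop("transition matrix rows must each sum to 1 (tolerance 1e-9)")
  }
  for (col in c("p_active", "mean", "size")) {
    if (any(p$activity[[col]] < 0)) stop("activity parameter '", col, "' must be >= 0")
  }
  for (col in c("hr_bpm", "sdnn_ms", "lf_amp_ms", "hf_amp_ms", "resp_hz")) {
    if (any(p$cardiac[[col]] < 0)) stop("cardiac parameter '", col, "' must be >= 0")
  }
  if (any(p$cardiac$hr_bpm <= 0)) stop("hr_bpm must be positive")
  if (p$spo2_dropout < 0 || p$spo2_dropout > 0.4) stop("spo2_dropout must be in [0, 0.4]")
  if (p$lights_off_epoch < 0 || p$lights_off_epoch >= p$n_epochs) {
    stop("lights_off_epoch must lie inside the record")
  }
  invisible(p)
}

#' Stationary distribution of a stage-transition matrix
#'
#' Leading left eigenvector of the row-stochastic matrix, normalized to
#' sum to one.
#'
#' @param transition Row-stochastic square matrix.
#' @return Named numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(transition) {
  e <- eigen(t(transition))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  names(v) <- rownames(transition)
  v
}

#' Simulate a five-stage hypnogram
#'
#' Realizes a first-order Markov chain over `W,N1,N2,N3,REM` at the
#' 30-s epoch grid, starting in `W`. Deterministic given the seed.
#'
#' @param params A [sim_params()] object.
#' @param seed Optional seed overriding `params$seed`.
#' @return Character vector of five-stage labels, length `n_epochs`,
#'   of class `stage_sequence`.
#' @export
simulate_hypnogram <- function(params, seed = params$seed) {
  validate_sim_params(params)
  tm <- params$transition
  n <- params$n_epochs
  labels <- withr::with_seed(seed, {
    out <- integer(n)
    out[1] <- 1L  # start in W
    if (n > 1) {
      u <- stats::runif(n - 1)
      cum <- t(apply(tm, 1, cumsum))
      for (i in 2:n) {
        out[i] <- findInterval(u[i - 1], cum[out[i - 1], ]) + 1L
      }
    }
    STAGES5[out]
  })
  structure(labels, class = "stage_sequence", epoch_len = EPOCH_SEC)
}

#' Simulate per-epoch activity counts
#'
#' Stage-conditioned counts emulating PIM-mode actigraphy: each epoch
#' is active with stage probability `p_active`; active epochs draw a
#' negative-binomial count (mean `mean`, dispersion `size`), inactive
#' epochs are zero. Wake is configured high-mean and overdispersed,
#' sleep stages mostly zero with rare bursts.
#'
#' @param stages Stage label vector (five- or three-class).
#' @param params A [sim_params()] object.
#' @param seed Seed (defaults to `params$seed`).
#' @return Integer vector of non-negative counts, one per epoch.
#' @export
simulate_activity <- function(stages, params, seed = params$seed) {
  validate_sim_params(params)
  if (length(stages) < 1) stop("stages must be non-empty")
  act <- params$activity[as.character(stages), ]
  if (anyNA(act$p_active)) stop("stages contain labels absent from activity params")
  withr::with_seed(seed, {
    n <- length(stages)
    on <- stats::rbinom(n, 1L, act$p_active)
    counts <- integer(n)
    idx <- which(on == 1L & act$mean > 0)
    if (length(idx)) {
      counts[idx] <- stats::rnbinom(length(idx), size = act$size[idx], mu = act$mean[idx])
    }
    counts
  })
}

#' Simulate an RR-interval series for a staged record
#'
#' Piecewise-stationary generation per stage: the interval laid down at
#' elapsed time t is `60000 / hr_bpm(stage)` ms plus an LF sinusoid at
#' 0.1 Hz, an HF (respiratory) sinusoid at `resp_hz`, and white jitter
#' with SD `sdnn_ms`, all stage-conditioned. Intervals are floored at
#' 250 ms so the series stays physiological. Beats are generated until
#' the record end (`n_epochs * 30` s).
#'
#' @inheritParams simulate_activity
#' @return An [rr_series()] spanning the record.
#' @export
simulate_rr <- function(stages, params, seed = params$seed) {
  validate_sim_params(params)
  if (length(stages) < 1) stop("stages must be non-empty")
  card <- params$cardiac[as.character(stages), ]
  if (anyNA(card$hr_bpm)) stop("stages contain labels absent from cardiac params")
  total_s <- length(stages) * EPOCH_SEC
  base_ms <- 60000 / card$hr_bpm
  n_max <- ceiling(total_s / 0.25) + 2L
  withr::with_seed(seed, {
    jit <- stats::rnorm(n_max)
    times <- numeric(n_max)
    rrs <- numeric(n_max)
    t <- 0
    k <- 0L
    while (t < total_s) {
      ep <- min(floor(t / EPOCH_SEC) + 1, length(stages))
      rr <- base_ms[ep] +
        card$lf_amp_ms[ep] * sin(2 * pi * 0.1 * t) +
        card$hf_amp_ms[ep] * sin(2 * pi * card$resp_hz[ep] * t) +
        card$sdnn_ms[ep] * jit[k + 1L]
      rr <- max(rr, 250)
      t <- t + rr / 1000
      k <- k + 1L
      times[k] <- t
      rrs[k] <- rr
    }
    rr_series(times[seq_len(k)], rrs[seq_len(k)])
  })
}

simulate_spo2 <- function(n_epochs, dropout, seed) {
  withr::with_seed(seed, {
    max_drop <- floor(dropout * n_epochs)
    lead <- if (max_drop > 0) sample(0:max_drop, 1L) else 0L
    trail <- if (max_drop > 0) sample(0:max_drop, 1L) else 0L
    cov <- rep(30, n_epochs)
    if (lead > 0) cov[seq_len(lead)] <- 0
    if (trail > 0) cov[seq(n_epochs - trail + 1L, n_epochs)] <- 0
    cov
  })
}

derive_subject_seed <- function(master, i) {
  as.integer((as.numeric(master) + 99991 * i) %% (.Machine$integer.max - 1) + 1)
}

#' Simulate a cohort of subject-nights
#'
#' Generates `n_subjects` independent records; per-subject seeds are
#' derived deterministically from the master seed so the cohort is
#' reproducible as a whole.
#'
#' Each record bundles the epoch grid (activity count, SpO2 coverage
#' seconds, reference five-stage label), the RR series, and the
#' lights-off time.
#'
#' @param params A [sim_params()] object.
#' @return List of `subject_record` objects (see [subject_record()]).
#' @export
simulate_cohort <- function(params) {
  validate_sim_params(params)
  lapply(seq_len(params$n_subjects), function(i) {
    s <- derive_subject_seed(params$seed, i)
    stages <- simulate_hypnogram(params, seed = s)
    counts <- simulate_activity(stages, params, seed = s + 1L)
    rr <- simulate_rr(stages, params, seed = s + 2L)
    spo2 <- simulate_spo2(params$n_epochs, params$spo2_dropout, seed = s + 3L)
    subject_record(
      subject = sprintf("S%03d", i),
      epochs = data.frame(
        epoch = seq_len(params$n_epochs) - 1L,
        t_start_s = (seq_len(params$n_epochs) - 1L) * EPOCH_SEC,
        activity_count = counts,
        spo2_coverage_s = spo2,
        psg_stage = as.character(stages)
      ),
      rr = rr,
      lights_off_s = params$lights_off_epoch * EPOCH_SEC,
      seed = s
    )
  })
}

#' Split subjects into training and test sets
#'
#' Seeded shuffle, then `round(train_frac * N)` subjects to training and
#' the remainder to test — the 65/35 design at any cohort size.
#'
#' @param ids Vector of subject ids (or a list of records, whose
#'   `$subject` fields are used).
#' @param train_frac Training fraction (default 0.65).
#' @param seed Integer seed for the shuffle.
#' @return List with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
train_test_split <- function(ids, train_frac = 0.65, seed = 1L) {
  if (is.list(ids) && !is.null(ids[[1]]$subject)) {
    ids <- vapply(ids, `[[`, character(1), "subject")
  }
  n <- length(ids)
  if (n < 1) stop("need at least one subject")
  perm <- withr::with_seed(seed, sample(n))
  n_train <- round(train_frac * n)
  list(train = ids[perm[seq_len(n_train)]],
       test = ids[perm[setdiff(seq_len(n), seq_len(n_train))]])
}
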