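test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(transition = matrix(1, 5, 5)), "sum to 1")
  bad <- default_cardiac(); bad$lf_amp_ms[1] <- -1
  expect_error(sim_params(cardiac = bad), "must be >= 0")
  bad_a <- default_activity(); bad_a$mean[2] <- -5
  expect_error(sim_params(activity = bad_a), "must be >= 0")
  expect_error(sim_params(n_epochs = 0), "n_epochs")
})

test_that("hypnogram chain: absorbing state, determinism, stationary recovery", {
  p <- tiny_params(n_epochs = 50)
  ident <- diag(5); dimnames(ident) <- dimnames(default_transition())
  p_abs <- sim_params(n_epochs = 50, transition = ident, seed = 3)
  expect_true(all(simulate_hypnogram(p_abs) == "W"))

  expect_identical(simulate_hypnogram(p, seed = 9), simulate_hypnogram(p, seed = 9))

  # empirical stage frequencies, averaged over a few 960-epoch nights to
  # tame the autocorrelation of the chain, match the eigen-analysis
  # stationary distribution within 3 percentage points
  p_long <- sim_params(n_subjects = 10, n_epochs = 960, seed = 21)
  labs <- unlist(lapply(simulate_cohort(p_long),
                        function(r) r$epochs$psg_stage))
  emp <- table(factor(labs, levels = rownames(p_long$transition))) / length(labs)
  stat <- stationary_distribution(p_long$transition)  # eigen-analysis oracle
  expect_true(all(abs(as.numeric(emp) - stat) < 0.03))
})

test_that("long-chain transition counts recover the configured matrix", {
  p <- sim_params(n_epochs = 10000, seed = 5)
  h <- unclass(simulate_hypnogram(p))
  from <- factor(h[-length(h)], rownames(p$transition))
  to <- factor(h[-1], rownames(p$transition))
  counts <- table(from, to)
  # chi-square goodness of fit per row at alpha = 0.01
  for (s in rownames(p$transition)) {
    obs <- as.numeric(counts[s, ])
    pr <- p$transition[s, ]
    keep <- pr > 0
    pval <- stats::chisq.test(obs[keep], p = pr[keep] / sum(pr[keep]))$p.value
    expect_gt(pval, 0.01)
  }
})

test_that("activity counts follow the stage-conditioned distributions", {
  p <- sim_params(n_epochs = 10000, seed = 8)
  all_w <- structure(rep("W", 10000), class = "stage_sequence")
  a <- simulate_activity(all_w, p)
  expect_true(all(a >= 0))
  cfg_mean <- p$activity["W", "p_active"] * p$activity["W", "mean"]
  expect_lt(abs(mean(a) - cfg_mean) / cfg_mean, 0.10)

  quiet <- p
  quiet$activity["N2", "p_active"] <- 0
  all_n2 <- structure(rep("N2", 100), class = "stage_sequence")
  expect_true(all(simulate_activity(all_n2, quiet) == 0))

  expect_identical(simulate_activity(all_n2, p, seed = 4),
                   simulate_activity(all_n2, p, seed = 4))
})

test_that("RR generation tracks configured heart rates and is deterministic", {
  const <- default_cardiac()
  const[, c("sdnn_ms", "lf_amp_ms", "hf_amp_ms")] <- 0
  p <- sim_params(n_epochs = 20, cardiac = const, seed = 2)
  h <- structure(rep("N2", 20), class = "stage_sequence")
  rr <- simulate_rr(h, p)
  expect_true(all(abs(rr$rr_ms - 60000 / const["N2", "hr_bpm"]) < 1e-9))

  p2 <- sim_params(n_epochs = 960, seed = 13)
  h2 <- simulate_hypnogram(p2)
  rr2 <- simulate_rr(h2, p2)
  stage_at <- unclass(h2)[pmin(floor(rr2$beat_time_s / 30) + 1, 960)]
  hr <- 60000 / rr2$rr_ms
  m <- tapply(hr, collapse_stages(stage_at, "three"), mean)
  expect_gt(m[["W"]], m[["REM"]])
  expect_gt(m[["REM"]], m[["NREM"]])

  expect_identical(simulate_rr(h, p2, seed = 6), simulate_rr(h, p2, seed = 6))
})

test_that("REM carries elevated LF/HF relative to NREM in simulated records", {
  p <- sim_params(n_epochs = 480, seed = 17)
  h <- simulate_hypnogram(p)
  rr <- simulate_rr(h, p)
  f <- hrv_per_epoch(rr, 480, window_len = 300)
  three <- collapse_stages(unclass(h), "three")
  # a 5-min trailing window is stage-pure only inside long bouts; compare
  # epochs whose full trailing window is one stage
  pure <- vapply(seq_len(480), function(e) {
    lo <- max(1, e - 9)
    length(unique(three[lo:e])) == 1
  }, logical(1))
  lfhf_rem <- median(f$LF_HF[pure & three == "REM"], na.rm = TRUE)
  lfhf_nrem <- median(f$LF_HF[pure & three == "NREM"], na.rm = TRUE)
  expect_gt(lfhf_rem, lfhf_nrem)
})

test_that("cohort generation is reproducible with distinct realizations", {
  p <- sim_params(n_subjects = 3, n_epochs = 40, seed = 30)
  recs <- simulate_cohort(p)
  expect_length(recs, 3)
  expect_false(identical(recs[[1]]$epochs$activity_count,
                         recs[[2]]$epochs$activity_count))
  recs2 <- simulate_cohort(p)
  expect_identical(recs, recs2)

  nodrop <- sim_params(n_subjects = 1, n_epochs = 40, spo2_dropout = 0, seed = 30)
  r <- simulate_cohort(nodrop)[[1]]
  b <- detect_record_bounds(r$epochs$spo2_coverage_s)
  expect_identical(b$start_epoch, 0L)
  expect_identical(b$end_epoch, 40L)
})

test_that("65/35 subject split follows the rounding rule", {
  ids <- sprintf("S%02d", 1:20)
  sp <- train_test_split(ids, seed = 4)
  expect_length(sp$train, 13)
  expect_length(sp$test, 7)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
})

test_that("a threshold on activity alone separates sleep from wake", {
  p <- sim_params(n_subjects = 4, n_epochs = 480, seed = 55)
  recs <- simulate_cohort(p)
  acc <- vapply(recs, function(r) {
    pred <- ifelse(r$epochs$activity_count > 40, "wake", "sleep")
    epoch_metrics(r$epochs$psg_stage, pred, "sleep")[["accuracy"]]
  }, numeric(1))
  expect_true(all(acc >= 90))
})
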