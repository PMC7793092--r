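test_that("perfect and constant raters give the closed-form metrics", {
  ref <- c(rep("sleep", 30), rep("wake", 20))
  m <- epoch_metrics(ref, ref, "sleep")
  expect_equal(unname(m), c(100, 100, 100, 100))

  all_sleep <- rep("sleep", 50)
  m2 <- epoch_metrics(ref, all_sleep, "sleep")
  expect_equal(m2[["sensitivity"]], 100)
  expect_equal(m2[["specificity"]], 0)
  expect_equal(m2[["kappa"]], 0)   # constant rater
})

test_that("the 2x2 toy matches the brute-force kappa oracle", {
  # TP=40 TN=30 FP=10 FN=20
  ref <- c(rep("sleep", 60), rep("wake", 40))
  pred <- c(rep("sleep", 40), rep("wake", 20), rep("sleep", 10), rep("wake", 30))
  m <- epoch_metrics(ref, pred, "sleep")
  expect_equal(m[["accuracy"]], 70)
  expect_equal(m[["sensitivity"]], 100 * 40 / 60, tolerance = 1e-12)  # 66.67
  expect_equal(m[["specificity"]], 75)
  expect_equal(m[["kappa"]], oracle_kappa(40, 30, 10, 20), tolerance = 1e-12)
})

test_that("stage metrics use one-vs-rest framing", {
  ref <- c("REM", "REM", "NREM", "W", "NREM", "REM")
  pred <- c("REM", "NREM", "NREM", "W", "REM", "REM")
  m <- epoch_metrics(ref, pred, "REM")
  # TP=2 FN=1 FP=1 TN=2
  expect_equal(m[["accuracy"]], 100 * 4 / 6, tolerance = 1e-12)
  expect_equal(m[["sensitivity"]], 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(m[["specificity"]], 100 * 2 / 3, tolerance = 1e-12)
  expect_error(epoch_metrics(ref, pred[-1]), "equal length")
})

test_that("rater swap preserves accuracy/kappa; class flip swaps sens/spec", {
  withr::with_seed(3, {
    ref <- sample(c("sleep", "wake"), 200, replace = TRUE, prob = c(0.7, 0.3))
    pred <- ifelse(runif(200) < 0.8, ref, sample(c("sleep", "wake"), 200, TRUE))
  })
  a <- epoch_metrics(ref, pred, "sleep")
  swapped <- epoch_metrics(pred, ref, "sleep")
  expect_equal(a[["accuracy"]], swapped[["accuracy"]])
  expect_equal(a[["kappa"]], swapped[["kappa"]])
  flipped <- epoch_metrics(ref, pred, "wake")
  expect_equal(a[["accuracy"]], flipped[["accuracy"]])
  expect_equal(a[["kappa"]], flipped[["kappa"]])
  expect_equal(a[["sensitivity"]], flipped[["specificity"]])
  expect_equal(a[["specificity"]], flipped[["sensitivity"]])
})

test_that("subject summaries use the t-distribution CI and exclusion rule", {
  s <- summarize_subjects(c(60, 70, 80))
  expect_equal(s[["mean"]], 70)
  half <- qt(0.975, 2) * sd(c(60, 70, 80)) / sqrt(3)
  expect_equal(s[["lower"]], 70 - half, tolerance = 1e-12)
  expect_equal(s[["upper"]], 70 + half, tolerance = 1e-12)

  same <- summarize_subjects(rep(42, 5))
  expect_equal(same[["lower"]], same[["upper"]])

  with_na <- summarize_subjects(c(rep(50, 9), NA))
  expect_equal(with_na[["n_used"]], 9)
  expect_equal(with_na[["n_excluded"]], 1)
  expect_true(is.na(summarize_subjects(c(5, NA))[["lower"]]))
})

test_that("Bland-Altman handles identity and constant offset exactly", {
  x <- c(400, 420, 380, 450, 410, 395)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa, c(0, 0))
  expect_equal(ba0$mae, 0)

  ba <- bland_altman(x, x - 10)
  expect_equal(ba$bias, 10)      # device underestimates -> positive bias
  expect_equal(ba$sd, 0)
  expect_equal(ba$mae, 10)
  expect_equal(ba$slope, 0)
})

test_that("Bland-Altman statistics match the formula-by-formula oracle", {
  ref <- c(61, 54, 72, 38, 55, 49)
  est <- c(50, 60, 58, 31, 62, 40)
  ba <- bland_altman(ref, est, "SOL")
  o <- oracle_bland_altman(ref, est)
  expect_equal(ba$bias, o$bias, tolerance = 1e-9)
  expect_equal(ba$loa, o$loa, tolerance = 1e-9)
  expect_equal(ba$t_p, o$t_p, tolerance = 1e-9)
  expect_equal(ba$slope, o$slope, tolerance = 1e-9)
  expect_equal(ba$slope_p, o$slope_p, tolerance = 1e-9)
  expect_equal(ba$mae, o$mae, tolerance = 1e-9)
  expect_gte(ba$mae, abs(ba$bias))
  expect_error(bland_altman(ref, est[-1]), "paired")
})

test_that("bias sign convention: device underestimation is positive", {
  psg <- c(100, 110, 120, 105)
  underestimating_device <- psg - c(5, 8, 6, 7)
  expect_gt(bland_altman(psg, underestimating_device)$bias, 0)
  overestimating_device <- psg + 10
  expect_lt(bland_altman(psg, overestimating_device)$bias, 0)
})

test_that("bias comparison is a paired t-test on difference-of-differences", {
  d1 <- c(5, 7, 3, 6, 8)
  expect_equal(unname(compare_bias(d1, d1)), c(0, 1))
  expect_equal(compare_bias(d1, d1 - 4)[["d"]], 4)
  withr::with_seed(8, {
    a <- rnorm(12, 3, 2); b <- rnorm(12, 1, 2)
  })
  got <- compare_bias(a, b)
  want <- t.test(a - b)
  expect_equal(got[["d"]], abs(mean(a - b)), tolerance = 1e-12)
  expect_equal(got[["p"]], want$p.value, tolerance = 1e-9)
  expect_error(compare_bias(a, b[-1]), "same subjects")
})

test_that("multiclass kappa is 0 for constant raters and 100 for identity", {
  ref <- c("W", "NREM", "REM", "NREM", "W", "NREM")
  expect_equal(multiclass_kappa(ref, ref), 100)
  expect_equal(multiclass_kappa(ref, rep("NREM", 6)), 0)
})

test_that("the Bland-Altman plot builds with bias and LoA layers", {
  ba <- bland_altman(c(1, 2, 3, 4), c(1.2, 1.8, 3.3, 4.1), "TST")
  p <- bland_altman_plot(ba)
  expect_s3_class(p, "ggplot")
})
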