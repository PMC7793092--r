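make_tiny_cohort <- function(n_subjects = 2, n_epochs = 60, seed = 42) {
  simulate_cohort(sim_params(n_subjects = n_subjects, n_epochs = n_epochs,
                             seed = seed))
}

test_that("windows have shape 21 x channels with replicate edge padding", {
  recs <- make_tiny_cohort(1, 100)
  rec <- recs[[1]]
  hrv <- hrv_per_epoch(rec$rr, 100, window_len = 30)
  ch <- epoch_channels(rec, hrv)
  # 30-s windows never span enough signal for VLF: those channels are
  # unobserved and standardize to zero
  expect_warning(stats <- channel_stats(list(ch)), "unobserved")
  x <- build_windows(ch, stats)
  expect_identical(dim(x), c(100L, 21L, 18L))
  # epoch 0: rows 1..11 all replicate epoch 0's channel vector
  for (r in 1:11) expect_equal(x[1, r, ], x[1, 11, ])
  # center row of window n equals the standardized channels at epoch n
  xs <- sweep(sweep(ch, 2, stats$mean), 2, stats$sd, `/`)
  xs[is.na(xs)] <- 0
  expect_equal(x[37, 11, ], unname(xs[37, ]))
  expect_equal(x[37, 12, ], unname(xs[38, ]))
})

test_that("a channel that training observed but the record lacks errors by name", {
  recs <- make_tiny_cohort(1, 50)
  ch <- cbind(epoch_channels(recs[[1]]), LF_HF = rnorm(50))
  stats <- channel_stats(list(ch))           # LF_HF observed in training
  broken <- ch
  broken[, "LF_HF"] <- NA_real_
  expect_error(build_windows(broken, stats), "LF_HF")
  # a channel unobserved at training standardizes to zero instead
  allna <- ch
  allna[, "LF_HF"] <- NA_real_
  expect_warning(stats2 <- channel_stats(list(allna)), "LF_HF")
  x <- build_windows(allna, stats2)
  expect_true(all(x[, , ncol(ch)] == 0))
})

test_that("parameter count matches the closed-form sum over layers", {
  cfg <- ha_config(n_conv = 9, filters = 32, n_lstm = 4, lstm_units = 32,
                   n_classes = 3)
  spec <- build_deepconvlstm(cfg, 18)
  # closed form: conv1 3*18*32+32+2*32, conv2..9 3*32*32+32+64, lstm1
  # 4*(32*32+32*32+32), lstm2..4 same, dense 32*3+3
  manual <- (3 * 18 * 32 + 32 + 64) + 8 * (3 * 32 * 32 + 32 + 64) +
    4 * (4 * (32 * 32 + 32 * 32 + 32)) + (32 * 3 + 3)
  expect_identical(spec$n_parameters, manual)
  expect_identical(hypnoscore:::n_parameters_layers(spec$layers),
                   as.numeric(manual))
})

test_that("untrained forward passes respect the output geometry", {
  x <- withr::with_seed(1, array(rnorm(4 * 21 * 3), c(4, 21, 3)))
  spec3 <- build_deepconvlstm(ha_config(n_conv = 2, filters = 4, n_lstm = 1,
                                        lstm_units = 5, n_classes = 3), 3)
  p3 <- model_forward(spec3, x)
  expect_identical(dim(p3), c(4L, 3L))
  expect_true(all(p3 > 0 & p3 < 1))
  expect_equal(rowSums(p3), rep(1, 4), tolerance = 1e-6)

  spec2 <- build_deepconvlstm(ha_config(n_conv = 1, filters = 4, n_lstm = 1,
                                        lstm_units = 5, n_classes = 2), 3)
  p2 <- model_forward(spec2, x)
  expect_identical(dim(p2), c(4L, 1L))
  expect_true(all(p2 > 0 & p2 < 1))
})

test_that("gradients match finite differences through every layer type", {
  cfg <- ha_config(n_conv = 2, filters = 3, n_lstm = 2, lstm_units = 4,
                   n_classes = 3, seed = 3)
  spec <- build_deepconvlstm(cfg, 2)
  withr::with_seed(5, {
    x <- array(rnorm(5 * 21 * 2), c(5, 21, 2))
    y <- sample(1:3, 5, replace = TRUE)
  })
  w <- rep(1, 5)
  r <- hypnoscore:::nn_loss_grad(spec$layers, x, y, 3, w, cfg$l2)
  eps <- 1e-5
  withr::with_seed(6, {
    for (li in seq_along(spec$layers)) {
      g <- r$grads[[li]]
      if (is.null(g)) next
      for (nm in names(g)) {
        ix <- sample(length(spec$layers[[li]][[nm]]), 1)
        lp <- spec$layers; lp[[li]][[nm]][ix] <- lp[[li]][[nm]][ix] + eps
        lm_ <- spec$layers; lm_[[li]][[nm]][ix] <- lm_[[li]][[nm]][ix] - eps
        num <- (hypnoscore:::nn_loss_grad(lp, x, y, 3, w, cfg$l2)$loss -
                  hypnoscore:::nn_loss_grad(lm_, x, y, 3, w, cfg$l2)$loss) /
          (2 * eps)
        an <- g[[nm]][ix]
        expect_lt(abs(num - an) / max(1e-8, abs(num) + abs(an)), 1e-4)
      }
    }
  })
})

test_that("a capacity-reduced model memorizes a tiny window set", {
  withr::with_seed(20, {
    n <- 120
    y <- sample(c("W", "NREM", "REM"), n, replace = TRUE)
    mu <- cbind(W = c(3, 0), NREM = c(-2, 1), REM = c(0, -3))
    x <- array(0, c(n, 21, 2))
    for (i in seq_len(n)) {
      x[i, , ] <- rep(mu[, y[i]], each = 21) + rnorm(42, 0, 0.3)
    }
  })
  data <- list(x = x, y = y,
               subject = rep(c("A", "B"), length.out = 120))
  cfg <- ha_config(n_conv = 2, filters = 8, n_lstm = 1, lstm_units = 8,
                   max_epochs = 60, patience = 60, batch_size = 32,
                   lr = 3e-3, n_classes = 3, seed = 9)
  tm <- train_model(build_deepconvlstm(cfg, 2), data, "A", "B")
  pred <- predict_stages(tm, x[data$subject == "A", , , drop = FALSE])
  acc <- mean(pred$labels == y[data$subject == "A"])
  expect_gte(acc, 0.99)
})

test_that("training is seeded-deterministic with min-val-loss checkpointing", {
  withr::with_seed(21, {
    x <- array(rnorm(80 * 21 * 2), c(80, 21, 2))
    y <- ifelse(x[, 11, 1] > 0, "sleep", "wake")
  })
  data <- list(x = x, y = y, subject = rep(c("A", "B"), each = 40))
  cfg <- ha_config(n_conv = 1, filters = 4, n_lstm = 1, lstm_units = 4,
                   max_epochs = 8, patience = 8, batch_size = 32,
                   n_classes = 2, seed = 33)
  tm1 <- train_model(build_deepconvlstm(cfg, 2), data, "A", "B")
  tm2 <- train_model(build_deepconvlstm(cfg, 2), data, "A", "B")
  expect_identical(tm1$best_val_loss, tm2$best_val_loss)
  expect_identical(tm1$layers, tm2$layers)
  # checkpoint rule: stored loss is the minimum of the recorded history
  expect_equal(tm1$best_val_loss, min(tm1$history$val_loss))
  expect_identical(tm1$best_epoch, which.min(tm1$history$val_loss))
})

test_that("subject leakage between train and validation is a hard error", {
  data <- list(x = array(0, c(4, 21, 1)), y = rep("W", 4),
               subject = c("A", "A", "B", "B"))
  spec <- build_deepconvlstm(ha_config(n_conv = 1, filters = 2, n_lstm = 1,
                                       lstm_units = 2), 1)
  expect_error(train_model(spec, data, c("A", "B"), "B"), "leakage")
})

test_that("prediction enforces channel compatibility and label shapes", {
  withr::with_seed(2, {
    x <- array(rnorm(30 * 21 * 2), c(30, 21, 2))
    y <- sample(c("sleep", "wake"), 30, replace = TRUE)
  })
  data <- list(x = x, y = y, subject = rep(c("A", "B"), each = 15))
  cfg <- ha_config(n_conv = 1, filters = 2, n_lstm = 1, lstm_units = 3,
                   max_epochs = 2, patience = 2, n_classes = 2, seed = 1)
  tm <- train_model(build_deepconvlstm(cfg, 2), data, "A", "B")
  pred <- predict_stages(tm, x)
  expect_length(pred$labels, 30)
  expect_true(all(pred$labels %in% c("sleep", "wake")))
  expect_error(predict_stages(tm, array(0, c(5, 21, 3))), "channel")
})

test_that("subject folds partition the ids exactly", {
  ids <- sprintf("S%02d", 1:13)
  folds <- subject_folds(ids, k = 5, seed = 2)
  expect_length(folds, 5)
  expect_setequal(unlist(folds), ids)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(folds[[i]], folds[[j]]), 0)
  }
})

test_that("random search is seeded and ranked by its reported losses", {
  withr::with_seed(31, {
    n <- 160
    x <- array(rnorm(n * 21 * 2), c(n, 21, 2))
    y <- ifelse(x[, 11, 1] + 0.5 * x[, 11, 2] > 0, "NREM", "W")
  })
  data <- list(x = x, y = y,
               subject = rep(sprintf("S%d", 1:8), each = 20))
  res1 <- random_search(data, sprintf("S%d", 1:5), sprintf("S%d", 6:8),
                        n_cnn = 2, n_dclstm = 2, top_k = 1, cv_folds = 2,
                        search_epochs = 1, seed = 12)
  res2 <- random_search(data, sprintf("S%d", 1:5), sprintf("S%d", 6:8),
                        n_cnn = 2, n_dclstm = 2, top_k = 1, cv_folds = 2,
                        search_epochs = 1, seed = 12)
  expect_identical(res1, res2)
  expect_identical(res1$val_loss, sort(res1$val_loss))
  expect_false(is.na(res1$cv_loss[1]))
  expect_true(all(is.na(res1$cv_loss[-1])))
  expect_identical(res1$n_lstm[res1$family == "cnn"], rep(0L, 2))
})

test_that("trained models round-trip through save/load with a JSON sidecar", {
  withr::with_seed(2, {
    x <- array(rnorm(20 * 21 * 1), c(20, 21, 1))
    y <- sample(c("sleep", "wake"), 20, replace = TRUE)
  })
  data <- list(x = x, y = y, subject = rep(c("A", "B"), each = 10))
  cfg <- ha_config(n_conv = 1, filters = 2, n_lstm = 1, lstm_units = 2,
                   max_epochs = 1, patience = 1, n_classes = 2, seed = 5)
  tm <- train_model(build_deepconvlstm(cfg, 1), data, "A", "B")
  path <- file.path(withr::local_tempdir(), "model.rds")
  save_trained_model(tm, path)
  expect_true(file.exists(paste0(path, ".json")))
  tm2 <- load_trained_model(path)
  expect_identical(tm$layers, tm2$layers)
})
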