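#' Classifier configuration
#'
#' Architecture and training hyperparameters of the Conv-LSTM sleep
#' scorer: a stack of `n_conv` 1-D convolutions along the 21-epoch
#' window axis, each followed by batch normalization and ReLU, then
#' `n_lstm` LSTM layers, and a dense head — sigmoid for the binary
#' sleep/wake task (`n_classes = 2`, binary cross entropy) or softmax
#' for the three-class wake/NREM/REM task (`n_classes = 3`). L2 weight
#' decay is applied to convolution kernels. The default architecture
#' is 9 convolutional layers and 4 LSTM layers.
#'
#' @param n_conv Number of convolutional layers (>= 1).
#' @param filters Filters per convolutional layer.
#' @param kernel Odd kernel size along the window axis.
#' @param n_lstm Number of LSTM layers (0 gives a pure CNN with global
#'   average pooling before the head).
#' @param lstm_units Hidden units per LSTM layer.
#' @param l2 Kernel regularization rate (> 0).
#' @param lr Adam learning rate (> 0).
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without a new
#'   minimum validation loss).
#' @param n_classes 2 (sleep/wake) or 3 (W/NREM/REM).
#' @param seed Integer seed for initialization and batching.
#' @return List of class `model_config`.
#' @export
ha_config <- function(n_conv = 9, filters = 32, kernel = 3, n_lstm = 4,
                      lstm_units = 32, l2 = 1e-4, lr = 1e-3,
                      batch_size = 128, max_epochs = 30, patience = 8,
                      n_classes = 3, seed = 42L) {
  cfg <- list(n_conv = as.integer(n_conv), filters = as.integer(filters),
              kernel = as.integer(kernel), n_lstm = as.integer(n_lstm),
              lstm_units = as.integer(lstm_units), l2 = l2, lr = lr,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              n_classes = as.integer(n_classes), seed = as.integer(seed))
  if (cfg$n_conv < 1) stop("need at least one convolutional layer")
  if (cfg$n_lstm < 0) stop("n_lstm must be >= 0")
  if (cfg$kernel %% 2 != 1) stop("kernel size must be odd")
  if (cfg$l2 <= 0 || cfg$lr <= 0) stop("rates must be positive")
  if (!cfg$n_classes %in% c(2L, 3L)) stop("n_classes must be 2 or 3")
  structure(cfg, class = "model_config")
}

#' @rdname ha_config
#' @param ... Overrides passed to [ha_config()].
#' @details `desk_config()` is a reduced-capacity configuration (3
#'   convolutional layers of 16 filters, 2 LSTM layers of 24 units, 12
#'   training epochs) for laptop-scale experiments and the synthetic
#'   validation runs.
#' @export
desk_config <- function(...) {
  do.call(ha_config, utils::modifyList(
    list(n_conv = 3, filters = 16, n_lstm = 2, lstm_units = 24,
         max_epochs = 12, patience = 12, batch_size = 256), list(...)))
}

#' Build the model specification
#'
#' Instantiates the layer stack of a configuration for a given channel
#' count, with seeded Glorot initialization.
#'
#' @param cfg A [ha_config()].
#' @param n_channels Input channels (1 for count-only, 18 for
#'   count + 17 HRV metrics).
#' @return List of class `model_spec` with `layers`, `cfg`,
#'   `n_channels`, and `n_parameters`.
#' @export
build_deepconvlstm <- function(cfg, n_channels) {
  stopifnot(inherits(cfg, "model_config"))
  layers <- withr::with_seed(cfg$seed, nn_init_layers(cfg, n_channels))
  structure(list(layers = layers, cfg = cfg, n_channels = n_channels,
                 n_parameters = count_parameters(cfg, n_channels)),
            class = "model_spec")
}

#' Forward pass of an (un)trained model
#'
#' @param spec A `model_spec` or `trained_model`.
#' @param x Window array `(N, 21, C)`.
#' @return Probability matrix: one column (binary, P(sleep-positive
#'   class)) or `n_classes` columns summing to 1.
#' @export
model_forward <- function(spec, x) {
  layers <- if (inherits(spec, "trained_model")) spec$layers else spec$layers
  cfg <- spec$cfg
  nn_forward(layers, x, cfg$n_classes, train = FALSE)$probs
}

# ---- windows -----------------------------------------------------------

#' Per-epoch channel matrix for one record
#'
#' Column 1 is the activity count; the 17 HRV metric columns follow
#' when a feature data frame is supplied (count-only mode otherwise).
#'
#' @param rec A [subject_record()].
#' @param hrv Optional [hrv_per_epoch()] data frame for the record.
#' @return Numeric matrix `n_epochs x C` with named columns.
#' @export
epoch_channels <- function(rec, hrv = NULL) {
  m <- cbind(activity = rec$epochs$activity_count)
  if (!is.null(hrv)) {
    if (nrow(hrv) != nrow(rec$epochs)) {
      stop("HRV features and epoch grid are misaligned")
    }
    m <- cbind(m, as.matrix(hrv[, hrv_metric_names()]))
  }
  m
}

#' Channel normalization statistics
#'
#' Per-channel mean and SD pooled over the supplied (training)
#' channel matrices, ignoring missing values. Computed on training
#' subjects only and reused verbatim at validation/test time.
#'
#' @param channel_list List of matrices from [epoch_channels()].
#' @return List of class `channel_stats` with `mean` and `sd`.
#' @export
channel_stats <- function(channel_list) {
  all <- do.call(rbind, channel_list)
  mu <- colMeans(all, na.rm = TRUE)
  sd_ <- apply(all, 2, stats::sd, na.rm = TRUE)
  unobserved <- colnames(all)[is.nan(mu)]
  if (length(unobserved)) {
    # e.g. VLF metrics under a 30-s window, which never spans enough
    # signal: carried as zero-after-standardization channels
    warning("channel(s) unobserved in training data (imputed to zero): ",
            paste(unobserved, collapse = ", "))
    mu[is.nan(mu)] <- 0
  }
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  structure(list(mean = mu, sd = sd_, unobserved = unobserved),
            class = "channel_stats")
}

#' Build classifier input windows for one record
#'
#' One window per scoreable epoch: the 21 rows are the channel vectors
#' of epochs `n - 10 ... n + 10` (configurable half-width), with record
#' edges padded by replicating the terminal epoch's channels. Channels
#' are standardized with the supplied training-set statistics and
#' missing values imputed to the (standardized) channel mean, so
#' windows are finite.
#'
#' @param channels Matrix from [epoch_channels()].
#' @param stats A [channel_stats()] (from training subjects).
#' @param half_width Epochs on each side of the center (default 10).
#' @return Array `(n_epochs, 2 * half_width + 1, C)`.
#' @export
build_windows <- function(channels, stats, half_width = 10) {
  stopifnot(inherits(stats, "channel_stats"))
  empty <- colnames(channels)[colSums(!is.na(channels)) == 0]
  bad <- setdiff(empty, stats$unobserved)
  if (length(bad)) {
    stop("channel(s) entirely missing: ", paste(bad, collapse = ", "))
  }
  x <- sweep(sweep(channels, 2, stats$mean), 2, stats$sd, `/`)
  x[is.na(x)] <- 0
  n <- nrow(x); C <- ncol(x); T <- 2L * half_width + 1L
  out <- array(0, c(n, T, C))
  for (o in -half_width:half_width) {
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)
    out[, o + half_width + 1L, ] <- x[idx, , drop = FALSE]
  }
  out
}

#' Windows, labels and subject ids for a cohort
#'
#' @param records List of [subject_record()]s.
#' @param hrv_list Optional named list of [hrv_per_epoch()] frames
#'   (count-only channels when `NULL`).
#' @param stats A [channel_stats()] computed on the training subjects.
#' @param n_classes 2 or 3 — controls the returned label alphabet.
#' @param half_width Window half-width.
#' @return List: `x` array `(N, 21, C)`, `y` label vector, `subject`
#'   id vector.
#' @export
cohort_windows <- function(records, hrv_list = NULL, stats, n_classes = 3,
                           half_width = 10) {
  xs <- list(); ys <- list(); ss <- list()
  for (rec in records) {
    ch <- epoch_channels(rec, hrv_list[[rec$subject]])
    xs[[rec$subject]] <- build_windows(ch, stats, half_width)
    ys[[rec$subject]] <- if (n_classes == 3) {
      collapse_stages(rec$epochs$psg_stage, "three")
    } else {
      collapse_stages(rec$epochs$psg_stage, "binary")
    }
    ss[[rec$subject]] <- rep(rec$subject, nrow(rec$epochs))
  }
  n_tot <- sum(vapply(xs, function(a) dim(a)[1], numeric(1)))
  d1 <- dim(xs[[1]])
  x <- array(0, c(n_tot, d1[2], d1[3]))
  at <- 0L
  for (a in xs) {
    x[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  list(x = x, y = unlist(ys, use.names = FALSE),
       subject = unlist(ss, use.names = FALSE))
}

class_levels <- function(n_classes) {
  if (n_classes == 2) c("wake", "sleep") else STAGES3
}

# ---- training ----------------------------------------------------------

#' Train the Conv-LSTM sleep scorer
#'
#' Minibatch Adam with class weights inversely proportional to epoch
#' frequencies, validation loss evaluated after every training epoch,
#' and min-validation-loss checkpointing: the returned weights are the
#' ones from the epoch with the lowest validation loss. Training and
#' validation sets must come from disjoint subjects (split by subject,
#' never by epoch); overlap is a hard error.
#'
#' @param spec A [build_deepconvlstm()] model spec.
#' @param data A [cohort_windows()] list (`x`, `y`, `subject`).
#' @param train_subjects,val_subjects Disjoint subject id vectors.
#' @param stats The [channel_stats()] used to build the windows
#'   (stored for reuse at inference).
#' @param verbose Print per-epoch losses.
#' @return List of class `trained_model`: `layers` (best weights),
#'   `cfg`, `history` (per-epoch train/val loss), `best_epoch`,
#'   `stats`, `levels`, `n_channels`.
#' @export
train_model <- function(spec, data, train_subjects, val_subjects,
                        stats = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(intersect(train_subjects, val_subjects)) > 0) {
    stop("subject leakage: train and validation subject sets overlap")
  }
  cfg <- spec$cfg
  lev <- class_levels(cfg$n_classes)
  tr <- which(data$subject %in% train_subjects)
  va <- which(data$subject %in% val_subjects)
  if (!length(tr) || !length(va)) stop("empty train or validation set")
  y_idx <- match(data$y, lev)
  if (anyNA(y_idx)) stop("labels outside the model's class alphabet")
  freq <- tabulate(y_idx[tr], nbins = length(lev))
  cw <- ifelse(freq > 0, sum(freq) / (length(lev) * pmax(freq, 1)), 0)
  x_va <- data$x[va, , , drop = FALSE]
  y_va <- y_idx[va]
  w_va <- cw[y_va]

  layers <- spec$layers
  opt <- adam_init(layers)
  hist_tr <- numeric(0); hist_va <- numeric(0)
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  step <- 0L
  withr::with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$max_epochs)) {
      ord <- sample(tr)
      ep_loss <- 0; n_b <- 0L
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        r <- nn_loss_grad(layers, data$x[bi, , , drop = FALSE], y_idx[bi],
                          cfg$n_classes, cw[y_idx[bi]], cfg$l2)
        layers <- r$layers
        step <- step + 1L
        u <- adam_step(layers, r$grads, opt, cfg$lr, step)
        layers <- u$layers; opt <- u$opt
        ep_loss <- ep_loss + r$loss; n_b <- n_b + 1L
      }
      val_loss <- eval_loss(layers, x_va, y_va, w_va, cfg$n_classes)
      hist_tr <- c(hist_tr, ep_loss / n_b)
      hist_va <- c(hist_va, val_loss)
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %.4f", ep,
                        ep_loss / n_b, val_loss))
      }
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, layers = layers, epoch = ep)
      }
      if (ep - best$epoch >= cfg$patience) break
    }
  })
  structure(list(layers = best$layers, cfg = cfg,
                 history = data.frame(epoch = seq_along(hist_tr),
                                      train_loss = hist_tr,
                                      val_loss = hist_va),
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 stats = stats, levels = lev,
                 n_channels = spec$n_channels),
            class = "trained_model")
}

eval_loss <- function(layers, x, y_idx, w, n_classes, chunk = 2048L) {
  n <- dim(x)[1]
  tot <- 0
  eps <- 1e-12
  for (b0 in seq(1, n, by = chunk)) {
    bi <- b0:min(b0 + chunk - 1L, n)
    p <- nn_forward(layers, x[bi, , , drop = FALSE], n_classes,
                    train = FALSE)$probs
    if (n_classes == 2) {
      yb <- as.numeric(y_idx[bi] == 2L)
      tot <- tot + sum(-w[bi] * (yb * log(p[, 1] + eps) +
                                   (1 - yb) * log(1 - p[, 1] + eps)))
    } else {
      tot <- tot + sum(-w[bi] * log(p[cbind(seq_along(bi), y_idx[bi])] + eps))
    }
  }
  tot / n
}

#' Score windows with a trained model
#'
#' @param tm A [train_model()] result.
#' @param x Window array `(N, 21, C)` built with the model's stored
#'   normalization statistics.
#' @return List of class `scored_hypnogram`: `labels` (argmax class
#'   per epoch), `sleep_wake` (binary collapse), `probs`.
#' @export
predict_stages <- function(tm, x) {
  stopifnot(inherits(tm, "trained_model"))
  if (dim(x)[3] != tm$n_channels) {
    stop("window channel count (", dim(x)[3], ") does not match model (",
         tm$n_channels, ")")
  }
  n <- dim(x)[1]
  probs <- NULL
  for (b0 in seq(1, n, by = 2048L)) {
    bi <- b0:min(b0 + 2047L, n)
    p <- nn_forward(tm$layers, x[bi, , , drop = FALSE], tm$cfg$n_classes,
                    train = FALSE)$probs
    probs <- rbind(probs, p)
  }
  if (tm$cfg$n_classes == 2) {
    labels <- ifelse(probs[, 1] >= 0.5, "sleep", "wake")
    sw <- labels
  } else {
    colnames(probs) <- tm$levels
    labels <- tm$levels[max.col(probs, ties.method = "first")]
    sw <- collapse_stages(labels, "binary")
  }
  structure(list(labels = labels, sleep_wake = sw, probs = probs),
            class = "scored_hypnogram")
}

# ---- experiments -------------------------------------------------------

#' Partition subjects into k cross-validation folds
#'
#' @param ids Subject id vector.
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return List of k disjoint id vectors whose union is `ids`.
#' @export
subject_folds <- function(ids, k = 5, seed = 1L) {
  ids <- unique(ids)
  perm <- withr::with_seed(seed, sample(ids))
  split(perm, rep_len(seq_len(k), length(perm)))
}

#' Random hyperparameter search
#'
#' Samples `n_cnn` pure-CNN and `n_dclstm` Conv-LSTM configurations
#' from the hyperparameter space (regularization rate, learning rate,
#' number of convolution layers, filters per layer, hidden units,
#' number of LSTM layers), trains each briefly, ranks them by
#' validation loss, and re-scores the top `top_k` by subject-level
#' k-fold cross-validation.
#'
#' @param data A [cohort_windows()] list.
#' @param train_subjects,val_subjects Disjoint subject sets for the
#'   screening stage.
#' @param n_cnn,n_dclstm Candidates per family (desk default 5 + 5).
#' @param space Named list of sampling ranges: `n_conv`, `filters`,
#'   `n_lstm`, `lstm_units` (integer vectors), `l2`, `lr` (log-uniform
#'   ranges, length 2).
#' @param top_k Candidates re-scored with cross-validation.
#' @param cv_folds Folds for the re-scoring stage.
#' @param search_epochs Training epochs per screening run.
#' @param n_classes Passed to each candidate config.
#' @param seed Seed controlling sampling, initialization and batching.
#' @return Data frame ranked by screening validation loss with columns
#'   for each hyperparameter, `family`, `val_loss`, and `cv_loss`
#'   (`NA` outside the top `top_k`).
#' @export
random_search <- function(data, train_subjects, val_subjects,
                          n_cnn = 5, n_dclstm = 5,
                          space = list(n_conv = 1:4, filters = c(8, 16, 32),
                                       n_lstm = 1:3, lstm_units = c(8, 16, 32),
                                       l2 = c(1e-5, 1e-3), lr = c(3e-4, 3e-3)),
                          top_k = 3, cv_folds = 5, search_epochs = 3,
                          n_classes = 3, seed = 7L) {
  if (n_cnn + n_dclstm < 1) stop("need at least one candidate")
  draws <- withr::with_seed(seed, {
    fam <- c(rep("cnn", n_cnn), rep("dclstm", n_dclstm))
    lapply(seq_along(fam), function(i) {
      list(family = fam[i],
           n_conv = sample(space$n_conv, 1),
           filters = sample(space$filters, 1),
           n_lstm = if (fam[i] == "cnn") 0L else sample(space$n_lstm, 1),
           lstm_units = sample(space$lstm_units, 1),
           l2 = exp(stats::runif(1, log(space$l2[1]), log(space$l2[2]))),
           lr = exp(stats::runif(1, log(space$lr[1]), log(space$lr[2]))))
    })
  })
  n_ch <- dim(data$x)[3]
  run_one <- function(d, tr_ids, va_ids, cfg_seed) {
    cfg <- ha_config(n_conv = d$n_conv, filters = d$filters,
                     n_lstm = d$n_lstm, lstm_units = d$lstm_units,
                     l2 = d$l2, lr = d$lr, max_epochs = search_epochs,
                     patience = search_epochs, batch_size = 256,
                     n_classes = n_classes, seed = cfg_seed)
    tm <- train_model(build_deepconvlstm(cfg, n_ch), data, tr_ids, va_ids)
    tm$best_val_loss
  }
  val_loss <- vapply(seq_along(draws), function(i) {
    run_one(draws[[i]], train_subjects, val_subjects, seed + i)
  }, numeric(1))
  res <- cbind(data.frame(candidate = seq_along(draws),
                          family = vapply(draws, `[[`, "", "family")),
               do.call(rbind, lapply(draws, function(d) {
                 data.frame(n_conv = d$n_conv, filters = d$filters,
                            n_lstm = d$n_lstm, lstm_units = d$lstm_units,
                            l2 = d$l2, lr = d$lr)
               })),
               val_loss = val_loss, cv_loss = NA_real_)
  res <- res[order(res$val_loss), ]
  all_ids <- unique(c(train_subjects, val_subjects))
  folds <- subject_folds(all_ids, k = cv_folds, seed = seed)
  for (r in seq_len(min(top_k, nrow(res)))) {
    d <- draws[[res$candidate[r]]]
    fold_loss <- vapply(seq_along(folds), function(f) {
      run_one(d, setdiff(all_ids, folds[[f]]), folds[[f]],
              seed + 1000L + res$candidate[r])
    }, numeric(1))
    res$cv_loss[r] <- mean(fold_loss)
  }
  rownames(res) <- NULL
  res
}

#' Compare input feature sets (count-only vs count + HRV windows)
#'
#' The window-length experiment: trains one model per feature set —
#' activity count only, count + 30-s HRV, count + 3-min HRV, count +
#' 5-min HRV — on the training subjects and evaluates each on held-out
#' test subjects. Reports per-feature-set mean and 95% CI of
#' sleep/wake accuracy, sensitivity, specificity and kappa across test
#' subjects, plus the mean three-class kappa.
#'
#' @param records Cohort list from [simulate_cohort()] (or loaded).
#' @param cfg A [ha_config()] used for every feature set.
#' @param feature_sets Character subset of
#'   `c("count", "count+30s", "count+3min", "count+5min")`.
#' @param split A [train_test_split()] list; defaults to a 65/35 split
#'   seeded from `cfg$seed`.
#' @param val_frac Fraction of training subjects held out as the
#'   validation set (for checkpointing).
#' @return List: `table` (one row per feature set: metric means and CI
#'   bounds, `kappa3`), `models` (named list of trained models),
#'   `per_subject` (long data frame of per-subject metrics).
#' @export
compare_feature_sets <- function(records, cfg = desk_config(),
                                 feature_sets = c("count", "count+30s",
                                                  "count+3min", "count+5min"),
                                 split = NULL, val_frac = 0.25) {
  ids <- vapply(records, `[[`, character(1), "subject")
  names(records) <- ids
  if (is.null(split)) split <- train_test_split(ids, seed = cfg$seed)
  n_val <- max(1L, round(val_frac * length(split$train)))
  val_ids <- split$train[seq_len(n_val)]
  tr_ids <- setdiff(split$train, val_ids)
  win_of <- c("count+30s" = 30, "count+3min" = 180, "count+5min" = 300)
  hrv_cache <- list()
  rows <- list(); models <- list(); per_subj <- list()
  for (fs in feature_sets) {
    hrv_list <- NULL
    if (fs %in% names(win_of)) {
      wl <- as.character(win_of[[fs]])
      if (is.null(hrv_cache[[wl]])) {
        hrv_cache[[wl]] <- cohort_hrv(records, window_len = win_of[[fs]])
      }
      hrv_list <- hrv_cache[[wl]]
    }
    ch_train <- lapply(records[tr_ids], function(r) {
      epoch_channels(r, hrv_list[[r$subject]])
    })
    stats <- channel_stats(ch_train)
    data <- cohort_windows(records, hrv_list, stats,
                           n_classes = cfg$n_classes)
    spec <- build_deepconvlstm(cfg, dim(data$x)[3])
    tm <- train_model(spec, data, tr_ids, val_ids, stats = stats)
    models[[fs]] <- tm
    m <- matrix(NA_real_, length(split$test), 5,
                dimnames = list(split$test,
                                c("accuracy", "sensitivity", "specificity",
                                  "kappa", "kappa3")))
    for (sid in split$test) {
      sel <- data$subject == sid
      pred <- predict_stages(tm, data$x[sel, , , drop = FALSE])
      ref <- records[[sid]]$epochs$psg_stage
      m[sid, 1:4] <- epoch_metrics(ref, pred$sleep_wake, "sleep")
      m[sid, 5] <- if (cfg$n_classes == 3) {
        multiclass_kappa(collapse_stages(ref, "three"), pred$labels)
      } else NA_real_
    }
    sm <- apply(m, 2, summarize_subjects)
    rows[[fs]] <- data.frame(
      feature_set = fs,
      accuracy = sm["mean", "accuracy"],
      accuracy_lo = sm["lower", "accuracy"], accuracy_hi = sm["upper", "accuracy"],
      sensitivity = sm["mean", "sensitivity"],
      sensitivity_lo = sm["lower", "sensitivity"],
      sensitivity_hi = sm["upper", "sensitivity"],
      specificity = sm["mean", "specificity"],
      specificity_lo = sm["lower", "specificity"],
      specificity_hi = sm["upper", "specificity"],
      kappa = sm["mean", "kappa"],
      kappa_lo = sm["lower", "kappa"], kappa_hi = sm["upper", "kappa"],
      kappa3 = sm["mean", "kappa3"])
    per_subj[[fs]] <- data.frame(feature_set = fs, subject = rownames(m), m,
                                 row.names = NULL)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       models = models,
       per_subject = do.call(rbind, c(per_subj, list(make.row.names = FALSE))),
       split = split)
}

#' Save / load a trained model
#'
#' The weights are serialized with `saveRDS`; a JSON sidecar
#' (`<path>.json`) records the configuration and normalization
#' statistics for inspection.
#'
#' @param tm A [train_model()] result.
#' @param path Output path (`.rds`).
#' @return `load_trained_model()` returns the `trained_model`.
#' @export
save_trained_model <- function(tm, path) {
  stopifnot(inherits(tm, "trained_model"))
  saveRDS(tm, path)
  sidecar <- list(cfg = unclass(tm$cfg), levels = tm$levels,
                  n_channels = tm$n_channels, best_epoch = tm$best_epoch,
                  stats = if (!is.null(tm$stats)) {
                    list(mean = as.list(tm$stats$mean), sd = as.list(tm$stats$sd))
                  })
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_trained_model
#' @export
load_trained_model <- function(path) {
  tm <- readRDS(path)
  stopifnot(inherits(tm, "trained_model"))
  tm
}
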