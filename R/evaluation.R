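#' Epoch-by-epoch agreement metrics
#'
#' Confusion-matrix agreement between a reference and a predicted
#' hypnogram for a stated positive class, reported as percentages:
#' accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, and Cohen's kappa `(p_o - p_e)/(1 - p_e)` with
#' marginal-product chance agreement. Kappa is defined as 0 when either
#' rater is constant (`p_e = 1`). Undefined cells (no positives or no
#' negatives in the reference) yield `NA` for the affected metric.
#'
#' The positive class is matched one-vs-rest: `"sleep"` against wake,
#' or a stage (e.g. `"REM"`) against all other labels (NREM + wake).
#'
#' @param ref,pred Aligned label vectors of equal length (five-stage,
#'   three-stage or binary; both are collapsed as needed to decide
#'   membership in `positive_class`).
#' @param positive_class `"sleep"`, `"wake"`, `"REM"`, `"NREM"` or `"W"`.
#' @return Named numeric vector: accuracy, sensitivity, specificity,
#'   kappa (all in percent; kappa ranges from -100 to 100).
#' @export
epoch_metrics <- function(ref, pred, positive_class = "sleep") {
  ref <- unclass(ref); pred <- unclass(pred)
  if (length(ref) != length(pred)) {
    stop("ref and pred must have equal length")
  }
  as_pos <- function(x) {
    if (positive_class %in% c("sleep", "wake")) {
      collapse_stages(x, "binary") == positive_class
    } else {
      collapse_stages(x, "three") == positive_class
    }
  }
  r <- as_pos(ref); p <- as_pos(pred)
  keep <- !is.na(r) & !is.na(p)
  r <- r[keep]; p <- p[keep]
  n <- length(r)
  if (n == 0) stop("no scoreable epochs")
  tp <- sum(r & p); tn <- sum(!r & !p)
  fp <- sum(!r & p); fn <- sum(r & !p)
  acc <- 100 * (tp + tn) / n
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kap <- if (abs(1 - pe) < 1e-12) 0 else 100 * (po - pe) / (1 - pe)
  c(accuracy = acc, sensitivity = sens, specificity = spec, kappa = kap)
}

#' Multi-class Cohen's kappa
#'
#' Kappa over the full label alphabet (not one-vs-rest), in percent;
#' 0 when either rater is constant.
#'
#' @param ref,pred Aligned label vectors.
#' @return Kappa in percent.
#' @export
multiclass_kappa <- function(ref, pred) {
  ref <- unclass(ref); pred <- unclass(pred)
  if (length(ref) != length(pred)) stop("ref and pred must have equal length")
  lev <- union(unique(ref), unique(pred))
  tab <- table(factor(ref, lev), factor(pred, lev))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(0)
  100 * (po - pe) / (1 - pe)
}

#' Summarize per-subject metrics as mean and 95% CI
#'
#' Mean over subjects with a t-distribution confidence interval
#' (`mean +/- t_{0.975, n-1} * SD / sqrt(n)`). `NA`-valued subjects are
#' excluded and their count reported.
#'
#' @param values Numeric vector, one value per subject.
#' @param level Confidence level (default 0.95).
#' @param ci_method `"t"` (default) or `"normal"`.
#' @return Named vector: mean, lower, upper, n_used, n_excluded.
#'   CI bounds are `NA` when fewer than 2 defined values exist.
#' @export
summarize_subjects <- function(values, level = 0.95, ci_method = c("t", "normal")) {
  ci_method <- match.arg(ci_method)
  excl <- sum(is.na(values))
  x <- values[!is.na(values)]
  n <- length(x)
  m <- if (n > 0) mean(x) else NA_real_
  if (n < 2) {
    return(c(mean = m, lower = NA_real_, upper = NA_real_,
             n_used = n, n_excluded = excl))
  }
  q <- if (ci_method == "t") stats::qt(1 - (1 - level) / 2, n - 1)
       else stats::qnorm(1 - (1 - level) / 2)
  half <- q * stats::sd(x) / sqrt(n)
  c(mean = m, lower = m - half, upper = m + half, n_used = n, n_excluded = excl)
}

#' Bland–Altman method comparison
#'
#' Paired differences `d_i = ref_i - est_i` (reference minus device
#' estimate, so a positive bias means the device underestimates the
#' reference). Reports the bias with its 95% CI and paired-t p value,
#' the 95% limits of agreement `bias +/- 1.96 * SD(d)`, an ordinary
#' least-squares proportional-trend test of `d` on the pair means
#' `(ref + est)/2`, and the mean absolute error.
#'
#' @param ref_vals,est_vals Paired numeric vectors (n >= 3).
#' @param parameter Optional parameter name carried into the result.
#' @return List of class `ba_result`: bias, ci (length 2), loa
#'   (length 2), t_p, slope, slope_p, mae, n, parameter, and the
#'   difference/mean vectors for plotting.
#' @export
bland_altman <- function(ref_vals, est_vals, parameter = "parameter") {
  if (length(ref_vals) != length(est_vals)) {
    stop("ref_vals and est_vals must be paired (equal length)")
  }
  keep <- !is.na(ref_vals) & !is.na(est_vals)
  ref_vals <- ref_vals[keep]; est_vals <- est_vals[keep]
  n <- length(ref_vals)
  if (n < 3) stop("Bland-Altman needs at least 3 pairs")
  d <- ref_vals - est_vals
  m <- (ref_vals + est_vals) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  half <- stats::qt(0.975, n - 1) * sdd / sqrt(n)
  t_p <- if (sdd > 0) stats::t.test(d)$p.value else if (abs(bias) > 0) 0 else 1
  if (stats::var(m) > 0) {
    fit <- stats::lm(d ~ m)
    slope <- unname(stats::coef(fit)[2])
    # a zero-residual fit (constant offset) makes the slope test moot
    slope_p <- suppressWarnings(summary(fit)$coefficients[2, 4])
  } else {
    slope <- 0; slope_p <- NA_real_
  }
  structure(list(parameter = parameter, n = n, bias = bias,
                 ci = c(bias - half, bias + half),
                 loa = c(bias - 1.96 * sdd, bias + 1.96 * sdd),
                 sd = sdd, t_p = t_p, slope = slope, slope_p = slope_p,
                 mae = mean(abs(d)), diffs = d, means = m),
            class = "ba_result")
}

#' @export
print.ba_result <- function(x, ...) {
  cat(sprintf(
    "<Bland-Altman: %s> n=%d bias=%.2f (95%% CI %.2f, %.2f) LoA [%.2f, %.2f] MAE=%.2f trend slope=%.3f (p=%.3g)\n",
    x$parameter, x$n, x$bias, x$ci[1], x$ci[2], x$loa[1], x$loa[2],
    x$mae, x$slope, x$slope_p))
  invisible(x)
}

#' Bland–Altman plot
#'
#' Pair means on the x axis, reference-minus-estimate differences on
#' the y axis, a solid bias line and dashed limits of agreement.
#'
#' @param ba A [bland_altman()] result.
#' @return A ggplot object.
#' @export
bland_altman_plot <- function(ba) {
  df <- data.frame(mean = ba$means, diff = ba$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$bias, linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = ba$loa, linetype = "dashed") +
    ggplot2::labs(x = sprintf("Mean of methods (%s)", ba$parameter),
                  y = "Reference - estimate",
                  title = sprintf("Bland-Altman: %s", ba$parameter)) +
    ggplot2::theme_minimal()
}

#' Compare the biases of two scorers
#'
#' `d = |mean(diffs_1) - mean(diffs_2)|` and a paired t-test on
#' `diffs_1 - diffs_2` (the same subjects scored by both methods).
#'
#' @param diffs_1,diffs_2 Reference-minus-estimate difference vectors
#'   over the same subjects, in the same order.
#' @return Named vector `d`, `p`.
#' @export
compare_bias <- function(diffs_1, diffs_2) {
  if (length(diffs_1) != length(diffs_2)) {
    stop("difference vectors must cover the same subjects")
  }
  delta <- diffs_1 - diffs_2
  d <- abs(mean(delta))
  p <- if (stats::sd(delta) > 0) stats::t.test(delta)$p.value
       else if (d > 0) 0 else 1
  c(d = d, p = p)
}
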