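#' Confusion matrix at a diagnostic FFR threshold
#'
#' Cross-tabulates estimated against reference FFR at the clinical
#' ischemia threshold. A vessel is positive (ischemic) when its FFR is
#' less than or equal to the threshold; the comparison is inclusive, so a
#' value of exactly 0.8 is positive.
#'
#' @param estimates numeric vector of estimated FFR.
#' @param references numeric vector of reference (invasive) FFR, same
#'   length.
#' @param threshold diagnostic cut-off (default 0.8).
#' @return a `confusion_counts` list with integer `tp`, `fp`, `fn`, `tn`
#'   (positive class = reference at or below threshold).
#' @export
#' @examples
#' confusion_at_threshold(c(0.7, 0.9, 0.75), c(0.72, 0.88, 0.85))
confusion_at_threshold <- function(estimates, references, threshold = 0.8) {
  if (length(estimates) != length(references))
    stop("estimates and references must have equal length", call. = FALSE)
  if (length(estimates) == 0L)
    stop("empty input", call. = FALSE)
  est_pos <- estimates <= threshold
  ref_pos <- references <= threshold
  structure(list(tp = sum(est_pos & ref_pos),
                 fp = sum(est_pos & !ref_pos),
                 fn = sum(!est_pos & ref_pos),
                 tn = sum(!est_pos & !ref_pos)),
            class = "confusion_counts")
}

#' Diagnostic performance metrics from a 2x2 table
#'
#' Sensitivity, specificity, positive and negative predictive value and
#' accuracy, as percentages. A metric with a zero denominator is reported
#' as `NA` (not available), never as 0. Full precision is retained; round
#' only for display.
#'
#' @param counts a `confusion_counts` from [confusion_at_threshold()], or
#'   a list with `tp`, `fp`, `fn`, `tn`.
#' @return a `diagnostic_metrics` list: `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `accuracy` (percent), and `n`.
#' @export
#' @examples
#' diagnostic_metrics(list(tp = 30, fp = 4, fn = 2, tn = 50))
diagnostic_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  n <- tp + fp + fn + tn
  if (n == 0L) stop("empty confusion table", call. = FALSE)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(list(sensitivity = pct(tp, tp + fn),
                 specificity = pct(tn, tn + fp),
                 ppv = pct(tp, tp + fp),
                 npv = pct(tn, tn + fn),
                 accuracy = pct(tp + tn, n),
                 n = n),
            class = "diagnostic_metrics")
}

#' Bland-Altman agreement summary
#'
#' Mean difference (estimate minus reference), its standard deviation
#' (n - 1 denominator) and the 95% limits of agreement
#' `mean +/- 1.96 sd`.
#'
#' @param estimates,references paired numeric vectors, length >= 2.
#' @return a `bland_altman` list: `mean_diff`, `sd_diff`, `lower`,
#'   `upper`, `n`, and the per-pair `differences`.
#' @export
bland_altman <- function(estimates, references) {
  if (length(estimates) != length(references))
    stop("estimates and references must have equal length", call. = FALSE)
  if (length(estimates) < 2L)
    stop("Bland-Altman requires at least 2 pairs", call. = FALSE)
  d <- estimates - references
  m <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = m, sd_diff = s,
                 lower = m - 1.96 * s, upper = m + 1.96 * s,
                 n = length(d), differences = d),
            class = "bland_altman")
}

#' Area under the ROC curve for FFR estimates
#'
#' AUC as the Mann-Whitney concordance probability, computed from the rank
#' statistic with ties counted one half. Scores are oriented so that a
#' LOWER estimated FFR indicates disease (the estimate is negated before
#' ranking), so a perfect estimator scores 1. An optional seeded bootstrap
#' gives a percentile confidence interval.
#'
#' @param estimates numeric FFR estimates.
#' @param labels logical (or 0/1) disease labels, `TRUE` = diseased
#'   (reference FFR at or below threshold). Both classes must be present.
#' @param ci logical; compute a bootstrap confidence interval.
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return a `roc_auc` list: `auc`, `n_pos`, `n_neg`, and `ci_lower`,
#'   `ci_upper` when requested.
#' @export
roc_auc <- function(estimates, labels, ci = FALSE, n_boot = 2000L,
                    conf = 0.95, seed = 1L) {
  labels <- as.logical(labels)
  if (length(estimates) != length(labels))
    stop("estimates and labels must have equal length", call. = FALSE)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  auc1 <- function(score, lab) {
    r <- rank(score)  # midranks handle ties as 1/2
    (sum(r[lab]) - sum(lab) * (sum(lab) + 1) / 2) / (sum(lab) * sum(!lab))
  }
  score <- -estimates  # lower FFR = more diseased = higher score
  out <- list(auc = auc1(score, labels), n_pos = n_pos, n_neg = n_neg)
  if (ci) {
    set.seed(seed)
    idx <- seq_along(score)
    boot <- replicate(n_boot, {
      k <- sample(idx, replace = TRUE)
      if (any(labels[k]) && any(!labels[k])) auc1(score[k], labels[k])
      else NA_real_
    })
    qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
    out$ci_lower <- qs[1]
    out$ci_upper <- qs[2]
  }
  structure(out, class = "roc_auc")
}

#' Full diagnostic report
#'
#' Convenience wrapper combining the 2x2 table, the derived metrics, the
#' Bland-Altman summary and the AUC for one method against the reference.
#'
#' @inheritParams confusion_at_threshold
#' @param threshold diagnostic cut-off (default 0.8).
#' @param auc_ci logical; bootstrap CI on the AUC.
#' @param seed seed for the bootstrap.
#' @return a `diagnostic_report` list: `counts`, `metrics`,
#'   `bland_altman`, `auc`, `threshold`.
#' @export
diagnostic_report <- function(estimates, references, threshold = 0.8,
                              auc_ci = FALSE, seed = 1L) {
  counts <- confusion_at_threshold(estimates, references, threshold)
  structure(list(counts = counts,
                 metrics = diagnostic_metrics(counts),
                 bland_altman = bland_altman(estimates, references),
                 auc = roc_auc(estimates, references <= threshold,
                               ci = auc_ci, seed = seed),
                 threshold = threshold),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", v)
  cat("sensitivity ", fmt(x$sensitivity),
      "  specificity ", fmt(x$specificity), "\n",
      "ppv         ", fmt(x$ppv),
      "  npv         ", fmt(x$npv), "\n",
      "accuracy    ", fmt(x$accuracy), "  (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @export
print.diagnostic_report <- function(x, ...) {
  c0 <- x$counts
  cat("Diagnostic report (threshold ", x$threshold, ")\n", sep = "")
  cat(sprintf("  2x2: TP %d  FP %d  FN %d  TN %d\n",
              c0$tp, c0$fp, c0$fn, c0$tn))
  print(x$metrics)
  ba <- x$bland_altman
  cat(sprintf("  Bland-Altman: mean %.4f, limits [%.4f, %.4f]\n",
              ba$mean_diff, ba$lower, ba$upper))
  cat(sprintf("  AUC: %.4f\n", x$auc$auc))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x a `bland_altman` object.
#' @param references optional reference vector for the x axis mean; if
#'   omitted the difference index is used.
#' @param estimates optional estimate vector paired with `references`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, references = NULL, estimates = NULL, ...) {
  xs <- if (!is.null(references) && !is.null(estimates))
    (references + estimates) / 2 else seq_along(x$differences)
  graphics::plot(xs, x$differences,
                 xlab = if (is.null(references)) "pair index"
                        else "mean of methods",
                 ylab = "difference (estimate - reference)", ...)
  graphics::abline(h = c(x$lower, x$mean_diff, x$upper),
                   lty = c(2, 1, 2), col = c("red", "blue", "red"))
  invisible(x)
}
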