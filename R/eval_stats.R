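# Diagnostic-evaluation statistics: confusion-matrix metrics with binomial
# CIs, ROC/AUC, segmentation IoU, Cohen's kappa, and the two-sided McNemar
# test.

#' Confusion counts
#'
#' @param TP,FP,FN,TN non-negative integer counts.
#' @return list of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, FP, FN, TN) {
  counts <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("confusion table is empty", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

counts_from_calls <- function(predictions, truth) {
  predictions <- as.logical(predictions); truth <- as.logical(truth)
  confusion_counts(TP = sum(predictions & truth),
                   FP = sum(predictions & !truth),
                   FN = sum(!predictions & truth),
                   TN = sum(!predictions & !truth))
}

#' The five diagnostic proportion metrics
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, PPV `TP/(TP+FP)`, NPV `TN/(TN+FN)`. A metric whose
#' denominator is zero is reported as `NA` (undefined), never as 0.
#'
#' @param counts a [confusion_counts()] object.
#' @return named numeric vector of the five estimates.
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  with(counts, c(
    accuracy = ratio(TP + TN, TP + FP + FN + TN),
    sensitivity = ratio(TP, TP + FN),
    specificity = ratio(TN, TN + FP),
    ppv = ratio(TP, TP + FP),
    npv = ratio(TN, TN + FN)
  ))
}

#' Binomial confidence interval
#'
#' `clopper_pearson` inverts the binomial tail tests exactly (beta-quantile
#' form); `wald` is the normal approximation `p +/- z * sqrt(p(1-p)/n)`,
#' clipped to \[0, 1\].
#'
#' @param successes,n number of successes and trials (`0 <= successes <= n`).
#' @param level confidence level in (0, 1), default 0.95.
#' @param method `"clopper_pearson"` (default) or `"wald"`.
#' @return named vector `c(low, high)`.
#' @export
binomial_ci <- function(successes, n, level = 0.95,
                        method = c("clopper_pearson", "wald")) {
  method <- match.arg(method)
  if (!is.finite(level) || level <= 0 || level >= 1) {
    stop("level must be in (0, 1)", call. = FALSE)
  }
  if (n <= 0 || successes < 0 || successes > n) {
    stop("need 0 <= successes <= n with n > 0", call. = FALSE)
  }
  alpha <- 1 - level
  if (method == "clopper_pearson") {
    low <- if (successes == 0) 0 else qbeta(alpha / 2, successes, n - successes + 1)
    high <- if (successes == n) 1 else qbeta(1 - alpha / 2, successes + 1, n - successes)
  } else {
    p <- successes / n
    z <- qnorm(1 - alpha / 2)
    half <- z * sqrt(p * (1 - p) / n)
    low <- max(0, p - half)
    high <- min(1, p + half)
  }
  c(low = low, high = high)
}

#' ROC curve and AUC
#'
#' The AUC is computed by pairwise concordance over all positive/negative
#' score pairs, with ties counting one half -- identical to trapezoidal
#' integration of the empirical ROC curve.
#'
#' @param scores continuous per-case scores (larger = more cancer-like).
#' @param labels logical (or 0/1) truth per case; both classes required.
#' @return list with `auc` and `curve` (data.frame of threshold, fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("NA in scores or labels", call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires both classes present", call. = FALSE)
  }
  # Mann-Whitney / rank form of pairwise concordance with half-tie credit
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  )
  list(auc = auc, curve = curve)
}

#' Intersection-over-union of two binary masks
#'
#' `|A inter B| / |A union B|`; defined as 1 when both masks are empty
#' (agreement that no lesion is present).
#'
#' @param mask_a,mask_b binary matrices of identical shape.
#' @return value in \[0, 1\].
#' @export
iou <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("IoU requires masks of identical shape", call. = FALSE)
  }
  a <- mask_a > 0; b <- mask_b > 0
  union <- sum(a | b)
  if (union == 0) return(1)
  sum(a & b) / union
}

#' Median IoU over truth-positive images
#'
#' Segmentation performance is summarized over images whose ground truth
#' contains a lesion; truth-empty images are excluded from the median.
#'
#' @param predicted,truth lists of binary masks, aligned.
#' @return median IoU, or `NA` if no truth-positive image exists.
#' @export
median_iou <- function(predicted, truth) {
  pos <- vapply(truth, function(m) sum(m) > 0, logical(1))
  if (!any(pos)) return(NA_real_)
  median(mapply(iou, predicted[pos], truth[pos]))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the product of marginals. Undefined (`NA`) when both
#' raters are constant and identical (`p_e = 1`).
#'
#' @param ratings_a,ratings_b equal-length categorical vectors (>= 2 items).
#' @return kappa in \[-1, 1\], or `NA` when undefined.
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b) || length(ratings_a) < 2L) {
    stop("need two equal-length rating vectors with >= 2 items", call. = FALSE)
  }
  levels <- union(unique(ratings_a), unique(ratings_b))
  a <- factor(ratings_a, levels = levels)
  b <- factor(ratings_b, levels = levels)
  tab <- table(a, b) / length(a)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (1 - p_e < .Machine$double.eps * 100) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Two-sided McNemar test on discordant counts
#'
#' `exact`: binomial test of `b` successes in `b + c` trials at p = 0.5
#' (doubled smaller tail, capped at 1). `cc_chi2`: continuity-corrected
#' chi-square `(|b - c| - 1)^2 / (b + c)` on 1 df (no correction when
#' `b == c`). With `method = "auto"` the exact test is used when
#' `b + c < 25`.
#'
#' @param b,c discordant counts (case called positive by one classifier and
#'   negative by the other, and vice versa).
#' @param method `"auto"`, `"exact"`, or `"cc_chi2"`.
#' @return list with `p_value`, `method`, `b`, `c`.
#' @export
mcnemar_test <- function(b, c, method = c("auto", "exact", "cc_chi2")) {
  method <- match.arg(method)
  if (b < 0 || c < 0) stop("discordant counts must be non-negative", call. = FALSE)
  n <- b + c
  if (n == 0) {
    return(list(p_value = 1, method = "degenerate (no discordant pairs)",
                b = b, c = c))
  }
  if (method == "auto") method <- if (n < 25) "exact" else "cc_chi2"
  p <- if (method == "exact") {
    k <- min(b, c)
    tail <- pbinom(k, n, 0.5)
    if (b == c) 1 else min(1, 2 * tail)
  } else {
    # the continuity correction only applies when b != c, so that perfectly
    # balanced discordance keeps a zero statistic
    stat <- max(abs(b - c) - 1, 0)^2 / n
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(p_value = p, method = method, b = b, c = c)
}

metric_with_ci <- function(num, den, level, method) {
  if (den == 0) {
    return(list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                method = method, level = level))
  }
  ci <- binomial_ci(num, den, level, method)
  list(estimate = num / den, ci_low = unname(ci["low"]),
       ci_high = unname(ci["high"]), method = method, level = level)
}

#' Assemble a full diagnostic evaluation report
#'
#' Combines confusion counts, the five proportion metrics with binomial
#' confidence intervals, AUC (when continuous scores are given), median
#' segmentation IoU (when masks are given), Cohen's kappa and the McNemar
#' test (when a paired rater is given), with modality-stratified sub-reports
#' (all / WLI / NBI).
#'
#' @param predictions logical per-case cancer calls.
#' @param truth logical per-case ground truth.
#' @param scores optional continuous scores for ROC/AUC.
#' @param modality optional per-case `"WLI"`/`"NBI"` tags enabling
#'   stratified sub-reports.
#' @param masks optional list with `predicted` and `truth` mask lists for
#'   median IoU.
#' @param paired_rater optional second set of logical calls on the same
#'   cases (e.g. a laryngologist) for kappa and McNemar.
#' @param ci_method `"clopper_pearson"` (default) or `"wald"`.
#' @param level confidence level.
#' @return list of class `eval_report`.
#' @export
build_report <- function(predictions, truth, scores = NULL, modality = NULL,
                         masks = NULL, paired_rater = NULL,
                         ci_method = c("clopper_pearson", "wald"),
                         level = 0.95) {
  ci_method <- match.arg(ci_method)
  predictions <- as.logical(predictions); truth <- as.logical(truth)
  stopifnot(length(predictions) == length(truth))
  counts <- counts_from_calls(predictions, truth)
  report <- report_from_counts(counts, ci_method, level)
  if (!is.null(scores) && length(unique(truth)) == 2L) {
    report$auc <- roc_auc(scores, truth)$auc
  }
  if (!is.null(masks)) {
    report$median_iou <- median_iou(masks$predicted, masks$truth)
  }
  if (!is.null(paired_rater)) {
    paired_rater <- as.logical(paired_rater)
    correct_a <- predictions == truth
    correct_b <- paired_rater == truth
    report$kappa <- cohens_kappa(predictions, paired_rater)
    report$mcnemar <- mcnemar_test(sum(correct_a & !correct_b),
                                   sum(!correct_a & correct_b))
  }
  if (!is.null(modality)) {
    report$by_modality <- lapply(stats::setNames(MODALITIES, MODALITIES),
                                 function(m) {
      sel <- modality == m
      if (!any(sel)) return(NULL)
      sub <- build_report(predictions[sel], truth[sel],
                          scores = if (!is.null(scores) &&
                                       length(unique(truth[sel])) == 2L) {
                            scores[sel]
                          },
                          ci_method = ci_method, level = level)
      sub
    })
  }
  report
}

#' Report from a pre-computed confusion table
#'
#' @param counts a [confusion_counts()].
#' @param ci_method,level see [build_report()].
#' @return list of class `eval_report` with `counts` and the five
#'   [metric][confusion_metrics()] entries, each carrying an estimate and CI.
#' @export
report_from_counts <- function(counts,
                               ci_method = c("clopper_pearson", "wald"),
                               level = 0.95) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, structure(list(
    counts = counts,
    accuracy = metric_with_ci(TP + TN, TP + FP + FN + TN, level, ci_method),
    sensitivity = metric_with_ci(TP, TP + FN, level, ci_method),
    specificity = metric_with_ci(TN, TN + FP, level, ci_method),
    ppv = metric_with_ci(TP, TP + FP, level, ci_method),
    npv = metric_with_ci(TN, TN + FN, level, ci_method)
  ), class = "eval_report"))
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  fmt <- function(m) {
    if (is.na(m$estimate)) return("undefined")
    sprintf("%.*f (%.*f-%.*f)", digits, m$estimate, digits, m$ci_low,
            digits, m$ci_high)
  }
  cat("Diagnostic evaluation report\n")
  with(x$counts, cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", TP, FP, FN, TN)))
  for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
    cat(sprintf("  %-12s %s\n", nm, fmt(x[[nm]])))
  }
  if (!is.null(x$auc)) cat(sprintf("  %-12s %.3f\n", "auc", x$auc))
  if (!is.null(x$median_iou)) {
    cat(sprintf("  %-12s %.3f\n", "median IoU", x$median_iou))
  }
  if (!is.null(x$kappa)) cat(sprintf("  %-12s %.3f\n", "kappa", x$kappa))
  if (!is.null(x$mcnemar)) {
    cat(sprintf("  McNemar p = %.4g (%s)\n", x$mcnemar$p_value,
                x$mcnemar$method))
  }
  if (!is.null(x$by_modality)) {
    for (m in names(x$by_modality)) {
      if (is.null(x$by_modality[[m]])) next
      cat("-- ", m, " --\n", sep = "")
      print(x$by_modality[[m]], digits = digits)
    }
  }
  invisible(x)
}
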