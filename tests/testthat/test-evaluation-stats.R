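test_that("confusion metrics implement the five diagnostic proportions", {
  m <- confusion_metrics(confusion_counts(TP = 114, FP = 6, FN = 6, TN = 74))
  expect_equal(round(m[["accuracy"]], 3), 0.940)
  expect_equal(round(m[["sensitivity"]], 3), 0.950)
  expect_equal(round(m[["specificity"]], 3), 0.925)
  expect_equal(round(m[["ppv"]], 3), 0.950)
  expect_equal(round(m[["npv"]], 3), 0.925)

  # zero denominators are undefined, not zero
  m <- confusion_metrics(confusion_counts(TP = 0, FP = 0, FN = 0, TN = 10))
  expect_true(is.na(m[["sensitivity"]]))
  expect_true(is.na(m[["ppv"]]))
  expect_equal(m[["specificity"]], 1)

  m <- confusion_metrics(confusion_counts(TP = 5, FP = 0, FN = 0, TN = 5))
  expect_true(all(m == 1))

  expect_error(confusion_counts(-1, 0, 0, 2), "non-negative")
  expect_error(confusion_counts(0, 0, 0, 0), "empty")
})

test_that("binomial intervals: exact Clopper-Pearson and Wald approximation", {
  # boundary: zero successes pin the lower bound at exactly 0
  ci <- binomial_ci(0, 20, method = "clopper_pearson")
  expect_equal(ci[["low"]], 0)
  ci <- binomial_ci(20, 20, method = "clopper_pearson")
  expect_equal(ci[["high"]], 1)

  # Wald at z = 1.96 reproduces the printed 3-decimal intervals
  w <- binomial_ci(114, 120, method = "wald")
  expect_equal(round(unname(w), 3), c(0.911, 0.989))
  w <- binomial_ci(74, 80, method = "wald")
  expect_equal(round(unname(w), 3), c(0.867, 0.983))

  # Clopper-Pearson contains the point estimate and is wider than Wald at
  # the lower end for 188/200
  cp <- binomial_ci(188, 200, method = "clopper_pearson")
  w <- binomial_ci(188, 200, method = "wald")
  expect_lt(cp[["low"]], 0.94); expect_gt(cp[["high"]], 0.94)
  expect_lt(cp[["low"]], w[["low"]])

  expect_error(binomial_ci(5, 4), "successes")
  expect_error(binomial_ci(5, 10, level = 1.2), "level")
})

test_that("Clopper-Pearson equals brute-force inversion of the binomial tails", {
  for (n in c(10, 50, 120)) {
    for (x in unique(c(0, 1, round(n / 3), n - 1, n))) {
      got <- binomial_ci(x, n, method = "clopper_pearson")
      want <- oracle_cp_ci(x, n)
      expect_equal(unname(got), unname(want), tolerance = 1e-6)
    }
  }
})

test_that("Clopper-Pearson intervals achieve nominal coverage", {
  withr::local_seed(101)
  n <- 50
  for (p in c(0.1, 0.5, 0.9)) {
    x <- rbinom(2000, n, p)
    cover <- vapply(x, function(xi) {
      ci <- binomial_ci(xi, n, method = "clopper_pearson")
      ci[["low"]] <= p && p <= ci[["high"]]
    }, logical(1))
    mc_err <- sqrt(0.95 * 0.05 / 2000)
    expect_gte(mean(cover), 0.95 - 3 * mc_err)
  }
})

test_that("AUC by pairwise concordance, with the half-tie convention", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))$auc,
               0.5)
  # positives {0.9, 0.4}, negatives {0.5, 0.1}: 3 of 4 pairs concordant
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.1),
                       c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("pairwise AUC equals trapezoidal integration on random score sets", {
  withr::local_seed(55)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(roc_auc(scores, labels)$auc,
                 oracle_auc_trapezoid(scores, labels))
  }
})

test_that("AUC and kappa agree with independent reference implementations", {
  skip_if_not_installed("pROC")
  skip_if_not_installed("e1071")
  withr::local_seed(77)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    scores <- round(runif(n), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<",
                                          levels = c(FALSE, TRUE))))
    expect_equal(roc_auc(scores, labels)$auc, ref)
    a <- sample(c("x", "y", "z"), n, replace = TRUE)
    b <- sample(c("x", "y", "z"), n, replace = TRUE)
    ref_k <- e1071::classAgreement(table(factor(a, c("x", "y", "z")),
                                         factor(b, c("x", "y", "z"))))$kappa
    expect_equal(cohens_kappa(a, b), ref_k)
  }
})

test_that("IoU counts pixels with the empty-empty convention", {
  a <- matrix(0L, 6, 6); a[2:3, 2:3] <- 1L
  expect_equal(iou(a, a), 1)
  b <- matrix(0L, 6, 6); b[5:6, 5:6] <- 1L
  expect_equal(iou(a, b), 0)
  # 2x2 squares offset by one column: intersection 2, union 6
  c1 <- matrix(0L, 6, 6); c1[2:3, 2:3] <- 1L
  c2 <- matrix(0L, 6, 6); c2[2:3, 3:4] <- 1L
  expect_equal(iou(c1, c2), 1 / 3)
  expect_equal(iou(c2, c1), 1 / 3)
  expect_equal(iou(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)
  expect_error(iou(a, matrix(0L, 5, 5)), "shape")

  # median over truth-positive images only
  preds <- list(a, c2, b)
  truths <- list(a, c1, matrix(0L, 6, 6))
  expect_equal(median_iou(preds, truths), median(c(1, 1 / 3)))
  expect_true(is.na(median_iou(list(a), list(matrix(0L, 6, 6)))))
})

test_that("Cohen's kappa matches hand-computed agreement tables", {
  expect_equal(cohens_kappa(c(1, 2, 1, 2), c(1, 2, 1, 2)), 1)
  # 2x2 table a=45, b=5, c=5, d=45: p_o = 0.9, p_e = 0.5 -> kappa 0.8
  a <- rep(c("pos", "pos", "neg", "neg"), c(45, 5, 5, 45))
  b <- rep(c("pos", "neg", "pos", "neg"), c(45, 5, 5, 45))
  expect_equal(cohens_kappa(a, b), 0.8)
  # independence with matched marginals -> 0
  a0 <- rep(c("x", "x", "y", "y"), c(25, 25, 25, 25))
  b0 <- rep(c("x", "y", "x", "y"), c(25, 25, 25, 25))
  expect_equal(cohens_kappa(a0, b0), 0)
  # invariant under relabeling
  relab <- function(v) ifelse(v == "pos", "B", "A")
  expect_equal(cohens_kappa(relab(a), relab(b)), cohens_kappa(a, b))
  # both raters constant and identical: undefined
  expect_true(is.na(cohens_kappa(rep("z", 5), rep("z", 5))))
  expect_error(cohens_kappa(1:3, 1:4), "equal-length")
})

test_that("exact McNemar reproduces binomial-tail hand calculations", {
  expect_equal(mcnemar_test(7, 7, method = "exact")$p_value, 1)
  expect_equal(mcnemar_test(10, 0, method = "exact")$p_value, 2 * 0.5^10)
  expect_equal(mcnemar_test(2, 9, method = "exact")$p_value, 134 / 2048)
  expect_equal(mcnemar_test(0, 0)$p_value, 1)
  expect_match(mcnemar_test(0, 0)$method, "degenerate")
  expect_error(mcnemar_test(-1, 3), "non-negative")
})

test_that("exact McNemar equals exhaustive enumeration for b + c <= 12", {
  for (n in c(1, 2, 5, 8, 12)) {
    for (b in 0:n) {
      expect_equal(mcnemar_test(b, n - b, method = "exact")$p_value,
                   oracle_mcnemar_enum(b, n - b),
                   info = sprintf("b=%d c=%d", b, n - b))
    }
  }
})

test_that("continuity-corrected chi-square McNemar matches the reference test", {
  for (bc in list(c(15, 30), c(40, 25), c(10, 10))) {
    got <- mcnemar_test(bc[1], bc[2], method = "cc_chi2")$p_value
    tab <- matrix(c(5, bc[1], bc[2], 5), 2, 2)
    want <- stats::mcnemar.test(tab, correct = TRUE)$p.value
    expect_equal(got, want)
  }
  # auto switches to the exact test for small discordant totals
  expect_equal(mcnemar_test(3, 4)$method, "exact")
  expect_equal(mcnemar_test(30, 40)$method, "cc_chi2")
})

test_that("reports assemble metrics, AUC, IoU, kappa and stratification", {
  truth <- c(rep(TRUE, 6), rep(FALSE, 6))
  perfect <- truth
  scores <- c(runif(6, 0.6, 1), runif(6, 0, 0.4))
  modality <- rep(c("WLI", "NBI"), 6)
  rep1 <- build_report(perfect, truth, scores = scores, modality = modality)
  expect_equal(rep1$accuracy$estimate, 1)
  expect_equal(rep1$auc, 1)
  # stratified counts partition the pooled counts
  pooled <- unlist(rep1$counts[c("TP", "FP", "FN", "TN")])
  strat <- mapply(function(a, b) a + b,
                  unlist(rep1$by_modality$WLI$counts[c("TP", "FP", "FN", "TN")]),
                  unlist(rep1$by_modality$NBI$counts[c("TP", "FP", "FN", "TN")]))
  expect_equal(unname(pooled), unname(strat))

  # paired-rater wiring: kappa of identical raters is 1, McNemar p = 1
  rep2 <- build_report(perfect, truth, paired_rater = perfect)
  expect_equal(rep2$kappa, 1)
  expect_equal(rep2$mcnemar$p_value, 1)

  # CI method flows through to every metric
  rep3 <- report_from_counts(confusion_counts(114, 6, 6, 74),
                             ci_method = "wald")
  expect_equal(round(rep3$sensitivity$ci_low, 3), 0.911)
  expect_equal(round(rep3$sensitivity$ci_high, 3), 0.989)
  expect_output(print(rep3), "sensitivity")
})
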