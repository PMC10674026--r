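test_that("confusion counts partition the evaluated pixels", {
  gt <- matrix(0, 4, 4); gt[1, 1:4] <- 1                 # 4 vessel pixels
  pred <- matrix(0, 4, 4); pred[1, 1:3] <- 1; pred[2, 1:2] <- 1
  cm <- confusion(pred, gt)
  expect_equal(cm$TP, 3); expect_equal(cm$FN, 1)
  expect_equal(cm$FP, 2); expect_equal(cm$TN, 10)
  expect_equal(cm$TN + cm$FP + cm$FN + cm$TP, 16)

  # perfect prediction
  cmp <- confusion(gt, gt)
  expect_equal(cmp$FP + cmp$FN, 0)
  expect_equal(cmp$TP, 4)

  # FOV restriction changes the denominator
  fov <- matrix(0, 4, 4); fov[1:2, ] <- 1
  cmf <- confusion(pred, gt, fov)
  expect_equal(cmf$TN + cmf$FP + cmf$FN + cmf$TP, sum(fov))
  expect_error(confusion(pred * 2, gt), "binary")
  expect_error(confusion(pred[1:2, ], gt), "shape")
})

test_that("worked confusion matrices reproduce their published accuracies", {
  cm1 <- structure(list(TN = 58445, FP = 3603, FN = 3453, TP = 798),
                   class = "confusion_matrix")
  expect_equal(round(100 * accuracy(cm1), 1), 89.4)
  cm2 <- structure(list(TN = 58342, FP = 3263, FN = 3187, TP = 744),
                   class = "confusion_matrix")
  expect_equal(round(100 * accuracy(cm2), 2), 90.16)

  # remaining ratios on the first matrix, by direct arithmetic
  expect_equal(precision(cm1), 798 / 4401, tolerance = 1e-12)
  expect_equal(sensitivity(cm1), 798 / 4251, tolerance = 1e-12)
  expect_equal(f1_score(cm1), 1596 / 8652, tolerance = 1e-12)
  expect_equal(jaccard(cm1), 798 / 7854, tolerance = 1e-12)
})

test_that("metrics agree with formula-free pixel-counting oracles", {
  set.seed(31)
  for (i in 1:40) {
    mp <- random_mask_pair(12)
    fov <- if (i %% 2 == 0) mp$fov else NULL
    cm <- confusion(mp$pred, mp$gt, fov)
    oc <- count_confusion(mp$pred, mp$gt, fov)
    expect_equal(cm$TP, oc$TP); expect_equal(cm$TN, oc$TN)
    expect_equal(cm$FP, oc$FP); expect_equal(cm$FN, oc$FN)
    tot <- oc$TN + oc$FP + oc$FN + oc$TP
    expect_equal(accuracy(cm), (oc$TP + oc$TN) / tot)
    if (oc$TP + oc$FP > 0) expect_equal(precision(cm), oc$TP / (oc$TP + oc$FP))
    if (oc$TP + oc$FN > 0) expect_equal(sensitivity(cm), oc$TP / (oc$TP + oc$FN))
    if (oc$TP > 0) {
      # harmonic-mean identity and jaccard <= f1
      pr <- precision(cm); se <- sensitivity(cm)
      expect_equal(f1_score(cm), 2 * pr * se / (pr + se), tolerance = 1e-12)
      expect_lte(jaccard(cm), f1_score(cm))
    }
    for (v in c(accuracy(cm), precision(cm), sensitivity(cm), f1_score(cm),
                jaccard(cm))) {
      if (!is.na(v)) { expect_gte(v, 0); expect_lte(v, 1) }
    }
  }
})

test_that("undefined ratios surface as NA, never a silent zero", {
  cm <- confusion(matrix(0, 3, 3), matrix(0, 3, 3))
  expect_warning(p <- precision(cm), "undefined")
  expect_true(is.na(p))
  expect_warning(s <- sensitivity(cm), "undefined")
  expect_true(is.na(s))
  expect_error(accuracy(structure(list(TN = 0, FP = 0, FN = 0, TP = 0),
                                  class = "confusion_matrix")), "degenerate")
})

test_that("ROC-AUC equals the pairwise-ordering probability", {
  g <- matrix(c(1, 1, 1, 0, 0, 0), 1, 6)
  p <- matrix(c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2), 1, 6)
  expect_equal(roc_auc(p, g), 8 / 9, tolerance = 1e-12)
  expect_equal(roc_auc(p, g), pair_count_auc(p, g), tolerance = 1e-12)

  # probabilities equal to the truth: perfect ranking
  expect_equal(roc_auc(g, g), 1)
  # constant prediction: chance
  expect_equal(roc_auc(matrix(0.5, 1, 6), g), 0.5)
  expect_error(roc_auc(p, matrix(1, 1, 6)), "single class|degenerate")

  set.seed(12)
  for (i in 1:30) {
    gg <- matrix(rbinom(30, 1, 0.4), 5, 6)
    if (sum(gg) == 0 || sum(gg) == 30) next
    pp <- matrix(round(runif(30), 2), 5, 6)     # rounded: ties occur
    expect_equal(roc_auc(pp, gg), pair_count_auc(pp, gg), tolerance = 1e-12)
  }
})

test_that("ROC-AUC cross-checks against an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  g <- matrix(rbinom(100, 1, 0.3), 10, 10)
  p <- matrix(runif(100), 10, 10)
  ref <- suppressMessages(as.numeric(pROC::auc(as.vector(g), as.vector(p),
                                               direction = "<")))
  expect_equal(roc_auc(p, g), ref, tolerance = 1e-10)
})

test_that("rank-sum test: exact enumeration, ties, and monotonicity", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 3)
  expect_equal(r$p.value, 2 / 6, tolerance = 1e-12)

  # identical samples: exchangeable, p ~ 1
  ri <- wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))
  expect_gte(ri$p.value, 0.99)

  # exact branch agrees with full enumeration on random small samples
  set.seed(21)
  for (i in 1:15) {
    a <- sample(1:8, sample(2:5, 1), replace = TRUE)
    b <- sample(1:8, sample(2:5, 1), replace = TRUE)
    r <- wilcoxon_rank_sum(a, b)
    expect_equal(r$p.value, enumerate_ranksum_p(a, b), tolerance = 1e-12)
  }

  # tie-free exact case agrees with stats::wilcox.test
  a <- c(1.1, 2.3, 3.7, 4.2); b <- c(0.5, 2.9, 5.1)
  ref <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(wilcoxon_rank_sum(a, b)$p.value, ref$p.value, tolerance = 1e-12)

  # shifting b upward cannot make a look larger
  a <- 1:6; b <- 4:9
  p1 <- wilcoxon_rank_sum(a, b)$statistic
  p2 <- wilcoxon_rank_sum(a, b + 10)$statistic
  expect_lte(p2, p1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty")

  # large samples switch to the tie-corrected normal approximation
  set.seed(2)
  aa <- rnorm(30); bb <- rnorm(30, 0.2)
  appr <- wilcoxon_rank_sum(aa, bb)
  ref <- stats::wilcox.test(aa, bb, exact = FALSE, correct = FALSE)
  expect_equal(appr$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("metrics_report bundles the suite into one tibble row", {
  s <- small_phantom(seed = 8, hw = 48)
  prob <- s$vessel_mask * 0.9 + 0.05
  rep <- metrics_report(prob, s$vessel_mask, s$fov_mask)
  expect_s3_class(rep, "tbl_df")
  expect_equal(unlist(rep[1, c("accuracy", "precision", "sensitivity",
                               "f1", "jaccard", "auc")]),
               c(accuracy = 1, precision = 1, sensitivity = 1, f1 = 1,
                 jaccard = 1, auc = 1))
})
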