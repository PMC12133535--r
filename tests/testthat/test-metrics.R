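# Metric implementations against independent brute-force oracles and
# their closed-form worked examples.

oracle_counts <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]
      g <- truth[i, j]
      if (p == 1 && g == 1) tp <- tp + 1
      if (p == 0 && g == 0) tn <- tn + 1
      if (p == 1 && g == 0) fp <- fp + 1
      if (p == 0 && g == 1) fn <- fn + 1
    }
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

oracle_hausdorff <- function(A, B) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  directed <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) best <- min(best, d(P[i, ], Q[j, ]))
      worst <- max(worst, best)
    }
    worst
  }
  max(directed(A, B), directed(B, A))
}

test_that("dice matches worked examples and the counting oracle", {
  g <- matrix(0, 4, 4); g[1:2, 1] <- 1            # |G| = 2
  p <- matrix(0, 4, 4); p[1:2, 1:2] <- 1          # |P| = 4, overlap 2
  expect_equal(dice(p, g), 2 * 2 / 6)
  expect_equal(dice(g, g), 1)
  p2 <- matrix(0, 4, 4); p2[4, 4] <- 1
  expect_equal(dice(p2, g), 0)
  expect_warning(d0 <- dice(matrix(0, 2, 2), matrix(0, 2, 2)), "empty")
  expect_equal(d0, 1)
  expect_error(dice(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(dice(matrix(2, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("miou matches the direct enumeration example and edge cases", {
  # 2x2 image, G = [[1,1],[0,0]], P = [[1,0],[0,0]] (row-wise)
  g <- rbind(c(1, 1), c(0, 0))
  p <- rbind(c(1, 0), c(0, 0))
  expect_equal(miou(p, truth = g), (1 / 2 + 2 / 3) / 2)
  expect_equal(miou(g, truth = g), 1)
  # total inversion with both classes present: zero overlap in each class
  expect_equal(miou(1 - g, truth = g), 0)
  # class absent from both prediction and truth is excluded
  cm <- confusion_matrix(matrix(0, 2, 2), matrix(0, 2, 2), n_classes = 2)
  expect_equal(miou(cm), 1)
})

test_that("accuracy/sensitivity/specificity match stated arithmetic", {
  # construct masks with TP=8, TN=80, FP=2, FN=10 (100 pixels)
  g <- matrix(0, 10, 10); g[1:18] <- 1
  p <- matrix(0, 10, 10); p[1:8] <- 1; p[19:20] <- 1
  cm <- confusion_matrix(p, g)
  expect_equal(unname(cm[2, 2]), 8)   # TP
  expect_equal(unname(cm[1, 1]), 80)  # TN
  r <- accuracy_sensitivity_specificity(cm)
  expect_equal(unname(r["accuracy"]), 0.88)
  expect_equal(unname(r["sensitivity"]), 8 / 18, tolerance = 1e-12)
  expect_equal(unname(r["specificity"]), 80 / 82, tolerance = 1e-12)
  # degenerate denominator: all-foreground truth, all-background prediction
  g1 <- matrix(1, 3, 3)
  p1 <- matrix(0, 3, 3)
  expect_warning(r1 <- accuracy_sensitivity_specificity(p1, truth = g1),
                 "specificity undefined")
  expect_equal(unname(r1["sensitivity"]), 0)
  expect_true(is.nan(r1["specificity"]))
})

test_that("hausdorff distance matches worked examples and is symmetric", {
  A <- matrix(c(0, 0), 1, 2, byrow = TRUE)
  B <- matrix(c(3, 4), 1, 2, byrow = TRUE)
  expect_equal(hausdorff_distance(A, B), 5)
  expect_equal(hausdorff_distance(A, A), 0)
  A2 <- rbind(c(0, 0), c(10, 0))
  expect_equal(hausdorff_distance(A2, A), 10)
  expect_equal(hausdorff_distance(A, A2), 10)
  m <- matrix(0, 6, 6); m[3:4, 3:4] <- 1
  expect_equal(hausdorff_distance(m, m), 0)
  expect_error(hausdorff_distance(m, matrix(0, 6, 6)), "empty")
})

test_that("boundary extraction is the 4-connectivity erosion difference", {
  m <- matrix(0, 5, 5)
  m[2:4, 2:4] <- 1
  bp <- boundary_points(m)
  expect_equal(nrow(bp), 8)          # 3x3 square: all but center
  expect_false(any(bp[, 1] == 3 & bp[, 2] == 3))
  # single pixel is its own boundary
  s <- matrix(0, 3, 3); s[2, 2] <- 1
  expect_equal(unname(boundary_points(s)), matrix(c(2, 2), 1))
})

test_that("vectorized metrics agree exactly with loop oracles on random pairs", {
  set.seed(31)
  for (rep in 1:60) {
    p <- random_mask(16, stats::runif(1, 0.1, 0.9))
    g <- random_mask(16, stats::runif(1, 0.1, 0.9))
    cnt <- oracle_counts(p, g)
    cm <- confusion_matrix(p, g, n_classes = 2)
    expect_identical(unname(c(cm[1, 1], cm[1, 2], cm[2, 1], cm[2, 2])),
                     unname(c(cnt["tn"], cnt["fp"], cnt["fn"], cnt["tp"])))
    if (cnt["tp"] + cnt["fp"] + cnt["fn"] > 0) {
      expect_equal(dice(p, g),
                   2 * cnt[["tp"]] / (2 * cnt[["tp"]] + cnt[["fp"]] + cnt[["fn"]]))
      # Dice-IoU identity
      iou <- cnt[["tp"]] / (cnt[["tp"]] + cnt[["fp"]] + cnt[["fn"]])
      expect_equal(dice(p, g), 2 * iou / (1 + iou))
    }
    if (sum(p) > 0 && sum(g) > 0) {
      expect_equal(hausdorff_distance(p, g),
                   oracle_hausdorff(boundary_points(p), boundary_points(g)))
    }
  }
})

test_that("hausdorff grows under dilation of the discrepant region", {
  g <- matrix(0, 20, 20); g[9:12, 9:12] <- 1
  base <- hausdorff_distance(g, g)
  p1 <- g; p1[9:12, 13] <- 1         # protrude 1 px
  p2 <- g; p2[9:12, 13:15] <- 1      # protrude 3 px
  expect_lt(base, hausdorff_distance(p1, g))
  expect_lt(hausdorff_distance(p1, g), hausdorff_distance(p2, g))
})

test_that("roc_auc matches the concordance worked example and conventions", {
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)
  # perfectly separable
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  # all tied scores
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "positive and one negative")
  # curve starts at (0,0) and ends at (1,1)
  expect_equal(unlist(r$curve[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
})

test_that("AUC is invariant to strictly monotone score transforms and
           matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- stats::runif(400)
  l <- (stats::runif(400) < stats::plogis(6 * (s - 0.5))) * 1
  a1 <- roc_auc(s, l)$auc
  expect_equal(roc_auc(s^3, l)$auc, a1, tolerance = 1e-12)
  expect_equal(roc_auc(stats::qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)), l)$auc,
               a1, tolerance = 1e-12)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE))))
  expect_equal(a1, ref, tolerance = 1e-10)
})

test_that("evaluate_masks aggregates per-image and pooled metrics coherently", {
  set.seed(17)
  preds <- lapply(1:5, function(i) random_mask(12, 0.35))
  truths <- lapply(1:5, function(i) random_mask(12, 0.35))
  ev <- evaluate_masks(preds, truths)
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(nrow(tidy(ev)), 5)
  expect_equal(unname(ev$macro["dice"]), mean(tidy(ev)$dice))
  # pooled equals metrics of the concatenated masks
  big_p <- do.call(rbind, preds)
  big_g <- do.call(rbind, truths)
  expect_equal(unname(ev$pooled["dice"]), dice(big_p, big_g))
  expect_equal(unname(ev$pooled["miou"]), miou(big_p, truth = big_g))
  g <- glance(ev)
  expect_true(all(c("macro_dice", "pooled_miou") %in% names(g)))
})
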