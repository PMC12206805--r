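
test_that("confusion matrices tally (true, predicted) pairs", {
  y <- c(1, 1, 2, 2, 3, 3)
  expect_identical(unclass(confusion(y, y, 3)), diag(2L, 3))

  yt <- c(1, 1, 1, 2, 2, 2); yp <- c(1, 1, 2, 1, 2, 2)
  cm <- confusion(yt, yp, 2)
  expect_identical(unclass(cm), matrix(c(2L, 1L, 1L, 2L), 2))
  expect_identical(unname(rowSums(cm)), c(3, 3))  # per-class true counts
  expect_error(confusion(c(1, 7), c(1, 1), 2), "labels")
})

test_that("classification metrics match direct arithmetic", {
  perfect <- classification_metrics(diag(5L, 4))
  expect_identical(c(perfect$accuracy, perfect$macro_precision,
                     perfect$macro_recall, perfect$macro_f1,
                     perfect$macro_mcc), rep(1, 5))

  cm <- matrix(c(2L, 1L, 1L, 2L), 2, byrow = TRUE)
  rep2 <- classification_metrics(cm)
  expect_equal(rep2$accuracy, 4 / 6)
  expect_equal(rep2$per_class$mcc, c(1 / 3, 1 / 3))

  # a class never predicted: its precision is defined as 0
  cm0 <- matrix(c(3L, 0L, 2L, 0L), 2, byrow = TRUE)
  rep0 <- classification_metrics(cm0)
  expect_identical(rep0$per_class$precision[2], 0)
})

test_that("metrics agree with the scalar oracle on random matrices", {
  withr::with_seed(19, {
    for (rep in 1:100) {
      cm <- matrix(rpois(36, 8), 6, 6)
      r <- classification_metrics(cm)
      o <- lapply(1:6, metrics_oracle, cm = cm)
      expect_equal(r$per_class$precision,
                   vapply(o, `[[`, 0, "precision"))
      expect_equal(r$per_class$recall, vapply(o, `[[`, 0, "recall"))
      expect_equal(r$per_class$f1, vapply(o, `[[`, 0, "f1"))
      expect_equal(r$per_class$mcc, vapply(o, `[[`, 0, "mcc"))
      expect_equal(r$per_class$accuracy, vapply(o, `[[`, 0, "accuracy"))
      expect_equal(r$accuracy, sum(diag(cm)) / sum(cm))
      expect_equal(r$macro_f1, mean(vapply(o, `[[`, 0, "f1")))
    }
  })
})

test_that("macro metrics are invariant under class permutation", {
  withr::with_seed(23, cm <- matrix(rpois(36, 6), 6, 6))
  perm <- c(3, 1, 6, 2, 5, 4)
  r1 <- classification_metrics(cm)
  r2 <- classification_metrics(cm[perm, perm])
  expect_equal(r1$macro_precision, r2$macro_precision)
  expect_equal(r1$macro_mcc, r2$macro_mcc)
  expect_equal(r1$accuracy, r2$accuracy)
})

test_that("macro one-vs-rest AUC behaves as a rank statistic", {
  withr::with_seed(29, y <- sample(1:6, 300, replace = TRUE))
  onehot <- hyperleaf:::one_hot(y, 6)
  expect_equal(roc_auc_ovr_macro(onehot, y), 1)

  withr::with_seed(30, {
    scores <- matrix(runif(2000 * 6), 2000, 6)
    yr <- sample(1:6, 2000, replace = TRUE)
  })
  null_auc <- roc_auc_ovr_macro(scores, yr)
  expect_gt(null_auc, 0.45); expect_lt(null_auc, 0.55)

  # invariance under a strictly increasing transform
  expect_equal(roc_auc_ovr_macro(exp(3 * scores), yr), null_auc)

  # cross-check one class against an independent implementation
  skip_if_not_installed("pROC")
  k <- 2
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(yr == k, scores[, k], quiet = TRUE))))
  expect_equal(hyperleaf:::auc_binary(scores[, k], yr == k), ref,
               tolerance = 1e-10)

  expect_warning(roc_auc_ovr_macro(scores[yr != 6, ], yr[yr != 6]),
                 "absent")
})

test_that("Dunn's test with Bonferroni flags separated groups only", {
  groups <- list(high = c(0.90, 0.91, 0.92), low = c(0.50, 0.51, 0.52),
                 mid = c(0.70, 0.71, 0.72))
  res <- dunn_bonferroni(groups)
  hl <- res$pairs[res$pairs$group1 %in% c("high", "low") &
                  res$pairs$group2 %in% c("high", "low"), ]
  expect_lt(hl$p_adj, 0.05)
  expect_equal(res$pairs$p_adj,
               pmin(1, res$pairs$p_raw * nrow(res$pairs)))
  # letters sorted by median: best group gets 'a'
  expect_identical(res$letters$letters[res$letters$group == "high"], "a")

  same <- dunn_bonferroni(list(a = c(1, 1, 1), b = c(1, 1, 1)))
  expect_identical(same$pairs$p_adj, 1)
  expect_identical(unique(same$letters$letters), "a")

  # two groups, exact rank arithmetic on 6 values (no ties):
  # ranks 4,5,6 vs 1,2,3 -> z = (5 - 2) / sqrt((6*7/12)*(2/3)) = 1.9640
  two <- dunn_bonferroni(list(a = c(0.9, 0.91, 0.92),
                              b = c(0.5, 0.51, 0.52)))
  expect_equal(abs(two$pairs$z), 3 / sqrt((6 * 7 / 12) * (2 / 3)),
               tolerance = 1e-10)
  expect_error(dunn_bonferroni(list(a = c(1, 2))), ">= 3 values|>= 2 groups")
})
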