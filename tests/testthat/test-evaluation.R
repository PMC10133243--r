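test_that("confusion counts conserve annotations and route misses correctly", {
  pairs <- data.frame(
    true_cls = rep(c("cancer", "lymphocyte", "stromal"), each = 10),
    pred_cls = rep(c("cancer", "lymphocyte", "stromal"), each = 10)
  )
  cm <- confusion_counts(pairs)
  expect_equal(unname(diag(cm[, 1:3])), rep(10L, 3))
  expect_equal(sum(cm), 30)

  all_other <- data.frame(true_cls = pairs$true_cls, pred_cls = "other")
  cm2 <- confusion_counts(all_other)
  expect_equal(sum(cm2[, "other"]), 30)
  expect_equal(sum(cm2[, c("cancer", "lymphocyte", "stromal")]), 0)

  with_miss <- data.frame(true_cls = c("cancer", "cancer"),
                          pred_cls = c("cancer", NA))
  cm3 <- confusion_counts(with_miss)
  expect_equal(unname(cm3["cancer", "missed"]), 1L)
  expect_equal(sum(cm3), 2)

  expect_error(confusion_counts(pairs[0, ]), "No annotation")
  expect_error(confusion_counts(data.frame(true_cls = "other",
                                           pred_cls = "cancer")),
               "cancer, lymphocyte, stromal")
})

test_that("metrics reproduce hand-computed balanced accuracy", {
  # hand case: rows true, columns predicted
  cm <- matrix(c(8, 1, 1,
                 2, 7, 1,
                 1, 1, 8), 3, byrow = TRUE,
               dimnames = list(cell_classes(core = TRUE),
                               cell_classes(core = TRUE)))
  mr <- classification_metrics(cm)
  b <- mr$per_class
  # cancer: sens 8/10; spec 1 - 3/20 = 0.85 -> bcacc 0.825
  expect_equal(b$bcacc[b$cls == "cancer"], 0.825)
  expect_equal(mr$overall_bcacc, mean(b$bcacc))

  # perfect classifier
  perfect <- diag(c(10, 10, 10))
  dimnames(perfect) <- dimnames(cm)
  mp <- classification_metrics(perfect)
  expect_equal(mp$overall_bcacc, 1.0)
  expect_equal(mp$per_class$f1, rep(1, 3))

  # everything predicted cancer
  allc <- matrix(0, 3, 3, dimnames = dimnames(cm))
  allc[, "cancer"] <- 10
  ma <- classification_metrics(allc)
  expect_equal(ma$per_class$sensitivity[ma$per_class$cls == "cancer"], 1)
  expect_equal(ma$per_class$specificity[ma$per_class$cls == "cancer"], 0)
  expect_equal(ma$per_class$bcacc[ma$per_class$cls == "cancer"], 0.5)

  expect_equal(glance(mr)$n_annotations, 30)
})

test_that("a random classifier on balanced data scores near 0.5 overall", {
  truth <- random_truth(6000, seed = 13)
  rand_cm <- matrix(1 / 3, 3, 3,
                    dimnames = list(cell_classes(core = TRUE),
                                    cell_classes(core = TRUE)))
  preds <- gen_predictions(truth, confusion_spec(rand_cm), seed = 14)
  mr <- score_predictions(truth, preds)
  expect_equal(mr$overall_bcacc, 0.5, tolerance = 0.02)
})

test_that("kruskal_wallis matches hand computation and handles constants", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                       n_boot = 0)
  expect_equal(kw$H, 3.857142857, tolerance = 1e-8)
  expect_equal(kw$df, 1)

  kc <- kruskal_wallis(rep(2, 8), rep(c("a", "b"), each = 4), n_boot = 0)
  expect_equal(kc$H, 0)

  expect_error(kruskal_wallis(1:3, c("a", "a", "a"), n_boot = 0),
               "two groups")
  # bootstrap CI is seed-stable
  k1 <- kruskal_wallis(runif(20), rep(1:2, 10), n_boot = 200, seed = 3)
  k2 <- kruskal_wallis(runif(20), rep(1:2, 10), n_boot = 200, seed = 3)
  expect_false(identical(k1$eta_sq, k2$eta_sq))  # different data
  d <- rnorm(20)
  g <- rep(1:2, 10)
  expect_identical(kruskal_wallis(d, g, n_boot = 200, seed = 3)$eta_sq_ci,
                   kruskal_wallis(d, g, n_boot = 200, seed = 3)$eta_sq_ci)
})

test_that("pairwise rank contrasts equal mean-rank differences and flag separation", {
  v <- c(1:10, 101:110, 201:210)
  g <- rep(c("a", "b", "c"), each = 10)
  ct <- pairwise_rank_contrasts(v, g)
  r <- rank(v)
  mr <- tapply(r, g, mean)
  expect_equal(ct$estimate[ct$group_a == "a" & ct$group_b == "b"],
               unname(mr["a"] - mr["b"]))
  expect_equal(ct$estimate[ct$group_a == "b" & ct$group_b == "c"],
               unname(mr["b"] - mr["c"]))
  expect_true(all(ct$significant))
  expect_true(all(ct$p.value < 0.05))

  same <- pairwise_rank_contrasts(rep(1:10, 2), rep(c("a", "b"), each = 10))
  expect_equal(same$estimate, 0)
  expect_true(same$conf_low < 0 && same$conf_high > 0)
  expect_false(same$significant)
})

test_that("correlations behave for monotone and nonlinear relationships", {
  x <- 1:10
  expect_equal(correlate(x, x, "spearman")$estimate, 1)
  expect_equal(correlate(x, x, "pearson")$estimate, 1)
  y <- x^2
  expect_equal(correlate(x, y, "spearman")$estimate, 1)
  expect_lt(correlate(x, y, "pearson")$estimate, 1)
  expect_error(correlate(x, rep(1, 10), "pearson"), "zero variance")
})
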