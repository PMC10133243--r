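test_that("gen_cell_image conserves counts, is seed-deterministic and labels never overlap", {
  img <- gen_cell_image(
    n_per_class = c(cancer = 30, lymphocyte = 30, stromal = 30),
    canvas = c(220, 220), seed = 5)
  expect_equal(max(img$mask), 90)
  expect_equal(nrow(img$truth), 90)
  expect_equal(as.integer(table(img$truth$cls)[c("cancer", "lymphocyte", "stromal")]),
               c(30L, 30L, 30L))
  # every label is one contiguous set of >= 3 exclusive pixels
  expect_equal(sort(unique(as.integer(img$mask[img$mask > 0]))), 1:90)

  img2 <- gen_cell_image(
    n_per_class = c(cancer = 30, lymphocyte = 30, stromal = 30),
    canvas = c(220, 220), seed = 5)
  expect_identical(img$mask, img2$mask)
  expect_identical(img$intensity, img2$intensity)
  expect_equal(img$truth, img2$truth)

  expect_error(
    gen_cell_image(n_per_class = c(cancer = 400), canvas = c(60, 60),
                   seed = 1),
    "canvas")
})

test_that("generated lymphocyte areas follow the profile distribution", {
  img <- gen_cell_image(n_per_class = c(lymphocyte = 500),
                        canvas = c(400, 400), seed = 11)
  f <- extract_features(img$mask, img$intensity, scale = img$spec$scale)
  prof <- morphology_profile()
  med <- prof$area_median[prof$cls == "lymphocyte"]
  expect_lt(abs(median(f$area) - med) / med, 0.05)
  ks <- suppressWarnings(
    ks.test(f$area, function(q) plnorm(q, log(med),
                                       prof$area_dispersion[prof$cls == "lymphocyte"])))
  expect_gt(ks$p.value, 0.01)
})

test_that("gen_predictions reproduces identity, forced and degraded specs", {
  truth <- random_truth(200, seed = 7)
  ident <- gen_predictions(truth, confusion_spec(), seed = 1)
  expect_equal(nrow(ident), 200)
  expect_equal(ident$cls, truth$cls)
  expect_equal(ident$x, truth$x)
  expect_equal(ident$y, truth$y)

  forced <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, byrow = TRUE,
                   dimnames = list(cell_classes(core = TRUE),
                                   cell_classes(core = TRUE)))
  p <- gen_predictions(truth, confusion_spec(forced), seed = 2)
  expect_true(all(p$cls[truth$cls == "cancer"] == "lymphocyte"))

  noisy <- gen_predictions(truth,
                           confusion_spec(jitter_sd = 1, miss_rate = 0.3,
                                          spurious_rate = 0.2), seed = 3)
  expect_lt(sum(!is.na(noisy$truth_id)), 200)
  expect_gt(sum(is.na(noisy$truth_id)), 0)
  expect_error(confusion_spec(matrix(c(0.5, 0.5, 0.5), 3, 3)), "sum to 1")
})

test_that("point patterns return exact counts and colocalisation orders with theta", {
  pp <- gen_point_pattern(coloc_spec(n_cancer = 300, n_lymph = 150), seed = 2)
  expect_equal(nrow(pp$cancer), 300)
  expect_equal(nrow(pp$lymph), 150)
  expect_true(all(pp$cancer$x >= 0 & pp$cancer$x <= 2000))

  pp_b <- gen_point_pattern(coloc_spec(n_cancer = 300, n_lymph = 150), seed = 2)
  expect_equal(pp, pp_b)

  mh_by_theta <- vapply(c(0, 1), function(th) {
    mean(vapply(1:20, function(r) {
      pp <- gen_point_pattern(coloc_spec(theta = th), seed = r)
      colocalization_score(pp$cancer, pp$lymph)$mh
    }, numeric(1)))
  }, numeric(1))
  expect_gt(mh_by_theta[2], mh_by_theta[1])
})

test_that("survival generator realises the proportional-hazards model", {
  # no effects, no censoring: everyone has an event
  d0 <- gen_survival(survival_spec(n = 50, beta_coloc = 0, beta_age = 0,
                                   beta_lymph = 0, censor_rate = 0), seed = 1)
  expect_true(all(d0$event == 1))

  # parameter recovery at n = 2000
  d <- gen_survival(survival_spec(n = 2000, censor_rate = 0.2), seed = 5)
  fit <- fit_cox(d)
  b <- fit$coefficients
  expect_lt(abs(b$estimate[b$term == "coloc100"] - (-0.02)), 0.005)

  # null coloc effect: 95% Wald CI covers HR = 1 in >= 93/100 replicates
  covered <- vapply(1:100, function(r) {
    d <- gen_survival(survival_spec(n = 150, beta_coloc = 0), seed = r)
    b <- fit_cox(d)$coefficients
    i <- which(b$term == "coloc100")
    b$hr_low[i] <= 1 && 1 <= b$hr_high[i]
  }, logical(1))
  expect_gte(sum(covered), 93)
})
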