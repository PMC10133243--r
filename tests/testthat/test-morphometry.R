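test_that("closed-form shapes: rectangle, degenerate row, rasterised ellipse", {
  m <- matrix(0L, 10, 12)
  m[3:6, 4:8] <- 1L  # 4 x 5 rectangle
  f <- extract_features(m, flat_intensity(m), scale = 1)
  expect_equal(f$area, 20)
  expect_equal(f$extent, 1.0)
  expect_equal(f$euler_number, 1L)
  expect_equal(f$solidity, 1.0)
  expect_equal(f$filled_area, 20)
  expect_equal(f$int_mean, 120)
  expect_equal(f$int_sd, 0)
  expect_equal(f$int_entropy, 0)

  s <- matrix(0L, 5, 15)
  s[3, 3:12] <- 1L  # single row of 10 pixels
  fs <- extract_features(s, flat_intensity(s), scale = 1)
  expect_gt(fs$aspect_ratio, 5)
  expect_gt(fs$eccentricity, 0.99)
  expect_lt(fs$eccentricity, 1)

  e <- ellipse_mask(a = 20, b = 10)
  fe <- extract_features(e, flat_intensity(e), scale = 1)
  expect_lt(abs(fe$major_axis_length - 40) / 40, 0.05)
  expect_lt(abs(fe$minor_axis_length - 20) / 20, 0.05)
  expect_lt(abs(fe$area - pi * 20 * 10) / (pi * 200), 0.05)
  expect_lt(fe$circularity, 1)
  expect_gt(fe$circularity, 0.7)
})

test_that("a region with a hole has euler number 0 and a larger filled area", {
  m <- matrix(0L, 12, 12)
  m[3:9, 3:9] <- 1L
  m[5:7, 5:7] <- 0L
  f <- extract_features(m, flat_intensity(m), scale = 1)
  expect_equal(f$euler_number, 0L)
  expect_equal(f$filled_area, 49)
  expect_equal(f$area, 40)
})

test_that("length features scale by s, areas by s^2, ratios not at all", {
  e <- ellipse_mask(a = 15, b = 8)
  f1 <- extract_features(e, flat_intensity(e), scale = 1)
  f2 <- extract_features(e, flat_intensity(e), scale = 0.5)
  reg <- feature_registry()
  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    expected <- switch(reg$kind[i],
      length = f1[[nm]] * 0.5,
      area = f1[[nm]] * 0.25,
      f1[[nm]]
    )
    expect_equal(f2[[nm]], expected, tolerance = 1e-9,
                 info = paste("feature:", nm))
  }
})

test_that("90-degree rotation changes area, eccentricity and solidity by < 3%", {
  e <- ellipse_mask(a = 18, b = 9)
  er <- t(e)[rev(seq_len(ncol(e))), ]  # 90-degree rotation
  f <- extract_features(e, flat_intensity(e), scale = 1)
  fr <- extract_features(er, flat_intensity(er), scale = 1)
  for (nm in c("area", "eccentricity", "solidity")) {
    expect_lt(abs(f[[nm]] - fr[[nm]]) / f[[nm]], 0.03)
  }
})

test_that("tiny labels are skipped with a warning and the registry hash travels", {
  m <- matrix(0L, 8, 8)
  m[2:5, 2:5] <- 1L
  m[7, 7] <- 2L  # 1 pixel: moments undefined
  expect_warning(f <- extract_features(m, flat_intensity(m), scale = 1),
                 "< 3 pixels")
  expect_equal(nrow(f), 1)
  expect_equal(attr(f, "registry_hash"), rlang::hash(feature_registry()$name))
})

test_that("label and intensity images round-trip through 16-bit files", {
  img <- gen_cell_image(n_per_class = c(cancer = 5, lymphocyte = 5),
                        canvas = c(90, 90), seed = 3)
  fm <- withr::local_tempfile(fileext = ".tif")
  fi <- withr::local_tempfile(fileext = ".png")
  write_label_image(img$mask, fm)
  write_intensity_image(img$intensity, fi)
  expect_identical(read_label_image(fm), img$mask)
  expect_identical(read_intensity_image(fi), img$intensity)
  expect_error(write_label_image(img$mask, withr::local_tempfile(fileext = ".png")),
               "16-bit TIFF")
})

test_that("annotation matching is greedy, one-to-one and threshold-bounded", {
  ann <- tibble::tibble(cell_id = c("a1", "a2"), x = c(0, 3), y = c(0, 0))
  cen <- tibble::tibble(cell_id = "d1", x = 0, y = 1.0)
  m <- map_annotations_to_cells(ann, cen, max_dist = 1.824)
  expect_equal(m$matched_id, c("d1", NA))

  cen2 <- tibble::tibble(cell_id = "d1", x = 0, y = 2.5)
  m2 <- map_annotations_to_cells(ann, cen2, max_dist = 1.824)
  expect_true(all(is.na(m2$matched_id)))

  # one centroid between two annotations: nearer annotation wins
  ann3 <- tibble::tibble(cell_id = c("a1", "a2"), x = c(0, 1.5), y = c(0, 0))
  cen3 <- tibble::tibble(cell_id = "d1", x = 1.0, y = 0)
  m3 <- map_annotations_to_cells(ann3, cen3, max_dist = 1.824)
  expect_equal(m3$matched_id, c(NA, "d1"))
  expect_equal(m3$distance[2], 0.5)
})

test_that("greedy matching agrees with exhaustive assignment on tiny instances", {
  # brute force: over all one-to-one assignments within threshold, greedy by
  # ascending distance must reproduce the same matched set when the optimal
  # assignment is unique and nested (<= 5 points)
  withr::with_seed(99, {
    for (rep in 1:20) {
      na <- sample(2:4, 1); nc <- sample(1:4, 1)
      ann <- tibble::tibble(cell_id = paste0("a", 1:na),
                            x = runif(na, 0, 6), y = runif(na, 0, 6))
      cen <- tibble::tibble(cell_id = paste0("d", 1:nc),
                            x = runif(nc, 0, 6), y = runif(nc, 0, 6))
      got <- map_annotations_to_cells(ann, cen, max_dist = 2)
      # oracle: sequential greedy over the explicit sorted pair list
      d <- as.matrix(dist(rbind(cbind(ann$x, ann$y), cbind(cen$x, cen$y))))
      d <- d[1:na, na + (1:nc), drop = FALSE]
      pairs <- which(d <= 2, arr.ind = TRUE)
      exp_match <- rep(NA_character_, na)
      if (nrow(pairs) > 0) {
        used <- character(0)
        for (k in order(d[pairs])) {
          i <- pairs[k, 1]; j <- pairs[k, 2]
          if (is.na(exp_match[i]) && !(paste0("d", j) %in% used)) {
            exp_match[i] <- paste0("d", j)
            used <- c(used, paste0("d", j))
          }
        }
      }
      expect_equal(got$matched_id, exp_match)
    }
  })
})
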