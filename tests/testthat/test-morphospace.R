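test_that("embedding is deterministic, shape-stable and refuses tiny inputs", {
  withr::with_seed(1, {
    X <- tibble::as_tibble(matrix(rnorm(200 * 5), 200),
                           .name_repair = "minimal")
  })
  names(X) <- paste0("f", 1:5)
  cfg <- embedding_config(perplexity = 20, seed = 9, max_iter = 300)
  e1 <- embed_morphospace(X, cfg, feature_cols = names(X))
  e2 <- embed_morphospace(X, cfg, feature_cols = names(X))
  expect_equal(e1$tsne1, e2$tsne1)
  expect_equal(nrow(e1), 200)
  expect_true(all(is.finite(e1$tsne1)), all(is.finite(e1$tsne2)))

  expect_error(embed_morphospace(X[1:30, ], embedding_config(perplexity = 50),
                                 feature_cols = names(X)),
               "at least 152")
})

test_that("well-separated feature clusters stay separated in the embedding", {
  withr::with_seed(3, {
    a <- matrix(rnorm(150 * 6), 150)
    b <- matrix(rnorm(150 * 6), 150) + 10
  })
  X <- tibble::as_tibble(rbind(a, b), .name_repair = "minimal")
  names(X) <- paste0("f", 1:6)
  emb <- embed_morphospace(X, embedding_config(perplexity = 30, seed = 2,
                                               max_iter = 400),
                           feature_cols = names(X))
  sil <- mean_silhouette(cbind(emb$tsne1, emb$tsne2),
                         rep(c("a", "b"), each = 150))
  expect_gt(sil, 0.5)
})

test_that("port overlap has its closed-form values", {
  withr::with_seed(5, {
    A <- cbind(runif(4000), runif(4000))
    B <- cbind(runif(4000) / 2, runif(4000))
  })
  expect_equal(port_overlap(A, A), 1.0)
  expect_equal(port_overlap(A, A + 10), 0.0)
  # B's support is half of A's in dimension 1: fraction of A inside B ~ 0.5
  expect_equal(port_overlap(A, B, alphas = 0), 0.5, tolerance = 0.05)
  # and A contains B entirely
  expect_equal(port_overlap(B, A, alphas = 0), 1.0, tolerance = 0.02)
})

test_that("port is invariant under joint affine maps and decreases with separation", {
  withr::with_seed(8, {
    A <- cbind(rnorm(500), rnorm(500))
    B <- cbind(rnorm(500, 1), rnorm(500, 1))
  })
  p0 <- port_overlap(A, B)
  f <- function(M) cbind(3 * M[, 1] - 7, 0.25 * M[, 2] + 2)
  expect_equal(port_overlap(f(A), f(B)), p0, tolerance = 1e-12)

  seps <- c(0, 2, 4)
  ports <- vapply(seps, function(s) {
    mean(vapply(1:10, function(r) {
      withr::with_seed(100 * r + s, {
        a <- cbind(rnorm(300), rnorm(300))
        b <- cbind(rnorm(300, s), rnorm(300))
      })
      port_overlap(a, b)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ports) < 0))
})

test_that("degenerate zero-width samples fall back to the point rule with a warning", {
  A <- cbind(rep(1, 12), rep(2, 12))
  B <- cbind(seq(0, 3, length.out = 20), seq(0, 3, length.out = 20))
  expect_warning(expect_warning(p <- port_overlap(A, B, alphas = 0),
                                "Zero-length"), "Zero-length")
  expect_equal(p, 1.0)
  expect_warning(expect_warning(p2 <- port_overlap(A, B + 100, alphas = 0),
                                "Zero-length"), "Zero-length")
  expect_equal(p2, 0.0)
})

test_that("overlap matrices are asymmetric, unit-diagonal and flag degeneracy", {
  withr::with_seed(11, {
    emb <- tibble::tibble(
      tsne1 = c(rnorm(60), rnorm(60), rnorm(60, 50)),
      tsne2 = c(rnorm(60), rnorm(60), rnorm(60, 50)),
      group = rep(c("h-can", "a-can", "h-lymp"), each = 60)
    )
  })
  om <- overlap_matrix(emb)
  expect_s3_class(om, "overlap_matrix")
  expect_equal(unname(diag(unclass(om))), rep(1, 3))
  # identical distributions overlap highly in both directions
  expect_gt(om["a-can", "h-can"], 0.5)
  expect_gt(om["h-can", "a-can"], 0.5)
  # the disjoint group overlaps nobody
  expect_lt(om["h-lymp", "h-can"], 0.01)
  expect_lt(om["a-can", "h-lymp"], 0.01)
  # constructed ordering: a-can is nearer h-can than h-lymp
  expect_gt(om["a-can", "h-can"], om["a-can", "h-lymp"])

  td <- tidy(om)
  expect_equal(nrow(td), 9)

  # literally identical groups give 1.0 in both directions
  dup <- tibble::tibble(tsne1 = rep(emb$tsne1[1:60], 2),
                        tsne2 = rep(emb$tsne2[1:60], 2),
                        group = rep(c("g1", "g2"), each = 60))
  om2 <- overlap_matrix(dup)
  expect_equal(unname(unclass(om2)["g1", "g2"]), 1.0)
  expect_equal(unname(unclass(om2)["g2", "g1"]), 1.0)
})

test_that("mean counterpart overlap averages both directions and checks groups", {
  m <- matrix(0.5, 4, 4,
              dimnames = list(c("a-can", "a-lymp", "h-can", "h-lymp"),
                              c("a-can", "a-lymp", "h-can", "h-lymp")))
  m["a-can", "h-can"] <- 0.2
  m["h-can", "a-can"] <- 0.4
  m["a-lymp", "h-lymp"] <- 0.6
  m["h-lymp", "a-lymp"] <- 0.8
  class(m) <- c("overlap_matrix", class(m))
  expect_equal(mean_sample_overlap(m), 0.5)

  expect_error(mean_sample_overlap(m[1:3, 1:3]), "h-lymp")
})
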