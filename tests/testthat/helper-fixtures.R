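# Shared in-code fixtures for the test suite.

# Rasterise an axis-aligned ellipse into a label matrix (label 1).
ellipse_mask <- function(a, b, h = ceiling(2 * b) + 21, w = ceiling(2 * a) + 21,
                         cx = w / 2, cy = h / 2) {
  cc <- matrix(rep(seq_len(w), each = h), h)
  rr <- matrix(rep(seq_len(h), w), h)
  m <- matrix(0L, h, w)
  m[(((cc - 0.5) - cx) / a)^2 + (((rr - 0.5) - cy) / b)^2 <= 1] <- 1L
  m
}

flat_intensity <- function(mask, value = 120L) {
  matrix(as.integer(value), nrow(mask), ncol(mask))
}

# A small uniform truth table.
random_truth <- function(n, extent = 1000, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    cell_id = sprintf("t%05d", seq_len(n)),
    x = runif(n, 0, extent),
    y = runif(n, 0, extent),
    cls = sample(cell_classes(core = TRUE), n, replace = TRUE),
    source = "annotation"
  ))
}

# Independent Kruskal-Wallis oracle straight from the definition:
# H = (N - 1) * sum n_i (rbar_i - rbar)^2 / sum (r_ij - rbar)^2
# (tie-corrected automatically because ranks use averages).
kw_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(r)
  rbar <- mean(r)
  num <- sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - rbar)^2))
  den <- sum((r - rbar)^2)
  if (den == 0) return(0)
  (N - 1) * num / den
}

# Mean silhouette width of a 2-D embedding against true labels.
mean_silhouette <- function(coords, labels) {
  s <- cluster::silhouette(as.integer(factor(labels)), stats::dist(coords))
  mean(s[, "sil_width"])
}
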