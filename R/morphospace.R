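#' t-SNE embedding configuration
#'
#' Parameters of the 2-D morphospace embedding: exact-gradient t-SNE
#' (`theta = 0`) at perplexity 50, on per-feature z-scored values. The
#' perplexity must satisfy `perplexity < (n - 1) / 3`, i.e. at least
#' `3 * perplexity + 2` cells.
#'
#' @param perplexity t-SNE perplexity.
#' @param theta Barnes-Hut accuracy parameter; 0 = exact gradient.
#' @param dims Output dimensionality (fixed at 2 for the morphospace).
#' @param seed RNG seed making the embedding reproducible.
#' @param standardise Z-score each feature before embedding (recommended:
#'   raw areas would otherwise dominate the distance).
#' @param max_iter Optimisation iterations.
#' @return A list of class `embedding_config`.
#' @export
embedding_config <- function(perplexity = 50, theta = 0, dims = 2,
                             seed = 1L, standardise = TRUE, max_iter = 1000) {
  stopifnot(dims == 2, perplexity > 0, theta >= 0)
  structure(list(perplexity = perplexity, theta = theta, dims = dims,
                 seed = seed, standardise = standardise,
                 max_iter = max_iter),
            class = "embedding_config")
}

#' Embed feature vectors into the 2-D morphospace
#'
#' Reduces the morphometric feature table to two dimensions with t-SNE.
#' Deterministic for a fixed `cfg$seed`.
#'
#' @param features Data frame containing the registry feature columns (plus
#'   any id columns, which are carried through).
#' @param cfg An [embedding_config()].
#' @param feature_cols Names of the columns to embed; defaults to the
#'   registry features present in `features`.
#' @return The input tibble with `tsne1`, `tsne2` appended; attribute
#'   `embedding_config`.
#' @export
embed_morphospace <- function(features, cfg = embedding_config(),
                              feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- intersect(feature_registry()$name, names(features))
    if (length(feature_cols) == 0) {
      feature_cols <- names(features)[purrr::map_lgl(features, is.numeric)]
    }
  }
  X <- as.matrix(features[, feature_cols])
  if (!all(is.finite(X))) abort("Feature matrix contains non-finite values.")
  n_min <- 3 * cfg$perplexity + 2
  if (nrow(X) < n_min) {
    abort(paste0("t-SNE at perplexity ", cfg$perplexity, " needs at least ",
                 n_min, " cells; got ", nrow(X), "."))
  }
  if (cfg$standardise) {
    keep <- apply(X, 2, sd) > 0
    X <- scale(X[, keep, drop = FALSE])
  }
  emb <- with_seed_if(cfg$seed, {
    Rtsne::Rtsne(X, dims = cfg$dims, perplexity = cfg$perplexity,
                 theta = cfg$theta, max_iter = cfg$max_iter,
                 pca = FALSE, check_duplicates = FALSE, verbose = FALSE)
  })
  out <- as_tibble(features)
  out$tsne1 <- emb$Y[, 1]
  out$tsne2 <- emb$Y[, 2]
  attr(out, "embedding_config") <- cfg
  attr(out, "kl_divergence") <- utils::tail(emb$itercosts, 1)
  out
}

#' Morphospace overlap between two point sets (port)
#'
#' Fraction of sample A's morphospace lying inside sample B's, computed over
#' a quantile ladder: for each dimension d and each ladder level alpha, the
#' level interval of a group is `[Q_alpha, Q_(1-alpha)]` of its coordinates
#' in d; the per-dimension score is the mean over alpha of
#' `|I_alpha(A, d) intersect I_alpha(B, d)| / |I_alpha(A, d)|`, and the port
#' is the product of the per-dimension scores. Asymmetric by construction:
#' `port(A, B)` is the fraction of A inside B.
#'
#' @param A,B Matrices or data frames of coordinates with the same number of
#'   columns (2 for the t-SNE morphospace).
#' @param alphas Quantile ladder, a subset of \[0, 0.5).
#' @return A single overlap value in \[0, 1\].
#' @export
#' @examples
#' a <- cbind(runif(100), runif(100))
#' port_overlap(a, a)  # 1
port_overlap <- function(A, B, alphas = seq(0, 0.49, by = 0.01)) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) abort("A and B must have the same dimensionality.")
  if (any(alphas < 0) || any(alphas >= 0.5)) {
    abort("Quantile ladder must lie in [0, 0.5).")
  }
  if (nrow(A) < 2 || nrow(B) < 2) abort("Need at least 2 points per sample.")
  if (nrow(A) < 10 || nrow(B) < 10) {
    warn("Fewer than 10 points in a group; overlap estimate is unstable.")
  }
  per_dim <- purrr::map_dbl(seq_len(ncol(A)), function(d) {
    qa <- quantile(A[, d], c(alphas, 1 - alphas), names = FALSE)
    qb <- quantile(B[, d], c(alphas, 1 - alphas), names = FALSE)
    k <- length(alphas)
    scores <- purrr::map_dbl(seq_len(k), function(i) {
      a_lo <- qa[i]; a_hi <- qa[k + i]
      b_lo <- qb[i]; b_hi <- qb[k + i]
      len <- a_hi - a_lo
      if (len <= 0) {
        warn("Zero-length quantile interval; using point-membership rule.")
        return(as.numeric(a_lo >= b_lo && a_lo <= b_hi))
      }
      max(0, min(a_hi, b_hi) - max(a_lo, b_lo)) / len
    })
    mean(scores)
  })
  prod(per_dim)
}

#' Pairwise morphospace overlap between cell-class groups
#'
#' Computes [port_overlap()] for every ordered pair of groups in an embedded
#' feature table. Entry `[A, B]` is the fraction of group A's morphospace
#' inside group B's, so the matrix is asymmetric and is read row-wise.
#' Degenerate groups (< 2 points) get `NA` entries rather than fabricated
#' values; groups under 10 members are flagged.
#'
#' @param embedded Data frame with `tsne1`, `tsne2` and a grouping column.
#' @param group_col Name of the grouping column (e.g. `"group"` holding
#'   labels such as `h-can`, `h-lymp`, `a-can`, `a-lymp`).
#' @param alphas Quantile ladder passed to [port_overlap()].
#' @return A numeric matrix of class `overlap_matrix` with group dimnames;
#'   attribute `flagged` lists groups with fewer than 10 members.
#' @export
overlap_matrix <- function(embedded, group_col = "group",
                           alphas = seq(0, 0.49, by = 0.01)) {
  stopifnot(group_col %in% names(embedded),
            all(c("tsne1", "tsne2") %in% names(embedded)))
  g <- as.character(embedded[[group_col]])
  gl <- sort(unique(g))
  if (length(gl) < 2) abort("Need at least 2 groups.")
  coords <- split(as.data.frame(embedded[, c("tsne1", "tsne2")]), g)
  sizes <- purrr::map_int(coords, nrow)
  flagged <- names(sizes)[sizes < 10]
  m <- matrix(NA_real_, length(gl), length(gl), dimnames = list(gl, gl))
  for (a in gl) {
    for (b in gl) {
      if (sizes[[a]] >= 2 && sizes[[b]] >= 2) {
        m[a, b] <- suppressWarnings(
          port_overlap(coords[[a]], coords[[b]], alphas = alphas))
      }
    }
  }
  attr(m, "flagged") <- flagged
  attr(m, "alphas") <- alphas
  class(m) <- c("overlap_matrix", class(m))
  m
}

#' @rdname overlap_matrix
#' @param x An `overlap_matrix`.
#' @param ... Unused.
#' @method tidy overlap_matrix
#' @export
tidy.overlap_matrix <- function(x, ...) {
  m <- unclass(x)
  tidyr::expand_grid(group_a = rownames(m), group_b = colnames(m)) |>
    dplyr::mutate(overlap = purrr::map2_dbl(.data$group_a, .data$group_b,
                                            function(a, b) m[a, b]))
}

#' Mean counterpart overlap for one sample
#'
#' Averages the morphospace overlap between each animal cell class and its
#' human counterpart (a-can vs h-can, a-lymp vs h-lymp), in both directions.
#' This is the per-sample score whose cohort-level correlation with balanced
#' accuracy indicates whether the classifier is morphologically suited to a
#' new sample.
#'
#' @param om An [overlap_matrix()].
#' @param pairs List of counterpart group pairs.
#' @return Mean of the available counterpart overlaps (both directions).
#' @export
mean_sample_overlap <- function(om,
                                pairs = list(c("a-can", "h-can"),
                                             c("a-lymp", "h-lymp"))) {
  groups <- unique(unlist(pairs))
  absent <- setdiff(groups, rownames(om))
  if (length(absent) > 0) {
    abort(paste0("Counterpart group(s) missing from overlap matrix: ",
                 paste(absent, collapse = ", "), "."))
  }
  vals <- unlist(lapply(pairs, function(p) c(om[p[1], p[2]], om[p[2], p[1]])))
  mean(vals, na.rm = TRUE)
}
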