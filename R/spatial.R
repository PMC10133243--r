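#' Quadrat counts for two point patterns
#'
#' Overlays a regular grid of square quadrats on the joint bounding box of
#' the cancer and lymphocyte point patterns and counts each pattern per
#' quadrat. The grid is anchored at the joint bounding-box minimum and
#' quadrats are half-open `[a, b)`, so a point on an interior boundary falls
#' in the higher-index quadrat and every point is counted exactly once.
#'
#' @param cancer,lymph Data frames with `x`, `y` in micrometres.
#' @param width Quadrat side length in micrometres (default 250).
#' @return A tibble of class `quadrat_counts` with one row per grid cell:
#'   `qx`, `qy` (0-based indices), `n_cancer`, `n_lymph`; attributes `width`,
#'   `origin`.
#' @export
quadrat_counts <- function(cancer, lymph, width = 250) {
  if (!is.finite(width) || width <= 0) abort("Quadrat `width` must be > 0.")
  if (nrow(cancer) == 0 || nrow(lymph) == 0) {
    abort("Both point sets must be non-empty.")
  }
  x0 <- min(cancer$x, lymph$x)
  y0 <- min(cancer$y, lymph$y)
  ix <- function(p) floor((p$x - x0) / width)
  iy <- function(p) floor((p$y - y0) / width)
  nx <- max(ix(cancer), ix(lymph)) + 1L
  ny <- max(iy(cancer), iy(lymph)) + 1L
  key <- function(p) iy(p) * nx + ix(p)
  all_keys <- 0:(nx * ny - 1L)
  cc <- tabulate(match(key(cancer), all_keys), nbins = length(all_keys))
  lc <- tabulate(match(key(lymph), all_keys), nbins = length(all_keys))
  out <- tibble(
    qx = as.integer(all_keys %% nx),
    qy = as.integer(all_keys %/% nx),
    n_cancer = as.integer(cc),
    n_lymph = as.integer(lc)
  )
  attr(out, "width") <- width
  attr(out, "origin") <- c(x = x0, y = y0)
  class(out) <- c("quadrat_counts", class(out))
  out
}

#' Morisita-Horn tumour-immune colocalisation
#'
#' The Morisita-Horn overlap index between the quadrat count distributions of
#' cancer cells and lymphocytes:
#' \deqn{MH = \frac{2 \sum_i x_i y_i}{\left(\sum_i x_i^2 / X^2 + \sum_i y_i^2 / Y^2\right) X Y}}
#' with \eqn{X = \sum_i x_i}, \eqn{Y = \sum_i y_i}. MH lies in \[0, 1\]: 1
#' when the two patterns occupy quadrats in identical proportions, 0 when
#' they never share a quadrat. For interpretability in survival models the
#' score is also returned multiplied by 100 (`coloc100`).
#'
#' @param q Either a [quadrat_counts()] tibble or a list/data frame with
#'   numeric `n_cancer` and `n_lymph`.
#' @return A one-row tibble: `mh`, `coloc100`, `quadrat_width`, `n_quadrats`.
#' @export
#' @examples
#' morisita_horn(data.frame(n_cancer = c(2, 1), n_lymph = c(1, 2)))  # 0.8
morisita_horn <- function(q) {
  x <- as.numeric(q$n_cancer)
  y <- as.numeric(q$n_lymph)
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0) {
    abort("Morisita-Horn undefined: a point set has zero total count.")
  }
  mh <- 2 * sum(x * y) / ((sum(x^2) / X^2 + sum(y^2) / Y^2) * X * Y)
  tibble(mh = mh, coloc100 = 100 * mh,
         quadrat_width = attr(q, "width") %||% NA_real_,
         n_quadrats = length(x))
}

#' Colocalisation score from raw cell positions
#'
#' Convenience chain: [quadrat_counts()] then [morisita_horn()].
#'
#' @inheritParams quadrat_counts
#' @return As [morisita_horn()].
#' @export
colocalization_score <- function(cancer, lymph, width = 250) {
  morisita_horn(quadrat_counts(cancer, lymph, width = width))
}

#' Sensitivity of the colocalisation score to quadrat width
#'
#' Diagnostic sweep: recomputes the Morisita-Horn score over a ladder of
#' quadrat widths so the dependence on the discretisation scale can be
#' inspected rather than guessed.
#'
#' @inheritParams quadrat_counts
#' @param widths Vector of quadrat widths (µm).
#' @return Tibble with one row per width.
#' @export
coloc_width_sweep <- function(cancer, lymph,
                              widths = c(50, 100, 150, 200, 250, 350, 500)) {
  purrr::map_dfr(widths, function(w) colocalization_score(cancer, lymph, w))
}

#' Lymphocyte relative abundance
#'
#' Percentage of lymphocytes among classified cells. `other` cells are
#' excluded from the denominator, which covers cancer + lymphocyte + stromal.
#'
#' @param cells Data frame with a `cls` column.
#' @return A one-row tibble: `lymphocyte_pct`, `n_lymph`, `n_classified`.
#' @export
immune_abundance <- function(cells) {
  core <- cells$cls[cells$cls %in% CORE_CLASSES]
  if (length(core) == 0) {
    abort("No cells classified as cancer, lymphocyte or stromal.")
  }
  n_l <- sum(core == "lymphocyte")
  tibble(lymphocyte_pct = 100 * n_l / length(core),
         n_lymph = n_l, n_classified = length(core))
}
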