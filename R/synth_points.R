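#' Clustered point-pattern specification
#'
#' Parameters of the Thomas-type cluster process used to emulate tumour and
#' immune cell positions with a tunable degree of colocalisation. Cancer
#' cells form Gaussian clusters around uniformly placed parents; each
#' lymphocyte attaches with probability `theta` to a cancer parent (sharing
#' the tumour's cluster centres) and otherwise to an independent parent set.
#' `theta = 1` forces full spatial mixing, `theta = 0` spatially independent
#' immune clusters.
#'
#' @param width,height Field size in µm.
#' @param n_cancer,n_lymph Exact point counts to return.
#' @param cluster_sd Gaussian cluster spread (µm).
#' @param n_parents Number of cluster parents per parent set.
#' @param theta Mixing probability in \[0, 1\].
#' @return A list of class `coloc_spec`.
#' @export
coloc_spec <- function(width = 2000, height = 2000, n_cancer = 600,
                       n_lymph = 400, cluster_sd = 60, n_parents = 12,
                       theta = 0.5) {
  stopifnot(width > 0, height > 0, n_cancer > 0, n_lymph > 0,
            cluster_sd > 0, n_parents >= 1)
  if (theta < 0 || theta > 1) abort("`theta` must be in [0, 1].")
  structure(list(width = width, height = height, n_cancer = n_cancer,
                 n_lymph = n_lymph, cluster_sd = cluster_sd,
                 n_parents = n_parents, theta = theta),
            class = "coloc_spec")
}

#' Generate cancer and lymphocyte point patterns
#'
#' Simulates the two point sets described by a [coloc_spec()]. Offspring that
#' fall outside the field are wrapped toroidally so the requested counts are
#' returned exactly and the marginal intensity stays uniform.
#'
#' @param spec A [coloc_spec()].
#' @param seed RNG seed.
#' @return List with tibbles `cancer` and `lymph` (columns `x`, `y` in µm)
#'   and the generating `spec`.
#' @export
#' @examples
#' pp <- gen_point_pattern(coloc_spec(theta = 1), seed = 3)
#' nrow(pp$cancer)
gen_point_pattern <- function(spec = coloc_spec(), seed = 1L) {
  stopifnot(inherits(spec, "coloc_spec"))
  with_seed_if(seed, {
    parents_c <- cbind(runif(spec$n_parents, 0, spec$width),
                       runif(spec$n_parents, 0, spec$height))
    parents_i <- cbind(runif(spec$n_parents, 0, spec$width),
                       runif(spec$n_parents, 0, spec$height))
    offspring <- function(parents, idx, n) {
      x <- parents[idx, 1] + rnorm(n, 0, spec$cluster_sd)
      y <- parents[idx, 2] + rnorm(n, 0, spec$cluster_sd)
      tibble(x = x %% spec$width, y = y %% spec$height)
    }
    cancer <- offspring(parents_c,
                        sample.int(spec$n_parents, spec$n_cancer, TRUE),
                        spec$n_cancer)
    use_cancer_parent <- runif(spec$n_lymph) < spec$theta
    idx <- sample.int(spec$n_parents, spec$n_lymph, TRUE)
    lx <- ifelse(use_cancer_parent, parents_c[idx, 1], parents_i[idx, 1]) +
      rnorm(spec$n_lymph, 0, spec$cluster_sd)
    ly <- ifelse(use_cancer_parent, parents_c[idx, 2], parents_i[idx, 2]) +
      rnorm(spec$n_lymph, 0, spec$cluster_sd)
    lymph <- tibble(x = lx %% spec$width, y = ly %% spec$height)
    list(cancer = cancer, lymph = lymph, spec = spec)
  })
}
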