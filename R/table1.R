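#' Published per-species balanced accuracies
#'
#' Loads the bundled 20-species summary of the human-lung model's overall
#' balanced classification accuracy (BCAcc) on the pan-species cohort: one
#' H&E section per species, with its tumour type and the number of
#' pathologist single-cell annotations used for evaluation.
#'
#' @return A tibble with 20 rows and columns `code`, `common_name`,
#'   `scientific_name`, `diagnosis`, `site`, `tumour_type`, `annotations`,
#'   `bcacc`.
#' @export
#' @examples
#' load_table1_fixture()
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_species_bcacc.csv",
                      package = "panspecies", mustWork = TRUE)
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(nrow(tb) == 20L)
  types <- sort(table(tb$tumour_type), decreasing = TRUE)
  # cohort composition is fixed: 9 epithelial, 4 round-cell, 4 mesenchymal,
  # 2 neuroendocrine, 1 sex-cord stromal
  stopifnot(identical(unname(as.integer(types)), c(9L, 4L, 4L, 2L, 1L)))
  tb
}

#' Canine prostate per-class balanced accuracies
#'
#' The three per-class BCAcc values of the human-lung model on the canine
#' prostate carcinoma cohort (26,997 annotations): cancer 0.88, lymphocyte
#' 0.95, stromal 0.87.
#'
#' @return A tibble with columns `cls` and `bcacc`.
#' @export
load_prostate_fixture <- function() {
  path <- system.file("extdata", "canine_prostate_bcacc.csv",
                      package = "panspecies", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Cohort-level summaries of the per-species accuracies
#'
#' Computes the descriptive and inferential statistics reported for the
#' 20-species cohort: mean/min/max overall BCAcc, counts of species reaching
#' 0.70 and 0.80, a Kruskal-Wallis comparison of BCAcc across tumour types
#' with rank-based effect size, and the Spearman correlation between the
#' number of annotations and BCAcc.
#'
#' @param fixture Tibble as returned by [load_table1_fixture()].
#' @param n_boot Bootstrap replicates for the effect-size CI.
#' @param seed Seed for the bootstrap.
#' @return A list of class `table1_summary` with elements `bcacc_mean`,
#'   `bcacc_min`, `bcacc_max`, `n_ge_070`, `n_ge_080`, `kw` (a `kw_effect`
#'   object) and `spearman` (a tibble from [correlate()]).
#' @export
table1_summaries <- function(fixture = load_table1_fixture(),
                             n_boot = 2000, seed = 7L) {
  kw <- kruskal_wallis(fixture$bcacc, fixture$tumour_type,
                       n_boot = n_boot, seed = seed)
  sp <- correlate(fixture$annotations, fixture$bcacc, method = "spearman")
  out <- list(
    bcacc_mean = mean(fixture$bcacc),
    bcacc_min = min(fixture$bcacc),
    bcacc_max = max(fixture$bcacc),
    n_ge_070 = sum(fixture$bcacc >= 0.70),
    n_ge_080 = sum(fixture$bcacc >= 0.80),
    kw = kw,
    spearman = sp
  )
  class(out) <- "table1_summary"
  out
}

#' @export
print.table1_summary <- function(x, ...) {
  cat("Pan-species cohort summary (n = 20 species)\n")
  cat(sprintf("  overall BCAcc: mean %.3f, range %.2f-%.2f\n",
              x$bcacc_mean, x$bcacc_min, x$bcacc_max))
  cat(sprintf("  species with BCAcc >= 0.70: %d/20; >= 0.80: %d/20\n",
              x$n_ge_070, x$n_ge_080))
  cat(sprintf("  Kruskal-Wallis by tumour type: H(%d) = %.3f, p = %.3f, eta^2 = %.3f\n",
              x$kw$df, x$kw$H, x$kw$p, x$kw$eta_sq))
  cat(sprintf("  Spearman annotations vs BCAcc: rho = %.3f, p = %.3f\n",
              x$spearman$estimate, x$spearman$p))
  invisible(x)
}
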