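#' Simulate a cross-species transfer cohort
#'
#' End-to-end desk-scale emulation of the transfer-evaluation analysis: a
#' synthetic cohort of "species" whose cell classes sit at increasing
#' feature-space distance from a fixed human reference, scored both by the
#' morphospace-overlap metric and by the balanced accuracy of a classifier
#' trained on the human cells only.
#'
#' For each species, human and animal cancer/lymphocyte/stromal cells are
#' drawn from class-conditional Gaussians in the 27-dimensional feature
#' space; each animal class centroid is displaced from its human counterpart
#' by `separation` standard deviations along its own random direction drawn
#' inside the subspace spanned by the class centroids. (Displacement
#' orthogonal to that discriminative subspace would neither confuse a
#' classifier nor should it; drift inside it emulates an animal cell class
#' coming to resemble a different human class.) A nearest-centroid
#' classifier fitted on the human cells predicts the animal cells, yielding
#' a per-species BCAcc via
#' [classification_metrics()]; in parallel the species' human + animal cells
#' are jointly embedded with [embed_morphospace()] and the mean counterpart
#' overlap is computed with [overlap_matrix()] + [mean_sample_overlap()].
#' Higher separation should depress both scores, so the cohort-level
#' correlation between mean overlap and BCAcc is expected to be positive.
#'
#' @param n_species Number of synthetic species.
#' @param separations Feature-space displacement (in SD units) per species;
#'   defaults to an even ladder from 0 to 4.
#' @param n_human,n_animal Cells per class for the human reference and the
#'   animal sample.
#' @param class_sep Distance between the human class centroids (SD units).
#' @param n_features Dimensionality of the feature space.
#' @param cfg Embedding configuration; the default uses a reduced iteration
#'   count to keep the 20-embedding cohort fast.
#' @param seed Cohort seed (per-species seeds are derived from it).
#' @return Tibble: `species`, `separation`, `mean_overlap`, `bcacc`.
#' @export
simulate_transfer_cohort <- function(n_species = 20,
                                     separations = seq(0, 4,
                                                       length.out = n_species),
                                     n_human = 120, n_animal = 100,
                                     class_sep = 4, n_features = 27,
                                     cfg = embedding_config(max_iter = 500),
                                     seed = 1L) {
  stopifnot(length(separations) == n_species)
  purrr::map_dfr(seq_len(n_species), function(s) {
    sp_seed <- derive_seed(seed, s)
    res <- with_seed_if(sp_seed, {
      mu_h <- lapply(seq_along(CORE_CLASSES), function(k) {
        mu <- rep(0, n_features)
        mu[k] <- class_sep  # orthogonal class axes
        mu
      })
      names(mu_h) <- CORE_CLASSES
      # per-class drift direction inside the class-discriminative subspace
      # (the first three feature axes, which span the class centroids)
      shift <- lapply(CORE_CLASSES, function(cl) {
        d3 <- rnorm(3)
        d3 <- d3 / sqrt(sum(d3^2))
        c(separations[s] * d3, rep(0, n_features - 3))
      })
      names(shift) <- CORE_CLASSES
      draw <- function(mu, n) {
        matrix(rnorm(n * n_features), n) + matrix(mu, n, n_features,
                                                  byrow = TRUE)
      }
      Xh <- do.call(rbind, lapply(CORE_CLASSES, function(cl)
        draw(mu_h[[cl]], n_human)))
      Xa <- do.call(rbind, lapply(CORE_CLASSES, function(cl)
        draw(mu_h[[cl]] + shift[[cl]], n_animal)))
      cls_h <- rep(CORE_CLASSES, each = n_human)
      cls_a <- rep(CORE_CLASSES, each = n_animal)

      # nearest-centroid classifier trained on the human reference
      cents <- do.call(rbind, lapply(CORE_CLASSES, function(cl)
        colMeans(Xh[cls_h == cl, , drop = FALSE])))
      d2 <- outer(rowSums(Xa^2), rep(1, 3)) - 2 * Xa %*% t(cents) +
        outer(rep(1, nrow(Xa)), rowSums(cents^2))
      pred <- CORE_CLASSES[max.col(-d2)]
      mr <- classification_metrics(confusion_counts(
        data.frame(true_cls = cls_a, pred_cls = pred)))

      feats <- as_tibble(rbind(Xh, Xa), .name_repair = "minimal")
      names(feats) <- paste0("f", seq_len(n_features))
      short <- c(cancer = "can", lymphocyte = "lymp", stromal = "strom")
      feats$group <- c(paste0("h-", short[cls_h]), paste0("a-", short[cls_a]))
      cfg_s <- cfg
      cfg_s$seed <- sp_seed
      emb <- embed_morphospace(feats, cfg_s,
                               feature_cols = paste0("f", seq_len(n_features)))
      om <- overlap_matrix(emb, "group")
      list(ov = mean_sample_overlap(om), bcacc = mr$overall_bcacc)
    })
    tibble(species = sprintf("sp%02d", s), separation = separations[s],
           mean_overlap = res$ov, bcacc = res$bcacc)
  })
}
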