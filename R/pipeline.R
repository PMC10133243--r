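#' Run the analysis pipeline from a configuration
#'
#' Chains the package's stages from a single configuration (a YAML/JSON file
#' or an equivalent named list). Recognised stages, run in the order given:
#'
#' * `simulate` — generate a labelled cell image, predictions from a
#'   confusion specification, a clustered point pattern and a survival
#'   cohort; cell tables are written when `out` is set.
#' * `featurize` — extract the 27 morphometric features from the simulated
#'   image.
#' * `morphospace` — embed the features and compute the class overlap matrix.
#' * `evaluate` — match predictions to truth and compute the confusion
#'   matrix and balanced-accuracy report.
#' * `colocalize` — quadrat counts and the Morisita-Horn score of the point
#'   pattern.
#' * `survive` — VIF screen and multivariate Cox fit of the survival cohort,
#'   plus the lower-quartile dichotomised fit.
#' * `table1-stats` — cohort summaries of the bundled per-species accuracies.
#'
#' Every stochastic stage consumes a seed derived from `config$seed`, and all
#' parameters and seeds are recorded in the returned report (and in
#' `report.json` under `config$out`). Re-running with the same configuration
#' reproduces the reports exactly.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, or a named list with
#'   elements `stages` (character vector), `seed` (integer, default 1),
#'   optional `out` (output directory) and optional per-stage parameter
#'   lists (`simulate`, `morphospace`, `colocalize`, `survive`).
#' @return Named list of stage reports (class `pipeline_report`), invisibly
#'   written to `out/report.json` when `out` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    ext <- tolower(sub(".*\\.", "", config))
    config <- switch(ext,
      yaml = ,
      yml = yaml::read_yaml(config),
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      abort("Config must be a .yaml/.yml/.json file or a list.")
    )
  }
  stopifnot(is.list(config))
  stages <- unlist(config$stages)
  known <- c("simulate", "featurize", "morphospace", "evaluate",
             "colocalize", "survive", "table1-stats")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", "),
                 ". Known stages: ", paste(known, collapse = ", "),
                 ". (Model training is out of scope.)"))
  }
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  state <- new.env(parent = emptyenv())
  reports <- list(config = list(stages = stages, seed = seed))

  for (st in stages) {
    reports[[st]] <- tryCatch(
      run_stage(st, config, seed, state, out_dir),
      error = function(e) {
        abort(paste0("Stage '", st, "' failed: ", conditionMessage(e)))
      }
    )
  }
  class(reports) <- "pipeline_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(strip_reports(reports),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  reports
}

run_stage <- function(st, config, seed, state, out_dir) {
  switch(st,
    "simulate" = {
      p <- config$simulate %||% list()
      img <- gen_cell_image(
        n_per_class = unlist(p$n_per_class %||%
                               c(cancer = 40, lymphocyte = 40, stromal = 40)),
        canvas = p$canvas %||% c(220, 220),
        scale = p$scale %||% 0.456,
        seed = derive_seed(seed, 1))
      cs <- confusion_spec(
        confusion = p$confusion %||%
          matrix(c(0.9, 0.05, 0.05,
                   0.05, 0.9, 0.05,
                   0.05, 0.05, 0.9), 3, byrow = TRUE,
                 dimnames = list(CORE_CLASSES, CORE_CLASSES)),
        jitter_sd = p$jitter_sd %||% 0.5,
        miss_rate = p$miss_rate %||% 0.05)
      preds <- gen_predictions(img$truth, cs, seed = derive_seed(seed, 2))
      pp <- gen_point_pattern(coloc_spec(theta = p$theta %||% 0.7),
                              seed = derive_seed(seed, 3))
      surv <- gen_survival(survival_spec(), seed = derive_seed(seed, 4))
      state$img <- img; state$preds <- preds; state$pp <- pp
      state$surv <- surv
      if (!is.null(out_dir)) {
        write_cell_table(img$truth, file.path(out_dir, "truth.csv"))
        write_cell_table(preds[, c("cell_id", "x", "y", "cls", "source")],
                         file.path(out_dir, "predictions.csv"))
        write_survival_table(surv, file.path(out_dir, "survival.csv"))
      }
      list(seed = derive_seed(seed, 1), n_cells = nrow(img$truth),
           n_predictions = nrow(preds), n_subjects = nrow(surv))
    },
    "featurize" = {
      if (is.null(state$img)) abort("run the 'simulate' stage first")
      feats <- extract_features(state$img$mask, state$img$intensity,
                                scale = state$img$spec$scale)
      state$features <- feats
      if (!is.null(out_dir)) {
        readr::write_csv(feats, file.path(out_dir, "features.csv"))
      }
      list(n_cells = nrow(feats), registry_hash = attr(feats, "registry_hash"))
    },
    "morphospace" = {
      if (is.null(state$features)) abort("run the 'featurize' stage first")
      feats <- state$features
      truth <- state$img$truth
      # label k in the mask is the k-th truth row
      feats$group <- truth$cls[as.integer(feats$cell_id)]
      cfg <- embedding_config(
        perplexity = (config$morphospace %||% list())$perplexity %||% 20,
        seed = derive_seed(seed, 5), max_iter = 500)
      emb <- embed_morphospace(feats, cfg)
      om <- overlap_matrix(emb, "group")
      if (!is.null(out_dir)) {
        readr::write_csv(tidy(om), file.path(out_dir, "overlap.csv"))
      }
      list(seed = cfg$seed, overlap = as.list(as.data.frame(unclass(om))))
    },
    "evaluate" = {
      if (is.null(state$preds)) abort("run the 'simulate' stage first")
      mr <- score_predictions(state$img$truth, state$preds)
      list(overall_bcacc = mr$overall_bcacc,
           per_class = as.list(setNames(mr$per_class$bcacc,
                                        mr$per_class$cls)))
    },
    "colocalize" = {
      if (is.null(state$pp)) abort("run the 'simulate' stage first")
      w <- (config$colocalize %||% list())$width %||% 250
      sc <- colocalization_score(state$pp$cancer, state$pp$lymph, width = w)
      as.list(sc)
    },
    "survive" = {
      if (is.null(state$surv)) abort("run the 'simulate' stage first")
      vif <- vif_report(state$surv)
      fit <- fit_cox(state$surv,
                     covariates = vif$term[vif$retained])
      grp <- dichotomize_lower_quartile(state$surv$coloc100)
      d <- state$surv
      d$group <- grp
      fit_d <- fit_cox(d, covariates = c("group", "age", "lymphocyte_pct"))
      list(vif = as.list(setNames(vif$vif, vif$term)),
           continuous = as.list(setNames(fit$coefficients$hr,
                                         fit$coefficients$term)),
           dichotomised = as.list(setNames(fit_d$coefficients$hr,
                                           fit_d$coefficients$term)))
    },
    "table1-stats" = {
      s <- table1_summaries(seed = derive_seed(seed, 6))
      list(bcacc_mean = s$bcacc_mean, n_ge_070 = s$n_ge_070,
           n_ge_080 = s$n_ge_080, kw_H = s$kw$H, kw_p = s$kw$p,
           eta_sq = s$kw$eta_sq, spearman_rho = s$spearman$estimate)
    }
  )
}

# drop non-serialisable bits before writing JSON
strip_reports <- function(reports) {
  reports[setdiff(names(reports), "")]
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report; stages:",
      paste(setdiff(names(x), "config"), collapse = ", "), "\n")
  invisible(x)
}
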