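#' Classifier error specification
#'
#' Stand-in for a cell classifier's error behaviour: a row-stochastic
#' confusion matrix P(predicted class | true class) over the three annotated
#' classes (with an optional `other` column), Gaussian positional jitter,
#' a detection miss rate and a spurious-detection rate.
#'
#' @param confusion Numeric matrix, rows named `cancer`, `lymphocyte`,
#'   `stromal`; columns a subset of [cell_classes()]; each row sums to 1.
#' @param jitter_sd SD (µm) of isotropic Gaussian positional noise.
#' @param miss_rate Probability a true cell is not detected, in \[0, 1).
#' @param spurious_rate Expected number of spurious detections per true cell
#'   (>= 0); spurious cells get a class drawn uniformly from the three core
#'   classes and a uniform position.
#' @return A list of class `confusion_spec`.
#' @export
#' @examples
#' confusion_spec()  # identity classifier
confusion_spec <- function(confusion = diag(3), jitter_sd = 0,
                           miss_rate = 0, spurious_rate = 0) {
  confusion <- as.matrix(confusion)
  if (is.null(rownames(confusion))) rownames(confusion) <- CORE_CLASSES
  if (is.null(colnames(confusion))) {
    colnames(confusion) <- CELL_CLASSES[seq_len(ncol(confusion))]
  }
  stopifnot(identical(rownames(confusion), CORE_CLASSES),
            all(colnames(confusion) %in% CELL_CLASSES),
            all(confusion >= 0))
  if (any(abs(rowSums(confusion) - 1) > 1e-8)) {
    abort("Each confusion row must sum to 1.")
  }
  if (jitter_sd < 0) abort("`jitter_sd` must be >= 0.")
  if (miss_rate < 0 || miss_rate >= 1) abort("`miss_rate` must be in [0, 1).")
  if (spurious_rate < 0) abort("`spurious_rate` must be >= 0.")
  structure(list(confusion = confusion, jitter_sd = jitter_sd,
                 miss_rate = miss_rate, spurious_rate = spurious_rate),
            class = "confusion_spec")
}

#' Simulate classifier predictions from ground truth
#'
#' Applies a [confusion_spec()] to an annotation table: each true cell is
#' dropped with probability `miss_rate`; kept cells get a predicted class
#' drawn from the confusion row of their true class and a position jittered
#' by N(0, `jitter_sd`^2) per axis; `Poisson(spurious_rate * n)` spurious
#' cells are added at uniform positions within the truth bounding box (or
#' `canvas` when given).
#'
#' @param truth Annotation table (`cell_id`, `x`, `y`, `cls`,
#'   `source = "annotation"`), classes within the three core classes.
#' @param spec A [confusion_spec()].
#' @param seed RNG seed.
#' @param canvas Optional c(width, height) µm extent for spurious positions.
#' @return Tibble of predictions (`source = "prediction"`), with a
#'   `truth_id` column linking each non-spurious prediction to its source
#'   annotation (`NA` for spurious cells).
#' @export
gen_predictions <- function(truth, spec = confusion_spec(), seed = 1L,
                            canvas = NULL) {
  stopifnot(inherits(spec, "confusion_spec"))
  if (!all(truth$source == "annotation")) {
    abort("`truth` must contain only annotation records.")
  }
  bad <- setdiff(unique(truth$cls), CORE_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("Truth classes must be core classes; got: ",
                 paste(bad, collapse = ", "), "."))
  }
  with_seed_if(seed, {
    n <- nrow(truth)
    keep <- runif(n) >= spec$miss_rate
    kept <- truth[keep, ]
    cm <- spec$confusion
    pred_cls <- purrr::map_chr(kept$cls, function(cl) {
      sample(colnames(cm), 1, prob = cm[cl, ])
    })
    out <- tibble(
      cell_id = sprintf("p%05d", seq_len(nrow(kept))),
      x = pmax(kept$x + rnorm(nrow(kept), 0, spec$jitter_sd), 0),
      y = pmax(kept$y + rnorm(nrow(kept), 0, spec$jitter_sd), 0),
      cls = pred_cls,
      source = "prediction",
      truth_id = kept$cell_id
    )
    n_spur <- if (spec$spurious_rate > 0) rpois(1, spec$spurious_rate * n) else 0L
    if (n_spur > 0) {
      ext <- if (!is.null(canvas)) {
        list(x = c(0, canvas[1]), y = c(0, canvas[2]))
      } else {
        list(x = range(truth$x), y = range(truth$y))
      }
      spur <- tibble(
        cell_id = sprintf("s%05d", seq_len(n_spur)),
        x = runif(n_spur, ext$x[1], ext$x[2]),
        y = runif(n_spur, ext$y[1], ext$y[2]),
        cls = sample(CORE_CLASSES, n_spur, replace = TRUE),
        source = "prediction",
        truth_id = NA_character_
      )
      out <- dplyr::bind_rows(out, spur)
    }
    out
  })
}

#' Score simulated predictions against their truth
#'
#' Convenience wrapper used throughout the tests: joins predictions to truth
#' by `truth_id` (missed cells become `NA` predictions) and evaluates
#' [confusion_counts()] + [classification_metrics()].
#'
#' @param truth Annotation table.
#' @param predictions Output of [gen_predictions()].
#' @return A `metrics_report`.
#' @export
score_predictions <- function(truth, predictions) {
  matched <- predictions[!is.na(predictions$truth_id), c("truth_id", "cls")]
  pairs <- dplyr::left_join(
    tibble(truth_id = truth$cell_id, true_cls = truth$cls),
    dplyr::rename(matched, pred_cls = "cls"),
    by = "truth_id"
  )
  classification_metrics(confusion_counts(pairs))
}
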