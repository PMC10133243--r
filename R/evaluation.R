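#' Confusion matrix from matched annotation/prediction pairs
#'
#' Tabulates true class against predicted class for pathologist-annotated
#' cells. Rows are the three annotated classes; columns are the four
#' classifier outputs plus a `missed` pseudo-column for annotations with no
#' matched detection (these count against the sensitivity of their true
#' class). Counts conserve the number of annotations.
#'
#' @param pairs Data frame with columns `true_cls` (in
#'   `cell_classes(core = TRUE)`) and `pred_cls` (in [cell_classes()] or `NA`
#'   for an unmatched annotation), e.g. the output of
#'   [map_annotations_to_cells()] joined to predicted classes.
#' @return An integer matrix of class `confusion_counts`,
#'   3 rows x 5 columns.
#' @export
#' @examples
#' pairs <- data.frame(true_cls = c("cancer", "cancer", "lymphocyte"),
#'                     pred_cls = c("cancer", "other", NA))
#' confusion_counts(pairs)
confusion_counts <- function(pairs) {
  if (nrow(pairs) == 0) abort("No annotation/prediction pairs supplied.")
  stopifnot(all(c("true_cls", "pred_cls") %in% names(pairs)))
  bad <- setdiff(unique(pairs$true_cls), CORE_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("Annotations must be one of ",
                 paste(CORE_CLASSES, collapse = ", "), "; got: ",
                 paste(bad, collapse = ", "), "."))
  }
  pred <- ifelse(is.na(pairs$pred_cls), "missed", pairs$pred_cls)
  bad_p <- setdiff(unique(pred), c(CELL_CLASSES, "missed"))
  if (length(bad_p) > 0) {
    abort(paste0("Unknown predicted class label(s): ",
                 paste(bad_p, collapse = ", "), "."))
  }
  m <- table(factor(pairs$true_cls, levels = CORE_CLASSES),
             factor(pred, levels = c(CELL_CLASSES, "missed")))
  m <- unclass(m)
  storage.mode(m) <- "integer"
  class(m) <- c("confusion_counts", class(m))
  m
}

#' Per-class and overall classification metrics
#'
#' One-vs-rest sensitivity, specificity, precision, F1 and balanced accuracy
#' per annotated class, and the overall balanced accuracy as the arithmetic
#' mean of the three per-class values. `other` or `missed` outcomes are
#' errors for the true class: they reduce its sensitivity but are not
#' positive predictions of any class. A class with zero annotated cells gets
#' `NA` metrics and is excluded from the overall mean with a warning.
#'
#' @param conf A matrix from [confusion_counts()] (rows true class, columns
#'   predicted class; extra columns such as `other`/`missed` allowed).
#' @return A `metrics_report`: list with `per_class` (tibble) and
#'   `overall_bcacc`; see also [tidy.metrics_report()].
#' @export
classification_metrics <- function(conf) {
  classes <- rownames(conf)
  stopifnot(!is.null(classes), all(classes %in% CELL_CLASSES))
  total <- sum(conf)
  per <- purrr::map_dfr(classes, function(cl) {
    tp <- if (cl %in% colnames(conf)) conf[cl, cl] else 0
    row_tot <- sum(conf[cl, ])
    pred_tot <- if (cl %in% colnames(conf)) sum(conf[, cl]) else 0
    fp <- pred_tot - tp
    neg <- total - row_tot
    tn <- neg - fp
    sens <- if (row_tot > 0) tp / row_tot else NA_real_
    spec <- if (neg > 0) tn / neg else NA_real_
    prec <- if (pred_tot > 0) tp / pred_tot else NA_real_
    f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0) {
      2 * prec * sens / (prec + sens)
    } else NA_real_
    tibble(cls = cl, n_annotated = as.integer(row_tot),
           sensitivity = sens, specificity = spec, precision = prec,
           f1 = f1, bcacc = (sens + spec) / 2)
  })
  if (any(per$n_annotated == 0)) {
    warn(paste0("Class(es) with zero annotations excluded from overall BCAcc: ",
                paste(per$cls[per$n_annotated == 0], collapse = ", "), "."))
  }
  out <- list(per_class = per,
              overall_bcacc = mean(per$bcacc[per$n_annotated > 0]),
              confusion = conf)
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Single-cell classification metrics\n")
  print(as.data.frame(x$per_class), digits = 3, row.names = FALSE)
  cat(sprintf("Overall BCAcc: %.3f\n", x$overall_bcacc))
  invisible(x)
}

#' @rdname classification_metrics
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @rdname classification_metrics
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble(overall_bcacc = x$overall_bcacc,
         n_annotations = sum(x$confusion),
         n_classes = nrow(x$per_class))
}

#' Kruskal-Wallis test with rank-based effect size
#'
#' Tie-corrected Kruskal-Wallis H with its chi-squared p-value, the
#' rank-based effect size eta^2 = (H - k + 1)/(N - k) (which can be negative
#' for small H), and a percentile bootstrap CI for eta^2 obtained by
#' resampling observations within groups. When every observation is equal the
#' tie-correction denominator vanishes and H is defined as 0.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 non-empty groups).
#' @param n_boot Bootstrap replicates for the eta^2 CI (0 to skip).
#' @param seed Seed for the bootstrap.
#' @param conf_level Confidence level of the percentile interval.
#' @return A `kw_effect` list: `H`, `df`, `p`, `eta_sq`, `eta_sq_ci`, `n`,
#'   `k`, `n_boot`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3), n_boot = 0)
kruskal_wallis <- function(values, groups, n_boot = 2000, seed = NULL,
                           conf_level = 0.95) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2) abort("Need at least two groups.")
  if (any(tab == 0)) abort("Empty group supplied.")
  k <- length(tab)
  N <- length(values)
  H <- kw_statistic(values, groups)
  df <- k - 1L
  p <- stats::pchisq(H, df = df, lower.tail = FALSE)
  eta <- (H - k + 1) / (N - k)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    idx_by_g <- split(seq_len(N), groups)
    boot <- with_seed_if(seed, {
      replicate(n_boot, {
        idx <- unlist(lapply(idx_by_g, function(i) sample(i, length(i), replace = TRUE)),
                      use.names = FALSE)
        hb <- kw_statistic(values[idx], groups[idx])
        (hb - k + 1) / (N - k)
      })
    })
    alpha <- (1 - conf_level) / 2
    ci <- unname(quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  out <- list(H = H, df = df, p = p, eta_sq = eta, eta_sq_ci = ci,
              n = N, k = k, n_boot = n_boot)
  class(out) <- "kw_effect"
  out
}

# Tie-corrected H via stats::kruskal.test; all-constant data gives 0/0 there,
# which we define as H = 0.
kw_statistic <- function(values, groups) {
  if (length(unique(values)) == 1L) return(0)
  unname(suppressWarnings(kruskal.test(values, factor(groups))$statistic))
}

#' @export
print.kw_effect <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H(%d) = %.4g, n = %d, p = %.3g\n",
              x$df, x$H, x$n, x$p))
  cat(sprintf("eta^2 = %.4g", x$eta_sq))
  if (!is.na(x$eta_sq_ci[1])) {
    cat(sprintf(" (95%% CI %.3g to %.3g, %d bootstrap reps)",
                x$eta_sq_ci[1], x$eta_sq_ci[2], x$n_boot))
  }
  cat("\n")
  invisible(x)
}

#' @rdname kruskal_wallis
#' @param x A `kw_effect` object.
#' @param ... Unused.
#' @method tidy kw_effect
#' @export
tidy.kw_effect <- function(x, ...) {
  tibble(H = x$H, df = x$df, p.value = x$p, eta_sq = x$eta_sq,
         eta_sq_low = x$eta_sq_ci[1], eta_sq_high = x$eta_sq_ci[2],
         n = x$n, k = x$k)
}

#' @rdname kruskal_wallis
#' @method glance kw_effect
#' @export
glance.kw_effect <- function(x, ...) tidy(x)

#' Pairwise rank contrasts between groups
#'
#' Post-hoc contrasts after a Kruskal-Wallis test: for every group pair, the
#' difference in mean rank (ranks over the pooled sample), its large-sample
#' standard error sqrt(S^2 (1/n_i + 1/n_j)) with the tie-corrected rank
#' variance S^2, a z statistic, Benjamini-Hochberg adjusted p-values and a
#' normal-theory CI for the difference. A pair is flagged significant iff its
#' CI excludes 0 at the stated level.
#'
#' @inheritParams kruskal_wallis
#' @param adjust Multiplicity adjustment passed to [stats::p.adjust()].
#' @param conf_level Confidence level.
#' @return Tibble with one row per group pair: `group_a`, `group_b`,
#'   `estimate` (mean-rank difference a - b), `se`, `z`, `p.value` (adjusted),
#'   `conf_low`, `conf_high`, `significant`, `flag_singleton`.
#' @export
pairwise_rank_contrasts <- function(values, groups, adjust = "BH",
                                    conf_level = 0.95) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  r <- rank(values)
  N <- length(r)
  # tie-corrected variance of the pooled ranks
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  gl <- sort(unique(groups))
  mr <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  pairs <- utils::combn(gl, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    est <- unname(mr[a] - mr[b])
    se <- sqrt(S2 * (1 / ng[[a]] + 1 / ng[[b]]))
    z <- if (se > 0) est / se else 0
    tibble(group_a = a, group_b = b, estimate = est, se = unname(se), z = z,
           p.value = 2 * pnorm(-abs(z)),
           flag_singleton = ng[[a]] == 1L || ng[[b]] == 1L)
  })
  out$p.value <- p.adjust(out$p.value, method = adjust)
  zc <- qnorm(1 - (1 - conf_level) / 2)
  out$conf_low <- out$estimate - zc * out$se
  out$conf_high <- out$estimate + zc * out$se
  out$significant <- out$conf_low > 0 | out$conf_high < 0
  out[, c("group_a", "group_b", "estimate", "se", "z", "p.value",
          "conf_low", "conf_high", "significant", "flag_singleton")]
}

#' Correlation with two-sided p-value
#'
#' Thin wrapper over [stats::cor.test()] returning a tidy one-row tibble.
#' Spearman uses tie-handled (average) ranks with the asymptotic p-value when
#' ties are present.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"spearman"` or `"pearson"`.
#' @return Tibble with `method`, `estimate`, `p`, `n`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("Need at least 3 paired observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: zero variance in x or y.")
  }
  ct <- suppressWarnings(cor.test(x, y, method = method))
  tibble(method = method, estimate = unname(ct$estimate),
         p = ct$p.value, n = length(x))
}
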