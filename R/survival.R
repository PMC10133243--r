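#' Dichotomise a score at its lower quartile
#'
#' Splits subjects into a `low` group (values at or below the first quartile)
#' and a `high` group (upper three quartiles). The quartile uses the
#' linear-interpolation convention (`type = 7`), configurable since "lower
#' quartile" is convention-dependent.
#'
#' @param values Numeric scores, length >= 4.
#' @param type Quantile type passed to [stats::quantile()].
#' @return Factor with levels `low`, `high`; attribute `cutoff`.
#' @export
#' @examples
#' dichotomize_lower_quartile(1:8)  # 1, 2 -> low
dichotomize_lower_quartile <- function(values, type = 7) {
  if (length(values) < 4) abort("Need at least 4 subjects to dichotomise.")
  if (length(unique(values)) == 1L) {
    abort("All values equal: no valid lower-quartile split.")
  }
  q1 <- unname(quantile(values, 0.25, type = type))
  out <- factor(ifelse(values <= q1, "low", "high"), levels = c("low", "high"))
  if (all(out == "low")) abort("Lower-quartile cutoff puts all subjects low.")
  attr(out, "cutoff") <- q1
  out
}

#' Multivariate Cox proportional-hazards fit
#'
#' Fits a Cox model for overall survival on the supplied covariates
#' (partial-likelihood maximisation, Efron tie handling by default) and
#' returns hazard ratios with Wald confidence intervals. Monotone likelihood
#' (perfect separation, recognisable by a diverging coefficient) is flagged.
#'
#' @param records Survival records: `time`, `event`, plus covariate columns.
#'   An optional `event_cause` column with values `tumour`/`other` recodes
#'   deaths unrelated to the tumour as censored (cause-specific censoring).
#' @param covariates Character vector of covariate column names (default: the
#'   package's three prognostic covariates).
#' @param ties Tie-handling rule for [survival::coxph()].
#' @param conf_level Confidence level of the Wald intervals.
#' @return A `cox_immune_fit`: list with the underlying `coxph` fit, a tidy
#'   coefficient table and counts. Use [tidy()]/[glance()] to extract.
#' @export
fit_cox <- function(records,
                    covariates = c("coloc100", "age", "lymphocyte_pct"),
                    ties = "efron", conf_level = 0.95) {
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov) > 0) {
    abort(paste0("Covariate(s) not in data: ",
                 paste(missing_cov, collapse = ", "), "."))
  }
  df <- as.data.frame(records)
  if ("event_cause" %in% names(df)) {
    df$event <- ifelse(df$event_cause == "tumour", df$event, 0L)
  }
  if (sum(df$event) < 2) abort("Need at least 2 events to fit a Cox model.")
  ok <- complete.cases(df[, c("time", "event", covariates)])
  df <- df[ok, ]
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties)
  s <- summary(fit, conf.int = conf_level)
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  zc <- qnorm(1 - (1 - conf_level) / 2)
  tt <- tibble(
    term = names(beta),
    estimate = unname(beta),
    se = unname(se),
    hr = exp(unname(beta)),
    hr_low = exp(unname(beta) - zc * se),
    hr_high = exp(unname(beta) + zc * se),
    p.value = unname(s$coefficients[, "Pr(>|z|)"])
  )
  separation <- any(abs(beta) > 15) || !is.null(fit$fail)
  if (separation) warn("Possible monotone likelihood (perfect separation).")
  out <- list(fit = fit, coefficients = tt, n = fit$n,
              n_events = fit$nevent, loglik = fit$loglik[2],
              ties = ties, conf_level = conf_level, flagged = separation,
              covariate_means = colMeans(Filter(is.numeric,
                                                df[, covariates, drop = FALSE])))
  class(out) <- "cox_immune_fit"
  out
}

#' @export
print.cox_immune_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  print(as.data.frame(x$coefficients), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @rdname fit_cox
#' @param x A `cox_immune_fit`.
#' @param ... Unused.
#' @method tidy cox_immune_fit
#' @export
tidy.cox_immune_fit <- function(x, ...) x$coefficients

#' @rdname fit_cox
#' @method glance cox_immune_fit
#' @export
glance.cox_immune_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
         flagged_separation = x$flagged)
}

#' Variance inflation factors
#'
#' VIF_j = 1/(1 - R^2_j) from the linear regression of covariate j on the
#' remaining covariates. Covariates with VIF >= 5 are flagged for removal;
#' exact collinearity yields an infinite VIF.
#'
#' @param records Data frame holding the covariates.
#' @param covariates Covariate column names (>= 2).
#' @param threshold Retention threshold (retained iff VIF < threshold).
#' @return Tibble: `term`, `vif`, `retained`.
#' @export
#' @examples
#' d <- data.frame(a = rnorm(50), b = rnorm(50))
#' vif_report(d, c("a", "b"))
vif_report <- function(records,
                       covariates = c("coloc100", "age", "lymphocyte_pct"),
                       threshold = 5) {
  stopifnot(length(covariates) >= 2)
  if (nrow(records) < length(covariates) + 2) {
    abort("Need at least `length(covariates) + 2` subjects for VIF.")
  }
  X <- as.data.frame(records)[, covariates]
  purrr::map_dfr(covariates, function(cv) {
    fml <- stats::as.formula(paste(cv, "~", paste(setdiff(covariates, cv),
                                                  collapse = " + ")))
    # suppress the "essentially perfect fit" warning on exact collinearity;
    # that case is reported as an infinite VIF below
    r2 <- suppressWarnings(summary(lm(fml, data = X))$r.squared)
    v <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    tibble(term = cv, vif = v, retained = v < threshold)
  })
}

#' Kaplan-Meier curves by group
#'
#' Product-limit survival estimates per group, optionally covariate-adjusted
#' from a multivariate Cox fit: `adjust = "mean"` evaluates each group's curve
#' at the cohort mean of the other covariates, `adjust = "reference"` at zero.
#'
#' @param records Survival records (`time`, `event`).
#' @param groups Group label per subject (e.g. from
#'   [dichotomize_lower_quartile()]).
#' @param cox_fit Optional `cox_immune_fit` whose model includes a group term;
#'   required for adjusted curves.
#' @param adjust `"none"` (plain KM), `"mean"` or `"reference"`.
#' @return Tibble of class `km_curves`: `group`, `time`, `n_risk`, `n_event`,
#'   `surv`.
#' @export
km_curves <- function(records, groups, cox_fit = NULL,
                      adjust = c("none", "mean", "reference")) {
  adjust <- match.arg(adjust)
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) abort("Empty group supplied.")
  df <- data.frame(time = records$time, event = records$event, group = groups)
  ev <- tapply(df$event, df$group, sum)
  if (adjust == "none") {
    sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
    strata <- rep(names(sf$strata) %||% paste0("group=", levels(groups)[1]),
                  sf$strata %||% length(sf$time))
    out <- tibble(
      group = sub("^group=", "", strata),
      time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
      surv = sf$surv
    )
  } else {
    if (is.null(cox_fit)) {
      abort("Adjusted curves need a `cox_fit` including the group term.")
    }
    fit <- cox_fit$fit
    covs <- setdiff(names(cox_fit$covariate_means), "group")
    ref <- if (adjust == "mean") cox_fit$covariate_means[covs] else
      setNames(rep(0, length(covs)), covs)
    nd <- as.data.frame(c(as.list(ref),
                          list(group = factor(levels(groups),
                                              levels = levels(groups)))))
    sf <- survival::survfit(fit, newdata = nd)
    surv <- as.matrix(sf$surv)
    out <- purrr::map_dfr(seq_along(levels(groups)), function(j) {
      tibble(group = levels(groups)[j], time = sf$time,
             n_risk = sf$n.risk, n_event = sf$n.event, surv = surv[, j])
    })
  }
  class(out) <- c("km_curves", class(out))
  attr(out, "adjust") <- adjust
  attr(out, "n_events_by_group") <- ev
  out
}
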