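# Genetically moderated treatment effect (GMTE) estimator family and the
# Q-statistic-gated triangulation, on the mean-difference scale for
# biomarkers and on the additive per-person-year rate scale for events.

#' Construct a GMTE estimate
#'
#' @param method One of `"GMTE1", "GMTE0", "RGMTE", "MR", "CAT", "COMBINED"`.
#' @param estimate Point estimate.
#' @param se Standard error (> 0).
#' @param scale `"mean_difference"` or `"per_year_risk_difference"`.
#' @param n_used Number of participants used.
#' @param constituents For `"COMBINED"`, the constituent method labels.
#' @return Object of class `gmte_estimate` with a two-sided Wald `p`.
#' @export
gmte_estimate <- function(method, estimate, se, scale, n_used,
                          constituents = NULL) {
  stopifnot(method %in% c("GMTE1", "GMTE0", "RGMTE", "MR", "CAT", "COMBINED"))
  if (!is.finite(se) || se <= 0) stop("se must be positive", call. = FALSE)
  structure(list(method = method, estimate = estimate, se = se,
                 p = wald_p(estimate, se), scale = scale, n_used = n_used,
                 constituents = constituents),
            class = "gmte_estimate")
}

#' @export
print.gmte_estimate <- function(x, ...) {
  ci <- wald_ci(x$estimate, x$se)
  cat(sprintf("%s [%s]: %.4g (95%% CI %.4g to %.4g), p = %.3g, n = %d\n",
              x$method, x$scale, x$estimate, ci[["low"]], ci[["high"]],
              x$p, x$n_used))
  invisible(x)
}

# Genotype coefficient from an adjusted OLS fit on a cohort subset.
stratum_genotype_coef <- function(cohort, carrier, outcome, covariates, idx) {
  sub <- cohort[idx, , drop = FALSE]
  g <- as.numeric(carrier)[idx]
  if (sum(g > 0, na.rm = TRUE) < 3) {
    stop("fewer than 3 carriers in the stratum", call. = FALSE)
  }
  r <- linear_association(sub, outcome, g, covariates)
  list(estimate = r$estimate, se = r$se, n = r$n)
}

#' GMTE1: genotype association among the treated
#'
#' The genotype coefficient from the covariate-adjusted model restricted to
#' treated participants. Under the pharmacogenetic assumptions this estimates
#' the extra outcome effect a treated carrier experiences.
#'
#' @param cohort Cohort data frame with a logical `treated` column.
#' @param carrier Carrier vector aligned with `cohort` rows.
#' @param outcome Outcome column name.
#' @param covariates Adjustment covariate names.
#' @return A [gmte_estimate()] on the mean-difference scale.
#' @export
gmte1 <- function(cohort, carrier, outcome = "ldl",
                  covariates = c("age", "sex", paste0("pc", 1:5))) {
  r <- stratum_genotype_coef(cohort, carrier, outcome, covariates,
                             which(cohort$treated))
  gmte_estimate("GMTE1", r$estimate, r$se, "mean_difference", r$n)
}

#' GMTE0: genotype association among the untreated
#'
#' The genotype coefficient restricted to untreated participants. Serves as
#' the no-direct-effect check: under a purely pharmacogenetic mechanism it is
#' zero in expectation.
#'
#' @inheritParams gmte1
#' @return A [gmte_estimate()].
#' @export
gmte0 <- function(cohort, carrier, outcome = "ldl",
                  covariates = c("age", "sex", paste0("pc", 1:5))) {
  r <- stratum_genotype_coef(cohort, carrier, outcome, covariates,
                             which(!cohort$treated))
  gmte_estimate("GMTE0", r$estimate, r$se, "mean_difference", r$n)
}

#' RGMTE: robust GMTE
#'
#' The treated-stratum association corrected for any genotype effect in the
#' untreated: estimate = GMTE1 - GMTE0, se = sqrt(se1^2 + se0^2).
#'
#' @param g1 A `"GMTE1"` [gmte_estimate()].
#' @param g0 A `"GMTE0"` [gmte_estimate()] on the same scale.
#' @return A [gmte_estimate()].
#' @export
rgmte <- function(g1, g0) {
  if (!identical(g1$scale, g0$scale)) {
    stop("cannot difference estimates on different scales", call. = FALSE)
  }
  gmte_estimate("RGMTE", g1$estimate - g0$estimate,
                sqrt(g1$se^2 + g0$se^2), g1$scale, g1$n_used + g0$n_used)
}

#' MR estimate of the GMTE
#'
#' The whole-cohort genotype coefficient deflated by the proportion treated:
#' under no effect in the untreated, the full-cohort association equals
#' pi x GMTE, so dividing by pi (and scaling the standard error by 1/pi)
#' recovers the GMTE.
#'
#' @inheritParams gmte1
#' @return A [gmte_estimate()].
#' @export
mr_estimate <- function(cohort, carrier, outcome = "ldl",
                        covariates = c("age", "sex", paste0("pc", 1:5))) {
  pi_t <- mean(cohort$treated, na.rm = TRUE)
  if (pi_t <= 0 || pi_t >= 1) {
    stop("proportion treated must lie strictly between 0 and 1", call. = FALSE)
  }
  r <- stratum_genotype_coef(cohort, carrier, outcome, covariates,
                             seq_len(nrow(cohort)))
  gmte_estimate("MR", r$estimate / pi_t, r$se / pi_t, "mean_difference", r$n)
}

#' CAT: corrected-as-treated estimate
#'
#' The apparent treatment effect among carriers minus the apparent treatment
#' effect among non-carriers, from genotype-stratified covariate-adjusted
#' fits. Reported for triangulation only: its treated-versus-untreated
#' contrasts make it sensitive to confounding by indication in ways the
#' within-treatment-stratum estimators are not.
#'
#' @inheritParams gmte1
#' @return A [gmte_estimate()].
#' @export
cat_estimate <- function(cohort, carrier, outcome = "ldl",
                         covariates = c("age", "sex", paste0("pc", 1:5))) {
  carrier <- as.numeric(carrier) > 0
  treat_coef <- function(idx) {
    sub <- cohort[idx, , drop = FALSE]
    if (!any(sub$treated) || !any(!sub$treated)) {
      stop("a genotype stratum lacks treated or untreated participants",
           call. = FALSE)
    }
    r <- linear_association(sub, outcome, as.numeric(sub$treated), covariates)
    list(estimate = r$estimate, se = r$se, n = r$n)
  }
  a <- treat_coef(which(carrier))
  b <- treat_coef(which(!carrier))
  gmte_estimate("CAT", a$estimate - b$estimate, sqrt(a$se^2 + b$se^2),
                "mean_difference", a$n + b$n)
}

#' Combine GMTE estimates with a Cochran's Q gate
#'
#' Computes Cochran's heterogeneity statistic
#' `Q = sum_i w_i (b_i - b_bar)^2` with inverse-variance weights
#' `w_i = 1/se_i^2` and `df = k - 1`. If the heterogeneity p-value exceeds
#' `alpha`, the estimates are pooled by inverse-variance weighting
#' (`se = 1/sqrt(sum w_i)`); otherwise the combination is refused.
#'
#' @param estimates List of [gmte_estimate()]s on a common scale (k >= 2).
#' @param alpha Q-gate significance level (default 0.05; combination
#'   proceeds when p > alpha).
#' @return List with elements `het` (`q_stat`, `df`, `p`, `combinable`) and
#'   `combined` (a `"COMBINED"` [gmte_estimate()], or `NULL` on refusal).
#' @export
gmte_combine <- function(estimates, alpha = 0.05) {
  if (length(estimates) < 2) stop("need at least 2 estimates", call. = FALSE)
  scales <- vapply(estimates, `[[`, character(1), "scale")
  if (length(unique(scales)) > 1) {
    stop("cannot combine estimates on different scales", call. = FALSE)
  }
  b <- vapply(estimates, `[[`, numeric(1), "estimate")
  w <- 1 / vapply(estimates, `[[`, numeric(1), "se")^2
  b_bar <- sum(w * b) / sum(w)
  q <- sum(w * (b - b_bar)^2)
  df <- length(b) - 1L
  p <- stats::pchisq(q, df, lower.tail = FALSE)
  het <- list(q_stat = q, df = df, p = p, combinable = p > alpha)
  combined <- NULL
  if (het$combinable) {
    combined <- gmte_estimate(
      "COMBINED", b_bar, 1 / sqrt(sum(w)), scales[1],
      max(vapply(estimates, `[[`, numeric(1), "n_used")),
      constituents = vapply(estimates, `[[`, character(1), "method"))
  }
  list(het = het, combined = combined)
}

# events and person-years in one cell; closed-form rate and Poisson variance.
rate_cell <- function(events, py) {
  if (py <= 0) stop("zero person-years in a cell; rate undefined", call. = FALSE)
  if (sum(events) < 5) {
    warning("fewer than 5 events in a cell; normal approximation is rough")
  }
  list(rate = sum(events) / py, var = sum(events) / py^2, n = length(events))
}

rate_difference <- function(cell1, cell0) {
  list(estimate = cell1$rate - cell0$rate, se = sqrt(cell1$var + cell0$var),
       n = cell1$n + cell0$n)
}

#' Per-person-year risk difference attributable to genotype under treatment
#'
#' Event-rate GMTE on the additive scale. With no covariates the estimators
#' are closed-form cell rate differences with Poisson variances:
#' GMTE1/GMTE0 contrast carriers against non-carriers within the
#' treated/untreated stratum, RGMTE differences the two, and MR deflates the
#' whole-cohort rate difference by the person-year-weighted proportion
#' treated. With covariates an identity-link Poisson person-years model is
#' fitted within the relevant stratum.
#'
#' @param cohort Cohort data frame with `<outcome>_event`, `<outcome>_time`
#'   (years at risk) and `treated` columns.
#' @param carrier Carrier vector aligned with `cohort` rows.
#' @param outcome Event outcome prefix (default `"muscle"`).
#' @param method One of `"GMTE1"`, `"GMTE0"`, `"RGMTE"`, `"MR"`.
#' @param covariates Optional covariate names for the adjusted person-years
#'   model (default `NULL`: closed-form cells).
#' @return A [gmte_estimate()] on the `per_year_risk_difference` scale.
#' @export
per_year_risk_difference <- function(cohort, carrier, outcome = "muscle",
                                     method = c("GMTE1", "GMTE0", "RGMTE", "MR"),
                                     covariates = NULL) {
  method <- match.arg(method)
  ev <- cohort[[paste0(outcome, "_event")]]
  py <- cohort[[paste0(outcome, "_time")]]
  if (is.null(ev) || is.null(py)) {
    stop("cohort lacks event/time columns for '", outcome, "'", call. = FALSE)
  }
  g <- as.numeric(carrier) > 0
  ok <- !is.na(ev) & !is.na(py) & !is.na(g) & py >= 0
  ev <- ev[ok]; py <- py[ok]; g <- g[ok]; treated <- cohort$treated[ok]
  covar_df <- if (!is.null(covariates)) cohort[ok, covariates, drop = FALSE]

  stratum_diff <- function(in_stratum) {
    if (is.null(covariates)) {
      rate_difference(rate_cell(ev[in_stratum & g], sum(py[in_stratum & g])),
                      rate_cell(ev[in_stratum & !g], sum(py[in_stratum & !g])))
    } else {
      fit_rate_model(ev[in_stratum], py[in_stratum], g[in_stratum],
                     covar_df[in_stratum, , drop = FALSE])
    }
  }
  switch(method,
    GMTE1 = {
      d <- stratum_diff(treated)
      gmte_estimate("GMTE1", d$estimate, d$se, "per_year_risk_difference", d$n)
    },
    GMTE0 = {
      d <- stratum_diff(!treated)
      gmte_estimate("GMTE0", d$estimate, d$se, "per_year_risk_difference", d$n)
    },
    RGMTE = {
      d1 <- stratum_diff(treated)
      d0 <- stratum_diff(!treated)
      gmte_estimate("RGMTE", d1$estimate - d0$estimate,
                    sqrt(d1$se^2 + d0$se^2), "per_year_risk_difference",
                    d1$n + d0$n)
    },
    MR = {
      pi_py <- sum(py[treated]) / sum(py)
      if (pi_py <= 0 || pi_py >= 1) {
        stop("person-year proportion treated must lie in (0, 1)", call. = FALSE)
      }
      d <- stratum_diff(rep(TRUE, length(ev)))
      gmte_estimate("MR", d$estimate / pi_py, d$se / pi_py,
                    "per_year_risk_difference", d$n)
    })
}

# Identity-link Poisson person-years model: E[events] = py * (b0 + bg*g + Xb).
fit_rate_model <- function(events, py, g, covar_df) {
  X <- stats::model.matrix(~ ., data = cbind(data.frame(g = as.numeric(g)),
                                             covar_df))
  Xpy <- X * py
  colnames(Xpy) <- colnames(X)
  crude <- c(sum(events[g == 0]) / sum(py[g == 0]),
             sum(events[g == 1]) / sum(py[g == 1]) -
               sum(events[g == 0]) / sum(py[g == 0]))
  start <- c(crude, rep(0, ncol(X) - 2))
  fit <- stats::glm.fit(Xpy, events, family = stats::poisson(link = "identity"),
                        start = start)
  # Identity-link Poisson information: X' diag(1/mu) X on the py-scaled design.
  mu <- pmax(fit$fitted.values, .Machine$double.eps)
  info <- t(Xpy) %*% (Xpy / mu)
  cov_b <- chol2inv(chol(info))
  j <- which(colnames(X) == "g")
  list(estimate = fit$coefficients[j], se = sqrt(cov_b[j, j]),
       n = length(events))
}

#' Core pharmacogenetic assumption checks
#'
#' Tests the assumptions the triangulation leans on: (a) the genotype does
#' not predict treatment (logistic regression of treatment on carrier
#' status); (b) the genotype is not associated with measured covariates
#' (per-covariate tests; constant covariates are skipped with a warning);
#' (c) no direct effect — GMTE0 on the primary outcome.
#'
#' @inheritParams gmte1
#' @param alpha Flagging level (default 0.05).
#' @return Data frame `check, term, statistic, p, pass`.
#' @export
assumption_checks <- function(cohort, carrier, outcome = "ldl",
                              covariates = c("age", "sex", paste0("pc", 1:5)),
                              alpha = 0.05) {
  g <- as.numeric(carrier)
  rows <- list()
  fit_t <- stats::glm(cohort$treated ~ g, family = stats::binomial())
  sm <- summary(fit_t)$coefficients
  rows[["treatment"]] <- data.frame(check = "genotype_predicts_treatment",
                                    term = "carrier", statistic = sm["g", "z value"],
                                    p = sm["g", "Pr(>|z|)"],
                                    stringsAsFactors = FALSE)
  for (cv in covariates) {
    x <- cohort[[cv]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("covariate '", cv, "' is constant; check skipped")
      next
    }
    if (is.numeric(x)) {
      sm <- summary(stats::lm(x ~ g))$coefficients
      rows[[cv]] <- data.frame(check = "genotype_covariate_association",
                               term = cv, statistic = sm["g", "t value"],
                               p = sm["g", "Pr(>|t|)"], stringsAsFactors = FALSE)
    } else {
      tb <- table(x, g > 0)
      ct <- suppressWarnings(stats::chisq.test(tb))
      rows[[cv]] <- data.frame(check = "genotype_covariate_association",
                               term = cv, statistic = unname(ct$statistic),
                               p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  g0 <- try(gmte0(cohort, carrier, outcome, covariates), silent = TRUE)
  if (!inherits(g0, "try-error")) {
    rows[["gmte0"]] <- data.frame(check = "no_direct_effect_gmte0",
                                  term = outcome,
                                  statistic = g0$estimate / g0$se, p = g0$p,
                                  stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$pass <- out$p > alpha
  out
}

#' Triangulate the GMTE across the estimator family
#'
#' Computes GMTE1, GMTE0, RGMTE, MR and (on the mean-difference scale) CAT,
#' runs the assumption checks, and combines the requested estimator subset
#' under the Cochran's Q gate.
#'
#' @inheritParams gmte1
#' @param scale `"mean_difference"` (biomarker outcome) or
#'   `"per_year_risk_difference"` (event outcome prefix).
#' @param combine Methods to pool (default `c("RGMTE", "MR")`).
#' @param alpha Q-gate level.
#' @return Object of class `gmte_triangulation`: list with `estimates`,
#'   `het`, `combined` (or `NULL` on refusal), `checks`, `scale`, `combine`.
#' @export
triangulate <- function(cohort, carrier, outcome = "ldl",
                        covariates = c("age", "sex", paste0("pc", 1:5)),
                        scale = c("mean_difference", "per_year_risk_difference"),
                        combine = c("RGMTE", "MR"), alpha = 0.05) {
  scale <- match.arg(scale)
  if (scale == "mean_difference") {
    g1 <- gmte1(cohort, carrier, outcome, covariates)
    g0 <- gmte0(cohort, carrier, outcome, covariates)
    ests <- list(GMTE1 = g1, GMTE0 = g0, RGMTE = rgmte(g1, g0),
                 MR = mr_estimate(cohort, carrier, outcome, covariates),
                 CAT = cat_estimate(cohort, carrier, outcome, covariates))
    checks <- assumption_checks(cohort, carrier, outcome, covariates, alpha)
  } else {
    ests <- lapply(c(GMTE1 = "GMTE1", GMTE0 = "GMTE0", RGMTE = "RGMTE",
                     MR = "MR"), function(m) {
      per_year_risk_difference(cohort, carrier, outcome, m)
    })
    checks <- assumption_checks(cohort, carrier, outcome = "ldl",
                                covariates = covariates, alpha = alpha)
  }
  comb <- gmte_combine(ests[combine], alpha)
  structure(list(estimates = ests, het = comb$het, combined = comb$combined,
                 checks = checks, scale = scale, combine = combine),
            class = "gmte_triangulation")
}

#' @export
print.gmte_triangulation <- function(x, ...) {
  cat("GMTE triangulation [", x$scale, "]\n", sep = "")
  for (e in x$estimates) print(e)
  cat(sprintf("Q = %.3f (df %d), p = %.3g -> %s\n", x$het$q_stat, x$het$df,
              x$het$p,
              if (x$het$combinable) "combinable" else "combination refused"))
  if (!is.null(x$combined)) print(x$combined)
  invisible(x)
}

#' Serialise a triangulation report to JSON
#'
#' @param x A [triangulate()] result.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
triangulation_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "gmte_triangulation"))
  payload <- list(
    scale = x$scale,
    estimates = lapply(x$estimates, function(e) {
      e[c("method", "estimate", "se", "p", "scale", "n_used")]
    }),
    heterogeneity = x$het,
    combined = if (!is.null(x$combined)) {
      x$combined[c("method", "estimate", "se", "p", "scale", "constituents")]
    },
    assumption_checks = x$checks
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
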