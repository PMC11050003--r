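# Covariate-adjusted association scans: linear models for baseline
# biomarkers, proportional-hazards models for GP outcomes, discontinuation
# labelling, and the Benjamini-Hochberg-controlled rare-variant scan.

assoc_row <- function(term, estimate, se, n, model, unstable = FALSE) {
  ci <- wald_ci(estimate, se)
  data.frame(term = term, estimate = estimate, se = se,
             ci_low = ci[["low"]], ci_high = ci[["high"]],
             p = wald_p(estimate, se), n = n, model = model,
             unstable = unstable, stringsAsFactors = FALSE)
}

# Shared design-matrix fit with explicit collinearity reporting.
fit_ols <- function(y, contrast, covar_df) {
  df <- data.frame(.y = y, .g = contrast)
  df <- cbind(df, covar_df)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- stats::lm(.y ~ ., data = df)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("rank-deficient design; collinear terms: ",
         paste(names(co)[is.na(co)], collapse = ", "), call. = FALSE)
  }
  list(fit = fit, n = nrow(df))
}

#' Linear association between a biomarker and a genotype contrast
#'
#' Ordinary-least-squares fit of a quantitative outcome on a genotype
#' contrast plus covariates. The contrast is either a factor (per-genotype
#' categories, first level the reference — e.g. het/hom vs wild type, or
#' haplotype carrier vs the haplotype's reference group with partial carriers
#' excluded) or a numeric/logical carrier coding.
#'
#' @param cohort Cohort data frame (one row per participant).
#' @param outcome Name of the outcome column (e.g. `"ldl"`, in mmol/L).
#' @param contrast Vector aligned with `cohort` rows: factor or
#'   numeric/logical. `NA` entries are dropped.
#' @param covariates Names of covariate columns to adjust for (default age,
#'   sex and five genetic principal components).
#' @return Data frame of association results, one row per contrast term:
#'   `term, estimate, se, ci_low, ci_high, p, n, model, unstable`. Estimates
#'   are mean differences in outcome units. Terms with fewer than 3 carriers
#'   are flagged `unstable`.
#' @export
linear_association <- function(cohort, outcome, contrast,
                               covariates = c("age", "sex", paste0("pc", 1:5))) {
  y <- cohort[[outcome]]
  if (is.null(y)) stop("no outcome column '", outcome, "'", call. = FALSE)
  if (is.logical(contrast)) contrast <- as.numeric(contrast)
  covar_df <- cohort[, covariates, drop = FALSE]
  n_terms <- 1L + length(covariates) +
    if (is.factor(contrast)) max(0L, nlevels(contrast) - 2L) else 0L
  if (sum(!is.na(y)) < 2 * (n_terms + 1)) {
    stop("too few non-missing outcome values for the model size", call. = FALSE)
  }
  fit <- fit_ols(y, contrast, covar_df)
  sm <- summary(fit$fit)$coefficients
  terms <- rownames(sm)[startsWith(rownames(sm), ".g")]
  out <- lapply(terms, function(tm) {
    label <- if (identical(tm, ".g")) "carrier" else sub("^\\.g", "", tm)
    n_in_group <- if (is.factor(contrast)) {
      sum(contrast == sub("^\\.g", "", tm), na.rm = TRUE)
    } else {
      sum(contrast > 0, na.rm = TRUE)
    }
    assoc_row(label, sm[tm, "Estimate"], sm[tm, "Std. Error"], fit$n,
              "linear", unstable = n_in_group < 3)
  })
  do.call(rbind, out)
}

#' Proportional-hazards association for a time-to-event outcome
#'
#' Cox proportional-hazards fit (Efron tie handling) of an event outcome on
#' carrier status, adjusted for sex, age at first prescription and further
#' covariates. Participants enter at their first statin prescription; the
#' analysis keeps those aged 40+ at entry with at least two months of
#' prescriptions, optionally restricted to at least `min_treatment_years`
#' years on statins, and excludes prevalent cases (events before entry).
#'
#' @param cohort Cohort data frame with columns `<outcome>_event` (0/1),
#'   `<outcome>_time` (years from entry), optional `<outcome>_prevalent`
#'   (logical), `age_first_rx` and `treatment_years`.
#' @param carrier Logical/numeric carrier vector aligned with `cohort` rows.
#' @param outcome Event outcome prefix, e.g. `"muscle"`.
#' @param covariates Extra covariate column names (default five principal
#'   components); sex and age at first prescription are always included.
#' @param min_treatment_years Minimum years on statins (default 2 months).
#' @return One-row data frame as in [linear_association()] with the estimate
#'   on the log-hazard scale plus a convenience `hr` column.
#' @export
survival_association <- function(cohort, carrier, outcome = "muscle",
                                 covariates = paste0("pc", 1:5),
                                 min_treatment_years = 2 / 12) {
  ev_col <- paste0(outcome, "_event")
  tm_col <- paste0(outcome, "_time")
  for (col in c(ev_col, tm_col, "age_first_rx", "treatment_years")) {
    if (is.null(cohort[[col]])) stop("no column '", col, "'", call. = FALSE)
  }
  keep <- cohort$age_first_rx >= 40 &
    cohort$treatment_years >= max(min_treatment_years, 2 / 12)
  prev_col <- paste0(outcome, "_prevalent")
  if (!is.null(cohort[[prev_col]])) keep <- keep & !cohort[[prev_col]]
  df <- data.frame(time = cohort[[tm_col]], event = cohort[[ev_col]],
                   g = as.numeric(carrier), sex = cohort$sex,
                   age_first_rx = cohort$age_first_rx)
  df <- cbind(df, cohort[, covariates, drop = FALSE])
  df <- df[keep & stats::complete.cases(df) & df$time > 0, , drop = FALSE]
  if (sum(df$event) < 10) {
    stop("fewer than 10 events after restrictions", call. = FALSE)
  }
  events_by_group <- tapply(df$event, df$g > 0, sum)
  unstable <- any(events_by_group == 0)
  if (unstable) warning("zero events in a genotype group; hazard ratio undefined")
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = df,
                         ties = "efron")
  sm <- summary(fit)$coefficients
  out <- assoc_row("carrier", sm["g", "coef"], sm["g", "se(coef)"],
                   nrow(df), "proportional_hazards", unstable = unstable)
  out$hr <- exp(out$estimate)
  out$n_events <- sum(df$event)
  out
}

#' Label statin discontinuation from prescription records
#'
#' A participant has discontinued when their last prescription falls at least
#' `gap_months` months (default 3) before their censoring date. The event
#' time is the span from first to last prescription, in years.
#'
#' @param prescriptions Data frame with columns `sample`, `first_rx`,
#'   `last_rx` and `censor_date` (ISO-8601 strings or `Date`s).
#' @param gap_months Gap defining discontinuation, in months.
#' @return Data frame `sample, discontinued, time` (years on treatment).
#' @export
define_discontinuation <- function(prescriptions, gap_months = 3) {
  need <- c("sample", "first_rx", "last_rx", "censor_date")
  if (!all(need %in% names(prescriptions))) {
    stop("prescriptions needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  first <- as.Date(prescriptions$first_rx)
  last <- as.Date(prescriptions$last_rx)
  censor <- as.Date(prescriptions$censor_date)
  if (any(last > censor)) {
    stop("prescriptions dated after the censor date", call. = FALSE)
  }
  gap_days <- gap_months * 365.25 / 12
  data.frame(sample = prescriptions$sample,
             discontinued = as.numeric(censor - last) >= gap_days,
             time = as.numeric(last - first) / 365.25,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment. Input p-values must lie in
#' (0, 1].
#'
#' @param pvalues Numeric vector of p-values.
#' @return Vector of q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Rare-variant association scan with FDR control
#'
#' Per-variant carrier-coded linear associations of a baseline biomarker,
#' Benjamini-Hochberg adjusted across the scanned set, plus a combined
#' analysis of carriers of any designated variant and sex-stratified combined
#' estimates.
#'
#' @param gm [genotype_matrix()] containing the rare variants.
#' @param rare_variants Data frame of rare variants (from
#'   [filter_variants()]`$rare`).
#' @param cohort Cohort data frame.
#' @param outcome Outcome column name (default `"ldl"`).
#' @param covariates Adjustment covariates (default age, sex, five PCs).
#' @param treated_only Restrict to participants on treatment (default TRUE,
#'   the baseline statin-user scan).
#' @param combine_rsids Variants entering the combined-carrier analysis
#'   (default: all scanned variants).
#' @return List: `per_variant` (with `mac` and `q` columns), `combined`,
#'   `by_sex`.
#' @export
rare_variant_scan <- function(gm, rare_variants, cohort, outcome = "ldl",
                              covariates = c("age", "sex", paste0("pc", 1:5)),
                              treated_only = TRUE,
                              combine_rsids = rare_variants$rsid) {
  idx <- if (treated_only) which(cohort$treated) else seq_len(nrow(cohort))
  sub <- cohort[idx, , drop = FALSE]
  dos <- gm$dosage[match(sub$sample, gm$samples), , drop = FALSE]
  res <- lapply(rare_variants$rsid, function(rs) {
    carrier <- dos[, rs] >= 1
    r <- linear_association(sub, outcome, carrier, covariates)
    r$term <- rs
    r$mac <- sum(dos[, rs], na.rm = TRUE)
    r
  })
  per_variant <- do.call(rbind, res)
  per_variant$q <- bh_fdr(per_variant$p)

  any_carrier <- rowSums(dos[, combine_rsids, drop = FALSE] >= 1,
                         na.rm = TRUE) > 0
  combined <- linear_association(sub, outcome, any_carrier, covariates)
  combined$term <- "combined_carrier"

  covar_nosex <- setdiff(covariates, "sex")
  by_sex <- lapply(split(seq_len(nrow(sub)), sub$sex), function(i) {
    r <- linear_association(sub[i, , drop = FALSE], outcome, any_carrier[i],
                            covar_nosex)
    r$term <- paste0("combined_carrier_", unique(sub$sex[i])[1])
    r
  })
  list(per_variant = per_variant, combined = combined,
       by_sex = do.call(rbind, by_sex))
}
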