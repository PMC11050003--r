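# Synthetic cohort generator: genotypes with haplotype coupling, baseline
# biomarkers with gene-by-treatment effects, prescription streams and
# time-to-event outcomes, with stored ground truth for every pipeline stage.

DEFAULT_GENOTYPE_FREQS <- list(
  # P(dosage of the risk allele = 0, 1, 2); risk alleles C, G, A, C.
  rs4149056 = c(0.7247, 0.2529, 0.0224),   # *5  TT/TC/CC
  rs2306283 = c(0.4003, 0.4483, 0.1514),   # *37 AA/AG/GG
  rs11045819 = c(0.7558, 0.2199, 0.0243),  # *4  CC/CA/AA
  rs34671512 = c(0.8969, 0.1006, 0.0025)   # *19 AA/AC/CC
)

DEFAULT_CARRIER_TARGETS <- c(star15 = 0.2372, star14 = 0.2371, star20 = 0.1013)

# Reference cohort size behind the shipped rare-variant minor allele counts.
RARE_REFERENCE_N <- 61893

DEFAULT_RARE_VARIANTS <- data.frame(
  rsid = c("rs374113543", "rs373327528", "rs960742177", "rs780911188"),
  mac_ref = c(4L, 9L, 7L, 4L),
  effect = c(1.05, 0.7, 0.7, 0.65),
  stringsAsFactors = FALSE
)

#' Configure the synthetic cohort generator
#'
#' Defaults emulate the study's statistical structure: genotype frequencies
#' of the four common SLCO1B1 variants, haplotype coupling reproducing the
#' *15/*14/*20 carrier fractions, a treated LDL mean of 2.75 mmol/L (SD
#' 0.66), gene-by-treatment LDL effects (e.g. +0.08 mmol/L for *5
#' homozygotes), additive muscle-symptom hazard increments for treated
#' carriers (+0.0008/yr for *15, +0.0005/yr for *20), discontinuation
#' behaviour and administrative censoring around a mean follow-up of 6.7
#' years.
#'
#' @param n_samples Number of participants.
#' @param seed Integer seed; one global RNG stream governs all draws.
#' @param genotype_freqs Per-variant risk-allele dosage probabilities.
#' @param carrier_targets Target unphased carrier fractions for the *15, *14
#'   and *20 haplotypes (drives the haplotype coupling).
#' @param rare_variants Data frame `rsid, mac_ref, effect` of rare variants;
#'   `mac_ref` is the minor allele count in a reference cohort of
#'   `rare_reference_n`, scaled to `n_samples` by frequency.
#' @param rare_reference_n Cohort size behind `mac_ref`.
#' @param prop_treated Proportion treated (pi).
#' @param baseline_ldl_mean Untreated LDL mean, mmol/L.
#' @param baseline_ldl_sd Residual LDL standard deviation, mmol/L.
#' @param treatment_effect Mean LDL change under treatment, mmol/L.
#' @param pgx_effects Named list of gene-by-treatment LDL effects (mmol/L),
#'   applied only to treated carriers.
#' @param direct_effects Named list of direct (treatment-independent) LDL
#'   effects per allele; all zero by default.
#' @param event_base_rate Muscle-symptom hazard, events per person-year.
#' @param pgx_excess_rate Named list of additive hazard increments for
#'   treated carriers (per year).
#' @param followup_years_mean,followup_years_sd Follow-up duration (gamma,
#'   truncated to 2 months-25 years).
#' @param discontinuation_rate Per-year hazard of discontinuing statins.
#' @param genotype_treatment_link Odds ratio linking *15 carrier status to
#'   treatment (1 = independence).
#' @param indication_ldl_effect,indication_treatment_strength,
#'   indication_centre_kappa,centre_carrier_shift Confounding-by-indication
#'   machinery: an unmeasured severity `U ~ N(0,1)` raises LDL by
#'   `indication_ldl_effect` per SD and drives treatment with logit slope
#'   `indication_treatment_strength * (1 + indication_centre_kappa)` in
#'   assessment centre B (vs `* 1` in centre A); `centre_carrier_shift` adds
#'   to the rs2306283 risk-allele frequency in centre B so carrier frequency
#'   varies along the same measured axis. All zero by default.
#' @param sex_effect,age_effect,pc_effect,centre_effect Covariate effects on
#'   LDL (female vs male contrast, per year, per PC, centre B vs A).
#' @param prevalent_muscle_rate Fraction with muscle diagnoses before entry.
#' @param baseline_date Start of the prescribing window (ISO date).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 10000,
                       seed = 1,
                       genotype_freqs = DEFAULT_GENOTYPE_FREQS,
                       carrier_targets = DEFAULT_CARRIER_TARGETS,
                       rare_variants = DEFAULT_RARE_VARIANTS,
                       rare_reference_n = RARE_REFERENCE_N,
                       prop_treated = 0.6,
                       baseline_ldl_mean = 3.90,
                       baseline_ldl_sd = 0.66,
                       treatment_effect = -1.15,
                       pgx_effects = list(star5_het = 0.02, star5_hom = 0.08,
                                          star15 = 0.03, star14 = -0.01,
                                          star20 = -0.01, star4 = -0.02,
                                          star37 = 0.01, star19 = 0,
                                          rare = c(rs374113543 = 1.05,
                                                   rs373327528 = 0.7,
                                                   rs960742177 = 0.7,
                                                   rs780911188 = 0.65)),
                       direct_effects = list(star15 = 0),
                       event_base_rate = 0.005,
                       pgx_excess_rate = list(star15 = 0.0008, star20 = 0.0005),
                       followup_years_mean = 6.7,
                       followup_years_sd = 4.7,
                       discontinuation_rate = 0.038,
                       genotype_treatment_link = 1.0,
                       indication_ldl_effect = 0,
                       indication_treatment_strength = 0,
                       indication_centre_kappa = 0,
                       centre_carrier_shift = 0,
                       sex_effect = 0.24,
                       age_effect = 0.005,
                       pc_effect = 0.01,
                       centre_effect = 0,
                       prevalent_muscle_rate = 0.02,
                       baseline_date = "2006-01-01") {
  for (f in genotype_freqs) {
    if (abs(sum(f) - 1) > 1e-6 || any(f < 0)) {
      stop("genotype frequencies must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  if (prop_treated <= 0 || prop_treated >= 1) {
    stop("prop_treated must lie in (0, 1)", call. = FALSE)
  }
  if (event_base_rate < 0 || any(unlist(pgx_excess_rate) < 0)) {
    stop("event rates must be non-negative", call. = FALSE)
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

risk_allele_freq <- function(f) f[2] / 2 + f[3]

#' Haplotype coupling solved from genotype frequencies and carrier targets
#'
#' Haplotypes over the four common sites are factorised on the rs2306283
#' allele: each chromosome draws its rs2306283 risk allele with probability
#' `p37`, then each other site's risk allele with a conditional probability
#' (`a_s` on a G chromosome, `b_s` on an A chromosome) solved in closed form
#' so that random pairing of haplotypes reproduces both the per-site allele
#' frequencies and the target unphased carrier fractions for *15, *14, *20.
#'
#' @param config A [sim_config()].
#' @return List with `p37` and per-site conditional probabilities
#'   `a` (given G) and `b` (given A) for rs4149056, rs11045819, rs34671512.
#' @export
haplotype_coupling <- function(config) {
  p37 <- risk_allele_freq(config$genotype_freqs$rs2306283)
  sites <- c(star15 = "rs4149056", star14 = "rs11045819",
             star20 = "rs34671512")
  a <- b <- numeric(0)
  for (h in names(sites)) {
    p_s <- risk_allele_freq(config$genotype_freqs[[sites[h]]])
    target <- config$carrier_targets[[h]]
    x2 <- target - 1 + (1 - p_s)^2 + (1 - p37)^2
    if (x2 < 0) stop("carrier target for ", h, " is unattainably low",
                     call. = FALSE)
    x <- sqrt(x2)   # P(chromosome carries neither risk allele)
    b_s <- 1 - x / (1 - p37)
    a_s <- (p_s - (1 - p37) * b_s) / p37
    if (b_s < 0 || b_s > 1 || a_s < 0 || a_s > 1) {
      stop("carrier target for ", h, " implies invalid haplotype frequencies",
           call. = FALSE)
    }
    a[sites[h]] <- a_s
    b[sites[h]] <- b_s
  }
  list(p37 = p37, a = a, b = b)
}

truncated_gamma <- function(n, mean, sd, lower, upper) {
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  x <- stats::rgamma(n, shape = shape, rate = rate)
  pmin(pmax(x, lower), upper)
}

#' Simulate a synthetic statin cohort
#'
#' Draws genotypes per the configured frequencies with haplotype coupling,
#' assigns treatment (independent of genotype unless
#' `genotype_treatment_link != 1` or the indication machinery is on), builds
#' baseline LDL from covariates plus treated-by-carrier pharmacogenetic
#' effects, draws exponential muscle-symptom event times with additive
#' treated-carrier hazard increments, and applies discontinuation and
#' administrative censoring.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_cohort`: list with `genotypes`
#'   ([genotype_matrix()]), `cohort` (phenotype/event table), `prescriptions`
#'   (dated records for the treated), `truth` (per-sample latent assignments
#'   and cohort totals) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("S%06d", seq_len(n))

  # --- covariates -----------------------------------------------------------
  sex <- ifelse(stats::runif(n) < 0.42, "F", "M")
  age <- pmin(pmax(stats::rnorm(n, 61.5, 6), 40), 70)
  pcs <- matrix(stats::rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("pc", 1:5)))
  centre <- ifelse(stats::runif(n) < 0.5, "A", "B")
  u_indication <- stats::rnorm(n)

  # --- genotypes ------------------------------------------------------------
  coup <- haplotype_coupling(config)
  p37_chrom <- rep(coup$p37, 2 * n)
  if (config$centre_carrier_shift != 0) {
    in_b <- rep(centre == "B", each = 2)
    p37_chrom[in_b] <- pmin(coup$p37 + config$centre_carrier_shift, 0.99)
  }
  hap37 <- stats::runif(2 * n) < p37_chrom
  hap_site <- function(rsid) {
    p <- ifelse(hap37, coup$a[rsid], coup$b[rsid])
    stats::runif(2 * n) < p
  }
  hap5 <- hap_site("rs4149056")
  hap4 <- hap_site("rs11045819")
  hap19 <- hap_site("rs34671512")
  pair_sum <- function(h) {
    as.integer(h[seq(1, 2 * n, 2)]) + as.integer(h[seq(2, 2 * n, 2)])
  }
  d37 <- pair_sum(hap37); d5 <- pair_sum(hap5)
  d4 <- pair_sum(hap4); d19 <- pair_sum(hap19)

  panel <- slco1b1_panel()
  rare <- config$rare_variants
  rare_freq <- rare$mac_ref / (2 * config$rare_reference_n)
  rare_dos <- vapply(rare_freq, function(f) {
    stats::rbinom(n, 2, f)
  }, integer(n))
  dosage <- matrix(NA_integer_, n, nrow(panel),
                   dimnames = list(samples, panel$rsid))
  dosage[, "rs4149056"] <- d5
  dosage[, "rs2306283"] <- d37
  dosage[, "rs11045819"] <- d4
  dosage[, "rs34671512"] <- d19
  dosage[, rare$rsid] <- rare_dos
  dosage[, c("rs000045", "rs000046")] <- 0L   # placeholder rare star alleles
  gm <- genotype_matrix(samples, panel, dosage)

  carrier15 <- d5 >= 1 & d37 >= 1
  carrier14 <- d4 >= 1 & d37 >= 1
  carrier20 <- d19 >= 1 & d37 >= 1
  rare_carrier <- rare_dos >= 1

  # --- treatment ------------------------------------------------------------
  slope <- config$indication_treatment_strength *
    (1 + config$indication_centre_kappa * (centre == "B"))
  lp <- stats::qlogis(config$prop_treated) +
    log(config$genotype_treatment_link) * carrier15 +
    slope * u_indication
  treated <- stats::runif(n) < stats::plogis(lp)

  # --- baseline LDL ---------------------------------------------------------
  pgx <- config$pgx_effects
  gene_treatment <- pgx$star5_het * (d5 == 1) + pgx$star5_hom * (d5 == 2) +
    pgx$star15 * carrier15 + pgx$star14 * carrier14 +
    pgx$star20 * carrier20 + pgx$star4 * (d4 >= 1) +
    pgx$star37 * (d37 >= 1) + pgx$star19 * (d19 >= 1)
  if (length(pgx$rare)) {
    for (k in seq_along(rare$rsid)) {
      eff <- pgx$rare[[rare$rsid[k]]]
      if (!is.null(eff) && !is.na(eff)) {
        gene_treatment <- gene_treatment + eff * rare_carrier[, k]
      }
    }
  }
  direct <- (config$direct_effects$star15 %||% 0) * carrier15
  ldl <- config$baseline_ldl_mean +
    config$sex_effect * (sex == "F") - config$sex_effect / 2 +
    config$age_effect * (age - 61.5) +
    config$pc_effect * rowSums(pcs) +
    config$centre_effect * (centre == "B") +
    config$indication_ldl_effect * u_indication +
    treated * (config$treatment_effect + gene_treatment) +
    direct +
    stats::rnorm(n, 0, config$baseline_ldl_sd)

  # --- follow-up, events, discontinuation -----------------------------------
  followup <- truncated_gamma(n, config$followup_years_mean,
                              config$followup_years_sd, 2 / 12, 25)
  hazard <- config$event_base_rate +
    treated * (config$pgx_excess_rate$star15 * carrier15 +
                 config$pgx_excess_rate$star20 * carrier20)
  event_time <- stats::rexp(n, pmax(hazard, 1e-12))
  muscle_event <- as.integer(event_time <= followup)
  muscle_time <- pmin(event_time, followup)
  muscle_prevalent <- stats::runif(n) < config$prevalent_muscle_rate

  disc_latent <- stats::rexp(n, config$discontinuation_rate)
  discontinued <- disc_latent < followup - 0.25
  base_date <- as.Date(config$baseline_date)
  first_rx <- base_date + round(stats::runif(n, 0, 365))
  censor_date <- first_rx + round(followup * 365.25)
  last_rx <- ifelse(discontinued,
                    first_rx + round(disc_latent * 365.25),
                    censor_date - round(stats::runif(n, 0, 55)))
  last_rx <- as.Date(last_rx, origin = "1970-01-01")

  cohort <- data.frame(
    sample = samples, age = age, sex = sex, centre = centre,
    pcs, treated = treated, ldl = ldl,
    age_first_rx = age,
    treatment_years = ifelse(treated,
                             as.numeric(last_rx - first_rx) / 365.25,
                             followup),
    person_years = followup,
    muscle_event = muscle_event, muscle_time = muscle_time,
    muscle_prevalent = muscle_prevalent,
    stringsAsFactors = FALSE
  )

  prescriptions <- data.frame(
    sample = samples[treated],
    first_rx = format(first_rx[treated]),
    last_rx = format(last_rx[treated]),
    censor_date = format(censor_date[treated]),
    n_prescriptions = pmax(1L, round(9 * as.numeric(last_rx[treated] -
                                                      first_rx[treated]) / 365.25)),
    stringsAsFactors = FALSE
  )

  per_sample <- data.frame(
    sample = samples, carrier15 = carrier15, carrier14 = carrier14,
    carrier20 = carrier20, rare_carrier = rowSums(rare_carrier) > 0,
    u_indication = u_indication, hazard = hazard, treated = treated,
    discontinued_truth = as.numeric(censor_date - last_rx) >=
      3 * 365.25 / 12,
    gene_treatment_effect = gene_treatment,
    stringsAsFactors = FALSE
  )
  carrier_py <- sum(muscle_time[treated & carrier15])
  totals <- list(
    carrier15_patient_years = carrier_py,
    expected_avoided_cases = config$pgx_excess_rate$star15 * carrier_py,
    cases_total_treated = sum(muscle_event[treated]),
    cases_carriers_treated = sum(muscle_event[treated & carrier15]),
    n_treated = sum(treated)
  )

  structure(list(genotypes = gm, cohort = cohort,
                 prescriptions = prescriptions,
                 truth = list(per_sample = per_sample, totals = totals),
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", nrow(x$cohort), "samples;",
      sum(x$cohort$treated), "treated;",
      sum(x$cohort$muscle_event), "muscle events\n")
  invisible(x)
}

#' Named fixture scenarios
#'
#' Deterministic small-cohort bundles for testing:
#' `default_pgx` (the full default effect structure), `null` (all genetic
#' effects zero), `direct_effect` (a genotype effect present in everyone,
#' violating the exclusion assumption), `confounded_treatment` (treatment
#' assigned on an unmeasured outcome-correlated indication whose prescribing
#' strength and carrier frequency both vary across assessment centres) and
#' `rare_variant_large_effect` (one rare variant with expected minor allele
#' count 9 and a +0.7 mmol/L treated-carrier effect).
#'
#' @param name Scenario name.
#' @param n_samples Cohort size (fixtures are small; default 5000).
#' @param seed Seed.
#' @return A [sim_config()].
#' @export
sim_scenario <- function(name = c("default_pgx", "null", "direct_effect",
                                  "confounded_treatment",
                                  "rare_variant_large_effect"),
                         n_samples = 5000, seed = 1) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stop("unknown scenario '", name[1], "'; options: default_pgx, null, ",
         "direct_effect, confounded_treatment, rare_variant_large_effect",
         call. = FALSE)
  })
  zero_pgx <- list(star5_het = 0, star5_hom = 0, star15 = 0, star14 = 0,
                   star20 = 0, star4 = 0, star37 = 0, star19 = 0,
                   rare = c(rs374113543 = 0, rs373327528 = 0,
                            rs960742177 = 0, rs780911188 = 0))
  switch(name,
    default_pgx = sim_config(n_samples = n_samples, seed = seed),
    null = sim_config(n_samples = n_samples, seed = seed,
                      pgx_effects = zero_pgx,
                      pgx_excess_rate = list(star15 = 0, star20 = 0)),
    direct_effect = {
      pgx <- zero_pgx
      pgx$star15 <- 0.08
      sim_config(n_samples = n_samples, seed = seed, pgx_effects = pgx,
                 direct_effects = list(star15 = 0.1))
    },
    confounded_treatment = {
      pgx <- zero_pgx
      pgx$star15 <- 0.08
      sim_config(n_samples = n_samples, seed = seed, pgx_effects = pgx,
                 indication_ldl_effect = 1.0,
                 indication_treatment_strength = 1,
                 indication_centre_kappa = 3,
                 centre_carrier_shift = 0.4)
    },
    rare_variant_large_effect = {
      pgx <- zero_pgx
      pgx$rare <- c(rs373327528 = 0.7)
      rare <- data.frame(rsid = "rs373327528", mac_ref = 9L, effect = 0.7)
      sim_config(n_samples = n_samples, seed = seed, pgx_effects = pgx,
                 rare_variants = rare, rare_reference_n = n_samples)
    })
}

#' Write a simulated cohort as the pipeline's input files
#'
#' Emits `genotypes.vcf` (plain text), `cohort.tsv`, `prescriptions.tsv`,
#' `truth.json` and a `config.yaml` snapshot into `dir`. Regenerating with
#' the same configuration and seed reproduces the files byte for byte.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
  write_tsv_file(sim$cohort, file.path(dir, "cohort.tsv"))
  write_tsv_file(sim$prescriptions, file.path(dir, "prescriptions.tsv"))
  truth <- sim$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  cfg <- sim$config
  cfg$rare_variants <- as.list(cfg$rare_variants)
  writeLines(yaml::as.yaml(unclass(cfg)), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Generate and write a named fixture bundle
#'
#' @inheritParams sim_scenario
#' @param dir Output directory.
#' @return The [simulate_cohort()] result, invisibly.
#' @export
make_fixture <- function(name, dir, n_samples = 5000, seed = 1) {
  sim <- simulate_cohort(sim_scenario(name, n_samples, seed))
  write_sim(sim, dir)
  invisible(sim)
}
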