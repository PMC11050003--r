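# GMTE estimator family: algebraic identities, closed-form oracles and
# simulation recovery.

test_that("RGMTE is exactly the difference of the stratum estimates", {
  g1 <- gmte_estimate("GMTE1", 0.08, 0.02, "mean_difference", 100)
  g0 <- gmte_estimate("GMTE0", 0.00, 0.01, "mean_difference", 80)
  r <- rgmte(g1, g0)
  expect_identical(r$estimate, 0.08)
  expect_identical(r$se, sqrt(0.0005))
  expect_identical(rgmte(g1, g1)$estimate, 0)
  g_rate <- gmte_estimate("GMTE0", 0, 0.01, "per_year_risk_difference", 10)
  expect_error(rgmte(g1, g_rate), "different scales")
})

test_that("treated/untreated stratum estimates equal their OLS oracles", {
  co <- toy_cohort(20)
  carrier <- c(rep(1, 6), rep(0, 14))  # three carriers in each stratum
  for (fn in list(gmte1, gmte0)) {
    est <- fn(co, carrier, "ldl", covariates = "age")
    idx <- if (identical(fn, gmte1)) co$treated else !co$treated
    X <- cbind(1, carrier[idx], co$age[idx])
    ne <- normal_equations(X, co$ldl[idx])
    expect_equal(est$estimate, ne$beta[2], tolerance = 1e-8)
    expect_equal(est$se, ne$se[2], tolerance = 1e-8)
  }
})

test_that("the MR estimate is the whole-cohort coefficient deflated by pi", {
  co <- toy_cohort(40, seed = 17)
  set.seed(18)
  carrier <- rbinom(40, 1, 0.5)
  full <- linear_association(co, "ldl", carrier, covariates = "age")
  mr <- mr_estimate(co, carrier, "ldl", covariates = "age")
  pi_t <- mean(co$treated)
  expect_equal(mr$estimate, full$estimate / pi_t, tolerance = 1e-12)
  expect_equal(mr$se, full$se / pi_t, tolerance = 1e-12)
  co$treated <- TRUE
  expect_error(mr_estimate(co, carrier, "ldl", covariates = "age"),
               "strictly between")
})

test_that("the Q-gated combination reproduces hand-computed examples", {
  e1 <- gmte_estimate("RGMTE", 0.10, 0.02, "mean_difference", 100)
  e2 <- gmte_estimate("MR", 0.06, 0.02, "mean_difference", 100)
  res <- gmte_combine(list(e1, e2))
  # by hand: w = 2500 each, pooled mean 0.08, Q = 2500*(0.02^2)*2 = 2
  expect_equal(res$het$q_stat, 2.0, tolerance = 1e-12)
  expect_equal(res$het$p, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(res$het$combinable)
  expect_equal(res$combined$estimate, 0.08, tolerance = 1e-12)
  expect_equal(res$combined$se, 0.02 / sqrt(2), tolerance = 1e-12)

  # identical inputs: Q exactly zero, p exactly one, se reduced by sqrt(2)
  res_id <- gmte_combine(list(e1, e1))
  expect_identical(res_id$het$q_stat, 0)
  expect_identical(res_id$het$p, 1)
  expect_equal(res_id$combined$se, e1$se / sqrt(2), tolerance = 1e-12)

  # strong heterogeneity: Q = 50, refusal
  f1 <- gmte_estimate("RGMTE", 0.10, 0.01, "mean_difference", 100)
  f2 <- gmte_estimate("MR", 0.00, 0.01, "mean_difference", 100)
  res_ref <- gmte_combine(list(f1, f2))
  expect_equal(res_ref$het$q_stat, 50, tolerance = 1e-12)
  expect_false(res_ref$het$combinable)
  expect_null(res_ref$combined)

  e_rate <- gmte_estimate("MR", 0.06, 0.02, "per_year_risk_difference", 100)
  expect_error(gmte_combine(list(e1, e_rate)), "different scales")
  expect_error(gmte_combine(list(e1)), "at least 2")
})

test_that("combined standard errors never exceed the smallest constituent", {
  set.seed(29)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    ests <- lapply(1:k, function(j) {
      gmte_estimate("MR", rnorm(1, 0.05, 0.005), runif(1, 0.01, 0.05),
                    "mean_difference", 100)
    })
    res <- gmte_combine(ests, alpha = 0)  # always combine for the property
    expect_lte(res$combined$se,
               min(vapply(ests, `[[`, numeric(1), "se")) + 1e-12)
  }
})

test_that("unadjusted rate differences match the closed two-cell form", {
  # treated carriers: 10 events over 5000 py; non-carriers: 5 over 5000 py
  co <- data.frame(
    sample = as.character(1:40),
    treated = TRUE,
    muscle_event = rep(c(1, 0, 1, 0), times = c(10, 10, 5, 15)),
    muscle_time = rep(c(250, 250, 250, 250), times = c(10, 10, 5, 15)),
    stringsAsFactors = FALSE
  )
  carrier <- rep(c(TRUE, FALSE), each = 20)
  est <- suppressWarnings(
    per_year_risk_difference(co, carrier, "muscle", "GMTE1"))
  expect_identical(est$estimate, 10 / 5000 - 5 / 5000)
  expect_identical(est$se, sqrt(10 / 5000^2 + 5 / 5000^2))
  expect_identical(est$scale, "per_year_risk_difference")

  # MR deflation identity on the same data with an untreated stratum
  co2 <- co; co2$treated <- rep(c(TRUE, FALSE), 20)
  all_diff <- suppressWarnings(
    per_year_risk_difference(co2, carrier, "muscle", "MR"))
  pi_py <- sum(co2$muscle_time[co2$treated]) / sum(co2$muscle_time)
  g1 <- suppressWarnings(per_year_risk_difference(co2, carrier, "muscle", "GMTE1"))
  g0 <- suppressWarnings(per_year_risk_difference(co2, carrier, "muscle", "GMTE0"))
  r <- suppressWarnings(per_year_risk_difference(co2, carrier, "muscle", "RGMTE"))
  expect_equal(r$estimate, g1$estimate - g0$estimate, tolerance = 1e-12)
  expect_equal(r$se, sqrt(g1$se^2 + g0$se^2), tolerance = 1e-12)
  expect_error(per_year_risk_difference(co[0, ], logical(0), "muscle", "GMTE1"))
  expect_lt(abs(all_diff$estimate * pi_py -
                  (sum(co2$muscle_event[carrier]) / sum(co2$muscle_time[carrier]) -
                     sum(co2$muscle_event[!carrier]) / sum(co2$muscle_time[!carrier]))),
            1e-12)
})

test_that("estimators recover an injected pharmacogenetic effect in one cohort", {
  cfg <- sim_scenario("null", n_samples = 10000, seed = 47)
  cfg$pgx_effects$star15 <- 0.08
  sim <- simulate_cohort(cfg)
  st <- call_star_alleles(sim$genotypes)
  tri <- triangulate(sim$cohort, st$star15_carrier, "ldl")
  for (m in c("GMTE1", "RGMTE", "MR", "CAT")) {
    e <- tri$estimates[[m]]
    expect_lt(abs(e$estimate - 0.08), 3 * e$se)
  }
  expect_lt(abs(tri$estimates$GMTE0$estimate), 3 * tri$estimates$GMTE0$se)
  expect_true(tri$het$combinable)
  json <- triangulation_json(tri)
  expect_true(jsonlite::validate(json))
})

test_that("a direct genotype effect shows up in the untreated stratum", {
  sim <- simulate_cohort(sim_scenario("direct_effect", n_samples = 10000,
                                      seed = 53))
  st <- call_star_alleles(sim$genotypes)
  g0 <- gmte0(sim$cohort, st$star15_carrier, "ldl")
  expect_lt(abs(g0$estimate - 0.1), 3 * g0$se)
})

test_that("assumption checks flag a genotype-treatment link and skip constants", {
  sim <- simulate_cohort(sim_config(n_samples = 60000, seed = 59,
                                    genotype_treatment_link = 1.2))
  st <- call_star_alleles(sim$genotypes)
  checks <- assumption_checks(sim$cohort, st$star15_carrier)
  trt <- checks[checks$check == "genotype_predicts_treatment", ]
  expect_lt(trt$p, 0.05)
  expect_false(trt$pass)

  sim0 <- simulate_cohort(sim_config(n_samples = 10000, seed = 60))
  st0 <- call_star_alleles(sim0$genotypes)
  co <- sim0$cohort
  co$flat <- 1
  expect_warning(
    checks0 <- assumption_checks(co, st0$star15_carrier,
                                 covariates = c("age", "flat")),
    "constant")
  expect_false("flat" %in% checks0$term)
})
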