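# Regression machinery against closed-form and numerical oracles.

test_that("linear association equals the normal-equations solution on a toy table", {
  co <- toy_cohort(20)
  set.seed(3)
  carrier <- rbinom(20, 1, 0.4)
  co$ldl <- co$ldl + 0.5 * carrier
  res <- linear_association(co, "ldl", carrier, covariates = c("age", "sex"))
  X <- cbind(1, carrier, co$age, as.numeric(co$sex == "M"))
  ne <- normal_equations(X, co$ldl)
  expect_equal(res$estimate, ne$beta[2], tolerance = 1e-8)
  expect_equal(res$se, ne$se[2], tolerance = 1e-8)
  expect_equal(res$n, 20L)
})

test_that("per-genotype category contrasts return one row per non-reference level", {
  set.seed(4)
  n <- 300
  co <- data.frame(sample = as.character(1:n), age = runif(n, 40, 70),
                   sex = sample(c("F", "M"), n, TRUE),
                   ldl = rnorm(n, 3, 0.5))
  geno <- factor(sample(c("TT", "TC", "CC"), n, TRUE, prob = c(0.7, 0.27, 0.03)),
                 levels = c("TT", "TC", "CC"))
  co$ldl <- co$ldl + 0.4 * (geno == "CC")
  res <- linear_association(co, "ldl", geno, covariates = c("age", "sex"))
  expect_equal(res$term, c("TC", "CC"))
  expect_lt(abs(res$estimate[res$term == "CC"] - 0.4), 3 * res$se[res$term == "CC"])
  expect_lt(abs(res$estimate[res$term == "TC"]), 3 * res$se[res$term == "TC"])
})

test_that("rank-deficient designs fail loudly naming the collinear term", {
  co <- toy_cohort(20)
  co$age2 <- co$age
  expect_error(linear_association(co, "ldl", rbinom(20, 1, 0.5),
                                  covariates = c("age", "age2")),
               "collinear")
})

test_that("null effects are recovered as approximately zero at scale", {
  sim <- simulate_cohort(sim_scenario("null", n_samples = 10000, seed = 8))
  st <- call_star_alleles(sim$genotypes)
  res <- linear_association(sim$cohort[sim$cohort$treated, ], "ldl",
                            st$star15_carrier[sim$cohort$treated])
  expect_lt(abs(res$estimate), 3 * res$se)
})

test_that("Cox fit matches an independent numerical partial-likelihood maximiser", {
  set.seed(12)
  n <- 30
  co <- data.frame(
    sample = as.character(1:n),
    sex = sample(c("F", "M"), n, TRUE),
    age_first_rx = runif(n, 45, 70),
    treatment_years = runif(n, 1, 10),
    pcz = rnorm(n)
  )
  g <- rbinom(n, 1, 0.5)
  co$muscle_time <- round(rexp(n, 0.1 * exp(0.5 * g)), 6)
  co$muscle_event <- as.integer(co$muscle_time < 8)
  co$muscle_time <- pmin(co$muscle_time, 8)
  stopifnot(!anyDuplicated(co$muscle_time[co$muscle_event == 1]))  # no ties
  res <- survival_association(co, g, "muscle", covariates = "pcz",
                              min_treatment_years = 0)

  # independent oracle: maximise the no-ties Cox partial likelihood directly
  X <- cbind(g = g, sex = as.numeric(co$sex == "M"),
             age_first_rx = co$age_first_rx, pcz = co$pcz)
  neg_logpl <- function(beta) {
    eta <- drop(X %*% beta)
    s <- 0
    for (i in which(co$muscle_event == 1)) {
      risk <- co$muscle_time >= co$muscle_time[i]
      s <- s - eta[i] + log(sum(exp(eta[risk])))
    }
    s
  }
  opt <- optim(rep(0, 4), neg_logpl, method = "BFGS")
  expect_equal(res$estimate, opt$par[1], tolerance = 1e-4)
  expect_equal(res$hr, exp(opt$par[1]), tolerance = 1e-4)
})

test_that("equal hazards give a hazard ratio near one", {
  sim <- simulate_cohort(sim_scenario("null", n_samples = 20000, seed = 13))
  st <- call_star_alleles(sim$genotypes)
  treated <- sim$cohort[sim$cohort$treated, ]
  res <- survival_association(treated, st$star15_carrier[sim$cohort$treated],
                              "muscle")
  expect_lt(abs(res$estimate), 3 * res$se)
  expect_gte(res$n_events, 10)
})

test_that("the minimum-treatment-years restriction shrinks the analysis set", {
  sim <- simulate_cohort(sim_config(n_samples = 20000, seed = 14))
  st <- call_star_alleles(sim$genotypes)
  treated <- sim$cohort[sim$cohort$treated, ]
  g <- st$star15_carrier[sim$cohort$treated]
  all_years <- survival_association(treated, g, "muscle")
  five_plus <- survival_association(treated, g, "muscle",
                                    min_treatment_years = 5)
  expect_lt(five_plus$n, all_years$n)
})

test_that("discontinuation labelling follows the three-month gap rule", {
  rx <- data.frame(
    sample = c("A", "B"),
    first_rx = c("2008-01-01", "2008-01-01"),
    last_rx = c("2015-11-01", "2016-02-01"),   # 4 months / 1 month before censor
    censor_date = c("2016-02-28", "2016-02-28"),
    stringsAsFactors = FALSE
  )
  lab <- define_discontinuation(rx)
  expect_equal(lab$discontinued, c(TRUE, FALSE))
  expect_equal(lab$time, as.numeric(as.Date(rx$last_rx) -
                                      as.Date(rx$first_rx)) / 365.25)
  rx$last_rx[1] <- "2017-01-01"
  expect_error(define_discontinuation(rx), "after the censor date")
})

test_that("discontinuation labels match generator ground truth exactly", {
  sim <- simulate_cohort(sim_config(n_samples = 4000, seed = 19))
  lab <- define_discontinuation(sim$prescriptions)
  truth <- sim$truth$per_sample
  truth <- truth[match(lab$sample, truth$sample), ]
  expect_equal(lab$discontinued, truth$discontinued_truth)
})

test_that("BH adjustment matches a hand-applied step-up and its invariants", {
  expect_equal(bh_fdr(0.03), 0.03)                       # m = 1 identity
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.9)),
               c(0.04, 0.04, 0.04, 0.9))                 # hand-computed
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    q <- bh_fdr(p)
    expect_true(all(q <= 1) && all(q >= p))
    expect_false(is.unsorted(q[order(p)]))  # q ranks consistent with p ranks
  }
})

test_that("rare-variant scan recovers a large injected effect and matches its OLS oracle", {
  sim <- simulate_cohort(sim_scenario("rare_variant_large_effect",
                                      n_samples = 30000, seed = 23))
  stats <- allele_stats(sim$genotypes)
  rare <- data.frame(rsid = "rs373327528", chrom = "chr12", pos = 21176661L,
                     ref = "G", alt = "A", impact = "MODERATE",
                     stringsAsFactors = FALSE)
  scan <- rare_variant_scan(sim$genotypes, rare, sim$cohort)
  hit <- scan$per_variant[scan$per_variant$term == "rs373327528", ]
  expect_lt(abs(hit$estimate - 0.7), 3 * hit$se)
  expect_true(all(c("combined_carrier_F", "combined_carrier_M") %in%
                    scan$by_sex$term))

  # combined-carrier coefficient equals single-regressor OLS on a toy table
  co <- toy_cohort(30, seed = 55)
  co$treated <- TRUE
  dos <- matrix(0L, 30, 4, dimnames = list(co$sample, toy_variants()$rsid))
  dos[c(2, 9, 20), "rs4149056"] <- 1L
  gm <- genotype_matrix(co$sample, toy_variants(), dos)
  rare_toy <- toy_variants()[1, , drop = FALSE]
  scan_toy <- rare_variant_scan(gm, rare_toy, co, covariates = character(0))
  X <- cbind(1, as.numeric(dos[, "rs4149056"] >= 1))
  ne <- normal_equations(X, co$ldl)
  expect_equal(scan_toy$combined$estimate, ne$beta[2], tolerance = 1e-8)
  expect_equal(scan_toy$combined$se, ne$se[2], tolerance = 1e-8)
})

test_that("BH keeps the family-wise false-positive rate controlled on null variants", {
  set.seed(61)
  hits <- vapply(1:60, function(i) {
    cfg <- sim_scenario("null", n_samples = 4000, seed = 6000 + i)
    cfg$rare_variants$mac_ref <- c(30L, 25L, 20L, 35L)  # enough carriers to test
    cfg$rare_reference_n <- 4000L
    sim <- simulate_cohort(cfg)
    rare <- sim$genotypes$variants[sim$genotypes$variants$rsid %in%
                                     cfg$rare_variants$rsid, ]
    scan <- rare_variant_scan(sim$genotypes, rare, sim$cohort,
                              covariates = c("age", "sex"))
    any(scan$per_variant$q < 0.05)
  }, logical(1))
  bound <- 0.05 + qnorm(0.995) * sqrt(0.05 * 0.95 / 60)
  expect_lte(mean(hits), bound)
})
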