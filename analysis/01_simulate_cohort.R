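#!/usr/bin/env Rscript

# Stage 1: generate the working synthetic cohort.
#
# Emulates the study's statistical structure at n = 60,000: Table-2-style
# genotype frequencies with haplotype coupling, a treated LDL mean of 2.75
# mmol/L, gene-by-treatment effects, additive muscle-symptom hazard
# increments for treated *15/*20 carriers, prescription streams with
# discontinuation, and administrative censoring. Writes the pipeline's input
# files under results/cohort/ plus the small named fixture bundles.

library(statinpgx)

out_dir <- "results/cohort"
sim <- simulate_cohort(sim_config(n_samples = 60000, seed = 2024))
write_sim(sim, out_dir)

message(sprintf("cohort: %d samples, %d treated (%.1f%%), %d muscle events",
                nrow(sim$cohort), sum(sim$cohort$treated),
                100 * mean(sim$cohort$treated), sum(sim$cohort$muscle_event)))
message(sprintf("treated LDL mean %.2f (SD %.2f) mmol/L",
                mean(sim$cohort$ldl[sim$cohort$treated]),
                sd(sim$cohort$ldl[sim$cohort$treated])))
message(sprintf("*15 carrier patient-years (treated): %.0f",
                sim$truth$totals$carrier15_patient_years))

for (scen in c("null", "direct_effect", "confounded_treatment",
               "rare_variant_large_effect")) {
  make_fixture(scen, file.path("results", "fixtures", scen),
               n_samples = 5000, seed = 2024)
  message("fixture written: ", scen)
}
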