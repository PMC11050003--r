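#!/usr/bin/env Rscript

# Stage 4: GP-prescription outcomes among treated participants.
# Discontinuation labelling under the three-month rule, proportional-hazards
# associations of *15/*20 carrier status with muscle symptoms (overall and
# with 5+ years on statins), and with discontinuation.

library(statinpgx)

cohort <- utils::read.delim("results/cohort/cohort.tsv")
rx <- utils::read.delim("results/cohort/prescriptions.tsv")
star <- utils::read.delim("results/tables/star_alleles.tsv")

disc <- define_discontinuation(rx)
write_tsv_file(disc, "results/tables/discontinuation.tsv")
message(sprintf("discontinuation: %d/%d treated (%.1f%%)",
                sum(disc$discontinued), nrow(disc),
                100 * mean(disc$discontinued)))

treated <- cohort$treated
co_t <- cohort[treated, ]
rows <- list()
for (h in c("star15", "star20")) {
  carrier <- star[[paste0(h, "_carrier")]][treated]
  for (min_y in c(2 / 12, 5)) {
    res <- survival_association(co_t, carrier, "muscle",
                                min_treatment_years = min_y)
    res$variant <- h
    res$min_treatment_years <- round(min_y, 2)
    rows[[paste(h, min_y)]] <- res
  }
}

# discontinuation as a time-to-event outcome (event time: first to last
# prescription span)
co_t$disc_event <- as.integer(disc$discontinued[match(co_t$sample, disc$sample)])
co_t$disc_time <- pmax(disc$time[match(co_t$sample, disc$sample)], 1 / 365.25)
carrier5 <- star$star5[treated] >= 1
res <- survival_association(co_t, carrier5, "disc")
res$variant <- "star5_carrier"
res$min_treatment_years <- NA
rows[["disc"]] <- res

surv_tab <- do.call(rbind, rows)
write_tsv_file(surv_tab, "results/tables/survival_outcomes.tsv")
message("proportional-hazards results:")
message(paste(capture.output(print(
  surv_tab[, c("variant", "min_treatment_years", "hr", "p", "n_events")])),
  collapse = "\n"))
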