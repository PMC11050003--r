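#!/usr/bin/env Rscript

# Stage 2: read the emitted VCF back, compute allele statistics, apply the
# impact/MAC filtering cascade, call star alleles and haplotype carrier
# status, and classify participants under GRS-1/2/3.

library(statinpgx)

gm <- read_genotypes("results/cohort/genotypes.vcf")
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

stats <- allele_stats(gm)
write_tsv_file(stats, "results/tables/allele_stats.tsv")
message("allele statistics for ", nrow(stats), " variants; MAF range ",
        sprintf("%.2g-%.2g", min(stats$maf, na.rm = TRUE),
                max(stats$maf, na.rm = TRUE)))

flt <- filter_variants(gm$variants, stats)
message(sprintf("filter cascade: %d common (MAF > 0.1%%), %d rare variants kept",
                nrow(flt$common), nrow(flt$rare)))
write_tsv_file(rbind(cbind(flt$common, class = "common"),
                     cbind(flt$rare, class = "rare")),
               "results/tables/filtered_variants.tsv")

star <- call_star_alleles(gm)
write_tsv_file(star, "results/tables/star_alleles.tsv")
summ <- star_allele_summary(star)
write_tsv_file(summ, "results/tables/star_allele_summary.tsv")
message(paste(capture.output(print(summ)), collapse = "\n"))

for (scheme in c("GRS1", "GRS2", "GRS3")) {
  calls <- assign_grs(star, gm, grs_scheme(scheme))
  write_tsv_file(calls, sprintf("results/tables/grs_calls_%s.tsv", scheme))
  counts <- grs_group_counts(calls)
  message(sprintf("%s: %d high risk, %d low risk, %d unclassified",
                  scheme, counts$n_high, counts$n_low, counts$n_missing))
}
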