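Package: statinpgx
Title: Pharmacogenetic Analysis of Statin Response from SLCO1B1 Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacogenetic analysis of statin treatment response
    driven by SLCO1B1 (OATP1B1) genetic variation. Reads unphased exome
    genotypes at defined SLCO1B1 sites, computes allele statistics and applies
    a minor-allele-count/impact filtering cascade, calls star alleles and
    unphased haplotype carrier status (*5, *15, *20 and friends) from a
    file-driven definition table, classifies participants under rule-based
    statin gene risk scores (GRS-1/2/3), runs covariate-adjusted linear and
    proportional-hazards association scans with Benjamini-Hochberg false
    discovery rate control for rare variants, triangulates the genetically
    moderated treatment effect (GMTE) with a family of estimators gated by
    Cochran's Q, converts per-year risk differences into avoidable
    adverse-event counts, and simulates synthetic cohorts with the statistical
    structure the analysis assumes so the whole pipeline is testable without
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
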