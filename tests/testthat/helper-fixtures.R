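# Shared fixtures: tiny variant panels, hand-written VCF text, toy cohorts
# and the exhaustive four-site diplotype grid used by the truth-table tests.

toy_variants <- function() {
  data.frame(
    rsid = c("rs4149056", "rs2306283", "rs11045819", "rs34671512"),
    chrom = "chr12",
    pos = c(21178615L, 21176804L, 21176868L, 21239042L),
    ref = c("T", "A", "C", "A"),
    alt = c("C", "G", "A", "C"),
    consequence = "missense_variant",
    impact = "MODERATE",
    stringsAsFactors = FALSE
  )
}

# Shipped star definitions restricted to the four common sites (so calls on
# the toy panel do not warn about the absent rare-allele sites).
toy_definitions <- function() {
  defs <- read_star_definitions()
  defs[defs$rsid %in% toy_variants()$rsid, , drop = FALSE]
}

# A genotype matrix holding every (d5, d37, d4, d19) dosage combination:
# 3^4 = 81 synthetic samples.
diplotype_grid_gm <- function() {
  grid <- expand.grid(d5 = 0:2, d37 = 0:2, d4 = 0:2, d19 = 0:2)
  gm <- genotype_matrix(sprintf("D%02d", seq_len(nrow(grid))), toy_variants(),
                        as.matrix(grid))
  list(gm = gm, grid = grid)
}

# Small cohort for regression oracles: random covariates, no structure.
toy_cohort <- function(n = 20, seed = 99) {
  set.seed(seed)
  data.frame(
    sample = sprintf("T%03d", seq_len(n)),
    age = runif(n, 40, 70),
    sex = sample(c("F", "M"), n, replace = TRUE),
    treated = rep(c(TRUE, FALSE), length.out = n),
    ldl = rnorm(n, 3, 0.5),
    stringsAsFactors = FALSE
  )
}

# Closed-form OLS via the normal equations, independent of lm().
normal_equations <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (nrow(X) - ncol(X))
  list(beta = unname(drop(beta)), se = unname(sqrt(diag(sigma2 * solve(XtX)))))
}

write_lines_vcf <- function(body_lines, samples = "S1") {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines
  ), path)
  path
}
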