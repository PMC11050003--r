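# Star-allele and haplotype calling from unphased diplotypes.

#' Read a star-allele definition table
#'
#' The table maps each star allele to its defining variant(s) and risk
#' allele(s). `role = "defining"` marks single-variant alleles (copies equal
#' the risk-allele dosage); `role = "constituent"` rows jointly define a
#' multi-variant haplotype.
#'
#' @param path Tab-delimited file with columns
#'   `star_allele, rsid, risk_allele, role`. Defaults to the shipped table.
#' @return Data frame of definitions.
#' @export
read_star_definitions <- function(path = statinpgx_file("star_allele_definitions.tsv")) {
  defs <- read_tsv_file(path)
  required <- c("star_allele", "rsid", "risk_allele", "role")
  if (!all(required %in% names(defs))) {
    stop("definition table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(defs$role), c("defining", "constituent"))
  if (length(bad)) stop("unknown role: ", paste(bad, collapse = ", "), call. = FALSE)
  defs
}

# "*15" -> "star15": syntactic column names for the calls table.
star_column <- function(star_allele) {
  paste0("star", sub("^\\*", "", star_allele))
}

#' Call star alleles and haplotype carrier status from unphased genotypes
#'
#' Single-variant star alleles get `copies` equal to the dosage of the
#' defining risk allele. Multi-variant haplotypes are called at carrier level
#' (genotypes are unphased): a sample is a *carrier* when it holds at least
#' one risk allele at every constituent site, and a member of the haplotype's
#' *reference group* when it holds zero copies at every constituent site.
#' Samples carrying some but not all constituent risk alleles belong to
#' neither group. A missing genotype at any constituent site makes both flags
#' missing for that sample.
#'
#' Star alleles whose defining variants are absent from `gm` are skipped with
#' a warning.
#'
#' @param gm A [genotype_matrix()].
#' @param definitions Definition table from [read_star_definitions()].
#' @return Data frame, one row per sample: `sample`, one `starX` integer
#'   column (copies 0/1/2) per single-variant allele, and
#'   `starX_carrier`/`starX_reference` logical columns per haplotype.
#' @export
call_star_alleles <- function(gm, definitions = read_star_definitions()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  res <- data.frame(sample = gm$samples, stringsAsFactors = FALSE)

  risk_dosage <- function(rsid, risk_allele) {
    v <- gm$variants[gm$variants$rsid == rsid, ]
    d <- gm$dosage[, rsid]
    if (identical(v$alt, risk_allele)) d
    else if (identical(v$ref, risk_allele)) 2L - d
    else stop("risk allele ", risk_allele, " matches neither allele of ",
              rsid, call. = FALSE)
  }

  for (allele in unique(definitions$star_allele)) {
    rows <- definitions[definitions$star_allele == allele, ]
    if (!all(rows$rsid %in% gm$variants$rsid)) {
      warning("skipping ", allele, ": defining variant(s) ",
              paste(setdiff(rows$rsid, gm$variants$rsid), collapse = ", "),
              " not in genotype matrix")
      next
    }
    if (all(rows$role == "defining")) {
      if (nrow(rows) != 1) {
        stop(allele, ": a single-variant allele must have exactly one defining row",
             call. = FALSE)
      }
      res[[star_column(allele)]] <- risk_dosage(rows$rsid, rows$risk_allele)
    } else {
      dos <- vapply(seq_len(nrow(rows)), function(k) {
        risk_dosage(rows$rsid[k], rows$risk_allele[k])
      }, numeric(length(gm$samples)))
      dos <- matrix(dos, nrow = length(gm$samples))
      carrier <- apply(dos, 1, function(x) {
        if (anyNA(x)) NA else all(x >= 1)
      })
      reference <- apply(dos, 1, function(x) {
        if (anyNA(x)) NA else all(x == 0)
      })
      res[[paste0(star_column(allele), "_carrier")]] <- carrier
      res[[paste0(star_column(allele), "_reference")]] <- reference
    }
  }
  res
}

#' Summarise star-allele calls
#'
#' Counts carriers per star allele (copies >= 1 for single-variant alleles,
#' carrier flag for haplotypes) and, for haplotypes, the size of the
#' reference group and the number of partially-carrying samples that belong
#' to neither group.
#'
#' @param star_table Output of [call_star_alleles()].
#' @return Data frame with columns `star_allele, carriers, reference, neither,
#'   missing`.
#' @export
star_allele_summary <- function(star_table) {
  cols <- setdiff(names(star_table), "sample")
  singles <- cols[!grepl("_(carrier|reference)$", cols)]
  haplos <- unique(sub("_(carrier|reference)$", "",
                       cols[grepl("_(carrier|reference)$", cols)]))
  rows <- list()
  for (s in singles) {
    x <- star_table[[s]]
    rows[[s]] <- data.frame(star_allele = s,
                            carriers = sum(x >= 1, na.rm = TRUE),
                            reference = sum(x == 0, na.rm = TRUE),
                            neither = 0L, missing = sum(is.na(x)))
  }
  for (h in haplos) {
    ca <- star_table[[paste0(h, "_carrier")]]
    re <- star_table[[paste0(h, "_reference")]]
    rows[[h]] <- data.frame(star_allele = h,
                            carriers = sum(ca, na.rm = TRUE),
                            reference = sum(re, na.rm = TRUE),
                            neither = sum(!ca & !re, na.rm = TRUE),
                            missing = sum(is.na(ca)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
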