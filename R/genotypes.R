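# Genotype handling: site panels, VCF input/output, allele statistics and the
# impact/minor-allele-count filtering cascade.

#' Default SLCO1B1 site panel
#'
#' The variant panel shipped with the package: the four common star-allele
#' sites (rs4149056, rs2306283, rs11045819, rs34671512), placeholder sites for
#' the rare *45/*46 alleles, and the rare missense sites scanned for
#' LDL effects. Columns `consequence` and `impact` stand in for VEP output.
#'
#' @param path Optional path to a tab-delimited panel file with columns
#'   `rsid, chrom, pos, ref, alt, consequence, impact`.
#' @return Data frame of variants, ordered by genomic position.
#' @export
slco1b1_panel <- function(path = statinpgx_file("slco1b1_panel.tsv")) {
  v <- read_tsv_file(path)
  validate_variants(v)
  v[order(v$chrom, v$pos), , drop = FALSE]
}

validate_variants <- function(variants) {
  required <- c("rsid", "chrom", "pos", "ref", "alt", "impact")
  missing <- setdiff(required, names(variants))
  if (length(missing)) {
    stop("variant table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(variants$pos <= 0)) stop("variant positions must be positive", call. = FALSE)
  if (any(variants$ref == variants$alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  bad <- setdiff(unique(variants$impact), c("HIGH", "MODERATE", "LOW", "MODIFIER"))
  if (length(bad)) {
    stop("unknown impact class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(variants)
}

#' Construct a genotype matrix object
#'
#' A genotype matrix holds per-sample minor-allele dosages (0/1/2, `NA` for
#' missing) at named variants.
#'
#' @param samples Character vector of sample IDs.
#' @param variants Data frame of variants (see [slco1b1_panel()]).
#' @param dosage Integer matrix, samples x variants; values in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, variants, dosage) {
  validate_variants(variants)
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(samples) || ncol(dosage) != nrow(variants)) {
    stop("dosage dimensions must match samples x variants", call. = FALSE)
  }
  if (!all(dosage %in% c(0L, 1L, 2L, NA))) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  dimnames(dosage) <- list(samples, variants$rsid)
  structure(list(samples = samples, variants = variants,
                 dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read genotypes at listed sites from a VCF file
#'
#' Decodes unphased GT fields into dosages of the listed ALT allele. Sites in
#' `site_list` that are absent from the file become all-missing columns with a
#' warning; a site whose ALT allele in the file disagrees with the panel is
#' also set all-missing, with a per-site warning.
#'
#' @param vcf_path Path to a VCF file (plain or bgzipped).
#' @param site_list Data frame of variants to extract (default panel:
#'   [slco1b1_panel()]).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(vcf_path, site_list = slco1b1_panel()) {
  if (!file.exists(vcf_path)) {
    stop("cannot read VCF file: ", vcf_path, call. = FALSE)
  }
  validate_variants(site_list)
  if (nrow(site_list) == 0) stop("site_list is empty", call. = FALSE)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt) %||% character(0)
  n <- length(samples)
  dosage <- matrix(NA_integer_, nrow = n, ncol = nrow(site_list),
                   dimnames = list(samples, site_list$rsid))
  key_file <- paste(fix$CHROM, fix$POS)
  for (j in seq_len(nrow(site_list))) {
    site <- site_list[j, ]
    i <- which(key_file == paste(site$chrom, site$pos))
    if (!length(i)) {
      i <- which(fix$ID == site$rsid)
    }
    if (!length(i)) {
      warning("site ", site$rsid, " not found in VCF; column set missing")
      next
    }
    i <- i[[1]]
    if (!identical(fix$ALT[i], site$alt) || !identical(fix$REF[i], site$ref)) {
      warning("allele mismatch at ", site$rsid, " (file ", fix$REF[i], ">",
              fix$ALT[i], ", panel ", site$ref, ">", site$alt,
              "); column set missing")
      next
    }
    dosage[, j] <- decode_gt(gt[i, ])
  }
  genotype_matrix(samples, site_list, dosage)
}

# "0/1"-style GT string -> count of ALT alleles; any missing allele -> NA.
decode_gt <- function(gt) {
  gt <- sub(":.*", "", gt)
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0 || any(is.na(a)) || any(a == ".")) return(NA_integer_)
    sum(a != "0")
  }, integer(1))
}

#' Write a genotype matrix to a plain-text VCF file
#'
#' Emits a minimal VCFv4.2 file with unphased GT fields; missing dosages are
#' written as `./.`. Round-trips exactly through [read_genotypes()].
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=statinpgx",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  ), con)
  ord <- order(v$chrom, v$pos)
  for (j in ord) {
    gt <- ifelse(is.na(gm$dosage[, j]), "./.", gt_code[gm$dosage[, j] + 1L])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$rsid[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Per-variant allele statistics
#'
#' Computes the minor allele count (MAC) and minor allele frequency (MAF) per
#' variant over non-missing calls, folding so that MAF <= 0.5. When the ALT
#' allele frequency exceeds 0.5, the REF allele is the minor allele and MAC
#' counts REF alleles.
#'
#' @param gm A [genotype_matrix()].
#' @return Data frame with columns `rsid, n_called, mac, maf, minor_allele,
#'   undefined`; `undefined` flags all-missing variants (whose `mac`/`maf` are
#'   `NA`, never silently zero).
#' @export
allele_stats <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  res <- lapply(seq_len(ncol(gm$dosage)), function(j) {
    d <- gm$dosage[, j]
    n_called <- sum(!is.na(d))
    if (n_called == 0) {
      return(data.frame(rsid = gm$variants$rsid[j], n_called = 0L,
                        mac = NA_integer_, maf = NA_real_,
                        minor_allele = NA_character_, undefined = TRUE))
    }
    alt_count <- sum(d, na.rm = TRUE)
    total <- 2L * n_called
    if (alt_count <= total - alt_count) {
      mac <- alt_count
      minor <- gm$variants$alt[j]
    } else {
      mac <- total - alt_count
      minor <- gm$variants$ref[j]
    }
    data.frame(rsid = gm$variants$rsid[j], n_called = n_called,
               mac = as.integer(mac), maf = mac / total,
               minor_allele = minor, undefined = FALSE)
  })
  do.call(rbind, res)
}

#' Filter variants by predicted impact and minor allele count
#'
#' Applies the selection cascade used for exome variants: keep variants whose
#' predicted impact is in `impact_classes` and whose MAC is strictly greater
#' than `min_mac`, then partition the kept variants into common
#' (MAF > `common_maf_threshold`) and rare. Ordering is stable by position.
#'
#' @param variants Data frame of variants.
#' @param stats Allele statistics from [allele_stats()], covering all
#'   `variants`.
#' @param min_mac Strict lower bound on MAC (default 3, i.e. keep MAC > 3).
#' @param impact_classes Impact classes to keep (default HIGH and MODERATE).
#' @param common_maf_threshold MAF above which a kept variant is "common"
#'   (default 0.001).
#' @return List with data frames `common` and `rare`.
#' @export
filter_variants <- function(variants, stats, min_mac = 3,
                            impact_classes = c("HIGH", "MODERATE"),
                            common_maf_threshold = 0.001) {
  validate_variants(variants)
  if (!all(variants$rsid %in% stats$rsid)) {
    stop("stats must cover all variants", call. = FALSE)
  }
  s <- stats[match(variants$rsid, stats$rsid), ]
  keep <- variants$impact %in% impact_classes &
    !is.na(s$mac) & s$mac > min_mac
  kept <- variants[keep, , drop = FALSE]
  kept_stats <- s[keep, , drop = FALSE]
  ord <- order(kept$pos)
  kept <- kept[ord, , drop = FALSE]
  kept_stats <- kept_stats[ord, , drop = FALSE]
  is_common <- kept_stats$maf > common_maf_threshold
  list(common = kept[is_common, , drop = FALSE],
       rare = kept[!is_common, , drop = FALSE])
}
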