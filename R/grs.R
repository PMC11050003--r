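# Rule-based statin gene risk scores (GRS-1/2/3) over the four common
# SLCO1B1 variants, optionally extended with LDL-increasing rare variants.

GRS_VARIANTS <- c(star5 = "rs4149056", star37 = "rs2306283",
                  star4 = "rs11045819", star19 = "rs34671512")

DEFAULT_GRS3_RARE <- c("rs374113543", "rs373327528", "rs960742177",
                       "rs780911188")

#' Define a gene-risk-score scheme
#'
#' Three rule-based schemes classify each participant as "high" or "low"
#' statin risk from the four common variant genotypes:
#'
#' * **GRS1** — high risk if homozygous for the *5 C allele (rs4149056-CC),
#'   or heterozygous for *5 (TC) while carrying *no* protective alleles:
#'   rs2306283-AA, rs11045819-CC and rs34671512-AA.
#' * **GRS2** — as GRS1, but with the rs2306283 G allele treated as acting
#'   with the detrimental *5 allele: the heterozygote branch requires
#'   rs2306283-GG instead of AA.
#' * **GRS3** — GRS2, additionally high risk for carriers of any designated
#'   LDL-increasing rare variant.
#'
#' @param name One of `"GRS1"`, `"GRS2"`, `"GRS3"`.
#' @param rare_rsids Rare variants whose carriers are high risk under GRS3
#'   (ignored otherwise). Defaults to the four LDL-increasing rare variants.
#' @return An object of class `grs_scheme`.
#' @export
grs_scheme <- function(name = c("GRS1", "GRS2", "GRS3"),
                       rare_rsids = DEFAULT_GRS3_RARE) {
  name <- match.arg(name)
  structure(list(name = name,
                 star37_required = if (name == "GRS1") 0L else 2L,
                 rare_rsids = if (name == "GRS3") rare_rsids else character(0)),
            class = "grs_scheme")
}

#' Assign gene-risk-score classes
#'
#' Evaluates a [grs_scheme()] for every sample. A sample with a missing
#' genotype at any scheme variant gets a missing class (never silently "low");
#' the number of such samples is reported via a message.
#'
#' @param star_table Star-allele calls from [call_star_alleles()]; the
#'   `star5`, `star37`, `star4` and `star19` copy columns are used.
#' @param gm The [genotype_matrix()] (used for GRS3 rare-variant carrier
#'   status; may be `NULL` for GRS1/GRS2).
#' @param scheme A [grs_scheme()].
#' @return Data frame with columns `sample, scheme, risk_class, rationale`;
#'   `risk_class` is `"high"`, `"low"` or `NA`.
#' @export
assign_grs <- function(star_table, gm = NULL, scheme = grs_scheme("GRS2")) {
  stopifnot(inherits(scheme, "grs_scheme"))
  need <- c("star5", "star37", "star4", "star19")
  if (!all(need %in% names(star_table))) {
    stop("star_table lacks copy columns: ",
         paste(setdiff(need, names(star_table)), collapse = ", "), call. = FALSE)
  }
  d5 <- star_table$star5    # copies of rs4149056-C
  d37 <- star_table$star37  # copies of rs2306283-G
  d4 <- star_table$star4    # copies of rs11045819-A
  d19 <- star_table$star19  # copies of rs34671512-C

  rare_carrier <- rep(FALSE, nrow(star_table))
  if (length(scheme$rare_rsids)) {
    if (is.null(gm)) stop("GRS3 needs the genotype matrix for rare variants",
                          call. = FALSE)
    present <- intersect(scheme$rare_rsids, colnames(gm$dosage))
    if (length(present) < length(scheme$rare_rsids)) {
      warning("rare variants absent from genotype matrix: ",
              paste(setdiff(scheme$rare_rsids, present), collapse = ", "))
    }
    if (length(present)) {
      rare_dos <- gm$dosage[match(star_table$sample, gm$samples), present,
                            drop = FALSE]
      rare_carrier <- rowSums(rare_dos >= 1, na.rm = TRUE) > 0
    }
  }

  hom_branch <- d5 == 2L
  het_branch <- d5 == 1L & d37 == scheme$star37_required & d4 == 0L & d19 == 0L
  high <- hom_branch | het_branch
  class <- ifelse(is.na(high), NA_character_, ifelse(high, "high", "low"))
  rationale <- rep(NA_character_, length(class))
  rationale[!is.na(hom_branch) & hom_branch] <- "star5 homozygote"
  rationale[!is.na(het_branch) & het_branch &
              !(hom_branch %in% TRUE)] <- "star5 heterozygote, no protective alleles"
  rationale[class %in% "low"] <- "remaining combination"
  if (length(scheme$rare_rsids)) {
    promote <- rare_carrier & !(class %in% "high")
    class[promote] <- "high"
    rationale[promote] <- "LDL-increasing rare-variant carrier"
  }
  n_missing <- sum(is.na(class))
  if (n_missing) {
    message(scheme$name, ": ", n_missing,
            " sample(s) unclassified due to missing genotypes")
  }
  data.frame(sample = star_table$sample, scheme = scheme$name,
             risk_class = class, rationale = rationale,
             stringsAsFactors = FALSE)
}

#' Count gene-risk-score groups
#'
#' @param calls Output of [assign_grs()].
#' @return Named list: `n_high`, `n_low`, `n_missing`.
#' @export
grs_group_counts <- function(calls) {
  if (!nrow(calls)) stop("no GRS calls to count", call. = FALSE)
  list(n_high = sum(calls$risk_class == "high", na.rm = TRUE),
       n_low = sum(calls$risk_class == "low", na.rm = TRUE),
       n_missing = sum(is.na(calls$risk_class)))
}
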