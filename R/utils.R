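#' @keywords internal
"_PACKAGE"

# Round half away from zero (base round() rounds half to even, which would
# turn 64.5 into 64; the avoidable-events arithmetic needs 65).
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Two-sided Wald p-value from an estimate and its standard error.
wald_p <- function(estimate, se) {
  2 * stats::pnorm(-abs(estimate / se))
}

# 95% Wald confidence bounds.
wald_ci <- function(estimate, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(low = estimate - z * se, high = estimate + z * se)
}

#' Locate a file shipped with the package
#'
#' Convenience wrapper around [system.file()] for the data files under
#' `extdata/` (star-allele definitions, default site panel, illustration
#' inputs).
#'
#' @param name File name under `extdata/`.
#' @return Absolute path to the file.
#' @export
statinpgx_file <- function(name) {
  path <- system.file("extdata", name, package = "statinpgx", mustWork = FALSE)
  if (!nzchar(path)) stop("no shipped file named '", name, "'", call. = FALSE)
  path
}

# Read a tab-delimited file, skipping '#' comment lines.
read_tsv_file <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

#' Write a data frame as tab-delimited text
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
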