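# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Round half away from zero
#'
#' Deterministic half-up rounding used for all displayed values (base
#' `round()` rounds half to even). Percentages are shown at 2 decimals and
#' skews at 3, matching the conventions of published mitogenome composition
#' tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

DNA_BASES <- c("A", "C", "G", "T")

# reverse complement of a plain character string (delegates to Biostrings)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

check_dna <- function(seq, allow_n = TRUE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stopf("%s must be a single character string", what)
  ok <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  s <- toupper(seq)
  if (!grepl(ok, s))
    stopf("%s contains characters outside {A,C,G,T%s}", what,
          if (allow_n) ",N" else "")
  s
}

# deterministic per-stream seeds derived from a master seed; arithmetic in
# doubles (exact below 2^53) so nested derivations never overflow, result
# kept < 2^31
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(stream) * 1013) %% 2147483563)
}
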