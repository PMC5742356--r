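# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed summary tables in this
#' field round half away from zero, so percentages such as 86.985 become
#' 86.99, not 86.98.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# percentage with 2-decimal half-away-from-zero rounding
pct2 <- function(num, den) round_half_up(100 * num / den, 2)

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# translate an in-frame nucleotide string via a plain codon lookup (much
# cheaper than building XString objects); "*" kept for stops, "X" for
# codons with ambiguous bases
translate_nt <- function(nt) {
  stopifnot(nchar(nt) %% 3 == 0)
  if (nchar(nt) == 0) return("")
  codons <- substring(toupper(nt), seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# random DNA string(s) under the current RNG state
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# force `base` at 1-based position `pos` of string `seq`
force_base <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

base_at <- function(seq, pos) substr(seq, pos, pos)

# 1-based inclusive interval as a length-2 integer vector
iv <- function(start, end) c(start = as.integer(start), end = as.integer(end))

iv_width <- function(x) x[["end"]] - x[["start"]] + 1L

iv_contains <- function(x, pos) pos >= x[["start"]] & pos <= x[["end"]]

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits; used only to
# stamp a configuration fingerprint into output headers.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte touches only the low 8 bits; keep h a double (it can
    # exceed the integer range, which bitwXor cannot take directly)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by 16777619 = 2^24 + 403, split so every
    # intermediate stays below 2^53 (doubles are exact there)
    h <- ((h %% 256) * 16777216 + (h * 403) %% 4294967296) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
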