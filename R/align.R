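# Thin layer over Biostrings::pairwiseAlignment with the package-wide
# nucleotide scoring scheme (match +2, mismatch -3, gap of length L costs
# 6 + L), plus alignment walking: difference extraction with left-shifted
# indels, and mapping of positions through an alignment.

.align_env <- new.env(parent = emptyenv())

score_matrix <- function() {
  if (is.null(.align_env$mat))
    .align_env$mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE)
  .align_env$mat
}

GAP_OPEN <- 6
GAP_EXT <- 1

# local alignment of one or more patterns against a single subject
align_local <- function(patterns, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = score_matrix(),
    gapOpening = GAP_OPEN, gapExtension = GAP_EXT)
}

# pattern aligned end-to-end inside a locally chosen window of the subject
align_glocal <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(pattern), Biostrings::DNAString(subject),
    type = "global-local", substitutionMatrix = score_matrix(),
    gapOpening = GAP_OPEN, gapExtension = GAP_EXT)
}

# full global alignment (used for read-vs-reference identity classification,
# where terminal deletions must be represented, not clipped)
align_global <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(pattern), Biostrings::DNAString(subject),
    type = "global", substitutionMatrix = score_matrix(),
    gapOpening = GAP_OPEN, gapExtension = GAP_EXT)
}

# Gapped alignment strings plus original-coordinate offsets of one
# alignment, extracted once.  The cheap accessors pattern()/subject() clip
# TERMINAL gap runs (a trailing deletion of the reference would vanish), so
# unaligned ends are re-padded explicitly from the original sequences:
# `pad = "global"` restores both ends (full global alignments), `"pattern"`
# restores unaligned pattern ends only (pattern-global alignments inside a
# local subject window), `"none"` leaves local alignments as reported.
# (The alignedPattern()/alignedSubject() accessors do this padding natively
# but are two orders of magnitude slower.)
aln_parts <- function(aln, i = 1L, pad = "global") {
  p_chr <- unname(as.character(Biostrings::pattern(aln))[i])
  s_chr <- unname(as.character(Biostrings::subject(aln))[i])
  p_start <- Biostrings::start(Biostrings::pattern(aln))[i]
  p_end <- Biostrings::end(Biostrings::pattern(aln))[i]
  s_start <- Biostrings::start(Biostrings::subject(aln))[i]
  s_end <- Biostrings::end(Biostrings::subject(aln))[i]
  if (pad != "none") {
    p_orig <- unname(as.character(
      Biostrings::unaligned(Biostrings::pattern(aln)))[i])
    s_orig <- unname(as.character(
      Biostrings::unaligned(Biostrings::subject(aln)))[if (length(
        Biostrings::unaligned(Biostrings::subject(aln))) >= i) i else 1L])
    # unaligned pattern prefix/suffix -> columns against subject gaps
    if (p_start > 1L) {
      pre <- substr(p_orig, 1L, p_start - 1L)
      p_chr <- paste0(pre, p_chr)
      s_chr <- paste0(strrep("-", nchar(pre)), s_chr)
      p_start <- 1L
    }
    if (p_end < nchar(p_orig)) {
      suf <- substr(p_orig, p_end + 1L, nchar(p_orig))
      p_chr <- paste0(p_chr, suf)
      s_chr <- paste0(s_chr, strrep("-", nchar(suf)))
      p_end <- nchar(p_orig)
    }
    if (pad == "global") {
      # unaligned subject prefix/suffix -> columns against pattern gaps
      if (s_start > 1L) {
        pre <- substr(s_orig, 1L, s_start - 1L)
        s_chr <- paste0(pre, s_chr)
        p_chr <- paste0(strrep("-", nchar(pre)), p_chr)
        s_start <- 1L
      }
      if (s_end < nchar(s_orig)) {
        suf <- substr(s_orig, s_end + 1L, nchar(s_orig))
        s_chr <- paste0(s_chr, suf)
        p_chr <- paste0(p_chr, strrep("-", nchar(suf)))
        s_end <- nchar(s_orig)
      }
    }
  }
  p <- strsplit(p_chr, "")[[1]]
  s <- strsplit(s_chr, "")[[1]]
  list(p = p_chr, s = s_chr, pv = p, sv = s,
       p_start = p_start, p_end = p_end,
       s_start = s_start, s_end = s_end,
       p_col = cumsum(p != "-") + p_start - 1L,
       s_col = cumsum(s != "-") + s_start - 1L)
}

# identity over all alignment columns (gap columns count in the denominator),
# as a percentage with 2-decimal half-away-from-zero rounding
aln_identity_pct <- function(aln, i = 1L, pad = "pattern") {
  parts_identity_pct(aln_parts(aln, i, pad))
}

parts_identity_pct <- function(parts) {
  p <- parts$pv
  s <- parts$sv
  pct2(sum(p == s & p != "-"), length(p))
}

# Enumerate differences of `subject` relative to `pattern` (the reference).
# Returns a data.frame with one row per event:
#   kind: substitution / insertion (extra subject bases) / deletion
#         (pattern bases missing from subject)
#   ppos: position on the pattern (for an insertion: the pattern position
#         after which the bases are inserted); pend: last pattern position of
#         a deletion run
#   spos: position on the subject (for a deletion: the subject position after
#         which the bases are missing)
#   ref, alt: pattern / subject bases involved (lowercase)
# Indel runs are merged and left-shifted against the pattern (deletions) or
# subject (insertions) so homopolymer events have canonical coordinates.
aln_diffs <- function(aln, i = 1L) {
  parts_diffs(aln_parts(aln, i))
}

parts_diffs <- function(parts) {
  p <- parts$pv
  s <- parts$sv
  n <- length(p)
  ppos_col <- parts$p_col
  spos_col <- parts$s_col
  out <- list()
  k <- 1L
  while (k <= n) {
    if (p[k] != "-" && s[k] != "-") {
      if (p[k] != s[k])
        out[[length(out) + 1L]] <- data.frame(
          kind = "substitution", ppos = ppos_col[k], pend = ppos_col[k],
          spos = spos_col[k], ref = tolower(p[k]), alt = tolower(s[k]),
          stringsAsFactors = FALSE)
      k <- k + 1L
    } else if (s[k] == "-") {            # deletion: pattern bases missing
      j <- k
      while (j < n && s[j + 1] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        kind = "deletion", ppos = ppos_col[k], pend = ppos_col[j],
        spos = spos_col[k], ref = tolower(paste(p[k:j], collapse = "")),
        alt = "", stringsAsFactors = FALSE)
      k <- j + 1L
    } else {                             # insertion: extra subject bases
      j <- k
      while (j < n && p[j + 1] == "-") j <- j + 1L
      out[[length(out) + 1L]] <- data.frame(
        kind = "insertion", ppos = ppos_col[k], pend = ppos_col[k],
        spos = spos_col[k], ref = "",
        alt = tolower(paste(s[k:j], collapse = "")), stringsAsFactors = FALSE)
      k <- j + 1L
    }
  }
  if (!length(out))
    return(data.frame(kind = character(), ppos = integer(), pend = integer(),
                      spos = integer(), ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  left_shift_indels(df, pattern_seq = gsub("-", "", parts$p),
                    subject_seq = gsub("-", "", parts$s),
                    p_start = parts$p_start, s_start = parts$s_start)
}

# content-based left normalization of indel coordinates
left_shift_indels <- function(df, pattern_seq, subject_seq, p_start, s_start) {
  pat_at <- function(pos) substr(pattern_seq, pos - p_start + 1L,
                                 pos - p_start + 1L)
  sub_at <- function(pos) substr(subject_seq, pos - s_start + 1L,
                                 pos - s_start + 1L)
  for (r in seq_len(nrow(df))) {
    if (df$kind[r] == "deletion") {
      # deleted pattern block [ppos..pend] may shift left while the base
      # preceding the block equals the block's last base
      while (df$ppos[r] > p_start &&
             tolower(pat_at(df$ppos[r] - 1L)) ==
             substr(df$ref[r], nchar(df$ref[r]), nchar(df$ref[r]))) {
        df$ref[r] <- paste0(tolower(pat_at(df$ppos[r] - 1L)),
                            substr(df$ref[r], 1, nchar(df$ref[r]) - 1L))
        df$ppos[r] <- df$ppos[r] - 1L
        df$pend[r] <- df$pend[r] - 1L
        df$spos[r] <- df$spos[r] - 1L
      }
    } else if (df$kind[r] == "insertion") {
      while (df$spos[r] > s_start &&
             tolower(sub_at(df$spos[r] - 1L)) ==
             substr(df$alt[r], nchar(df$alt[r]), nchar(df$alt[r]))) {
        df$alt[r] <- paste0(tolower(sub_at(df$spos[r] - 1L)),
                            substr(df$alt[r], 1, nchar(df$alt[r]) - 1L))
        df$spos[r] <- df$spos[r] - 1L
        df$ppos[r] <- df$ppos[r] - 1L
        df$pend[r] <- df$pend[r] - 1L
      }
    }
  }
  df[order(df$ppos, df$spos), , drop = FALSE]
}

# subject position aligned to pattern position `ppos` (first subject base at
# or after it if `ppos` falls in a subject gap); NA when out of range
map_pattern_pos <- function(aln, ppos, i = 1L) {
  parts_map_pos(aln_parts(aln, i), ppos)
}

parts_map_pos <- function(parts, ppos) {
  p <- parts$pv
  s <- parts$sv
  pc <- parts$p_col
  sc <- parts$s_col
  hit <- which(pc == ppos & p != "-")
  if (!length(hit)) return(NA_integer_)
  k <- hit[1]
  while (k <= length(s) && s[k] == "-") k <- k + 1L
  if (k > length(s)) return(NA_integer_)
  sc[k]
}

# number of differing nucleotides in an alignment: mismatches plus every
# inserted and deleted nt counts 1
aln_diff_count <- function(aln, i = 1L, pad = "pattern") {
  parts <- aln_parts(aln, i, pad)
  sum(parts$pv != parts$sv)
}
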