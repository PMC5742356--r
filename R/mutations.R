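# Mutation records, IMGT-style nomenclature, application to sequences, and
# localization against the amplicon geometry.
#
# A mutation set is a data.frame with one row per event:
#   kind: "substitution", "deletion" (single nt), "range_deletion", "insertion"
#   pos:  1-based position on the forward-oriented reference insert; for an
#         insertion, the reference position after which the bases are inserted
#   end:  last deleted position of a range_deletion, otherwise == pos
#   ref:  deleted/substituted reference base(s), lowercase ("" for insertions)
#   alt:  substituted/inserted base(s), lowercase ("" for deletions)

mutation_df <- function(kind = character(), pos = integer(),
                        end = integer(), ref = character(),
                        alt = character()) {
  data.frame(kind = kind, pos = as.integer(pos),
             end = as.integer(if (length(end)) end else pos),
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Format a mutation in IMGT-style nomenclature
#'
#' Substitution `c322>t`; single-nt deletion `a942>del`; multi-nt deletion
#' `a886-a977>del (92 nt)`; insertion `658^659>ins^cc` (bases inserted
#' between positions 658 and 659).
#'
#' @param kind one of `"substitution"`, `"deletion"`, `"range_deletion"`,
#'   `"insertion"`.
#' @param pos 1-based position (for insertions: position 5' of the inserted
#'   bases).
#' @param ref reference base(s), lowercase (ignored for insertions).
#' @param alt substituted or inserted base(s), lowercase.
#' @param end last position of a range deletion.
#' @param reference optional reference sequence; when given, `ref` is checked
#'   against it and a mismatch is an error.
#' @return the nomenclature string.
#' @export
format_mutation <- function(kind, pos, ref = "", alt = "", end = pos,
                            reference = NULL) {
  pos <- as.integer(pos); end <- as.integer(end)
  ref <- tolower(ref); alt <- tolower(alt)
  if (!is.null(reference)) {
    span <- if (kind == "insertion") "" else substr(reference, pos, end)
    if (kind != "insertion" && tolower(span) != ref)
      stopf("ref base(s) '%s' do not match reference '%s' at %d..%d",
            ref, tolower(span), pos, end)
  }
  switch(kind,
    substitution = sprintf("%s%d>%s", ref, pos, alt),
    deletion = sprintf("%s%d>del", ref, pos),
    range_deletion = sprintf("%s%d-%s%d>del (%d nt)",
                             substr(ref, 1, 1), pos,
                             substr(ref, nchar(ref), nchar(ref)), end,
                             end - pos + 1L),
    insertion = sprintf("%d^%d>ins^%s", pos, pos + 1L, alt),
    stopf("unknown mutation kind '%s'", kind))
}

#' Parse an IMGT-style mutation string
#'
#' Inverse of [format_mutation()]; whitespace around operators is tolerated.
#' For a range deletion the `ref` field holds only the first and last deleted
#' base (the printed nomenclature carries no more); [apply_mutations()]
#' checks those two against the reference.
#'
#' @param text nomenclature string, e.g. `"a545>g"`.
#' @return one-row mutation data.frame (columns `kind`, `pos`, `end`, `ref`,
#'   `alt`).
#' @export
parse_mutation <- function(text) {
  x <- gsub("\\s+", "", text)
  m <- regmatches(x, regexec("^([acgt])([0-9]+)-([acgt])([0-9]+)>del\\(([0-9]+)nt\\)$", x))[[1]]
  if (length(m)) {
    pos <- as.integer(m[3]); end <- as.integer(m[5])
    if (end - pos + 1L != as.integer(m[6]))
      stopf("range deletion length mismatch in '%s'", text)
    return(mutation_df("range_deletion", pos, end,
                       paste0(m[2], m[4]), ""))
  }
  m <- regmatches(x, regexec("^([acgt])([0-9]+)>del$", x))[[1]]
  if (length(m))
    return(mutation_df("deletion", as.integer(m[3]), ref = m[2], alt = ""))
  m <- regmatches(x, regexec("^([0-9]+)\\^([0-9]+)>ins\\^([acgt]+)$", x))[[1]]
  if (length(m)) {
    if (as.integer(m[3]) != as.integer(m[2]) + 1L)
      stopf("insertion positions not adjacent in '%s'", text)
    return(mutation_df("insertion", as.integer(m[2]), ref = "", alt = m[4]))
  }
  m <- regmatches(x, regexec("^([acgt])([0-9]+)>([acgt])$", x))[[1]]
  if (length(m))
    return(mutation_df("substitution", as.integer(m[3]), ref = m[2],
                       alt = m[4]))
  stopf("cannot parse mutation '%s'", text)
}

#' Parse several semicolon/comma separated mutation strings
#' @param text string such as `"a545>g; g686>a"`; empty string gives an
#'   empty mutation data.frame.
#' @return mutation data.frame.
#' @export
parse_mutations <- function(text) {
  text <- trimws(text)
  if (is.na(text) || text == "") return(mutation_df())
  parts <- trimws(strsplit(text, ";")[[1]])
  do.call(rbind, lapply(parts[parts != ""], parse_mutation))
}

# detect two rows editing the same reference position inconsistently
check_mutation_conflicts <- function(muts) {
  if (nrow(muts) < 2) return(invisible(muts))
  covered <- lapply(seq_len(nrow(muts)), function(i) {
    if (muts$kind[i] == "insertion") numeric(0) else muts$pos[i]:muts$end[i]
  })
  sig <- sprintf("%s:%d:%d:%s:%s", muts$kind, muts$pos, muts$end, muts$ref,
                 muts$alt)
  for (i in seq_len(nrow(muts) - 1)) {
    for (j in (i + 1):nrow(muts)) {
      if (length(intersect(covered[[i]], covered[[j]])) &&
          sig[i] != sig[j])
        stopf("contradictory mutations overlap at position %d",
              intersect(covered[[i]], covered[[j]])[1])
    }
  }
  invisible(muts)
}

#' Apply a mutation set to a reference sequence
#'
#' Events are applied from 3' to 5' so earlier coordinates stay valid.
#' Reference bases recorded in the mutation set are checked against the
#' sequence; a mismatch is an error.
#'
#' @param reference uppercase reference nucleotide string.
#' @param muts mutation data.frame (see [parse_mutation()]).
#' @return mutated sequence.
#' @export
apply_mutations <- function(reference, muts) {
  if (is.null(muts) || nrow(muts) == 0) return(reference)
  muts <- unique(muts[c("kind", "pos", "end", "ref", "alt")])
  check_mutation_conflicts(muts)
  if (any(muts$end > nchar(reference) | muts$pos < 1))
    stop("mutation position outside the reference", call. = FALSE)
  muts <- muts[order(-muts$pos), , drop = FALSE]
  seq <- reference
  for (i in seq_len(nrow(muts))) {
    m <- muts[i, ]
    if (m$kind == "substitution") {
      if (tolower(base_at(seq, m$pos)) != m$ref)
        stopf("ref base mismatch at %d: expected %s, found %s", m$pos,
              m$ref, tolower(base_at(seq, m$pos)))
      seq <- force_base(seq, m$pos, toupper(m$alt))
    } else if (m$kind == "deletion") {
      if (tolower(base_at(seq, m$pos)) != m$ref)
        stopf("ref base mismatch at %d: expected %s, found %s", m$pos,
              m$ref, tolower(base_at(seq, m$pos)))
      seq <- paste0(substr(seq, 1, m$pos - 1L),
                    substr(seq, m$pos + 1L, nchar(seq)))
    } else if (m$kind == "range_deletion") {
      first <- tolower(base_at(seq, m$pos))
      last <- tolower(base_at(seq, m$end))
      want <- c(substr(m$ref, 1, 1),
                substr(m$ref, nchar(m$ref), nchar(m$ref)))
      if (first != want[1] || last != want[2])
        stopf("ref base mismatch for range deletion %d-%d", m$pos, m$end)
      seq <- paste0(substr(seq, 1, m$pos - 1L),
                    substr(seq, m$end + 1L, nchar(seq)))
    } else if (m$kind == "insertion") {
      seq <- paste0(substr(seq, 1, m$pos), toupper(m$alt),
                    substr(seq, m$pos + 1L, nchar(seq)))
    } else stopf("unknown mutation kind '%s'", m$kind)
  }
  seq
}

#' Localize a mutation against the amplicon geometry
#'
#' Positions inside a primer map to the primer-end classes; positions between
#' the 3' core boundary and the reverse primer map to the reverse-primer
#' vicinity; everything else is classed by the insert feature it overlaps
#' (VH, linker, VL or vector flank).  A multi-nt deletion is localized by its
#' first deleted position.
#'
#' @param pos 1-based position on the forward-oriented insert.
#' @param geometry an [insert_geometry()].
#' @param domain_spans optional list with elements `vh`, `linker`, `vl`
#'   (1-based spans from a read annotation) overriding the geometry defaults.
#' @return localization label.
#' @export
localize_mutation <- function(pos, geometry, domain_spans = NULL) {
  g <- geometry
  if (pos < 1 || pos > g$total_len)
    stopf("position %d outside [1, %d]", pos, g$total_len)
  if (iv_contains(g$fwd_primer_span, pos)) return("fwd_primer_end")
  if (iv_contains(g$rev_primer_span, pos)) return("rev_primer_end")
  if (pos > g$core_span[["end"]] && pos < g$rev_primer_span[["start"]])
    return("rev_primer_vicinity")
  vh <- (domain_spans$vh %||% g$vh_span)
  lk <- (domain_spans$linker %||% g$linker_span)
  vl <- (domain_spans$vl %||% g$vl_span)
  if (iv_contains(vh, pos)) return("insert_VH")
  if (iv_contains(lk, pos)) return("insert_linker")
  if (iv_contains(vl, pos)) return("insert_VL")
  "insert_flank"
}

#' Describe the differences of a read relative to a reference insert
#'
#' Globally aligns the read against the reference and returns one row per
#' event with nomenclature, localization and a terminal flag (deletion runs
#' reaching into a primer span or the sequence ends, which are excluded from
#' provenance signatures).
#'
#' @param read forward-oriented read sequence.
#' @param reference reference insert sequence.
#' @param geometry an [insert_geometry()] for `reference`.
#' @param domain_spans optional domain spans for localization.
#' @return mutation data.frame with extra columns `nomenclature`,
#'   `localization`, `terminal`.
#' @export
describe_mutations <- function(read, reference, geometry,
                               domain_spans = NULL) {
  if (identical(read, reference)) {
    out <- mutation_df()
    out$nomenclature <- character(0)
    out$localization <- character(0)
    out$terminal <- logical(0)
    return(out)
  }
  aln <- align_global(read, reference)
  d <- aln_diffs(aln)                    # pattern = read, subject = reference
  # re-express relative to the reference: reference coords are subject coords
  muts <- mutation_df()
  for (i in seq_len(nrow(d))) {
    r <- d[i, ]
    if (r$kind == "substitution") {
      muts <- rbind(muts, mutation_df("substitution", r$spos,
                                      ref = r$alt, alt = r$ref))
    } else if (r$kind == "deletion") {
      # bases missing from the REFERENCE relative to the read = insertion
      muts <- rbind(muts, mutation_df("insertion", r$spos, ref = "",
                                      alt = r$ref))
    } else {
      # extra reference bases = deletion from the read
      n <- nchar(r$alt)
      kind <- if (n == 1) "deletion" else "range_deletion"
      muts <- rbind(muts, mutation_df(kind, r$spos,
                                      end = r$spos + n - 1L,
                                      ref = r$alt, alt = ""))
    }
  }
  annotate_mutation_table(muts, reference, geometry, domain_spans)
}

annotate_mutation_table <- function(muts, reference, geometry,
                                    domain_spans = NULL) {
  n <- nrow(muts)
  muts$nomenclature <- vapply(seq_len(n), function(i)
    format_mutation(muts$kind[i], muts$pos[i], muts$ref[i], muts$alt[i],
                    muts$end[i], reference = reference), character(1))
  muts$localization <- vapply(seq_len(n), function(i)
    localize_mutation(muts$pos[i], geometry, domain_spans), character(1))
  muts$terminal <- muts$kind %in% c("deletion", "range_deletion") &
    (muts$end >= geometry$rev_primer_span[["start"]] |
     muts$pos <= geometry$fwd_primer_span[["end"]])
  muts
}
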