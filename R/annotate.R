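# Dual-domain scFv annotation: locate up to two V domains per read, orient
# the read, assign closest germline V/(D)/J alleles, compute V-REGION
# identity, extract and translate the CDR3 junction, classify the domain
# layout and locate the inter-domain linker.
#
# Contract notes:
#  * every V allele is aligned locally against both orientations; the read is
#    re-oriented so the best hit is on the forward strand
#  * the second domain is the best non-overlapping hit with score >= min_score
#  * V-REGION identity = matches / alignment columns of an end-to-end
#    alignment of the V-REGION inside the read (gap columns count in the
#    denominator), reported to 2 decimals
#  * ties on v_call: highest identity, then longest aligned span, then
#    lexicographically smallest allele name

DEFAULT_MIN_V_SCORE <- 120
DEFAULT_MIN_J_SCORE <- 40

# batch scan: best V hit and orientation per read
scan_v_best <- function(reads, valleles) {
  n <- length(reads)
  best <- data.frame(score = rep(-Inf, n), allele = NA_character_,
                     strand = "forward", start = NA_integer_,
                     end = NA_integer_, stringsAsFactors = FALSE)
  fwd <- Biostrings::DNAStringSet(reads)
  rev <- Biostrings::reverseComplement(fwd)
  widths <- nchar(reads)
  for (k in seq_len(nrow(valleles))) {
    aseq <- valleles$sequence[k]
    aname <- valleles$allele_name[k]
    for (strand in c("forward", "reverse")) {
      subj <- if (strand == "forward") fwd else rev
      aln <- Biostrings::pairwiseAlignment(
        subj, Biostrings::DNAString(aseq), type = "local",
        substitutionMatrix = score_matrix(),
        gapOpening = GAP_OPEN, gapExtension = GAP_EXT)
      sc <- Biostrings::score(aln)
      st <- Biostrings::start(Biostrings::pattern(aln))
      en <- Biostrings::end(Biostrings::pattern(aln))
      upd <- sc > best$score |
        (sc == best$score & !is.na(best$allele) &
           (en - st > best$end - best$start |
              (en - st == best$end - best$start & aname < best$allele)))
      upd[is.na(upd)] <- FALSE
      best$score[upd] <- sc[upd]
      best$allele[upd] <- aname
      best$strand[upd] <- strand
      best$start[upd] <- st[upd]
      best$end[upd] <- en[upd]
    }
  }
  best
}

# best V hit within flanking segments (second-domain search)
scan_v_flanks <- function(flank_seqs, offsets, valleles, min_score) {
  n <- length(flank_seqs)
  best <- data.frame(score = rep(-Inf, n), allele = NA_character_,
                     start = NA_integer_, end = NA_integer_,
                     stringsAsFactors = FALSE)
  ok <- nchar(flank_seqs) >= 30L
  if (!any(ok)) return(best)
  set <- Biostrings::DNAStringSet(ifelse(ok, flank_seqs, "A"))
  for (k in seq_len(nrow(valleles))) {
    aln <- Biostrings::pairwiseAlignment(
      set, Biostrings::DNAString(valleles$sequence[k]), type = "local",
      substitutionMatrix = score_matrix(),
      gapOpening = GAP_OPEN, gapExtension = GAP_EXT)
    sc <- ifelse(ok, Biostrings::score(aln), -Inf)
    st <- Biostrings::start(Biostrings::pattern(aln))
    en <- Biostrings::end(Biostrings::pattern(aln))
    upd <- sc > best$score
    best$score[upd] <- sc[upd]
    best$allele[upd] <- valleles$allele_name[k]
    best$start[upd] <- st[upd] + offsets[upd]
    best$end[upd] <- en[upd] + offsets[upd]
  }
  best[best$score < min_score, c("allele", "start", "end")] <- NA
  best
}

#' Detect up to two V-domain hits in a read
#'
#' Aligns every V allele of the reference against both orientations of the
#' read, orients the read to put the best hit on the forward strand, then
#' searches the flanking segments for the best non-overlapping second hit
#' with score at least `min_score`.  An empty hit list is a valid result.
#'
#' @param read nucleotide string.
#' @param refdir germline reference directory.
#' @param min_score minimum local alignment score for a hit.
#' @return list with `strand` (orientation of the input that puts the best
#'   hit forward) and `hits`: data.frame of 0-2 rows (allele, score, start,
#'   end on the forward-oriented read), ordered 5' to 3'.
#' @export
detect_v_domains <- function(read, refdir, min_score = DEFAULT_MIN_V_SCORE) {
  res <- detect_v_domains_batch(stats::setNames(read, "r"), refdir, min_score)
  res[[1]]
}

detect_v_domains_batch <- function(reads, refdir,
                                   min_score = DEFAULT_MIN_V_SCORE) {
  valleles <- ref_alleles(refdir, "V")
  best <- scan_v_best(reads, valleles)
  oriented <- ifelse(best$strand == "reverse", revcomp_chr(reads), reads)
  left <- substr(oriented, 1L, pmax(best$start - 1L, 0L))
  right <- substr(oriented, best$end + 1L, nchar(oriented))
  b_left <- scan_v_flanks(left, rep(0L, length(reads)), valleles, min_score)
  b_right <- scan_v_flanks(right, best$end, valleles, min_score)
  lapply(seq_along(reads), function(i) {
    hits <- data.frame(allele = character(), score = numeric(),
                       start = integer(), end = integer(),
                       stringsAsFactors = FALSE)
    if (best$score[i] >= min_score)
      hits[1, ] <- list(best$allele[i], best$score[i], best$start[i],
                        best$end[i])
    cand <- list()
    if (!is.na(b_left$allele[i])) cand <- c(cand, list(b_left[i, ]))
    if (!is.na(b_right$allele[i])) cand <- c(cand, list(b_right[i, ]))
    second <- NULL
    if (length(cand))
      second <- cand[[which.max(vapply(cand, `[[`, numeric(1), "score"))]]
    if (nrow(hits) && !is.null(second))
      hits[2, ] <- list(second$allele, second$score, second$start, second$end)
    hits <- hits[order(hits$start), , drop = FALSE]
    rownames(hits) <- NULL
    list(strand = best$strand[i], oriented = oriented[[i]], hits = hits)
  })
}

#' Annotate one detected V domain
#'
#' Re-aligns the chosen V allele end-to-end inside the read window to obtain
#' V-REGION identity (gap columns in the denominator) and germline
#' mutations, aligns same-chain J alleles downstream of the V to call J,
#' maps both CDR3 anchors through the alignments, and extracts the junction.
#' If no J scores above `min_j_score` the domain is kept with an absent
#' `j_call` and `in_frame = FALSE`.
#'
#' @param read forward-oriented read.
#' @param hit one row of [detect_v_domains()] hits.
#' @param refdir germline reference directory.
#' @param min_j_score minimum J alignment score.
#' @return a `domain annotation` list.
#' @export
annotate_domain <- function(read, hit, refdir,
                            min_j_score = DEFAULT_MIN_J_SCORE) {
  al <- ref_allele(refdir, hit$allele)
  vr_seq <- substr(al$sequence, al$v_region_start, al$v_region_end)
  pad <- 40L
  win_start <- max(1L, hit$start - pad)
  win_end <- min(nchar(read), hit$end + pad)
  win <- substr(read, win_start, win_end)
  vala <- align_glocal(vr_seq, win)
  vparts <- aln_parts(vala, pad = "pattern")
  identity <- parts_identity_pct(vparts)
  vdiffs <- parts_diffs(vparts)
  mut <- mutation_df()
  if (nrow(vdiffs)) {
    mut <- data.frame(kind = vdiffs$kind,
                      pos = vdiffs$spos + win_start - 1L,
                      end = vdiffs$spos + win_start - 1L,
                      germline_pos = vdiffs$ppos + al$v_region_start - 1L,
                      ref = vdiffs$ref, alt = vdiffs$alt,
                      stringsAsFactors = FALSE)
  } else mut$germline_pos <- integer(0)
  v_read_start <- vparts$s_start + win_start - 1L
  v_read_end <- vparts$s_end + win_start - 1L
  anchor_pp <- al$anchor_pos - al$v_region_start + 1L
  cys_sp <- parts_map_pos(vparts, anchor_pp)
  cys_read <- if (is.na(cys_sp)) NA_integer_ else cys_sp + win_start - 1L

  # J assignment downstream of the V
  jdf <- ref_alleles(refdir, "J", al$chain_kind)
  j_call <- NA_character_
  j_anchor_end_read <- NA_integer_
  j_read_end <- NA_integer_
  jwin_start <- max(1L, v_read_end - 10L)
  jwin_end <- min(nchar(read), v_read_end + 130L)
  if (jwin_end - jwin_start + 1L >= 20L && nrow(jdf)) {
    jwin <- substr(read, jwin_start, jwin_end)
    jbest <- NULL
    jbest_score <- -Inf
    for (k in seq_len(nrow(jdf))) {
      ja <- align_glocal(jdf$sequence[k], jwin)
      sc <- Biostrings::score(ja)
      if (sc > jbest_score ||
          (sc == jbest_score && !is.null(jbest) &&
             jdf$allele_name[k] < jbest$name)) {
        jbest <- list(name = jdf$allele_name[k], aln = ja,
                      anchor = jdf$anchor_pos[k])
        jbest_score <- sc
      }
    }
    if (!is.null(jbest) && jbest_score >= min_j_score) {
      j_call <- jbest$name
      jparts <- aln_parts(jbest$aln, pad = "pattern")
      ae <- parts_map_pos(jparts, jbest$anchor + 2L)
      j_anchor_end_read <- if (is.na(ae)) NA_integer_ else
        ae + jwin_start - 1L
      j_read_end <- jparts$s_end + jwin_start - 1L
    }
  }

  junction_nt <- NA_character_
  junction_aa <- NA_character_
  in_frame <- FALSE
  if (!is.na(cys_read) && !is.na(j_anchor_end_read) &&
      j_anchor_end_read > cys_read) {
    junction_nt <- substr(read, cys_read, j_anchor_end_read)
    in_frame <- nchar(junction_nt) %% 3 == 0
    if (in_frame) junction_aa <- translate_nt(junction_nt)
  }

  domain_kind <- if (al$chain_kind == "heavy") "VH" else "VL"
  d_call <- "not assigned"
  if (domain_kind == "VH" && !is.na(junction_nt))
    d_call <- call_d_segment(junction_nt, refdir)

  list(domain_kind = domain_kind,
       read_span = iv(v_read_start, max(v_read_end, j_read_end, na.rm = TRUE)),
       v_span = iv(v_read_start, v_read_end),
       v_call = al$allele_name, j_call = j_call, d_call = d_call,
       v_identity_pct = identity,
       junction_span = if (!is.na(cys_read) && !is.na(j_anchor_end_read))
         iv(cys_read, j_anchor_end_read) else NULL,
       junction_nt = junction_nt, junction_aa = junction_aa,
       in_frame = in_frame, mutations = mut)
}

# longest exact substring (>= 5 nt) shared by the junction and a D allele
call_d_segment <- function(junction_nt, refdir, min_core = 5L) {
  dalleles <- ref_alleles(refdir, "D", "heavy")
  if (!nrow(dalleles)) return("not assigned")
  best_len <- min_core - 1L
  best <- "not assigned"
  jn <- toupper(junction_nt)
  for (k in order(dalleles$allele_name)) {
    dseq <- dalleles$sequence[k]
    for (len in seq(nchar(jn), min_core)) {
      found <- FALSE
      for (s in seq_len(nchar(jn) - len + 1L)) {
        if (grepl(substr(jn, s, s + len - 1L), dseq, fixed = TRUE)) {
          found <- TRUE
          break
        }
      }
      if (found) {
        if (len > best_len) {
          best_len <- len
          best <- dalleles$allele_name[k]
        }
        break
      }
    }
  }
  best
}

#' Classify the domain layout of an annotated read
#'
#' @param kinds character vector of detected domain kinds, 5' to 3'.
#' @return `"VH-VL"`, `"VL-VH"`, `"VH-VH"`, `"VL-VL"` or `"incomplete"`.
#' @export
classify_layout <- function(kinds) {
  if (length(kinds) < 2) return("incomplete")
  paste(kinds[1], kinds[2], sep = "-")
}

#' Locate the inter-domain linker
#'
#' Best edit-distance match of the linker inside the segment between the two
#' domain spans; absent (`NULL`) when the distance exceeds `max_mismatch`.
#'
#' @param read forward-oriented read.
#' @param between span (`iv`) separating the two domains.
#' @param linker_seq linker sequence.
#' @param max_mismatch maximum edit distance (default 5).
#' @return list(span, edit_distance) or `NULL`.
#' @export
locate_linker <- function(read, between, linker_seq = DEFAULT_LINKER,
                          max_mismatch = 5L) {
  if (between[["end"]] < between[["start"]]) return(NULL)
  seg <- substr(read, between[["start"]], between[["end"]])
  if (nchar(seg) < nchar(linker_seq) - max_mismatch) return(NULL)
  lv <- c("A", "C", "G", "T")
  mat <- matrix(-1, 4, 4, dimnames = list(lv, lv))
  diag(mat) <- 0
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(linker_seq), Biostrings::DNAString(seg),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1)
  dist <- -Biostrings::score(aln)
  if (dist > max_mismatch) return(NULL)
  list(span = iv(Biostrings::start(Biostrings::subject(aln)) +
                   between[["start"]] - 1L,
                 Biostrings::end(Biostrings::subject(aln)) +
                   between[["start"]] - 1L),
       edit_distance = dist)
}

#' Annotate a set of reads
#'
#' Full per-read annotation: domain detection, germline assignment, junction
#' extraction, layout classification and linker location.
#'
#' @param reads named character vector of read sequences.
#' @param refdir germline reference directory.
#' @param min_score minimum V hit score.
#' @param min_j_score minimum J hit score.
#' @param linker_seq linker used by [locate_linker()].
#' @param linker_max_mismatch maximum linker edit distance.
#' @return list of `scfv_annotation` objects (see [annotation_table()] for a
#'   tabular view).
#' @export
annotate_reads <- function(reads, refdir, min_score = DEFAULT_MIN_V_SCORE,
                           min_j_score = DEFAULT_MIN_J_SCORE,
                           linker_seq = DEFAULT_LINKER,
                           linker_max_mismatch = 5L) {
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  det <- detect_v_domains_batch(reads, refdir, min_score)
  out <- lapply(seq_along(reads), function(i) {
    d <- det[[i]]
    doms <- lapply(seq_len(nrow(d$hits)), function(r)
      annotate_domain(d$oriented, d$hits[r, ], refdir, min_j_score))
    kinds <- vapply(doms, `[[`, character(1), "domain_kind")
    layout <- classify_layout(kinds)
    linker <- NULL
    if (length(doms) == 2) {
      between <- iv(doms[[1]]$read_span[["end"]] + 1L,
                    doms[[2]]$read_span[["start"]] - 1L)
      linker <- locate_linker(d$oriented, between, linker_seq,
                              linker_max_mismatch)
    }
    structure(list(read_id = names(reads)[i], strand = d$strand,
                   layout = layout,
                   domain1 = if (length(doms) >= 1) doms[[1]] else NULL,
                   domain2 = if (length(doms) >= 2) doms[[2]] else NULL,
                   linker = linker,
                   is_scfv_candidate = length(doms) == 2),
              class = "scfv_annotation")
  })
  names(out) <- names(reads)
  out
}

#' Annotate a single read
#' @inheritParams annotate_reads
#' @param read a nucleotide string.
#' @param read_id identifier recorded in the annotation.
#' @return an `scfv_annotation`.
#' @export
annotate_read <- function(read, refdir, read_id = "read", ...) {
  annotate_reads(stats::setNames(read, read_id), refdir, ...)[[1]]
}

#' @export
print.scfv_annotation <- function(x, ...) {
  cat(sprintf("<scfv_annotation> %s [%s] layout %s\n", x$read_id, x$strand,
              x$layout))
  for (nm in c("domain1", "domain2")) {
    d <- x[[nm]]
    if (is.null(d)) next
    cat(sprintf("  %s %s %d-%d V=%s (%.2f%%) J=%s junction=%s in_frame=%s\n",
                nm, d$domain_kind, d$read_span[["start"]],
                d$read_span[["end"]], d$v_call, d$v_identity_pct,
                d$j_call %||% NA, d$junction_aa %||% NA, d$in_frame))
  }
  invisible(x)
}

#' Tabulate a list of annotations
#'
#' One row per read with the columns used by filtering, ranking and
#' reporting.
#'
#' @param anns list of `scfv_annotation` objects.
#' @param meta optional data.frame with `read_id`, `pcr_sample`, `smrt_cell`
#'   to merge in.
#' @return data.frame.
#' @export
annotation_table <- function(anns, meta = NULL) {
  fld <- function(a, nm, d, what, default) {
    dom <- a[[d]]
    if (is.null(dom)) return(default)
    v <- dom[[what]]
    if (is.null(v) || length(v) != 1 || is.na(v)) default else v
  }
  df <- data.frame(
    read_id = vapply(anns, `[[`, character(1), "read_id"),
    strand = vapply(anns, `[[`, character(1), "strand"),
    layout = vapply(anns, `[[`, character(1), "layout"),
    is_scfv_candidate = vapply(anns, `[[`, logical(1), "is_scfv_candidate"),
    d1_kind = vapply(anns, fld, character(1), d = "domain1",
                     what = "domain_kind", default = NA_character_),
    d1_v_call = vapply(anns, fld, character(1), d = "domain1",
                       what = "v_call", default = NA_character_),
    d1_j_call = vapply(anns, fld, character(1), d = "domain1",
                       what = "j_call", default = NA_character_),
    d1_d_call = vapply(anns, fld, character(1), d = "domain1",
                       what = "d_call", default = NA_character_),
    d1_identity = vapply(anns, fld, numeric(1), d = "domain1",
                         what = "v_identity_pct", default = NA_real_),
    d1_junction_aa = vapply(anns, fld, character(1), d = "domain1",
                            what = "junction_aa", default = NA_character_),
    d1_in_frame = vapply(anns, fld, logical(1), d = "domain1",
                         what = "in_frame", default = FALSE),
    d2_kind = vapply(anns, fld, character(1), d = "domain2",
                     what = "domain_kind", default = NA_character_),
    d2_v_call = vapply(anns, fld, character(1), d = "domain2",
                       what = "v_call", default = NA_character_),
    d2_j_call = vapply(anns, fld, character(1), d = "domain2",
                       what = "j_call", default = NA_character_),
    d2_d_call = vapply(anns, fld, character(1), d = "domain2",
                       what = "d_call", default = NA_character_),
    d2_identity = vapply(anns, fld, numeric(1), d = "domain2",
                         what = "v_identity_pct", default = NA_real_),
    d2_junction_aa = vapply(anns, fld, character(1), d = "domain2",
                            what = "junction_aa", default = NA_character_),
    d2_in_frame = vapply(anns, fld, logical(1), d = "domain2",
                         what = "in_frame", default = FALSE),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (!is.null(meta))
    df <- merge(df, meta, by = "read_id", sort = FALSE)
  df
}
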