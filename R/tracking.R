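# Clonotype association ranking and reference-clone tracking.
#
# A clonotype key is the pair of (V gene+allele, J gene+allele, junction AA)
# identities of the two domains, layout-aware: VH-VL and VL-VH built from the
# same domains are distinct keys.  A reference clone is tracked two ways:
# by clonotype characteristics, and by alignment against the reference scFv
# with a cap on total differing nucleotides.  Tracked reads are classified
# as identical over the full insert, identical over the core span only, or
# related; related reads are grouped by mutation signature and assigned a
# provenance category from their replication across PCR samples/SMRT cells.

#' Clonotype key of an annotated read
#'
#' @param ann_row one row of [annotation_table()] (or an `scfv_annotation`).
#' @return single string key.
#' @export
clonotype_key <- function(ann_row) {
  if (inherits(ann_row, "scfv_annotation")) {
    g <- function(d, w) ann_row[[d]][[w]] %||% NA_character_
    vals <- c(ann_row$layout,
              g("domain1", "v_call"), g("domain1", "j_call"),
              g("domain1", "junction_aa"),
              g("domain2", "v_call"), g("domain2", "j_call"),
              g("domain2", "junction_aa"))
  } else {
    need <- c("layout", "d1_v_call", "d1_j_call", "d1_junction_aa",
              "d2_v_call", "d2_j_call", "d2_junction_aa")
    miss <- setdiff(need, names(ann_row))
    if (length(miss))
      stopf("clonotype_key needs column(s): %s", paste(miss, collapse = ", "))
    vals <- unlist(ann_row[need], use.names = FALSE)
  }
  if (length(vals) != 7 || any(is.na(vals)))
    stop("untyped domain", call. = FALSE)
  paste(vals, collapse = "|")
}

clonotype_keys <- function(ann) {
  vapply(seq_len(nrow(ann)), function(i) clonotype_key(ann[i, ]),
         character(1))
}

#' Rank VH-VL associations by read count
#'
#' Only expected-layout reads (VH-VL, VL-VH) enter the ranking; ties share
#' the minimum rank; frequency = count / total expected-layout reads.
#'
#' @param ann annotation data.frame of filtered-in reads.
#' @return data.frame (key, n_reads, frequency, rank) in rank order.
#' @export
rank_associations <- function(ann) {
  ann <- ann[ann$layout %in% c("VH-VL", "VL-VH"), , drop = FALSE]
  if (nrow(ann) == 0)
    return(data.frame(key = character(), n_reads = integer(),
                      frequency = numeric(), rank = integer(),
                      stringsAsFactors = FALSE))
  keys <- clonotype_keys(ann)
  tab <- sort(table(keys), decreasing = TRUE)
  out <- data.frame(key = names(tab), n_reads = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$frequency <- out$n_reads / sum(out$n_reads)
  out$rank <- rank(-out$n_reads, ties.method = "min")
  out[order(out$rank, out$key), , drop = FALSE]
}

#' Track a reference clone by clonotype characteristics
#'
#' @param reference_key key from [clonotype_key()].
#' @param ann annotation data.frame of filtered-in reads.
#' @return character vector of read ids whose key equals the reference key.
#' @export
track_by_characteristics <- function(reference_key, ann) {
  if (nrow(ann) == 0) return(character(0))
  keys <- vapply(seq_len(nrow(ann)), function(i)
    tryCatch(clonotype_key(ann[i, ]), error = function(e) NA_character_),
    character(1))
  ann$read_id[!is.na(keys) & keys == reference_key]
}

#' Track a reference clone by alignment
#'
#' Aligns the reference scFv (both orientations) inside each read.  A read is
#' retained iff the alignment covers the full reference and the number of
#' differing nucleotides (mismatches plus every inserted and deleted nt) is
#' at most `max_diffs`.
#'
#' @param reference_seq reference scFv sequence (>= 100 nt).
#' @param reads named character vector.
#' @param max_diffs maximum differing nucleotides (default 20).
#' @return data.frame (read_id, strand, diff_count, identity_pct, ref_span)
#'   for retained reads.
#' @export
track_by_alignment <- function(reference_seq, reads, max_diffs = 20L) {
  if (nchar(reference_seq) < 100)
    stop("reference must be at least 100 nt", call. = FALSE)
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  out <- list()
  for (i in seq_along(reads)) {
    best <- NULL
    perfect <- 2 * nchar(reference_seq)    # match score x reference length
    for (strand in c("forward", "reverse")) {
      r <- if (strand == "forward") reads[[i]] else revcomp_chr(reads[[i]])
      aln <- align_glocal(reference_seq, r)  # reference end-to-end in read
      sc <- Biostrings::score(aln)
      if (is.null(best) || sc > best$score)
        best <- list(score = sc, aln = aln, strand = strand)
      if (sc >= perfect) break
    }
    dc <- aln_diff_count(best$aln)
    if (dc <= max_diffs) {
      sspan <- c(Biostrings::start(Biostrings::subject(best$aln)),
                 Biostrings::end(Biostrings::subject(best$aln)))
      out[[length(out) + 1L]] <- data.frame(
        read_id = names(reads)[i], strand = best$strand, diff_count = dc,
        identity_pct = aln_identity_pct(best$aln),
        read_start = sspan[1], read_end = sspan[2],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(read_id = character(), strand = character(),
                      diff_count = integer(), identity_pct = numeric(),
                      read_start = integer(), read_end = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Classify a tracked read against the full reference insert
#'
#' `identical_full`: the read equals the reference insert over its whole
#' length.  `identical_core`: the read matches the reference over the core
#' span and every difference lies outside the core.  Otherwise `related`.
#' The read is re-oriented to whichever strand matches the reference better.
#'
#' @param read read sequence (either orientation).
#' @param reference_insert full reference insert.
#' @param geometry [insert_geometry()] of the reference.
#' @return one of `"identical_full"`, `"identical_core"`, `"related"`.
#' @export
classify_identity <- function(read, reference_insert, geometry) {
  fwd <- read
  rev <- revcomp_chr(read)
  if (identical(fwd, reference_insert) || identical(rev, reference_insert))
    return("identical_full")
  pick <- function(s) {
    aln <- align_global(s, reference_insert)
    list(aln = aln, score = Biostrings::score(aln))
  }
  a_f <- pick(fwd); a_r <- pick(rev)
  best <- if (a_f$score >= a_r$score) a_f else a_r
  muts <- aln_to_reference_muts(best$aln)
  if (all(muts_outside_core(muts, geometry$core_span))) "identical_core"
  else "related"
}

muts_outside_core <- function(muts, core) {
  vapply(seq_len(nrow(muts)), function(i) {
    m <- muts[i, ]
    if (m$kind == "insertion")       # inserted between pos and pos+1
      m$pos < core[["start"]] || m$pos >= core[["end"]]
    else
      m$end < core[["start"]] || m$pos > core[["end"]]
  }, logical(1))
}

# reference-frame mutation table from a read-vs-reference global alignment
# (pattern = read, subject = reference)
aln_to_reference_muts <- function(aln) {
  d <- aln_diffs(aln)
  muts <- mutation_df()
  for (i in seq_len(nrow(d))) {
    r <- d[i, ]
    if (r$kind == "substitution")
      muts <- rbind(muts, mutation_df("substitution", r$spos, ref = r$alt,
                                      alt = r$ref))
    else if (r$kind == "deletion")   # read bases absent from the reference
      muts <- rbind(muts, mutation_df("insertion", r$spos, ref = "",
                                      alt = r$ref))
    else {                           # reference bases absent from the read
      n <- nchar(r$alt)
      muts <- rbind(muts, mutation_df(
        if (n == 1) "deletion" else "range_deletion", r$spos,
        end = r$spos + n - 1L, ref = r$alt, alt = ""))
    }
  }
  muts
}

#' Full tracking report for a reference clone
#'
#' Runs both tracking approaches, classifies every tracked read, recomputes
#' its mutation list against the reference insert (with nomenclature and
#' localization), and assigns provenance categories to the related reads.
#'
#' @param reads named character vector of filtered-in reads.
#' @param meta data.frame (read_id, pcr_sample, smrt_cell).
#' @param reference_insert full reference insert sequence.
#' @param reference_scfv reference scFv (sub)sequence used by the alignment
#'   tracker; defaults to the scfv span of `geometry` applied to
#'   `reference_insert`.
#' @param geometry [insert_geometry()] of the reference insert.
#' @param ann optional annotation data.frame of the same reads; when given
#'   (together with `reference_key`) the characteristics tracker contributes
#'   candidates.
#' @param reference_key optional [clonotype_key()] of the reference.
#' @param max_diffs alignment tracker cap (default 20).
#' @param category_a_rule `"samples"` (category A needs >= 2 distinct PCR
#'   samples) or `"cells"` (>= 2 distinct SMRT cells).
#' @return list of class `scfv_tracking_report`: `per_read` (read_id, class,
#'   n_mutations, mutations, pcr_sample, smrt_cell, tracked_by), `groups`
#'   (signature groups with category labels), `mutation_table` (one row per
#'   mutation per read), and the class tallies `n_identical_full`,
#'   `n_identical_core`, `n_related`.
#' @export
track_reference_clone <- function(reads, meta, reference_insert, geometry,
                                  reference_scfv = NULL, ann = NULL,
                                  reference_key = NULL, max_diffs = 20L,
                                  category_a_rule = c("samples", "cells")) {
  category_a_rule <- match.arg(category_a_rule)
  if (is.null(reference_scfv))
    reference_scfv <- substr(reference_insert,
                             geometry$scfv_span[["start"]],
                             geometry$scfv_span[["end"]])
  by_aln <- track_by_alignment(reference_scfv, reads, max_diffs)
  ids_aln <- by_aln$read_id
  ids_chr <- character(0)
  if (!is.null(ann) && !is.null(reference_key))
    ids_chr <- track_by_characteristics(reference_key, ann)
  ids <- union(ids_aln, ids_chr)
  ids <- ids[match(intersect(names(reads), ids), ids)]  # input order
  per_read <- list()
  mut_rows <- list()
  for (id in ids) {
    read <- reads[[id]]
    # orient the read against the reference; reuse one global alignment for
    # orientation, identity class and mutation description
    if (identical(read, reference_insert) ||
        identical(revcomp_chr(read), reference_insert)) {
      cls <- "identical_full"
      muts <- describe_mutations(reference_insert, reference_insert,
                                 geometry)
    } else {
      rc <- revcomp_chr(read)
      a_f <- align_global(read, reference_insert)
      a_r <- align_global(rc, reference_insert)
      best <- if (Biostrings::score(a_f) >= Biostrings::score(a_r)) a_f
              else a_r
      muts <- annotate_mutation_table(aln_to_reference_muts(best),
                                      reference_insert, geometry)
      cls <- if (nrow(muts) == 0) "identical_full"
             else if (all(muts_outside_core(muts, geometry$core_span)))
               "identical_core"
             else "related"
    }
    if (nrow(muts)) {
      muts$read_id <- id
      mut_rows[[length(mut_rows) + 1L]] <- muts
    }
    per_read[[length(per_read) + 1L]] <- data.frame(
      read_id = id, class = cls, n_mutations = nrow(muts),
      mutations = paste(muts$nomenclature, collapse = "; "),
      tracked_by = paste(c(if (id %in% ids_aln) "alignment",
                           if (id %in% ids_chr) "characteristics"),
                         collapse = "+"),
      stringsAsFactors = FALSE)
  }
  per_read <- if (length(per_read)) do.call(rbind, per_read) else
    data.frame(read_id = character(), class = character(),
               n_mutations = integer(), mutations = character(),
               tracked_by = character(), stringsAsFactors = FALSE)
  per_read <- merge(per_read, meta, by = "read_id", sort = FALSE,
                    all.x = TRUE)
  mutation_table <- if (length(mut_rows)) do.call(rbind, mut_rows) else NULL
  related <- per_read[per_read$class == "related", , drop = FALSE]
  prov <- classify_provenance(related, mutation_table, geometry,
                              category_a_rule)
  per_read$provenance <- rep(NA_character_, nrow(per_read))
  per_read$category <- rep(NA_character_, nrow(per_read))
  if (nrow(related)) {
    m <- match(per_read$read_id, prov$per_read$read_id)
    per_read$provenance <- prov$per_read$provenance[m]
    per_read$category <- prov$per_read$category[m]
  }
  structure(list(
    per_read = per_read, groups = prov$groups,
    mutation_table = mutation_table,
    n_identical_full = sum(per_read$class == "identical_full"),
    n_identical_core = sum(per_read$class == "identical_core"),
    n_related = sum(per_read$class == "related"),
    reference_len = nchar(reference_insert),
    core_len = iv_width(geometry$core_span)),
    class = "scfv_tracking_report")
}

#' @export
print.scfv_tracking_report <- function(x, ...) {
  cat(sprintf(paste0("<scfv_tracking_report> %d tracked reads: ",
                     "%d identical (full %d nt), %d identical (core %d nt), ",
                     "%d related\n"),
              nrow(x$per_read), x$n_identical_full, x$reference_len,
              x$n_identical_core, x$core_len, x$n_related))
  if (!is.null(x$groups) && nrow(x$groups))
    print(x$groups[c("signature", "n_reads", "n_samples", "category",
                     "provenance")])
  invisible(x)
}

# signature of one read: its non-excluded mutations, canonically ordered.
# Excluded: primer-end and primer-vicinity localizations, and terminal
# deletion runs (flagged by describe_mutations).
mutation_signature <- function(muts) {
  keep <- !(muts$localization %in%
              c("fwd_primer_end", "rev_primer_end", "rev_primer_vicinity")) &
    !muts$terminal
  m <- muts[keep, , drop = FALSE]
  if (!nrow(m)) return(list(sig = "", has_indel = FALSE))
  m <- m[order(m$pos, m$kind, m$alt), ]
  list(sig = paste(m$nomenclature, collapse = ";"),
       has_indel = any(m$kind != "substitution"))
}

#' Assign provenance categories to related reads
#'
#' Reads sharing a mutation signature (their non-excluded mutations: primer
#' and primer-vicinity events and terminal deletions are ignored) form a
#' group.  A group replicated in at least two distinct PCR samples (rule
#' `"samples"`; or SMRT cells under rule `"cells"`) is category A and its
#' mutations are attributed to the library.  All other groups are category
#' B: singletons whose signature contains an indel are flagged putative
#' sequencing errors, substitution-only singletons putative PCR or library
#' variants, and non-replicated multi-read groups stay unassigned.
#'
#' @param related per-read data.frame (read_id, pcr_sample, smrt_cell).
#' @param mutation_table mutation rows for those reads (from
#'   [describe_mutations()], with `read_id`).
#' @param geometry [insert_geometry()].
#' @param category_a_rule `"samples"` or `"cells"`.
#' @return list: `groups` data.frame (signature, read_ids, n_reads,
#'   n_samples, n_cells, category, provenance), `per_read` data.frame.
#' @export
classify_provenance <- function(related, mutation_table, geometry,
                                category_a_rule = c("samples", "cells")) {
  category_a_rule <- match.arg(category_a_rule)
  empty <- list(groups = data.frame(signature = character(),
                                    read_ids = character(),
                                    n_reads = integer(),
                                    n_samples = integer(),
                                    n_cells = integer(),
                                    category = character(),
                                    provenance = character(),
                                    stringsAsFactors = FALSE),
                per_read = data.frame(read_id = character(),
                                      category = character(),
                                      provenance = character(),
                                      stringsAsFactors = FALSE))
  if (is.null(related) || nrow(related) == 0) return(empty)
  sigs <- vapply(related$read_id, function(id) {
    m <- mutation_table[mutation_table$read_id == id, , drop = FALSE]
    mutation_signature(m)$sig
  }, character(1))
  has_indel <- vapply(related$read_id, function(id) {
    m <- mutation_table[mutation_table$read_id == id, , drop = FALSE]
    mutation_signature(m)$has_indel
  }, logical(1))
  groups <- list()
  per_read <- list()
  for (sig in unique(sigs)) {
    sel <- sigs == sig
    n_samples <- length(unique(related$pcr_sample[sel]))
    n_cells <- length(unique(related$smrt_cell[sel]))
    replicated <- sum(sel) >= 2 &&
      (if (category_a_rule == "samples") n_samples >= 2 else n_cells >= 2)
    if (replicated) {
      category <- "A"
      provenance <- "library"
    } else {
      category <- "B"
      provenance <- if (sum(sel) == 1) {
        if (any(has_indel[sel])) "putative_sequencing_error"
        else "putative_pcr_or_library"
      } else "unassigned"
    }
    groups[[length(groups) + 1L]] <- data.frame(
      signature = sig,
      read_ids = paste(related$read_id[sel], collapse = ","),
      n_reads = sum(sel), n_samples = n_samples, n_cells = n_cells,
      category = category, provenance = provenance, stringsAsFactors = FALSE)
    per_read[[length(per_read) + 1L]] <- data.frame(
      read_id = related$read_id[sel], category = category,
      provenance = provenance, stringsAsFactors = FALSE)
  }
  list(groups = do.call(rbind, groups), per_read = do.call(rbind, per_read))
}
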