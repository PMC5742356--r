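# Repertoire-style filtering of annotated scFv reads and per-batch summary
# statistics.
#
# A candidate read (two V regions found) passes the filter iff BOTH domains
# have V-REGION germline identity strictly above the threshold (default 85%)
# AND both junctions are in frame.  Percentages are rounded half away from
# zero to 2 decimals, matching printed summary tables.

#' Filter annotated scFv candidates
#'
#' @param ann data.frame from [annotation_table()]; only rows with
#'   `is_scfv_candidate = TRUE` are assessed (non-candidates are excluded
#'   upstream and may not be passed here).
#' @param identity_threshold_pct identity threshold; strict `>` comparison.
#' @param require_in_frame require both junctions in frame.
#' @return `ann` with logical column `passed` and character column
#'   `fail_reasons` (semicolon-separated, one entry per violated criterion).
#' @export
filter_scfv <- function(ann, identity_threshold_pct = 85,
                        require_in_frame = TRUE) {
  if (any(!ann$is_scfv_candidate))
    stop("filter_scfv expects only scFv candidates (two V regions)",
         call. = FALSE)
  reasons <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    r <- character(0)
    for (d in 1:2) {
      idc <- ann[[sprintf("d%d_identity", d)]][i]
      frc <- ann[[sprintf("d%d_in_frame", d)]][i]
      if (is.na(idc) || idc <= identity_threshold_pct)
        r <- c(r, sprintf("domain%d identity <= %s", d,
                          format(identity_threshold_pct)))
      if (require_in_frame && !isTRUE(frc))
        r <- c(r, sprintf("domain%d junction out of frame", d))
    }
    reasons[[i]] <- r
  }
  ann$passed <- lengths(reasons) == 0
  ann$fail_reasons <- vapply(reasons, paste, character(1), collapse = "; ")
  ann
}

#' Per-batch summary of analyzed / candidate / filtered-in reads
#'
#' Accepts either per-read rows (columns `pcr_sample`, `smrt_cell`,
#' `is_scfv_candidate`, `passed`) or pre-aggregated counts (columns
#' `pcr_sample`, `smrt_cell`, `n_analyzed`, `n_candidates`,
#' `n_filtered_in`).  Emits one row per (PCR sample, SMRT cell) plus a
#' grand-total row, with the three coverage percentages:
#' candidates/analyzed, filtered-in/candidates, filtered-in/analyzed.
#'
#' @param x data.frame in either shape.
#' @return data.frame of batch summaries; the total row has
#'   `pcr_sample = "Total"`.
#' @export
summarize_batch <- function(x) {
  if (nrow(x) == 0) stop("empty group", call. = FALSE)
  if (!all(c("n_analyzed", "n_candidates", "n_filtered_in") %in% names(x))) {
    need <- c("pcr_sample", "smrt_cell", "is_scfv_candidate", "passed")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stopf("summarize_batch needs columns: %s", paste(miss, collapse = ", "))
    agg <- stats::aggregate(
      cbind(n_analyzed = rep(1L, nrow(x)),
            n_candidates = as.integer(x$is_scfv_candidate),
            n_filtered_in = as.integer(x$is_scfv_candidate & x$passed)) ~
        pcr_sample + smrt_cell, data = x, FUN = sum)
    x <- agg[order(agg$pcr_sample, agg$smrt_cell), ]
  }
  if (any(x$n_filtered_in > x$n_candidates | x$n_candidates > x$n_analyzed))
    stop("counts must satisfy n_filtered_in <= n_candidates <= n_analyzed",
         call. = FALSE)
  total <- data.frame(pcr_sample = "Total", smrt_cell = NA_integer_,
                      n_analyzed = sum(x$n_analyzed),
                      n_candidates = sum(x$n_candidates),
                      n_filtered_in = sum(x$n_filtered_in),
                      stringsAsFactors = FALSE)
  out <- rbind(x[c("pcr_sample", "smrt_cell", "n_analyzed", "n_candidates",
                   "n_filtered_in")], total)
  out$pct_candidates <- pct2(out$n_candidates, out$n_analyzed)
  out$pct_scfv_of_filtered <- pct2(out$n_filtered_in, out$n_candidates)
  out$pct_scfv_of_analyzed <- pct2(out$n_filtered_in, out$n_analyzed)
  rownames(out) <- NULL
  out
}

#' Tally domain layouts among passed reads
#'
#' @param ann annotation data.frame (typically the `passed` subset).
#' @details Counts always sum to `nrow(ann)`.
#' @return list with `counts` (named integer vector over observed layouts),
#'   `n_expected` (VH-VL + VL-VH) and `n_off_type`.
#' @export
tally_layouts <- function(ann) {
  counts <- table(factor(ann$layout,
                         levels = union(LAYOUTS, unique(ann$layout))))
  counts <- stats::setNames(as.integer(counts), names(counts))
  n_exp <- sum(counts[c("VH-VL", "VL-VH")], na.rm = TRUE)
  list(counts = counts, n_expected = n_exp,
       n_off_type = sum(counts) - n_exp)
}
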