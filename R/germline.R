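# Germline V/(D)/J reference directory: loading, validation, writing, and a
# built-in seeded fixture so the whole pipeline runs without downloads.
#
# A directory is a plain data.frame of alleles plus a release tag.  Coordinates
# are 1-based inclusive throughout.  The V-REGION span delimits the portion of
# a V allele used as the denominator of germline identity; `anchor_pos` is the
# first nucleotide of the 2nd-CYS codon (V segments) or of the J-TRP/J-PHE
# codon (J segments).

ALLELE_COLS <- c("allele_name", "gene_name", "segment_kind", "chain_kind",
                 "sequence", "v_region_start", "v_region_end", "anchor_pos")

#' Construct a validated germline reference directory
#'
#' @param alleles data.frame with columns `allele_name`, `gene_name`,
#'   `segment_kind` (`"V"`, `"D"` or `"J"`), `chain_kind` (`"heavy"`,
#'   `"kappa"` or `"lambda"`), `sequence` (uppercase ACGT),
#'   `v_region_start`/`v_region_end` (NA for non-V segments) and `anchor_pos`
#'   (NA for D segments).
#' @param release_tag free-text label recorded in outputs.
#' @return an object of class `scfv_refdir`.
#' @export
reference_directory <- function(alleles, release_tag = "custom") {
  alleles <- as.data.frame(alleles, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ALLELE_COLS, names(alleles))
  if (length(missing_cols))
    stopf("reference metadata lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  alleles <- alleles[ALLELE_COLS]
  validate_alleles(alleles)
  for (ck in unique(alleles$chain_kind)) {
    sub <- alleles[alleles$chain_kind == ck, ]
    if (!any(sub$segment_kind == "V") || !any(sub$segment_kind == "J"))
      stopf("chain '%s' needs at least one V and one J allele", ck)
  }
  structure(list(alleles = alleles, release_tag = release_tag),
            class = "scfv_refdir")
}

validate_alleles <- function(df) {
  if (nrow(df) == 0) stop("no alleles", call. = FALSE)
  dup <- df$allele_name[duplicated(df$allele_name)]
  if (length(dup))
    stopf("duplicate allele_name: %s", paste(unique(dup), collapse = ", "))
  bad_seg <- setdiff(unique(df$segment_kind), c("V", "D", "J"))
  if (length(bad_seg)) stopf("invalid segment_kind: %s", bad_seg[1])
  bad_chain <- setdiff(unique(df$chain_kind), c("heavy", "kappa", "lambda"))
  if (length(bad_chain)) stopf("invalid chain_kind: %s", bad_chain[1])
  for (i in seq_len(nrow(df))) {
    a <- df[i, ]
    if (is.na(a$sequence) || nchar(a$sequence) == 0)
      stopf("allele %s: empty sequence", a$allele_name)
    bad <- regexpr("[^ACGT]", a$sequence)
    if (bad > 0)
      stopf("allele %s: invalid character '%s' at position %d",
            a$allele_name, substr(a$sequence, bad, bad), bad)
    n <- nchar(a$sequence)
    if (a$segment_kind == "V") {
      if (is.na(a$v_region_start) || is.na(a$v_region_end) ||
          a$v_region_start < 1 || a$v_region_end > n ||
          a$v_region_start > a$v_region_end)
        stopf("allele %s: invalid V-REGION span", a$allele_name)
      if (is.na(a$anchor_pos) || a$anchor_pos < a$v_region_start ||
          a$anchor_pos + 2 > a$v_region_end)
        stopf("allele %s: anchor outside V-REGION", a$allele_name)
    }
    if (a$segment_kind == "J") {
      if (is.na(a$anchor_pos) || a$anchor_pos < 1 || a$anchor_pos + 2 > n)
        stopf("allele %s: anchor outside sequence", a$allele_name)
    }
  }
  invisible(df)
}

#' @export
print.scfv_refdir <- function(x, ...) {
  tab <- table(x$alleles$chain_kind, x$alleles$segment_kind)
  cat(sprintf("<scfv_refdir> %d alleles (release %s)\n",
              nrow(x$alleles), x$release_tag))
  print(tab)
  invisible(x)
}

#' Subset alleles of a reference directory
#'
#' @param refdir an `scfv_refdir`.
#' @param segment_kind,chain_kind optional filters.
#' @return data.frame of alleles.
#' @export
ref_alleles <- function(refdir, segment_kind = NULL, chain_kind = NULL) {
  df <- refdir$alleles
  if (!is.null(segment_kind)) df <- df[df$segment_kind %in% segment_kind, ]
  if (!is.null(chain_kind)) df <- df[df$chain_kind %in% chain_kind, ]
  df
}

ref_allele <- function(refdir, allele_name) {
  df <- refdir$alleles[refdir$alleles$allele_name == allele_name, ]
  if (nrow(df) != 1) stopf("unknown allele '%s'", allele_name)
  df
}

#' Load a germline reference from FASTA plus a metadata sidecar
#'
#' The FASTA holds ungapped nucleotide allele sequences; the tab-separated
#' sidecar supplies, per `allele_name` (the FASTA header word), `gene_name`,
#' `segment_kind`, `chain_kind`, `v_region_start`, `v_region_end` and
#' `anchor_pos`.
#'
#' @param fasta_path path to the allele FASTA.
#' @param metadata_path path to the TSV sidecar.
#' @param release_tag label for the loaded directory.
#' @return an `scfv_refdir`.
#' @export
load_reference <- function(fasta_path, metadata_path,
                           release_tag = basename(fasta_path)) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) stop("no alleles", call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  missing <- setdiff(ids, meta$allele_name)
  if (length(missing))
    stopf("no metadata row for FASTA record(s): %s",
          paste(missing, collapse = ", "))
  if (anyDuplicated(ids))
    stopf("duplicate allele_name: %s", ids[duplicated(ids)][1])
  meta <- meta[match(ids, meta$allele_name), ]
  meta$sequence <- as.character(seqs)
  reference_directory(meta, release_tag = release_tag)
}

#' Write a reference directory back to FASTA + TSV
#'
#' Inverse of [load_reference()]: `load_reference()` on the written pair
#' reproduces the allele set exactly.
#'
#' @param refdir an `scfv_refdir`.
#' @param fasta_path,metadata_path output paths.
#' @return invisibly, the two paths.
#' @export
write_reference <- function(refdir, fasta_path, metadata_path) {
  df <- refdir$alleles
  seqs <- Biostrings::DNAStringSet(df$sequence)
  names(seqs) <- df$allele_name
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80)
  utils::write.table(df[setdiff(ALLELE_COLS, "sequence")], metadata_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta_path, metadata_path))
}

# Geometry constants of the built-in fixture alleles.  V alleles are 300 nt
# with the 2nd-CYS codon (TGT) at 292-294 and 6 germline CDR3 nt after it;
# heavy J alleles are 48 nt with J-TRP (TGG) at 10-12, light J alleles 50 nt
# with J-PHE (TTC) at 12-14.  (anchor_pos - 1) is divisible by 3 so the
# V-REGION reading frame runs through the junction.
FIXTURE_V_LEN <- 300L
FIXTURE_V_ANCHOR <- 292L
FIXTURE_JH_LEN <- 48L
FIXTURE_JH_ANCHOR <- 10L
FIXTURE_JL_LEN <- 50L
FIXTURE_JL_ANCHOR <- 12L

#' Generate the built-in miniature germline reference
#'
#' Deterministic for a fixed seed.  Emits 3 heavy, 2 kappa and 2 lambda V
#' alleles, 2 J alleles per chain and 2 heavy D alleles.  Sequences are
#' random, but every V allele carries a TGT (Cys) anchor codon and every J
#' allele a TGG (Trp, heavy) or TTC (Phe, light) anchor codon at the
#' annotated position.  This is a structural stand-in for a curated germline
#' directory, not a biological reference.
#'
#' @param seed integer seed.
#' @return an `scfv_refdir`.
#' @export
build_fixture_reference <- function(seed = 1L) {
  set.seed(seed)
  rows <- list()
  add <- function(gene, allele, seg, chain, seq, vs = NA, ve = NA, ap = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      allele_name = allele, gene_name = gene, segment_kind = seg,
      chain_kind = chain, sequence = seq,
      v_region_start = vs, v_region_end = ve, anchor_pos = ap,
      stringsAsFactors = FALSE)
  }
  make_v <- function() {
    s <- rand_dna(FIXTURE_V_LEN)
    substr(s, FIXTURE_V_ANCHOR, FIXTURE_V_ANCHOR + 2) <- "TGT"
    s
  }
  make_j <- function(len, anchor, codon) {
    s <- rand_dna(len)
    substr(s, anchor, anchor + 2) <- codon
    s
  }
  vh_genes <- c("IGHV1-10", "IGHV2-20", "IGHV3-30")
  for (g in vh_genes)
    add(g, paste0(g, "*01"), "V", "heavy", make_v(),
        1L, FIXTURE_V_LEN, FIXTURE_V_ANCHOR)
  for (g in c("IGKV1-5", "IGKV3-15"))
    add(g, paste0(g, "*01"), "V", "kappa", make_v(),
        1L, FIXTURE_V_LEN, FIXTURE_V_ANCHOR)
  for (g in c("IGLV1-40", "IGLV2-14"))
    add(g, paste0(g, "*01"), "V", "lambda", make_v(),
        1L, FIXTURE_V_LEN, FIXTURE_V_ANCHOR)
  for (g in c("IGHJ4", "IGHJ6"))
    add(g, paste0(g, "*01"), "J", "heavy",
        make_j(FIXTURE_JH_LEN, FIXTURE_JH_ANCHOR, "TGG"),
        ap = FIXTURE_JH_ANCHOR)
  for (g in c("IGKJ1", "IGKJ2"))
    add(g, paste0(g, "*01"), "J", "kappa",
        make_j(FIXTURE_JL_LEN, FIXTURE_JL_ANCHOR, "TTC"),
        ap = FIXTURE_JL_ANCHOR)
  for (g in c("IGLJ2", "IGLJ3"))
    add(g, paste0(g, "*01"), "J", "lambda",
        make_j(FIXTURE_JL_LEN, FIXTURE_JL_ANCHOR, "TTC"),
        ap = FIXTURE_JL_ANCHOR)
  for (g in c("IGHD2-2", "IGHD3-10"))
    add(g, paste0(g, "*01"), "D", "heavy", rand_dna(20L))
  reference_directory(do.call(rbind, rows),
                      release_tag = sprintf("fixture-%d", seed))
}
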