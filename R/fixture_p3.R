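# Reconstruction of the 85-read reference-clone tracking fixture.
#
# The real tracked clone ("P3") is a patented 767-bp scFv whose sequence is
# not public; this module builds a SYNTHETIC stand-in with identical
# geometry: a 977-nt insert (23-nt forward primer, 74-nt 5' flank, 351-nt
# VH, 53-nt linker, 363-nt VL, 93-nt 3' flank, 20-nt reverse-primer
# complement; core span 3-941) assembled from the built-in germline fixture.
# Bases at every position named by a printed mutation are forced to the
# published reference base, and deletion/insertion contexts are
# disambiguated (no equal neighbour bases) so that alignment-based mutation
# calling recovers the printed coordinates.  The 85 tracked reads are then
# reconstructed by applying the printed per-read mutation lists, with the
# printed PCR-sample and SMRT-cell provenance.

# identical reads: read_no, smrt_cell, class ("full" = identical over
# 977 nt, "core" = identical over the 939-nt core only)
p3_identical_reads <- function() {
  full <- list(`1` = c(1, 2, 3, 4, 6, 8), `2` = c(10, 30),
               `3` = c(16, 17, 19), `4` = c(32, 33), `5` = 36,
               `6` = c(37, 38, 39), `7` = c(20, 41, 44, 45, 46, 47, 48),
               `8` = c(49, 50, 51, 52, 53, 54), `9` = c(56, 57, 59, 60),
               `10` = c(63, 65, 66), `11` = 68, `12` = c(70, 72, 73),
               `13` = c(75, 76), `14` = c(21, 80, 83),
               `15` = c(23, 24, 25, 26, 27, 28, 29))
  core <- list(`2` = c(11, 12, 13), `3` = 15, `5` = 35, `10` = 64,
               `12` = 71)
  build <- function(lst, cls) do.call(rbind, lapply(names(lst), function(cell)
    data.frame(read_no = lst[[cell]], smrt_cell = as.integer(cell),
               class_truth = cls, stringsAsFactors = FALSE)))
  rbind(build(full, "full"), build(core, "core"))
}

# mutations of the seven core-identical reads (primer ends / 3' vicinity)
p3_core_mutations <- function() {
  c(`13` = "g2>del",
    `11` = "t975>del; a977>del",
    `15` = "c956>t",
    `12` = "a942>del",
    `35` = "a942>del",
    `71` = "a942>del",
    `64` = "a942>del; t975>del")
}

# the 25 related reads: read_no, smrt_cell, mutation list
p3_related_reads <- function() {
  pink <- "a545>g; g686>a; a757>g; c838>g"
  green <- "c741>t; g837>a; c838>g; g843>t"
  blue <- "c720>t; t744>c"
  df <- rbind(
    data.frame(read_no = c(7, 18, 43, 67, 69, 79),
               smrt_cell = c(1, 3, 7, 11, 12, 14), mutations = pink),
    data.frame(read_no = 58, smrt_cell = 9,
               mutations = paste0(pink, "; a886-a977>del (92 nt)")),
    data.frame(read_no = 61, smrt_cell = 9, mutations = green),
    data.frame(read_no = 74, smrt_cell = 13,
               mutations = paste0(green, "; a977>del")),
    data.frame(read_no = c(5, 14, 31, 34, 42, 82),
               smrt_cell = c(1, 2, 4, 4, 7, 14), mutations = blue),
    data.frame(read_no = 85, smrt_cell = 4, mutations = "c242>del"),
    data.frame(read_no = 40, smrt_cell = 6, mutations = "g600>del"),
    data.frame(read_no = 77, smrt_cell = 13, mutations = "g495>a"),
    data.frame(read_no = 22, smrt_cell = 14, mutations = "t624>c"),
    data.frame(read_no = 55, smrt_cell = 9, mutations = "a627>g"),
    data.frame(read_no = 62, smrt_cell = 10, mutations = "g736>a"),
    data.frame(read_no = 78, smrt_cell = 13,
               mutations = "t599>g; t975-a977>del (3 nt)"),
    data.frame(read_no = 81, smrt_cell = 14,
               mutations = "g2>del; a715>g; c959-a977>del (19 nt)"),
    data.frame(read_no = 84, smrt_cell = 5,
               mutations = "209^210>ins^a; 762^763>ins^t"),
    data.frame(read_no = 9, smrt_cell = 2,
               mutations = "c322>t; 658^659>ins^cc; c659>t; t660>a"))
  df$class_truth <- "related"
  df
}

cell_to_sample <- function(cell) {
  sprintf("s%d", findInterval(cell, c(1, 4, 8, 12)))
}

#' The 85-read tracking fixture table
#'
#' @return data.frame (read_no, pcr_sample, smrt_cell, class_truth,
#'   mutations) for all 85 tracked reads; `mutations` holds the
#'   semicolon-separated nomenclature applied to the reference (empty for
#'   the fully identical reads).
#' @export
p3_read_table <- function() {
  ident <- p3_identical_reads()
  core_muts <- p3_core_mutations()
  ident$mutations <- ifelse(ident$class_truth == "core",
                            unname(core_muts[as.character(ident$read_no)]),
                            "")
  rel <- p3_related_reads()
  tab <- rbind(ident[c("read_no", "smrt_cell", "class_truth", "mutations")],
               rel[c("read_no", "smrt_cell", "class_truth", "mutations")])
  tab$pcr_sample <- cell_to_sample(tab$smrt_cell)
  tab <- tab[order(tab$read_no), c("read_no", "pcr_sample", "smrt_cell",
                                   "class_truth", "mutations")]
  rownames(tab) <- NULL
  tab
}

# positions whose reference base is pinned by a printed mutation, plus
# disambiguation constraints around indel sites (neighbour must differ from
# the deleted/inserted base so alignment left-normalization reproduces the
# printed coordinate)
p3_base_constraints <- function() {
  list(
    exact = c(`242` = "C", `322` = "C", `545` = "A", `599` = "T",
              `600` = "G", `624` = "T", `627` = "A", `659` = "C",
              `660` = "T", `686` = "G", `715` = "A", `720` = "C",
              `736` = "G", `741` = "C", `744` = "T", `757` = "A",
              `837` = "G", `838` = "C", `843` = "G", `886` = "A",
              `942` = "A", `956` = "C"),
    forbidden = c(`209` = "A", `210` = "A", `241` = "C", `243` = "C",
                  `601` = "G", `658` = "C", `762` = "T", `763` = "T",
                  `941` = "A", `943` = "A"),
    # fixed by primer or linker sequence; checked, not forced
    asserted = c(`2` = "G", `495` = "G", `959` = "C", `975` = "T",
                 `977` = "A"))
}

#' Build the synthetic reference insert for tracking reconstructions
#'
#' @param seed integer seed; also seeds [build_fixture_reference()].
#' @return list: `refdir`, `insert` (977 nt), `scfv` (767 nt), `geometry`,
#'   `vh`/`vl` germline choices (v_call, j_call).
#' @export
build_p3_reference <- function(seed = 1L) {
  refdir <- build_fixture_reference(seed)  # seeds the RNG stream
  flank5 <- rand_dna(FIVE_FLANK_LEN)
  flank3 <- rand_dna(THREE_FLANK_LEN)
  vh_v <- ref_allele(refdir, "IGHV1-10*01")
  vh_j <- ref_allele(refdir, "IGHJ4*01")
  vl_v <- ref_allele(refdir, "IGKV1-5*01")
  vl_j <- ref_allele(refdir, "IGKJ1*01")
  vh <- paste0(vh_v$sequence, rand_dna(3L), vh_j$sequence)    # 351 nt
  vl <- paste0(vl_v$sequence, rand_dna(13L), vl_j$sequence)   # 363 nt
  insert <- paste0(FWD_PRIMER, flank5, vh, DEFAULT_LINKER, vl, flank3,
                   revcomp_chr(REV_PRIMER))
  cons <- p3_base_constraints()
  for (p in names(cons$exact))
    insert <- force_base(insert, as.integer(p), cons$exact[[p]])
  for (p in names(cons$forbidden)) {
    pos <- as.integer(p)
    if (base_at(insert, pos) == cons$forbidden[[p]]) {
      repl <- setdiff(c("A", "C", "G", "T"),
                      c(cons$forbidden[[p]],
                        base_at(insert, pos - 1L), base_at(insert, pos + 1L)))
      insert <- force_base(insert, pos, repl[1])
    }
  }
  for (p in names(cons$asserted))
    stopifnot(base_at(insert, as.integer(p)) == cons$asserted[[p]])
  geometry <- insert_geometry(vh_len = 351L, vl_len = 363L)
  stopifnot(nchar(insert) == geometry$total_len)
  list(refdir = refdir, insert = insert,
       scfv = substr(insert, geometry$scfv_span[["start"]],
                     geometry$scfv_span[["end"]]),
       geometry = geometry,
       vh = list(v_call = vh_v$allele_name, j_call = vh_j$allele_name),
       vl = list(v_call = vl_v$allele_name, j_call = vl_j$allele_name))
}

# library with no frequency-drawn clones (spike-only use)
empty_library <- function() {
  structure(list(
    clones = data.frame(clone_id = character(), sequence = character(),
                        layout = character(), d1_v_call = character(),
                        d1_j_call = character(),
                        d1_junction_aa = character(),
                        d2_v_call = character(), d2_j_call = character(),
                        d2_junction_aa = character(), frequency = numeric(),
                        stringsAsFactors = FALSE),
    clone_details = list(), flanks = NULL, config = NULL,
    forced_plan = NULL), class = "scfv_library")
}

#' Reconstruct the 85-read tracking fixture
#'
#' Builds the synthetic reference insert, spikes it (and the 22 printed
#' mutation signatures) into an empty library, and emits the 85 reads
#' error-free through the read simulator, so each read carries its printed
#' PCR-sample/SMRT-cell provenance and a random orientation.
#'
#' @param seed integer seed (reference construction and orientations).
#' @return list: everything from [build_p3_reference()] plus `reads` (named
#'   character vector, names `P3r01`..`P3r85`), `meta` (read_id, pcr_sample,
#'   smrt_cell), `table` (the [p3_read_table()] with read ids).
#' @export
p3_fixture <- function(seed = 1L) {
  ref <- build_p3_reference(seed)
  tab <- p3_read_table()
  variants <- lapply(seq_len(nrow(tab)), function(i)
    list(mutations = tab$mutations[i], pcr_sample = tab$pcr_sample[i],
         smrt_cell = tab$smrt_cell[i], copies = 1L))
  lib <- spike_reference_clone(empty_library(), ref$insert, variants,
                               reference_id = "P3")
  sim <- simulate_reads(lib, read_error_model(per_base_error = 0),
                        n_reads = 0L, seed = seed)
  stopifnot(nrow(sim$truth) == nrow(tab))
  ids <- sprintf("P3r%02d", tab$read_no)
  reads <- stats::setNames(unname(sim$reads), ids)
  tab$read_id <- ids
  meta <- data.frame(read_id = ids, pcr_sample = tab$pcr_sample,
                     smrt_cell = tab$smrt_cell, stringsAsFactors = FALSE)
  c(ref, list(reads = reads, meta = meta, table = tab))
}
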