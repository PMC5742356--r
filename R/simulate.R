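# Seeded scFv library and read simulator.
#
# The simulated world: a phagemid combinatorial library of scFv clones, each
# clone a recombined VH and VL joined by a fixed 53-nt linker and embedded in
# constant vector flanks between the two PCR primers.  Panning enrichment is
# modelled as a Zipf abundance profile over clones; reads are consensus-level
# (residual per-base error around 1e-3) and drawn independently per
# (PCR sample, SMRT cell) batch, in forward or reverse orientation with equal
# probability.  Deletions are boosted within a few nt of the amplicon ends to
# emulate primer-terminal artifacts.

LAYOUTS <- c("VH-VL", "VL-VH", "VH-VH", "VL-VL")

#' Configuration of the library simulator
#'
#' Defaults state the simulated world: 60/39.5% expected layouts with rare
#' VH-VH / VL-VL assemblies, Zipf(1.5) clone abundances (a few dominant
#' clones over a long tail, as panning enrichment produces), light-chain
#' mutation load exceeding the heavy-chain load, and junction insertion sizes
#' that keep the junction in frame for most clones.
#'
#' @param n_clones number of distinct clones.
#' @param zipf_exponent exponent of the clone abundance law.
#' @param layout_mix named probabilities over `VH-VL`, `VL-VH`, `VH-VH`,
#'   `VL-VL`; must sum to 1.
#' @param vh_mutation_rate,vl_mutation_rate expected substitutions per domain
#'   per clone (Poisson), relative to the recombined germline.
#' @param p_out_of_frame probability that a clone's junction is shifted out
#'   of frame (library junk that the in-frame filter removes).
#' @param linker_seq 53-nt linker; must contain EcoRI (GAATTC) and XbaI
#'   (TCTAGA) sites.
#' @param fwd_primer,rev_primer PCR primers.
#' @param seed integer seed used by [simulate_library()].
#' @return list of class `scfv_sim_config`.
#' @export
library_sim_config <- function(n_clones = 200L,
                               zipf_exponent = 1.5,
                               layout_mix = c("VH-VL" = 0.60, "VL-VH" = 0.395,
                                              "VH-VH" = 0.0005,
                                              "VL-VL" = 0.0045),
                               vh_mutation_rate = 0.5,
                               vl_mutation_rate = 2,
                               p_out_of_frame = 0.02,
                               linker_seq = DEFAULT_LINKER,
                               fwd_primer = FWD_PRIMER,
                               rev_primer = REV_PRIMER,
                               seed = 1L) {
  stopifnot(n_clones >= 1, zipf_exponent > 0,
            vh_mutation_rate >= 0, vl_mutation_rate >= 0,
            p_out_of_frame >= 0, p_out_of_frame <= 1)
  if (!setequal(names(layout_mix), LAYOUTS) ||
      abs(sum(layout_mix) - 1) > 1e-8)
    stop("layout_mix must be named over the four layouts and sum to 1",
         call. = FALSE)
  if (!grepl("GAATTC", linker_seq) || !grepl("TCTAGA", linker_seq))
    stop("linker must contain EcoRI (GAATTC) and XbaI (TCTAGA) sites",
         call. = FALSE)
  structure(list(n_clones = as.integer(n_clones),
                 zipf_exponent = zipf_exponent,
                 layout_mix = layout_mix[LAYOUTS],
                 vh_mutation_rate = vh_mutation_rate,
                 vl_mutation_rate = vl_mutation_rate,
                 p_out_of_frame = p_out_of_frame,
                 linker_seq = linker_seq, fwd_primer = fwd_primer,
                 rev_primer = rev_primer, seed = as.integer(seed)),
            class = "scfv_sim_config")
}

#' Residual consensus-read error model
#'
#' @param per_base_error probability of an error at each position (default
#'   1e-3, the residual error of >=99.9%-accurate consensus reads).
#' @param sub_frac,ins_frac,del_frac mixture over error kinds; must sum to 1.
#' @param primer_end_del_boost multiplier on the deletion probability within
#'   `end_window` nt of either amplicon end.
#' @param end_window width of the boosted terminal window, nt.
#' @return list of class `scfv_error_model`.
#' @export
read_error_model <- function(per_base_error = 0.001, sub_frac = 0.4,
                             ins_frac = 0.25, del_frac = 0.35,
                             primer_end_del_boost = 20, end_window = 3L) {
  stopifnot(per_base_error >= 0, per_base_error <= 1,
            sub_frac >= 0, ins_frac >= 0, del_frac >= 0,
            primer_end_del_boost >= 1, end_window >= 0)
  if (abs(sub_frac + ins_frac + del_frac - 1) > 1e-8)
    stop("error-kind mixture must sum to 1", call. = FALSE)
  structure(list(per_base_error = per_base_error, sub_frac = sub_frac,
                 ins_frac = ins_frac, del_frac = del_frac,
                 primer_end_del_boost = primer_end_del_boost,
                 end_window = as.integer(end_window)),
            class = "scfv_error_model")
}

# Recombine one V domain: germline V + junction N-insert + germline J, plus
# Poisson library substitutions.  Junction sizes are drawn so the junction
# length is a multiple of 3 unless the clone is flagged out of frame.
build_domain <- function(refdir, kind, config) {
  chain <- if (kind == "VH") "heavy" else sample(c("kappa", "lambda"), 1)
  vs <- ref_alleles(refdir, "V", chain)
  js <- ref_alleles(refdir, "J", chain)
  v <- vs[sample(nrow(vs), 1), ]
  j <- js[sample(nrow(js), 1), ]
  v_tail <- nchar(v$sequence) - v$anchor_pos + 1L   # Cys codon to V end
  j_head <- j$anchor_pos + 2L                       # J start to anchor end
  # n options keeping (v_tail + n + j_head) %% 3 == 0
  resid <- (3L - (v_tail + j_head) %% 3L) %% 3L
  n_opts <- resid + 3L * (0:4)
  n_ins <- sample(n_opts, 1)
  out_of_frame <- stats::runif(1) < config$p_out_of_frame
  if (out_of_frame) n_ins <- n_ins + 1L
  n_seq <- if (n_ins > 0) rand_dna(n_ins) else ""
  seq <- paste0(v$sequence, n_seq, j$sequence)
  rate <- if (kind == "VH") config$vh_mutation_rate else config$vl_mutation_rate
  n_mut <- stats::rpois(1, rate)
  mut_pos <- integer(0)
  if (n_mut > 0) {
    # library mutations target the V-REGION, sparing the anchor codon
    cand <- setdiff(seq_len(v$anchor_pos - 1L),
                    integer(0))
    mut_pos <- sort(sample(cand, min(n_mut, length(cand))))
    for (p in mut_pos) {
      cur <- base_at(seq, p)
      seq <- force_base(seq, p, sample(setdiff(c("A", "C", "G", "T"), cur), 1))
    }
  }
  junction_start <- v$anchor_pos
  junction_end <- nchar(v$sequence) + n_ins + j_head
  junction_nt <- substr(seq, junction_start, junction_end)
  in_frame <- nchar(junction_nt) %% 3 == 0
  list(kind = kind, chain = chain, sequence = seq,
       v_call = v$allele_name, j_call = j$allele_name,
       junction_nt = junction_nt,
       junction_aa = if (in_frame) translate_nt(junction_nt) else NA_character_,
       in_frame = in_frame, n_mutations = length(mut_pos))
}

#' Simulate one scFv clone consensus
#'
#' Uses the current RNG state (seed via `set.seed()` upstream or through
#' [simulate_library()]).
#'
#' @param refdir germline reference directory.
#' @param config a [library_sim_config()].
#' @param layout one of `"VH-VL"`, `"VL-VH"`, `"VH-VH"`, `"VL-VL"`; drawn
#'   from `config$layout_mix` when `NULL`.
#' @param flanks list with `five` and `three` vector flank sequences; random
#'   flanks are drawn when `NULL` (a library shares one vector, so
#'   [simulate_library()] passes fixed flanks).
#' @return list with the clone `sequence`, its `geometry`, `layout` and the
#'   two domain descriptors (`domain1`, `domain2`).
#' @export
simulate_clone <- function(refdir, config, layout = NULL, flanks = NULL) {
  if (is.null(layout))
    layout <- sample(LAYOUTS, 1, prob = config$layout_mix)
  layout <- match.arg(layout, LAYOUTS)
  kinds <- strsplit(layout, "-")[[1]]
  needed <- if (any(kinds == "VH")) "heavy" else character(0)
  if (any(kinds == "VL") &&
      nrow(ref_alleles(refdir, "V", c("kappa", "lambda"))) == 0)
    stopf("layout %s impossible: no light-chain V alleles", layout)
  if (any(kinds == "VH") && nrow(ref_alleles(refdir, "V", "heavy")) == 0)
    stopf("layout %s impossible: no heavy-chain V alleles", layout)
  if (is.null(flanks))
    flanks <- list(five = rand_dna(FIVE_FLANK_LEN),
                   three = rand_dna(THREE_FLANK_LEN))
  d1 <- build_domain(refdir, kinds[1], config)
  d2 <- build_domain(refdir, kinds[2], config)
  seq <- paste0(config$fwd_primer, flanks$five, d1$sequence,
                config$linker_seq, d2$sequence, flanks$three,
                revcomp_chr(config$rev_primer))
  geom <- insert_geometry(vh_len = nchar(d1$sequence),
                          vl_len = nchar(d2$sequence),
                          linker_len = nchar(config$linker_seq),
                          fwd_primer_len = nchar(config$fwd_primer),
                          rev_primer_len = nchar(config$rev_primer),
                          five_flank_len = nchar(flanks$five),
                          three_flank_len = nchar(flanks$three))
  list(sequence = seq, geometry = geom, layout = layout,
       domain1 = d1, domain2 = d2)
}

#' Simulate a full scFv library with Zipf abundances
#'
#' @param refdir germline reference directory.
#' @param config a [library_sim_config()]; `config$seed` seeds the RNG.
#' @return list of class `scfv_library`: `clones` (data.frame with clone_id,
#'   sequence, layout, per-domain calls and junctions, frequency),
#'   `clone_details` (list of [simulate_clone()] results), `flanks`,
#'   `config`.
#' @export
simulate_library <- function(refdir, config = library_sim_config()) {
  set.seed(config$seed)
  flanks <- list(five = rand_dna(FIVE_FLANK_LEN),
                 three = rand_dna(THREE_FLANK_LEN))
  details <- lapply(seq_len(config$n_clones), function(i)
    simulate_clone(refdir, config, flanks = flanks))
  freq <- seq_len(config$n_clones)^(-config$zipf_exponent)
  freq <- freq / sum(freq)
  clones <- data.frame(
    clone_id = sprintf("clone%04d", seq_len(config$n_clones)),
    sequence = vapply(details, `[[`, character(1), "sequence"),
    layout = vapply(details, `[[`, character(1), "layout"),
    d1_v_call = vapply(details, function(d) d$domain1$v_call, character(1)),
    d1_j_call = vapply(details, function(d) d$domain1$j_call, character(1)),
    d1_junction_aa = vapply(details, function(d)
      d$domain1$junction_aa %||% NA_character_, character(1)),
    d2_v_call = vapply(details, function(d) d$domain2$v_call, character(1)),
    d2_j_call = vapply(details, function(d) d$domain2$j_call, character(1)),
    d2_junction_aa = vapply(details, function(d)
      d$domain2$junction_aa %||% NA_character_, character(1)),
    frequency = freq,
    stringsAsFactors = FALSE)
  structure(list(clones = clones, clone_details = details, flanks = flanks,
                 config = config, forced_plan = NULL),
            class = "scfv_library")
}

#' Spike a reference clone and controlled variants into a library
#'
#' Adds a designated reference clone plus variant clones carrying exact
#' mutation signatures, together with a forced emission plan (per PCR sample
#' and SMRT cell copy counts) honoured by [simulate_reads()].  Used to
#' reconstruct replicate-tracking fixtures with known ground truth.
#'
#' @param lib an `scfv_library` (or a bare list with a `clones` data.frame).
#' @param reference_seq full insert sequence of the reference clone.
#' @param variants list of entries `list(mutations = <mutation data.frame or
#'   nomenclature string>, pcr_sample = , smrt_cell = , copies = )`; an entry
#'   with an empty mutation set emits the reference clone itself.
#' @param reference_id clone id stem for the spiked clones.
#' @return the library with spiked clones appended (`frequency` 0: they are
#'   emitted only through the forced plan) and `forced_plan` filled.
#' @export
spike_reference_clone <- function(lib, reference_seq, variants = list(),
                                  reference_id = "REF") {
  clones <- lib$clones
  plan <- list()
  new_rows <- list()
  sig_ids <- character(0)
  for (v in variants) {
    muts <- v$mutations
    if (is.character(muts)) muts <- parse_mutations(muts)
    if (is.null(muts)) muts <- mutation_df()
    check_mutation_conflicts(muts)
    sig <- paste0("sig:", if (nrow(muts))
      paste(sprintf("%s:%d:%s:%s", muts$kind, muts$pos, muts$ref, muts$alt),
            collapse = ";") else "")
    if (!sig %in% names(sig_ids)) {
      id <- if (sig == "sig:") reference_id else
        sprintf("%s.v%02d", reference_id,
                sum(names(sig_ids) != "sig:") + 1L)
      sig_ids[sig] <- id
      new_rows[[id]] <- data.frame(
        clone_id = id, sequence = apply_mutations(reference_seq, muts),
        layout = NA_character_, d1_v_call = NA_character_,
        d1_j_call = NA_character_, d1_junction_aa = NA_character_,
        d2_v_call = NA_character_, d2_j_call = NA_character_,
        d2_junction_aa = NA_character_, frequency = 0,
        stringsAsFactors = FALSE)
    }
    plan[[length(plan) + 1L]] <- data.frame(
      clone_id = sig_ids[[sig]], pcr_sample = v$pcr_sample,
      smrt_cell = as.integer(v$smrt_cell),
      copies = as.integer(v$copies %||% 1L), stringsAsFactors = FALSE)
  }
  if (length(new_rows)) {
    add <- do.call(rbind, new_rows)
    add <- add[!add$clone_id %in% clones$clone_id, , drop = FALSE]
    lib$clones <- rbind(clones, add)
  }
  lib$forced_plan <- if (length(plan)) do.call(rbind, plan) else NULL
  if (!is.null(lib$forced_plan)) rownames(lib$forced_plan) <- NULL
  lib
}

# apply the residual error model to one sequence; returns the mutated
# sequence and the event table (positions on the error-free sequence)
apply_read_errors <- function(seq, model) {
  n <- nchar(seq)
  if (model$per_base_error == 0)
    return(list(sequence = seq, errors = mutation_df()))
  near_end <- rep(FALSE, n)
  if (model$end_window > 0) {
    w <- min(model$end_window, n)
    near_end[c(seq_len(w), (n - w + 1L):n)] <- TRUE
  }
  p_sub <- rep(model$per_base_error * model$sub_frac, n)
  p_ins <- rep(model$per_base_error * model$ins_frac, n)
  p_del <- model$per_base_error * model$del_frac *
    ifelse(near_end, model$primer_end_del_boost, 1)
  u <- stats::runif(n)
  kind <- rep(NA_character_, n)
  kind[u < p_sub] <- "substitution"
  kind[u >= p_sub & u < p_sub + p_ins] <- "insertion"
  kind[u >= p_sub + p_ins & u < p_sub + p_ins + p_del] <- "deletion"
  hits <- which(!is.na(kind))
  if (!length(hits)) return(list(sequence = seq, errors = mutation_df()))
  muts <- mutation_df()
  for (p in hits) {
    cur <- tolower(base_at(seq, p))
    muts <- rbind(muts, switch(kind[p],
      substitution = mutation_df("substitution", p, ref = cur,
        alt = sample(setdiff(c("a", "c", "g", "t"), cur), 1)),
      insertion = mutation_df("insertion", p, ref = "",
        alt = sample(c("a", "c", "g", "t"), 1)),
      deletion = mutation_df("deletion", p, ref = cur, alt = "")))
  }
  list(sequence = apply_mutations(seq, muts), errors = muts)
}

#' Simulate consensus reads from a library
#'
#' Reads are drawn i.i.d. from the clone frequencies independently within
#' each (PCR sample, SMRT cell) batch; spiked clones from the library's
#' forced plan are emitted with their exact copy counts in their designated
#' batches.  Each read is reverse-complemented with probability 1/2 and then
#' passed through the error model.  Deterministic for a fixed seed.
#'
#' @param lib an `scfv_library`.
#' @param error_model a [read_error_model()].
#' @param n_reads number of frequency-drawn reads (forced-plan copies come on
#'   top); must be > 0 unless a forced plan is present.
#' @param cells_per_sample integer vector: number of SMRT cells per PCR
#'   sample (default `c(3, 4, 4, 4)`, i.e. 15 cells over 4 samples).
#' @param seed integer seed.
#' @return list: `reads` (named character vector, forward or reverse
#'   orientation as emitted), `truth` (data.frame with read_id, clone_id,
#'   pcr_sample, smrt_cell, layout, strand, n_errors, errors, forced).
#' @export
simulate_reads <- function(lib, error_model = read_error_model(),
                           n_reads = 1000L,
                           cells_per_sample = c(3L, 4L, 4L, 4L),
                           seed = 1L) {
  if (n_reads <= 0 && is.null(lib$forced_plan))
    stop("n_reads must be positive", call. = FALSE)
  set.seed(seed)
  cells <- data.frame(
    pcr_sample = rep(sprintf("s%d", seq_along(cells_per_sample)),
                     cells_per_sample),
    smrt_cell = seq_len(sum(cells_per_sample)), stringsAsFactors = FALSE)
  clones <- lib$clones
  layout_of <- stats::setNames(clones$layout, clones$clone_id)
  draws <- list()
  if (n_reads > 0) {
    idx <- sample(nrow(clones), n_reads, replace = TRUE,
                  prob = clones$frequency)
    batch <- sample(nrow(cells), n_reads, replace = TRUE)
    draws[[1]] <- data.frame(clone_id = clones$clone_id[idx],
                             pcr_sample = cells$pcr_sample[batch],
                             smrt_cell = cells$smrt_cell[batch],
                             forced = FALSE, stringsAsFactors = FALSE)
  }
  if (!is.null(lib$forced_plan)) {
    fp <- lib$forced_plan
    draws[[length(draws) + 1L]] <- data.frame(
      clone_id = rep(fp$clone_id, fp$copies),
      pcr_sample = rep(fp$pcr_sample, fp$copies),
      smrt_cell = rep(fp$smrt_cell, fp$copies),
      forced = TRUE, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, draws)
  n <- nrow(tab)
  tab$read_id <- sprintf("read%06d", seq_len(n))
  tab$strand <- ifelse(stats::runif(n) < 0.5, "forward", "reverse")
  seqs <- character(n)
  n_err <- integer(n)
  err_str <- character(n)
  seq_of <- stats::setNames(clones$sequence, clones$clone_id)
  for (i in seq_len(n)) {
    res <- apply_read_errors(seq_of[[tab$clone_id[i]]], error_model)
    s <- res$sequence
    if (tab$strand[i] == "reverse") s <- revcomp_chr(s)
    seqs[i] <- s
    n_err[i] <- nrow(res$errors)
    err_str[i] <- if (nrow(res$errors))
      paste(vapply(seq_len(nrow(res$errors)), function(k)
        format_mutation(res$errors$kind[k], res$errors$pos[k],
                        res$errors$ref[k], res$errors$alt[k],
                        res$errors$end[k]), character(1)), collapse = ";")
      else ""
  }
  tab$layout <- unname(layout_of[tab$clone_id])
  tab$n_errors <- n_err
  tab$errors <- err_str
  names(seqs) <- tab$read_id
  list(reads = seqs,
       truth = tab[c("read_id", "clone_id", "pcr_sample", "smrt_cell",
                     "layout", "strand", "n_errors", "errors", "forced")])
}

#' Write simulated reads as FASTQ (Sanger Phred+33, constant quality)
#'
#' @param reads named character vector of sequences.
#' @param path output path.
#' @param quality constant per-base Phred score (default 30).
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path, quality = 30L) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    paste(rep(rawToChar(as.raw(quality + 33L)), n), collapse = ""),
    character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read amplicon sequences from FASTA or FASTQ
#'
#' Qualities are ignored: consensus accuracy filtering happens upstream in
#' the sequencing pipeline.
#'
#' @param path input file; format decided by extension (`.fq`/`.fastq` vs
#'   anything else = FASTA).
#' @return named character vector of sequences.
#' @export
read_amplicons <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq"
         else "fasta"
  x <- if (fmt == "fastq") Biostrings::readDNAStringSet(path, format = "fastq")
       else Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
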