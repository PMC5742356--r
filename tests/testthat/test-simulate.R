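test_that("simulator configuration is validated", {
  expect_error(library_sim_config(layout_mix = c("VH-VL" = 1, "VL-VH" = 0.5,
                                                 "VH-VH" = 0, "VL-VL" = 0)),
               "layout_mix")
  expect_error(library_sim_config(linker_seq = strrep("A", 53)), "EcoRI")
  expect_error(read_error_model(sub_frac = 1, ins_frac = 1, del_frac = 1),
               "sum to 1")
  expect_error(simulate_reads(fix_sim()$lib, n_reads = 0), "positive")
})

test_that("library simulation is seed-deterministic", {
  rd <- fix_refdir()
  cfg <- library_sim_config(n_clones = 6, seed = 21)
  l1 <- simulate_library(rd, cfg)
  l2 <- simulate_library(rd, cfg)
  expect_identical(l1$clones, l2$clones)
  l3 <- simulate_library(rd, library_sim_config(n_clones = 6, seed = 22))
  expect_false(all(l1$clones$sequence == l3$clones$sequence))
  expect_equal(sum(l1$clones$frequency), 1)
  # zipf: frequencies strictly decreasing
  expect_true(all(diff(l1$clones$frequency) < 0))
})

test_that("zero mutation rates reproduce germline domains verbatim", {
  rd <- fix_refdir()
  cfg <- library_sim_config(n_clones = 4, seed = 31, vh_mutation_rate = 0,
                            vl_mutation_rate = 0, p_out_of_frame = 0)
  lib <- simulate_library(rd, cfg)
  for (d in lib$clone_details) {
    for (dom in list(d$domain1, d$domain2)) {
      v <- ref_alleles(rd)[ref_alleles(rd)$allele_name == dom$v_call, ]
      j <- ref_alleles(rd)[ref_alleles(rd)$allele_name == dom$j_call, ]
      expect_identical(substr(dom$sequence, 1, nchar(v$sequence)),
                       v$sequence)
      expect_identical(substr(dom$sequence,
                              nchar(dom$sequence) - nchar(j$sequence) + 1,
                              nchar(dom$sequence)), j$sequence)
      expect_true(dom$in_frame)
      expect_match(dom$junction_aa, "^C")
      expect_match(dom$junction_aa, "[WF]$")
    }
  }
})

test_that("requested layouts are honoured and impossible ones rejected", {
  rd <- fix_refdir()
  set.seed(41)
  cl <- simulate_clone(rd, library_sim_config(), layout = "VL-VL")
  expect_identical(cl$layout, "VL-VL")
  expect_identical(cl$domain1$kind, "VL")
  expect_identical(cl$domain2$kind, "VL")
  heavy_only <- reference_directory(
    ref_alleles(rd)[ref_alleles(rd)$chain_kind == "heavy", ])
  expect_error(simulate_clone(heavy_only, library_sim_config(),
                              layout = "VH-VL"), "impossible")
})

test_that("error-free reads equal their clone consensus up to orientation", {
  fs <- fix_sim()  # per_base_error = 0
  seq_of <- stats::setNames(fs$lib$clones$sequence, fs$lib$clones$clone_id)
  tr <- fs$sim$truth
  for (i in seq_len(nrow(tr))) {
    want <- seq_of[[tr$clone_id[i]]]
    got <- fs$sim$reads[[tr$read_id[i]]]
    if (tr$strand[i] == "reverse")
      got <- scfvtools:::revcomp_chr(got)
    expect_identical(got, want)
  }
  expect_true(all(tr$n_errors == 0))
})

test_that("read simulation is seed-deterministic (FASTQ bytes identical)", {
  fs <- fix_sim()
  s1 <- simulate_reads(fs$lib, read_error_model(), n_reads = 25, seed = 9)
  s2 <- simulate_reads(fs$lib, read_error_model(), n_reads = 25, seed = 9)
  expect_identical(s1, s2)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(s1$reads, f1)
  write_fastq(s2$reads, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("substitution-only errors conserve read length", {
  fs <- fix_sim()
  em <- read_error_model(per_base_error = 0.01, sub_frac = 1, ins_frac = 0,
                         del_frac = 0)
  sim <- simulate_reads(fs$lib, em, n_reads = 40, seed = 13)
  lens <- stats::setNames(nchar(fs$lib$clones$sequence),
                          fs$lib$clones$clone_id)
  expect_equal(unname(nchar(sim$reads)),
               unname(lens[sim$truth$clone_id]))
})

test_that("per-read error counts match the configured rate", {
  fs <- fix_sim()
  em <- read_error_model(per_base_error = 0.001, primer_end_del_boost = 1)
  sim <- simulate_reads(fs$lib, em, n_reads = 2000, seed = 17)
  lens <- stats::setNames(nchar(fs$lib$clones$sequence),
                          fs$lib$clones$clone_id)
  expected <- mean(lens[sim$truth$clone_id]) * 0.001
  se <- sqrt(expected / 2000)
  expect_lt(abs(mean(sim$truth$n_errors) - expected), 3 * se)
})

test_that("error-kind mixture is calibrated (no terminal boost)", {
  em <- read_error_model(per_base_error = 0.02, primer_end_del_boost = 1)
  set.seed(19)
  template <- scfvtools:::rand_dna(10000L)
  kinds <- character(0)
  set.seed(23)
  for (k in 1:100) {
    res <- scfvtools:::apply_read_errors(template, em)
    kinds <- c(kinds, res$errors$kind)
  }
  n <- length(kinds)       # ~2e4 simulated errors
  expect_gt(n, 15000)
  props <- c(substitution = 0.4, insertion = 0.25, deletion = 0.35)
  for (kind in names(props)) {
    p <- props[[kind]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(kinds == kind) - p), 3 * se)
  }
})

test_that("terminal deletion boost concentrates deletions at amplicon ends", {
  em <- read_error_model(per_base_error = 0.005, primer_end_del_boost = 20,
                         end_window = 3)
  set.seed(29)
  template <- scfvtools:::rand_dna(977L)
  pos <- integer(0)
  for (k in 1:300) {
    res <- scfvtools:::apply_read_errors(template, em)
    d <- res$errors[res$errors$kind == "deletion", ]
    pos <- c(pos, d$pos)
  }
  n_end <- sum(pos <= 3 | pos >= 975)
  # 6 boosted positions at x20 vs 971 at x1: expected end fraction ~ 11%
  expect_gt(n_end / length(pos), 0.05)
})

test_that("spiking adds variant clones with exact forced copies", {
  fx <- fix_p3()
  lib0 <- scfvtools:::empty_library()
  expect_null(spike_reference_clone(lib0, fx$insert, list())$forced_plan)
  spiked <- spike_reference_clone(
    lib0, fx$insert,
    list(list(mutations = "a545>g", pcr_sample = "s1", smrt_cell = 1,
              copies = 1),
         list(mutations = "", pcr_sample = "s2", smrt_cell = 5,
              copies = 2)))
  expect_equal(nrow(spiked$clones), 2)
  expect_equal(sum(spiked$forced_plan$copies), 3)
  sim <- simulate_reads(spiked, read_error_model(per_base_error = 0),
                        n_reads = 0, seed = 3)
  expect_equal(length(sim$reads), 3)
  carriers <- vapply(sim$reads, function(r) {
    if (substr(r, 1, 23) != FWD_PRIMER) r <- scfvtools:::revcomp_chr(r)
    substr(r, 545, 545) == "G"
  }, logical(1))
  expect_equal(sum(carriers), 1)  # exactly one read carries the spike
  expect_error(
    spike_reference_clone(lib0, fx$insert,
                          list(list(mutations = "a545>g; a545>c",
                                    pcr_sample = "s1", smrt_cell = 1,
                                    copies = 1))),
    "contradictory")
})
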