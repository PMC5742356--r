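test_that("error-free simulated reads are fully annotated and recovered", {
  fs <- fix_sim()
  tab <- fix_sim_ann()$tab
  expect_true(all(tab$is_scfv_candidate))
  tr <- sim_truth_calls(fs)
  m <- merge(tab, tr, by = "read_id", suffixes = c("", ".truth"))
  expect_equal(nrow(m), nrow(tab))
  expect_identical(m$layout, m$layout.truth)
  expect_identical(m$d1_v_call, m$d1_v_call.truth)
  expect_identical(m$d1_j_call, m$d1_j_call.truth)
  expect_identical(m$d2_v_call, m$d2_v_call.truth)
  expect_identical(m$d2_j_call, m$d2_j_call.truth)
  expect_identical(m$d1_junction_aa, m$d1_junction_aa.truth)
  expect_identical(m$d2_junction_aa, m$d2_junction_aa.truth)
  # junctions of in-frame domains are anchored Cys ... Trp/Phe
  okd <- !is.na(tab$d1_junction_aa)
  expect_true(all(grepl("^C", tab$d1_junction_aa[okd])))
  expect_true(all(grepl("[WF]$", tab$d1_junction_aa[okd])))
  # the annotation strand matches the simulated orientation
  expect_identical(m$strand, m$strand.truth)
})

test_that("annotation is invariant under reverse complement except strand", {
  fs <- fix_sim()
  reads <- fs$sim$reads[1:6]
  rc <- vapply(reads, scfvtools:::revcomp_chr, character(1))
  t1 <- annotation_table(annotate_reads(reads, fs$refdir))
  t2 <- annotation_table(annotate_reads(rc, fs$refdir))
  flip <- function(s) ifelse(s == "forward", "reverse", "forward")
  expect_identical(t2$strand, flip(t1$strand))
  cols <- setdiff(names(t1), "strand")
  expect_identical(t1[cols], t2[cols])
})

test_that("V-REGION identity hits the 85.00 boundary by construction", {
  rd <- fix_refdir()
  v <- ref_alleles(rd, "V", "heavy")
  v <- v[v$allele_name == "IGHV1-10*01", ]
  pos <- seq(3L, 267L, by = 6L)       # 45 distinct positions
  expect_length(pos, 45L)
  s <- v$sequence
  for (p in pos) {
    cur <- substr(s, p, p)
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  set.seed(7)
  read <- paste0(scfvtools:::rand_dna(60L), s, scfvtools:::rand_dna(60L))
  det <- detect_v_domains(read, rd)
  expect_gte(nrow(det$hits), 1L)
  dom <- annotate_domain(det$oriented, det$hits[1, ], rd)
  expect_identical(dom$v_call, "IGHV1-10*01")
  expect_identical(dom$v_identity_pct, 85.00)  # 255/300
  expect_equal(nrow(dom$mutations), 45L)
})

test_that("a pure germline domain annotates at 100.00 with no mutations", {
  rd <- fix_refdir()
  fs <- fix_sim()
  zero <- simulate_library(rd, library_sim_config(
    n_clones = 1, seed = 51, vh_mutation_rate = 0, vl_mutation_rate = 0,
    p_out_of_frame = 0))
  ann <- annotate_read(zero$clones$sequence[1], rd)
  expect_identical(ann$domain1$v_identity_pct, 100.00)
  expect_identical(ann$domain2$v_identity_pct, 100.00)
  expect_equal(nrow(ann$domain1$mutations), 0L)
  expect_true(ann$is_scfv_candidate)
})

test_that("truncated single-domain reads classify as incomplete", {
  fs <- fix_sim()
  full <- fs$sim$reads[[1]]
  if (fs$sim$truth$strand[1] == "reverse")
    full <- scfvtools:::revcomp_chr(full)
  one_domain <- substr(full, 1, 460)   # primer + flank + first domain only
  ann <- annotate_read(one_domain, fs$refdir)
  expect_false(ann$is_scfv_candidate)
  expect_identical(ann$layout, "incomplete")
  expect_null(ann$domain2)
  expect_identical(classify_layout(character(0)), "incomplete")
  expect_identical(classify_layout(c("VH", "VL")), "VH-VL")
  expect_identical(classify_layout(c("VL", "VL")), "VL-VL")
})

test_that("off-type VL-VL clones are annotated as VL-VL", {
  rd <- fix_refdir()
  set.seed(61)
  cl <- simulate_clone(rd, library_sim_config(p_out_of_frame = 0),
                       layout = "VL-VL")
  ann <- annotate_read(cl$sequence, rd)
  expect_identical(ann$layout, "VL-VL")
  expect_identical(ann$domain1$domain_kind, "VL")
  expect_identical(ann$domain2$domain_kind, "VL")
})

test_that("linker location matches an edit-distance oracle", {
  fs <- fix_sim()
  read <- fs$sim$reads[[2]]
  if (fs$sim$truth$strand[2] == "reverse")
    read <- scfvtools:::revcomp_chr(read)
  ann <- annotate_read(read, fs$refdir)
  expect_false(is.null(ann$linker))
  span <- ann$linker$span
  expect_equal(diff(unname(span)) + 1L, 53L)
  expect_equal(ann$linker$edit_distance, 0)
  expect_gt(span[["start"]], ann$domain1$read_span[["end"]])
  expect_lt(span[["end"]], ann$domain2$read_span[["start"]])

  # two substitutions in the linker: found at distance 2
  lk_start <- ann$linker$span[["start"]]
  mut <- read
  substr(mut, lk_start + 10L, lk_start + 10L) <-
    setdiff(c("A", "C", "G", "T"), substr(mut, lk_start + 10L,
                                          lk_start + 10L))[1]
  substr(mut, lk_start + 20L, lk_start + 20L) <-
    setdiff(c("A", "C", "G", "T"), substr(mut, lk_start + 20L,
                                          lk_start + 20L))[1]
  ann2 <- annotate_read(mut, fs$refdir)
  expect_equal(ann2$linker$edit_distance, 2)
  lk_seq <- substr(mut, ann2$linker$span[["start"]],
                   ann2$linker$span[["end"]])
  expect_equal(oracle_edit_distance(lk_seq, DEFAULT_LINKER), 2L)

  # scrambled inter-domain segment: absent
  set.seed(71)
  scr <- read
  substr(scr, lk_start, lk_start + 52L) <- scfvtools:::rand_dna(53L)
  ann3 <- annotate_read(scr, fs$refdir)
  expect_null(ann3$linker)
})

test_that("a constructed 42-nt anchored junction translates C..W in frame", {
  # TGT + 36 nt + TGG: 42 nt, 14 AA, starts C ends W
  set.seed(81)
  mid <- paste(rep("GCT", 12), collapse = "")
  junction <- paste0("TGT", mid, "TGG")
  expect_equal(nchar(junction), 42L)
  aa <- scfvtools:::translate_nt(junction)
  expect_equal(nchar(aa), 14L)
  expect_match(aa, "^C")
  expect_match(aa, "W$")
})
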