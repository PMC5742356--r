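ann_row <- function(layout, v1, j1, jaa1, v2, j2, jaa2, id = "r1") {
  data.frame(read_id = id, layout = layout, d1_v_call = v1, d1_j_call = j1,
             d1_junction_aa = jaa1, d2_v_call = v2, d2_j_call = j2,
             d2_junction_aa = jaa2, stringsAsFactors = FALSE)
}

test_that("clonotype keys are layout-aware and junction-sensitive", {
  a <- ann_row("VH-VL", "IGHV1*01", "IGHJ1*01", "CARW", "IGKV1*01",
               "IGKJ1*01", "CQQF")
  b <- a
  expect_identical(clonotype_key(a), clonotype_key(b))
  swapped <- ann_row("VL-VH", "IGKV1*01", "IGKJ1*01", "CQQF", "IGHV1*01",
                     "IGHJ1*01", "CARW")
  expect_false(clonotype_key(a) == clonotype_key(swapped))
  diff_j <- a
  diff_j$d2_junction_aa <- "CQQY"
  expect_false(clonotype_key(a) == clonotype_key(diff_j))
  untyped <- a
  untyped$d1_junction_aa <- NA
  expect_error(clonotype_key(untyped), "untyped domain")
})

test_that("reads of one clone share a key; a silent V substitution keeps it", {
  fs <- fix_sim()
  tab <- fix_sim_ann()$tab
  tr <- merge(tab, fs$sim$truth[c("read_id", "clone_id")], by = "read_id")
  for (cid in unique(tr$clone_id)) {
    sub <- tr[tr$clone_id == cid & tr$is_scfv_candidate, ]
    if (nrow(sub) >= 2)
      expect_length(unique(clonotype_keys(sub)), 1L)
  }
  # substitute one nt in the first domain's V region, outside the junction
  read <- fs$sim$reads[[1]]
  if (fs$sim$truth$strand[1] == "reverse")
    read <- scfvtools:::revcomp_chr(read)
  ann0 <- annotate_read(read, fs$refdir)
  p <- ann0$domain1$read_span[["start"]] + 30L
  mut <- read
  substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"), substr(mut, p, p))[1]
  ann1 <- annotate_read(mut, fs$refdir)
  expect_identical(clonotype_key(ann0), clonotype_key(ann1))
})

test_that("association ranking uses min-rank ties and recovers abundance", {
  rows <- do.call(rbind, c(
    replicate(5, ann_row("VH-VL", "A*01", "J1*01", "CAW", "K*01", "KJ*01",
                         "CQF"), simplify = FALSE),
    replicate(3, ann_row("VH-VL", "B*01", "J1*01", "CAW", "K*01", "KJ*01",
                         "CQF"), simplify = FALSE),
    replicate(3, ann_row("VH-VL", "C*01", "J1*01", "CAW", "K*01", "KJ*01",
                         "CQF"), simplify = FALSE)))
  rows$read_id <- sprintf("r%02d", seq_len(nrow(rows)))
  rk <- rank_associations(rows)
  expect_equal(rk$rank, c(1L, 2L, 2L))
  expect_equal(rk$n_reads, c(5L, 3L, 3L))
  expect_equal(sum(rk$frequency), 1)
  # rank stability: duplicating every read leaves ranks unchanged
  rk2 <- rank_associations(rbind(rows, transform(rows, read_id = paste0(
    read_id, "b"))))
  expect_equal(rk2$rank, rk$rank)
  expect_equal(rk2$n_reads, 2L * rk$n_reads)
  expect_equal(rk2$frequency, rk$frequency)
  # single-clone library
  one <- rank_associations(rows[1, ])
  expect_equal(one$frequency, 1)
  # off-type layouts are excluded from the ranking
  vlvl <- ann_row("VL-VL", "K*01", "KJ*01", "CQF", "K*01", "KJ*01", "CQF")
  expect_equal(nrow(rank_associations(rbind(rows, vlvl))), 3L)
})

test_that("a spiked dominant clone ranks at the top of its data set", {
  fs <- fix_sim()
  tab <- fix_sim_ann()$tab
  flt <- filter_scfv(tab[tab$is_scfv_candidate, ])
  passed <- flt[flt$passed & flt$layout %in% c("VH-VL", "VL-VH"), ]
  rk <- rank_associations(passed)
  tr <- merge(passed["read_id"], fs$sim$truth, by = "read_id")
  top_clone <- names(sort(table(tr$clone_id), decreasing = TRUE))[1]
  top_ids <- tr$read_id[tr$clone_id == top_clone]
  key_top <- clonotype_keys(passed[passed$read_id == top_ids[1], ])
  expect_equal(rk$rank[rk$key == key_top], 1L)
})

test_that("characteristics tracking returns exactly the matching reads", {
  expect_length(track_by_characteristics("k", ann_row("VH-VL", "A", "B",
    "C", "D", "E", "F")[0, ]), 0L)
  rows <- rbind(ann_row("VH-VL", "A*01", "J1*01", "CAW", "K*01", "KJ*01",
                        "CQF", id = "r1"),
                ann_row("VH-VL", "A*01", "J1*01", "CAW", "K*01", "KJ*01",
                        "CQY", id = "r2"))
  key <- clonotype_key(rows[1, ])
  expect_identical(track_by_characteristics(key, rows), "r1")
})

test_that("alignment tracking enforces full coverage and the diff cap", {
  fx <- fix_p3()
  ref <- fx$scfv
  reads <- c(exact = fx$insert)
  # 4 scattered substitutions inside the scFv
  m4 <- parse_mutations("a545>g; g686>a; a757>g; c838>g")
  reads["four"] <- apply_mutations(fx$insert, m4)
  # 21 scattered substitutions: over the cap
  set.seed(111)
  pos <- seq(110, 850, length.out = 21)
  r21 <- fx$insert
  for (p in as.integer(pos)) {
    cur <- substr(r21, p, p)
    substr(r21, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  reads["twentyone"] <- r21
  # truncated read missing half the reference: no full coverage
  reads["half"] <- substr(fx$insert, 1, 500)
  got <- track_by_alignment(ref, reads, max_diffs = 20)
  expect_setequal(got$read_id, c("exact", "four"))
  expect_equal(got$diff_count[got$read_id == "exact"], 0L)
  expect_equal(got$diff_count[got$read_id == "four"], 4L)
  expect_error(track_by_alignment(substr(ref, 1, 50), reads), "100 nt")
})

test_that("identity classification distinguishes full, core and related", {
  fx <- fix_p3()
  g <- fx$geometry
  expect_identical(classify_identity(fx$insert, fx$insert, g),
                   "identical_full")
  expect_identical(
    classify_identity(scfvtools:::revcomp_chr(fx$insert), fx$insert, g),
    "identical_full")
  del942 <- apply_mutations(fx$insert, parse_mutation("a942>del"))
  expect_identical(classify_identity(del942, fx$insert, g),
                   "identical_core")
  sub545 <- apply_mutations(fx$insert, parse_mutation("a545>g"))
  expect_identical(classify_identity(sub545, fx$insert, g), "related")
  # a deletion crossing the core boundary is related
  big <- apply_mutations(fx$insert,
                         parse_mutation("a886-a977>del (92 nt)"))
  expect_identical(classify_identity(big, fx$insert, g), "related")
})

test_that("provenance rule: replication across samples vs cells", {
  fx <- fix_p3()
  mk <- function(ids, samples, cells, spec) {
    related <- data.frame(read_id = ids, pcr_sample = samples,
                          smrt_cell = cells, stringsAsFactors = FALSE)
    muts <- do.call(rbind, lapply(ids, function(id) {
      m <- parse_mutations(spec)
      m <- scfvtools:::annotate_mutation_table(m, fx$insert, fx$geometry)
      m$read_id <- id
      m
    }))
    classify_provenance(related, muts, fx$geometry)
  }
  # same signature, one sample, two cells: B under the samples rule
  res <- mk(c("a", "b"), c("s1", "s1"), c(1, 2), "t624>c")
  expect_identical(res$groups$category, "B")
  expect_identical(res$groups$provenance, "unassigned")
  # ... but A under the cells rule
  related <- data.frame(read_id = c("a", "b"), pcr_sample = c("s1", "s1"),
                        smrt_cell = c(1, 2), stringsAsFactors = FALSE)
  muts <- do.call(rbind, lapply(c("a", "b"), function(id) {
    m <- scfvtools:::annotate_mutation_table(parse_mutations("t624>c"),
                                             fx$insert, fx$geometry)
    m$read_id <- id
    m
  }))
  res2 <- classify_provenance(related, muts, fx$geometry,
                              category_a_rule = "cells")
  expect_identical(res2$groups$category, "A")
  # two samples: A; an extra excluded-class difference does not split a group
  res3 <- mk(c("a", "b"), c("s1", "s3"), c(1, 9), "t624>c")
  expect_identical(res3$groups$category, "A")
  muts_b <- scfvtools:::annotate_mutation_table(
    parse_mutations("t624>c; a977>del"), fx$insert, fx$geometry)
  muts_b$read_id <- "b"
  muts_a <- scfvtools:::annotate_mutation_table(parse_mutations("t624>c"),
                                                fx$insert, fx$geometry)
  muts_a$read_id <- "a"
  res4 <- classify_provenance(related, rbind(muts_a, muts_b), fx$geometry)
  expect_equal(nrow(res4$groups), 1L)
  # singleton flags: indel -> sequencing error, substitution -> PCR/library
  res5 <- mk("a", "s1", 1, "209^210>ins^a")
  expect_identical(res5$groups$provenance, "putative_sequencing_error")
  res6 <- mk("a", "s1", 1, "t624>c")
  expect_identical(res6$groups$provenance, "putative_pcr_or_library")
})
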