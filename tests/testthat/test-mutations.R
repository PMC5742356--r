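test_that("nomenclature round-trips for every mutation kind", {
  set.seed(3)
  bases <- c("a", "c", "g", "t")
  for (k in 1:40) {
    kind <- sample(c("substitution", "deletion", "range_deletion",
                     "insertion"), 1)
    pos <- sample(900, 1)
    m <- switch(kind,
      substitution = {
        rb <- sample(bases, 1)
        mutation_df("substitution", pos, ref = rb,
                    alt = sample(setdiff(bases, rb), 1))
      },
      deletion = mutation_df("deletion", pos, ref = sample(bases, 1),
                             alt = ""),
      range_deletion = {
        end <- pos + sample(2:60, 1)
        mutation_df("range_deletion", pos, end = end,
                    ref = paste0(sample(bases, 1), sample(bases, 1)),
                    alt = "")
      },
      insertion = mutation_df("insertion", pos, ref = "",
                              alt = paste(sample(bases, sample(1:3, 1),
                                                 TRUE), collapse = "")))
    txt <- format_mutation(m$kind, m$pos, m$ref, m$alt, m$end)
    back <- parse_mutation(txt)
    expect_identical(back$kind, m$kind)
    expect_identical(back$pos, m$pos)
    expect_identical(back$end, m$end)
    expect_identical(back$alt, m$alt)
    if (m$kind == "range_deletion")  # nomenclature keeps only the end bases
      expect_identical(back$ref, paste0(substr(m$ref, 1, 1),
                                        substr(m$ref, nchar(m$ref),
                                               nchar(m$ref))))
    else expect_identical(back$ref, m$ref)
  }
})

test_that("parse_mutation tolerates spacing and rejects garbage", {
  expect_identical(parse_mutation("a942 > del")$kind, "deletion")
  expect_identical(parse_mutation("a886-a977 > del (92 nt)")$end, 977L)
  expect_identical(parse_mutation("t975-a977>del (3nt)")$pos, 975L)
  expect_error(parse_mutation("x99>y"), "cannot parse")
  expect_error(parse_mutation("a886-a977>del (91 nt)"), "length mismatch")
  expect_error(parse_mutation("658^700>ins^cc"), "not adjacent")
})

test_that("apply_mutations edits a toy sequence correctly", {
  ref <- "ACGTACGTAC"
  expect_identical(apply_mutations(ref, parse_mutation("g3>t")),
                   "ACTTACGTAC")
  expect_identical(apply_mutations(ref, parse_mutation("g7>del")),
                   "ACGTACTAC")
  expect_identical(apply_mutations(ref, parse_mutation("g3-a5>del (3 nt)")),
                   "ACCGTAC")
  expect_identical(apply_mutations(ref, parse_mutation("4^5>ins^gg")),
                   "ACGTGGACGTAC")
  # several events at once, 3'-to-5' application keeps coordinates stable
  both <- rbind(parse_mutation("c2>a"), parse_mutation("t8>del"))
  expect_identical(apply_mutations(ref, both), "AAGTACGAC")
  expect_error(apply_mutations(ref, parse_mutation("c3>a")),
               "ref base mismatch")
  expect_error(apply_mutations(ref, parse_mutation("a99>g")),
               "outside the reference")
})

test_that("contradictory overlapping mutations are rejected", {
  m <- rbind(parse_mutation("g3>t"), parse_mutation("g3>a"))
  expect_error(apply_mutations("ACGTACGT", m), "contradictory")
  # identical duplicates are not a contradiction
  m2 <- rbind(parse_mutation("g3>t"), parse_mutation("g3>t"))
  expect_error(apply_mutations("ACGTACGT", m2), NA)
})

test_that("localization follows the amplicon geometry", {
  g <- insert_geometry()  # 977-nt map, core 3-941
  cases <- list(c(2, "fwd_primer_end"), c(23, "fwd_primer_end"),
                c(50, "insert_flank"), c(242, "insert_VH"),
                c(495, "insert_linker"), c(545, "insert_VL"),
                c(886, "insert_flank"), c(942, "rev_primer_vicinity"),
                c(956, "rev_primer_vicinity"), c(959, "rev_primer_end"),
                c(975, "rev_primer_end"))
  for (cs in cases)
    expect_identical(localize_mutation(as.integer(cs[1]), g), cs[2])
  expect_error(localize_mutation(0, g), "outside")
  expect_error(localize_mutation(978, g), "outside")
})

test_that("describe_mutations recovers applied mutations bit-exactly", {
  fx <- fix_p3()
  specs <- c("a545>g; g686>a; a757>g; c838>g",
             "a942>del",
             "209^210>ins^a; 762^763>ins^t",
             "g2>del; a715>g; c959-a977>del (19 nt)")
  for (spec in specs) {
    muts <- parse_mutations(spec)
    read <- apply_mutations(fx$insert, muts)
    got <- describe_mutations(read, fx$insert, fx$geometry)
    want <- vapply(seq_len(nrow(muts)), function(i)
      format_mutation(muts$kind[i], muts$pos[i], muts$ref[i], muts$alt[i],
                      muts$end[i]), character(1))
    expect_setequal(got$nomenclature, want)
  }
  # identical sequence: empty table
  expect_equal(nrow(describe_mutations(fx$insert, fx$insert, fx$geometry)),
               0L)
})
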