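test_that("TR/VR classifier enforces the adenine-mismatch thresholds", {
  # 114 bp, 12 adenine-specific, 0 other: passes with copyA as template
  call <- classify_tr_vr(make_pair(114, 12, 0))
  expect_true(call$passed)
  expect_equal(call$tr_copy, "A")
  expect_equal(call$profile$n_adenine_wrt_A, 12)
  expect_equal(call$profile$n_other_wrt_A, 0)

  # 9 adenine-specific mismatches: below the >= 10 floor
  call <- classify_tr_vr(make_pair(114, 9, 0))
  expect_false(call$passed)
  expect_true("adenine-mismatches<10" %in% call$reasons)

  # 150 bp with 11 adenine and 4 non-adenine: allowed others = 2 * 1.5 = 3
  call <- classify_tr_vr(make_pair(150, 11, 4))
  expect_false(call$passed)
  expect_true("non-adenine-excess" %in% call$reasons)

  # identical copies: no mismatches at all
  s <- random_dna(120)
  call <- classify_tr_vr(list(copyA_start = 0L, copyA_end = 120L,
                              copyB_start = 500L, copyB_end = 620L,
                              orientation = "direct", aligned_len = 120L,
                              alnA = s, alnB = s))
  expect_false(call$passed)
  expect_true("adenine-mismatches<10" %in% call$reasons)
})

test_that("classifier is symmetric under swapping the two copies", {
  for (cfg in list(c(12, 0), c(9, 0), c(11, 4), c(15, 1))) {
    p <- make_pair(140, cfg[1], cfg[2], seed = 50 + cfg[1])
    q <- p
    q$alnA <- p$alnB; q$alnB <- p$alnA
    q$copyA_start <- p$copyB_start; q$copyA_end <- p$copyB_end
    q$copyB_start <- p$copyA_start; q$copyB_end <- p$copyA_end
    c1 <- classify_tr_vr(p); c2 <- classify_tr_vr(q)
    expect_equal(c1$passed, c2$passed)
    expect_setequal(c1$reasons, c2$reasons)
    if (c1$passed) {
      expect_equal(c1$tr$start, c2$tr$start)  # same genomic template either way
      expect_equal(c1$vr$start, c2$vr$start)
    }
  }
})

test_that("ambiguous template (equal adenine counts both ways) is rejected", {
  # a mismatch column carries an adenine on at most one side, so a pair can
  # only qualify both ways when long enough that the per-100-bp allowance
  # absorbs each side's opposite-adenine columns
  set.seed(60)
  tr <- sample(c("C", "G", "T"), 1000, replace = TRUE)
  vr <- tr
  tr[seq(10, 150, 10)] <- "A"     # 15 columns with A in copyA
  vr[seq(510, 650, 10)] <- "A"    # 15 columns with A in copyB
  call <- classify_tr_vr(list(copyA_start = 0L, copyA_end = 1000L,
                              copyB_start = 2000L, copyB_end = 3000L,
                              orientation = "direct", aligned_len = 1000L,
                              alnA = paste(tr, collapse = ""),
                              alnB = paste(vr, collapse = "")))
  expect_false(call$passed)
  expect_equal(call$reasons, "ambiguous-template")
})

test_that("find_repeat_pairs recovers planted direct and inverted pairs", {
  pl <- plant_repeat()
  anchor <- list(start = 3000L, end = 3100L)
  pairs <- find_repeat_pairs(pl$seq, anchor)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$orientation, "direct")
  expect_gte(pairs$aligned_len, 114)
  expect_lte(abs(pairs$copyA_start - pl$a[1]), 3)
  expect_lte(abs(pairs$copyB_start - pl$b[1]), 3)

  pli <- plant_repeat(inverted = TRUE, seed = 78)
  pairs_i <- find_repeat_pairs(pli$seq, anchor)
  expect_equal(nrow(pairs_i), 1)
  expect_equal(pairs_i$orientation, "inverted")
  expect_gte(pairs_i$aligned_len, 114)
  # alignment strings pair column-by-column: mismatch count equals plant
  expect_equal(pairs_i$n_mismatch, 12)
})

test_that("identical copies align full-length with zero mismatches", {
  set.seed(79)
  copy <- random_dna(200)
  s <- paste0(random_dna(500), copy, random_dna(800), copy, random_dna(500))
  # pin the columns flanking each copy to mismatching bases so the exact
  # extent of homology is the 200-bp copy itself
  substr(s, 500, 500) <- "A"; substr(s, 1500, 1500) <- "C"
  substr(s, 701, 701) <- "G"; substr(s, 1701, 1701) <- "T"
  pairs <- find_repeat_pairs(s, list(start = 1000L, end = 1100L),
                             min_repeat_len = 100)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$aligned_len, 200)
  expect_equal(pairs$n_mismatch, 0)
  expect_equal(pairs$copyA_start, 500)
  expect_equal(pairs$copyB_start, 1500)
})

test_that("a repeat-free record yields no pairs", {
  set.seed(80)
  s <- random_dna(4000)
  pairs <- find_repeat_pairs(s, list(start = 2000L, end = 2100L))
  expect_equal(nrow(pairs), 0)
  expect_error(find_repeat_pairs(s, list(start = -5L, end = 0L)), "anchor")
})

test_that("repeat discovery is invariant under reverse-complementing the record", {
  pl <- plant_repeat(seed = 81)
  anchor <- list(start = 3000L, end = 3100L)
  fwd <- find_repeat_pairs(pl$seq, anchor)
  L <- nchar(pl$seq)
  rev_anchor <- list(start = L - 3100L, end = L - 3000L)
  rev <- find_repeat_pairs(revcomp(pl$seq), rev_anchor)
  expect_equal(nrow(rev), nrow(fwd))
  # map reverse-record coordinates back to forward space
  mapped <- sort(c(L - rev$copyA_end, L - rev$copyB_end))
  expect_equal(mapped, sort(c(fwd$copyA_start, fwd$copyB_start)))
  expect_equal(rev$aligned_len, fwd$aligned_len)
  expect_equal(rev$n_mismatch, fwd$n_mismatch)
})

test_that("assemble_cassette flags intergenic VR as no-TP", {
  pl <- plant_repeat(seed = 82)
  pairs <- find_repeat_pairs(pl$seq, list(start = 3000L, end = 3100L))
  call <- classify_tr_vr(pairs[1, ])
  expect_true(call$passed)
  no_orfs <- find_orfs(pl$seq, min_protein_len = 3000)  # none that long
  cass <- assemble_cassette(dgrscope:::as_record(pl$seq),
                            rt = list(start = 3000L, end = 3100L, strand = "+"),
                            calls = list(call), orfs = no_orfs)
  expect_length(cass, 1)
  expect_true("no-TP" %in% cass[[1]]$flags)
  expect_true(cass[[1]]$complete)  # completeness is RT + passing TR/VR
})

test_that("a multi-cassette genome yields distinct assembled cassettes", {
  # elevated substitution rate so every cassette clears the classifier floor
  g <- generate_genome(sim_config(n_cassettes = 4, p_adenine_sub = 0.7, seed = 5))
  det <- detect_dgr(g$record)
  complete <- Filter(function(cc) cc$complete, det$cassettes)
  expect_equal(length(complete), 4)
  vr_keys <- vapply(complete, function(cc) paste(cc$trvr$vr$start, cc$trvr$vr$end),
                    character(1))
  expect_equal(length(unique(vr_keys)), 4)
  for (cc in complete) {
    expect_false(is.null(cc$tp_orf))
    expect_true(cc$trvr$vr$start >= cc$tp_orf$start &&
                  cc$trvr$vr$end <= cc$tp_orf$end)
  }
})

test_that("cassette_identity reports per-feature identity and NA for absent features", {
  rec1 <- dgrscope:::as_record("ACGT")
  rec2 <- dgrscope:::as_record("ACGA")
  mk <- function(vr) structure(list(
    record_id = "x", rt = NULL,
    trvr = structure(list(vr = list(start = 0L, end = 4L),
                          tr = NULL, orientation = "direct"), class = "trvr_call"),
    tp_orf = NULL, imh = NULL, hairpin = NULL, avd = NULL,
    complete = FALSE, flags = character(0)), class = "dgr_cassette")
  idy <- cassette_identity(mk(), mk(), rec1, rec2)
  expect_equal(unname(idy["VR"]), 75)
  expect_true(is.na(idy["RT"]))
  idy2 <- cassette_identity(mk(), mk(), rec1, rec1)
  expect_equal(unname(idy2["VR"]), 100)
})

test_that("RT motif scan finds YADD-class motifs and honours min length", {
  orfs <- data.frame(record_id = "r", start = 0L, end = 312L, strand = "+",
                     protein = paste0(strrep("G", 50), "YADD", strrep("G", 49)),
                     partial = FALSE, stringsAsFactors = FALSE)
  hits <- scan_rt_candidates(orfs, min_protein_len = 100)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$motif_hits[[1]]$position, 51L)
  expect_equal(hits$score, 1L)
  # no motif -> not emitted
  orfs$protein <- strrep("G", 103)
  expect_equal(nrow(scan_rt_candidates(orfs, min_protein_len = 100)), 0)
  # too short -> not emitted even with motif
  orfs$protein <- paste0("YIDD", strrep("G", 40))
  expect_equal(nrow(scan_rt_candidates(orfs, min_protein_len = 100)), 0)
  expect_equal(nrow(scan_rt_candidates(orfs[0, ])), 0)
})
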