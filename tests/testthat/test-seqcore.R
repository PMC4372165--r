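test_that("read_fasta parses, normalizes and validates records", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a first record", "acgt", ">b", "ACGU", "ACGT"), p)
  recs <- read_fasta(p)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$id, "a")
  expect_equal(recs[[1]]$description, "first record")
  expect_equal(recs[[1]]$sequence, "ACGT")
  expect_equal(recs[[2]]$sequence, "ACGTACGT")  # U -> T, lines joined

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), dup)
  expect_error(read_fasta(dup), "duplicate.*a")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGJ"), bad)
  expect_error(read_fasta(bad), "non-IUPAC.*position 4")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")
})

test_that("fasta round-trips through write_fasta", {
  p <- withr::local_tempfile(fileext = ".fasta")
  set.seed(7)
  recs <- list(structure(list(id = "chr1", sequence = random_dna(300),
                              description = "test", topology = "linear"),
                         class = "genome_record"))
  write_fasta(recs, p)
  back <- read_fasta(p)
  expect_equal(back[[1]]$sequence, recs[[1]]$sequence)
  expect_equal(back[[1]]$id, "chr1")
})

test_that("translate_dna follows the genetic code and rejects bad input", {
  expect_equal(translate_dna("ATG"), "M")
  expect_equal(translate_dna("TAA"), "*")
  expect_equal(translate_dna("AATAAC"), "NN")
  expect_equal(translate_dna("ATGAAATAA"), "MK*")
  expect_error(translate_dna("ATGA"), "divisible")
  expect_error(translate_dna("ATN"), "ambiguous")
})

test_that("find_orfs handles the minimal one-ORF cases on both strands", {
  o <- find_orfs("ATGAAATAA", min_protein_len = 2)
  expect_equal(nrow(o), 1)
  expect_equal(o$protein, "MK")
  expect_equal(o$strand, "+")
  expect_equal(c(o$start, o$end), c(0, 9))
  expect_false(o$partial)

  o2 <- find_orfs("TTATTTCAT", min_protein_len = 2)
  expect_equal(o2$protein, "MK")
  expect_equal(o2$strand, "-")
  expect_equal(c(o2$start, o2$end), c(0, 9))

  expect_equal(nrow(find_orfs("AT", min_protein_len = 1)), 0)
})

test_that("find_orfs matches the exhaustive six-frame oracle on random sequences", {
  set.seed(11)
  for (rep in 1:12) {
    s <- random_dna(1000)
    for (ml in c(10, 30, 100)) {
      got <- find_orfs(s, min_protein_len = ml)
      want <- oracle_orfs(s, ml)
      expect_equal(nrow(got), nrow(want), info = sprintf("rep %d min %d", rep, ml))
      if (nrow(want) > 0) {
        rownames(got) <- rownames(want) <- NULL
        expect_equal(got[, c("start", "end", "strand", "protein", "partial")], want)
      }
    }
  }
})

test_that("minus-strand ORFs are strand-consistent under translation", {
  set.seed(12)
  s <- random_dna(2000)
  orfs <- find_orfs(s, min_protein_len = 20)
  minus <- orfs[orfs$strand == "-" & !orfs$partial, , drop = FALSE]
  for (i in seq_len(nrow(minus))) {
    cds <- revcomp(substr(s, minus$start[i] + 1, minus$end[i]))
    expect_equal(translate_dna(cds), paste0(minus$protein[i], "*"))
  }
})

make_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- lapply(nchar(seqs), function(l) rep(30L, l))
  data.frame(id = sprintf("r%d", seq_along(seqs)), sequence = seqs,
             qualities = I(quals), stringsAsFactors = FALSE)
}

test_that("qc_filter_reads applies the four stages in order", {
  # one N-read among 10; floor(0.025 * 9) = 0 removed by length
  seqs <- c(replicate(9, random_dna(60)), paste0(random_dna(30), "N", random_dna(29)))
  res <- qc_filter_reads(make_reads(seqs))
  expect_equal(unname(res$report["ambiguous_base"]), 1)
  expect_equal(unname(res$report["length_tails"]), 0)
  expect_equal(nrow(res$kept), 9)

  # 200 equal-quality reads of lengths 50..249: 5 shortest and 5 longest out
  set.seed(21)
  lens <- sample(50:249)
  seqs <- vapply(lens, random_dna, character(1))
  res <- qc_filter_reads(make_reads(seqs))
  expect_equal(unname(res$report["length_tails"]), 10)
  kept_lens <- nchar(res$kept$sequence)
  expect_equal(sort(kept_lens), 55:244)

  # exact duplicates: first kept
  s <- random_dna(40)
  res <- qc_filter_reads(make_reads(c(s, random_dna(40), s)))
  expect_equal(unname(res$report["duplicate"]), 1)
  expect_equal(res$kept$id[1], "r1")
})

test_that("quality filter removes low mean-quality reads only", {
  set.seed(22)
  seqs <- replicate(40, random_dna(50))
  quals <- c(lapply(1:39, function(i) rep(35L, 50)), list(rep(5L, 50)))
  res <- qc_filter_reads(make_reads(seqs, quals), tail_frac = 0)
  expect_equal(unname(res$report["low_quality"]), 1)
  # equal qualities: sd = 0, nothing removed
  res2 <- qc_filter_reads(make_reads(seqs[1:10]))
  expect_equal(unname(res2$report["low_quality"]), 0)
})

test_that("all reads can be removed without error", {
  res <- qc_filter_reads(make_reads(c("ANA", "CNC")))
  expect_equal(nrow(res$kept), 0)
  expect_equal(unname(res$report["ambiguous_base"]), 2)
  expect_equal(unname(res$report["output"]), 0)
})

test_that("N-removal and dereplication stages are idempotent", {
  set.seed(23)
  seqs <- c(replicate(20, random_dna(50)), "ACNGT")
  res1 <- qc_filter_reads(make_reads(seqs), tail_frac = 0)
  res2 <- qc_filter_reads(res1$kept, tail_frac = 0)
  expect_equal(res2$kept$sequence, res1$kept$sequence)
  expect_equal(unname(res2$report["ambiguous_base"]), 0)
  expect_equal(unname(res2$report["duplicate"]), 0)
})

test_that("fastq reads round-trip with Phred+33 qualities", {
  p <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2 desc", "GGCC", "+", "!!#5"), p)
  r <- read_fastq(p)
  expect_equal(r$id, c("r1", "r2"))
  expect_equal(r$qualities[[1]], rep(40L, 4))
  expect_equal(r$qualities[[2]], c(0L, 0L, 2L, 20L))
})
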