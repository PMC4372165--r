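#' Quality-filter sequencing reads
#'
#' Applies four stages in order: (1) remove reads containing ambiguous (`N`)
#' bases; (2) remove the shortest 2.5% and longest 2.5% of the remaining
#' reads (`floor(0.025 * n)` reads per tail, ties broken by input order);
#' (3) remove reads whose mean quality score lies more than 2 standard
#' deviations below the mean of per-read mean qualities; (4) remove exact
#' duplicate sequences, keeping the first occurrence.
#'
#' @param reads data.frame as returned by [read_fastq()] (columns `id`,
#'   `sequence`, list-column `qualities`).
#' @param tail_frac fraction trimmed per length tail (default 0.025).
#' @param sd_cut quality cutoff in standard deviations below the mean.
#' @return list with `kept` (the surviving data.frame) and `report`, a named
#'   integer vector of reads removed at each stage plus input/output counts.
#' @export
qc_filter_reads <- function(reads, tail_frac = 0.025, sd_cut = 2) {
  stopifnot(is.data.frame(reads), nrow(reads) >= 1L,
            all(c("id", "sequence", "qualities") %in% names(reads)))
  n_in <- nrow(reads)

  # stage 1: ambiguous bases
  has_n <- grepl("N", reads$sequence, fixed = TRUE)
  n_ambig <- sum(has_n)
  reads <- reads[!has_n, , drop = FALSE]

  # stage 2: length tails, floor(tail_frac * n) per tail on the post-N set
  n_len <- 0L
  if (nrow(reads) > 0L) {
    k <- floor(tail_frac * nrow(reads))
    if (k > 0L) {
      len <- nchar(reads$sequence)
      ord <- order(len)                       # stable: ties keep input order
      drop <- c(ord[seq_len(k)], rev(ord)[seq_len(k)])
      n_len <- length(unique(drop))
      reads <- reads[-unique(drop), , drop = FALSE]
    }
  }

  # stage 3: mean quality > sd_cut s.d. below the mean
  n_qual <- 0L
  if (nrow(reads) > 1L) {
    mq <- vapply(reads$qualities, function(q) mean(as.numeric(q)), numeric(1))
    cut <- mean(mq) - sd_cut * stats::sd(mq)
    low <- mq < cut
    n_qual <- sum(low)
    reads <- reads[!low, , drop = FALSE]
  }

  # stage 4: exact-duplicate removal, first occurrence kept
  dup <- duplicated(reads$sequence)
  n_dup <- sum(dup)
  reads <- reads[!dup, , drop = FALSE]
  rownames(reads) <- NULL

  list(
    kept = reads,
    report = c(input = n_in, ambiguous_base = n_ambig, length_tails = n_len,
               low_quality = n_qual, duplicate = n_dup, output = nrow(reads))
  )
}
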