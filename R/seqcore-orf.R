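# genetic code table (NCBI numbering; 11 = bacterial/archaeal/plastid)
genetic_code_table <- function(genetic_code = 11) {
  Biostrings::getGeneticCode(as.character(genetic_code))
}

#' Translate a DNA coding sequence
#'
#' @param dna a single DNA string, length divisible by 3, bases A/C/G/T only.
#' @param genetic_code NCBI genetic code id (default 11,
#'   bacterial/archaeal/plastid; identical to the standard code at the
#'   codon-to-amino-acid level).
#' @return amino-acid string; stop codons are rendered `*`.
#' @export
translate_dna <- function(dna, genetic_code = 11) {
  stopifnot(is.character(dna), length(dna) == 1L)
  dna <- toupper(dna)
  if (nchar(dna) %% 3 != 0) stop("sequence length not divisible by 3")
  if (grepl("[^ACGT]", dna)) stop("ambiguous or non-ACGT base in coding sequence")
  if (nchar(dna) == 0L) return("")
  code <- genetic_code_table(genetic_code)
  starts <- seq(1L, nchar(dna), by = 3L)
  codons <- substring(dna, starts, starts + 2L)
  paste(unname(code[codons]), collapse = "")
}

#' Find open reading frames in all six frames
#'
#' Deterministic six-frame scanner: within each frame, an ORF runs from the
#' first start codon (ATG/GTG/TTG, common archaeal usage) following the
#' previous in-frame stop to the next in-frame stop (the stop codon is
#' included in the coordinates). Codons containing `N` break the frame: no
#' ORF spans them. Runs that reach the end of the sequence without a stop are
#' emitted with `partial = TRUE`.
#'
#' @param record a `genome_record` (or bare DNA string).
#' @param min_protein_len minimum protein length in residues (stop excluded).
#' @param genetic_code NCBI genetic code id.
#' @param include_partial emit stop-less ORFs truncated by the sequence end?
#' @return data.frame with columns `record_id`, `start`, `end` (0-based
#'   half-open, forward coordinates), `strand`, `protein`, `partial`,
#'   sorted by `start`.
#' @export
find_orfs <- function(record, min_protein_len = 100, genetic_code = 11,
                      include_partial = TRUE) {
  record <- as_record(record)
  s <- record$sequence
  L <- nchar(s)
  empty <- data.frame(record_id = character(0), start = integer(0), end = integer(0),
                      strand = character(0), protein = character(0), partial = logical(0),
                      stringsAsFactors = FALSE)
  if (L < 3L) return(empty)
  code <- genetic_code_table(genetic_code)
  start_codons <- c("ATG", "GTG", "TTG")
  res <- list()
  for (strand in c("+", "-")) {
    sq <- if (strand == "+") s else revcomp(s)
    for (frame in 0:2) {
      ncod <- (L - frame) %/% 3L
      if (ncod < 1L) next
      pos <- seq(frame + 1L, by = 3L, length.out = ncod)
      codons <- substring(sq, pos, pos + 2L)
      aa <- unname(code[codons])                  # NA for N-containing codons
      is_stop <- !is.na(aa) & aa == "*"
      is_break <- is.na(aa)
      is_start <- !is_break & codons %in% start_codons
      # segment boundaries: indices after which a new ORF may begin
      seg_end <- which(is_stop | is_break)
      seg_begin <- c(1L, seg_end + 1L)
      seg_close <- c(seg_end, ncod + 1L)          # ncod+1 marks sequence end
      for (k in seq_along(seg_begin)) {
        b <- seg_begin[k]; e <- seg_close[k]
        if (b > ncod || b > e) next
        if (e <= ncod && is_break[e]) next        # N-broken segment: no valid stop
        st_idx <- which(is_start[b:min(e - 1L, ncod)])
        if (length(st_idx) == 0L) next
        first_start <- b + st_idx[1] - 1L
        partial <- e > ncod
        last_cod <- if (partial) ncod else e
        n_aa <- last_cod - first_start + (if (partial) 1L else 0L)  # excl. stop
        if (partial && !include_partial) next
        if (n_aa < min_protein_len) next
        prot <- paste(aa[first_start:(if (partial) ncod else (e - 1L))], collapse = "")
        # frame-local 0-based nt coords on the scanned strand
        nt_start <- frame + (first_start - 1L) * 3L
        nt_end <- frame + last_cod * 3L
        if (strand == "+") {
          gs <- nt_start; ge <- nt_end
        } else {
          gs <- L - nt_end; ge <- L - nt_start
        }
        res[[length(res) + 1L]] <- data.frame(
          record_id = record$id, start = gs, end = ge, strand = strand,
          protein = prot, partial = partial, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0L) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
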