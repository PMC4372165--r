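#' Count adenines in a template repeat segment
#' @param tr_segment DNA string over A/C/G/T.
#' @return integer count of `A`.
#' @export
count_template_adenines <- function(tr_segment) {
  stopifnot(is.character(tr_segment), length(tr_segment) == 1L)
  tr_segment <- toupper(tr_segment)
  if (grepl("[^ACGT]", tr_segment)) stop("tr_segment contains non-ACGT characters")
  sum(seq_chars(tr_segment) == "A")
}

#' Exact count of nucleotide variants reachable by adenine mutagenesis
#'
#' Each template adenine may be read as any of the four bases during
#' error-prone reverse transcription, so `n` adenines yield exactly `4^n`
#' nucleotide sequence variants.
#'
#' @param n_adenines non-negative integer.
#' @return a `dgr_bigint` (exact; print or [bigint_str()] for the decimal
#'   string).
#' @export
nucleotide_variant_count <- function(n_adenines) {
  if (length(n_adenines) != 1L || is.na(n_adenines) || n_adenines < 0 ||
      n_adenines != floor(n_adenines)) stop("n_adenines must be a non-negative integer")
  bigint_pow(4, n_adenines)
}

#' Per-codon diversification analysis of a template segment
#'
#' For each complete codon of the template (in the reading frame of the
#' VR-containing target gene), enumerates all `4^k` substitutions of its `k`
#' adenine positions, translates each variant, and records the set of
#' reachable amino acids, whether a stop codon is reachable, whether the
#' codon is AAY (AAT/AAC, the maximally diversifiable case), and whether it
#' is diversifiable (at least one adenine and at least two reachable amino
#' acids). Partial codons at the segment edges are skipped and reported via
#' the `n_skipped_edge_bases` attribute.
#'
#' @param tr_segment template DNA string (A/C/G/T), read in VR orientation.
#' @param frame_offset number of 5' bases to skip so that codons align with
#'   the target-gene reading frame (0, 1 or 2).
#' @param genetic_code NCBI genetic code id.
#' @return data.frame with one row per complete codon: `codon_index`
#'   (0-based), `tr_codon`, list-columns `adenine_positions` (0-based within
#'   codon) and `reachable_aa`, and logicals `stop_reachable`, `is_aay`,
#'   `diversifiable`.
#' @export
codon_diversity <- function(tr_segment, frame_offset = 0, genetic_code = 11) {
  stopifnot(frame_offset %in% 0:2)
  tr_segment <- toupper(tr_segment)
  if (grepl("[^ACGT]", tr_segment)) stop("tr_segment contains non-ACGT characters")
  body <- substr(tr_segment, frame_offset + 1L, nchar(tr_segment))
  n_cod <- nchar(body) %/% 3L
  if (n_cod < 1L) stop("segment too short after frame offset: no complete codon")
  code <- genetic_code_table(genetic_code)
  bases <- c("A", "C", "G", "T")
  rows <- vector("list", n_cod)
  for (ci in seq_len(n_cod)) {
    codon <- substr(body, 3L * ci - 2L, 3L * ci)
    cc <- seq_chars(codon)
    apos <- which(cc == "A")
    k <- length(apos)
    if (k == 0L) {
      aas <- unname(code[codon])
      stop_reach <- aas == "*"
      reach <- setdiff(aas, "*")
    } else {
      grid <- expand.grid(rep(list(bases), k), stringsAsFactors = FALSE)
      variants <- apply(grid, 1, function(sub) {
        v <- cc; v[apos] <- sub; paste(v, collapse = "")
      })
      aas <- unname(code[variants])
      stop_reach <- any(aas == "*")
      reach <- unique(setdiff(aas, "*"))
    }
    rows[[ci]] <- data.frame(
      codon_index = ci - 1L, tr_codon = codon,
      adenine_positions = I(list(apos - 1L)),
      reachable_aa = I(list(sort(reach))),
      n_reachable_aa = length(reach),
      stop_reachable = isTRUE(any(stop_reach)),
      is_aay = codon %in% c("AAT", "AAC"),
      diversifiable = k >= 1L && length(reach) >= 2L,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_skipped_edge_bases") <- frame_offset + (nchar(body) - 3L * n_cod)
  out
}

#' Exact count of protein variants reachable by adenine mutagenesis
#'
#' The product over codons of the number of distinct reachable amino acids
#' (stops excluded from the sets; codons with no adenines contribute their
#' single amino acid). Per-codon choices are independent, so the product
#' equals the number of distinct proteins over all nucleotide variants.
#'
#' @param codons data.frame from [codon_diversity()].
#' @return a `dgr_bigint`.
#' @export
protein_variant_count <- function(codons) {
  bigint_prod(codons$n_reachable_aa)
}

#' Summarize the diversification potential of a DGR cassette
#'
#' Uses the TR segment aligned to VR, read in the target gene's frame, to
#' compute the adenine census, exact nucleotide and protein variant counts,
#' diversifiable / AAY codon counts, and the nonsense-mutation risk flag.
#' All counts are exact integers.
#'
#' @param cassette a `dgr_cassette` with a passing TR/VR call and a TP ORF,
#'   or `NULL` if `tr_segment` is given directly.
#' @param tr_segment,frame_offset direct inputs bypassing the cassette.
#' @param genetic_code NCBI genetic code id.
#' @return a `diversity_summary` list: `n_adenines`, `n_nt_variants`,
#'   `codons`, `n_diversifiable_codons`, `n_aay_codons`,
#'   `n_protein_variants`, `nonsense_risk`.
#' @export
summarize_diversity <- function(cassette = NULL, tr_segment = NULL,
                                frame_offset = NULL, genetic_code = 11) {
  if (is.null(tr_segment)) {
    stopifnot(inherits(cassette, "dgr_cassette"))
    call <- cassette$trvr
    if (!call$passed) stop("cassette has no passing TR/VR call")
    tp <- cassette$tp_orf
    if (is.null(tp)) stop("frame-unknown: cassette has no TP ORF")
    tr_segment <- tr_aligned_to_vr(call)
    vr <- call$vr
    if (tp$strand == "+") {
      phase <- (vr$start - tp$start) %% 3
    } else {
      tr_segment <- revcomp(tr_segment)
      phase <- (tp$end - vr$end) %% 3
    }
    frame_offset <- (3L - phase) %% 3L
  }
  stopifnot(!is.null(frame_offset))
  n_a <- count_template_adenines(tr_segment)
  codons <- codon_diversity(tr_segment, frame_offset, genetic_code)
  structure(list(
    n_adenines = n_a,
    n_nt_variants = nucleotide_variant_count(n_a),
    codons = codons,
    n_diversifiable_codons = sum(codons$diversifiable),
    n_aay_codons = sum(codons$is_aay),
    n_protein_variants = protein_variant_count(codons),
    nonsense_risk = any(codons$stop_reachable)
  ), class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf(
    "<diversity_summary> %d adenines; 4^%d = %s nucleotide variants\n  %d/%d codons diversifiable (%d AAY); %s protein variants; nonsense risk: %s\n",
    x$n_adenines, x$n_adenines, bigint_str(x$n_nt_variants),
    x$n_diversifiable_codons, nrow(x$codons), x$n_aay_codons,
    bigint_str(x$n_protein_variants), x$nonsense_risk))
  invisible(x)
}
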