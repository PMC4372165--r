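#' Locate the IMH / IMH* terminal motif pair
#'
#' DGR retrohoming requires an initiation-of-mutagenic-homing (IMH) motif at
#' the 3' end of VR and a cognate IMH* at the 3' end of TR. Both sequences
#' are scanned in a window of `search_span` bp on either side of their 3'
#' boundary; a hit is reported only when an IMH motif in VR and its paired
#' IMH* in TR occur at alignment-consistent offsets (|difference| <= 5). The
#' 3'-most consistent hit is returned. Anchoring at the 3' boundary makes the
#' result invariant to extra 5' context.
#'
#' @param vr_seq_with_flank VR sequence with `vr_flank_len` bp of 3' flank
#'   appended.
#' @param tr_seq_with_flank TR sequence with `tr_flank_len` bp of 3' flank,
#'   in the orientation that aligns with VR.
#' @param motif_pairs list of c(IMH, IMH*) motif string pairs.
#' @param search_span bp scanned on each side of the 3' boundary.
#' @param vr_flank_len,tr_flank_len flank lengths actually appended
#'   (default `search_span`).
#' @param max_offset_diff allowed |IMH offset - IMH* offset|.
#' @return `NULL` when absent, else a list with `imh` and `imh_star` (each
#'   `motif` + `offset` of the motif start relative to the repeat's 3'
#'   boundary; 0 means the motif starts right at the boundary) and
#'   `motif_pair_name`.
#' @export
find_imh <- function(vr_seq_with_flank, tr_seq_with_flank,
                     motif_pairs = list(c("TGGGGT", "TGGAAT")),
                     search_span = 40,
                     vr_flank_len = search_span, tr_flank_len = search_span,
                     max_offset_diff = 5) {
  scan_one <- function(seq_fl, flank_len, motif) {
    # offsets of motif start relative to the 3' boundary of the repeat
    bnd <- nchar(seq_fl) - flank_len            # 1-based index of last repeat base
    g <- gregexpr(motif, seq_fl, fixed = TRUE)[[1]]
    if (g[1] < 0) return(integer(0))
    off <- as.integer(g) - bnd - 1L             # 0 = starts immediately after boundary
    off[off >= -search_span & off + nchar(motif) <= flank_len]
  }
  best <- NULL
  for (mp in motif_pairs) {
    ov <- scan_one(vr_seq_with_flank, vr_flank_len, mp[1])
    ot <- scan_one(tr_seq_with_flank, tr_flank_len, mp[2])
    if (length(ov) == 0L || length(ot) == 0L) next
    for (o1 in sort(ov, decreasing = TRUE)) {
      cons <- ot[abs(ot - o1) <= max_offset_diff]
      if (length(cons) == 0L) next
      o2 <- cons[which.min(abs(cons - o1))]
      cand <- list(imh = list(motif = mp[1], offset = o1),
                   imh_star = list(motif = mp[2], offset = o2),
                   motif_pair_name = paste(mp[1], mp[2], sep = "/"))
      if (is.null(best) || o1 > best$imh$offset) best <- cand
      break
    }
  }
  best
}

#' Enumerate stem-loop (hairpin) structures in a DNA region
#'
#' Finds all maximal exact-reverse-complement stem-loops: arm lengths in
#' `[stem_min, stem_max]`, loop lengths in `[loop_min, loop_max]`. A hairpin
#' is maximal when its stem cannot be lengthened by one base outward (same
#' loop) or inward (loop shrinks by two) without leaving the bounds. Loops
#' are classified `GRA` (3 nt, G-[AG]-A), `GRNA` (4 nt, G-[AG]-N-A) or
#' `other`.
#'
#' @param region_seq DNA string to search.
#' @param stem_min,stem_max arm length bounds (bp).
#' @param loop_min,loop_max loop length bounds (nt).
#' @param require_loop_class optional filter: keep only this `loop_class`.
#' @return data.frame sorted by stem length (descending) then position:
#'   `start`, `end` (0-based half-open within `region_seq`), `stem_len`,
#'   `loop_seq`, `loop_class`.
#' @export
find_hairpins <- function(region_seq, stem_min = 4, stem_max = 12,
                          loop_min = 3, loop_max = 8,
                          require_loop_class = NULL) {
  region_seq <- toupper(region_seq)
  n <- nchar(region_seq)
  stopifnot(n >= 2 * stem_min + loop_min)
  x <- seq_chars(region_seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "#")  # N pairs with nothing
  is_pair <- function(a, b) !is.na(comp[a]) && comp[[a]] == b
  valid <- function(i, s, l) {
    # arms [i, i+s), loop [i+s, i+s+l), arm2 [i+s+l, i+s+l+s), 1-based i
    if (i < 1L || i + 2L * s + l - 1L > n) return(FALSE)
    for (t in seq_len(s)) {
      if (!is_pair(x[i + t - 1L], x[i + 2L * s + l - t])) return(FALSE)
    }
    TRUE
  }
  rows <- list()
  for (s in seq(stem_min, stem_max)) {
    for (l in seq(loop_min, loop_max)) {
      tot <- 2L * s + l
      if (tot > n) next
      for (i in seq_len(n - tot + 1L)) {
        if (!valid(i, s, l)) next
        # maximality: no outward or inward one-step stem growth
        if (s < stem_max && valid(i - 1L, s + 1L, l)) next
        if (s < stem_max && l - 2L >= loop_min && valid(i, s + 1L, l - 2L)) next
        loop <- substr(region_seq, i + s, i + s + l - 1L)
        cls <- if (l == 3L && grepl("^G[AG]A$", loop)) "GRA"
               else if (l == 4L && grepl("^G[AG][ACGT]A$", loop)) "GRNA"
               else "other"
        rows[[length(rows) + 1L]] <- data.frame(
          start = i - 1L, end = i + tot - 1L, stem_len = s,
          loop_seq = loop, loop_class = cls, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), stem_len = integer(0),
               loop_seq = character(0), loop_class = character(0),
               stringsAsFactors = FALSE)
  if (!is.null(require_loop_class)) out <- out[out$loop_class == require_loop_class, , drop = FALSE]
  out <- out[order(-out$stem_len, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# fixed charge model for pI: pKa values used throughout the package
PKA_TABLE <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

# average residue masses (Da); peptide MW = sum + one water (18.02)
RESIDUE_MASS <- c(
  G = 57.05, A = 71.08, S = 87.08, P = 97.12, V = 99.13, T = 101.10,
  C = 103.14, L = 113.16, I = 113.16, N = 114.10, D = 115.09, Q = 128.13,
  K = 128.17, E = 129.12, M = 131.19, H = 137.14, F = 147.18, R = 156.19,
  Y = 163.18, W = 186.21
)

# Henderson-Hasselbalch net charge of a protein at a given pH
protein_net_charge <- function(protein, ph) {
  aa <- seq_chars(protein)
  pos_pka <- c(PKA_TABLE$nterm, unname(PKA_TABLE$positive[aa[aa %in% names(PKA_TABLE$positive)]]))
  neg_pka <- c(PKA_TABLE$cterm, unname(PKA_TABLE$negative[aa[aa %in% names(PKA_TABLE$negative)]]))
  sum(1 / (1 + 10^(ph - pos_pka))) - sum(1 / (1 + 10^(neg_pka - ph)))
}

#' Isoelectric point of a protein
#'
#' Solves net charge = 0 by bisection on pH in [0, 14] under a fixed pKa
#' model (N-terminus 8.6, C-terminus 3.6, C 8.5, D 3.9, E 4.1, H 6.5,
#' K 10.8, R 12.5, Y 10.1).
#'
#' @param protein amino-acid string (one-letter codes, no internal stops).
#' @param tol bisection stops when |net charge| < tol.
#' @return pI in pH units.
#' @export
protein_pi <- function(protein, tol = 1e-4) {
  if (grepl("*", protein, fixed = TRUE)) stop("internal stop '*' in protein sequence")
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- protein_net_charge(protein, mid)
    if (abs(q) < tol || (hi - lo) < 1e-10) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Molecular weight of a protein in kDa
#' @param protein amino-acid string.
#' @return average molecular weight in kDa (residue masses + 18.02 Da water).
#' @export
protein_mw_kda <- function(protein) {
  if (grepl("*", protein, fixed = TRUE)) stop("internal stop '*' in protein sequence")
  aa <- seq_chars(protein)
  bad <- setdiff(aa, names(RESIDUE_MASS))
  if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ","))
  (sum(RESIDUE_MASS[aa]) + 18.02) / 1000
}

#' Select Avd-like accessory ORFs by isoelectric point and molecular weight
#'
#' The accessory variability determinant (Avd) is a small basic protein;
#' candidate ORFs between RT and the target gene are kept when their
#' computed pI and MW fall within `pi_center +- pi_tol` and
#' `mw_center_kda +- mw_tol_kda`.
#'
#' @param orfs ORF data.frame (needs a `protein` column).
#' @param pi_center,pi_tol pI acceptance window (pH units).
#' @param mw_center_kda,mw_tol_kda MW acceptance window (kDa).
#' @return the accepted rows with added `pI` and `mw_kda` columns.
#' @export
find_avd_candidates <- function(orfs, pi_center = 9, pi_tol = 1,
                                mw_center_kda = 10, mw_tol_kda = 5) {
  empty <- cbind(orfs[0, , drop = FALSE], data.frame(pI = numeric(0), mw_kda = numeric(0)))
  if (is.null(orfs) || nrow(orfs) == 0L) return(empty)
  prot <- sub("\\*$", "", orfs$protein)
  pI <- vapply(prot, protein_pi, numeric(1), USE.NAMES = FALSE)
  mw <- vapply(prot, protein_mw_kda, numeric(1), USE.NAMES = FALSE)
  keep <- abs(pI - pi_center) <= pi_tol & abs(mw - mw_center_kda) <= mw_tol_kda
  out <- orfs[keep, , drop = FALSE]
  out$pI <- pI[keep]
  out$mw_kda <- mw[keep]
  rownames(out) <- NULL
  out
}
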