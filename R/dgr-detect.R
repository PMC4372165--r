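# extract a 0-based half-open genomic slice, optionally reverse-complemented
extract_seq <- function(record, start, end, strand = "+") {
  s <- substr0(as_record(record)$sequence, start, end)
  if (strand == "-") revcomp(s) else s
}

#' Scan ORFs for reverse-transcriptase-like candidates
#'
#' Deterministic motif-based stand-in for database homology search: an ORF is
#' emitted when its protein matches at least `min_motifs` of the configured
#' patterns. The default pattern `[YF].[DA]D` covers the catalytic
#' YxDD/FxDD box of retroelement RTs.
#'
#' @param orfs ORF data.frame from [find_orfs()].
#' @param motifs named character vector of protein regular expressions.
#' @param min_motifs minimum number of distinct motifs matched.
#' @param min_protein_len minimum protein length to consider.
#' @return data.frame of candidates: ORF columns plus `motif_hits`
#'   (list-column of data.frames with `motif`, `position` 1-based) and
#'   `score` (number of distinct motifs matched).
#' @export
scan_rt_candidates <- function(orfs,
                               motifs = c(rt_catalytic = "[YF].[DA]D"),
                               min_motifs = 1,
                               min_protein_len = 100) {
  stopifnot(length(motifs) >= 1)
  empty <- cbind(orfs[0, , drop = FALSE],
                 data.frame(motif_hits = I(list()), score = integer(0)))
  if (is.null(orfs) || nrow(orfs) == 0L) return(empty)
  keep <- nchar(orfs$protein) >= min_protein_len
  orfs <- orfs[keep, , drop = FALSE]
  if (nrow(orfs) == 0L) return(empty)
  hits <- vector("list", nrow(orfs))
  score <- integer(nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    h <- list()
    for (m in names(motifs)) {
      g <- gregexpr(motifs[[m]], orfs$protein[i])[[1]]
      if (g[1] > 0) h[[m]] <- data.frame(motif = m, position = as.integer(g),
                                         stringsAsFactors = FALSE)
    }
    score[i] <- length(h)
    hits[[i]] <- if (length(h)) do.call(rbind, h) else
      data.frame(motif = character(0), position = integer(0))
  }
  out <- orfs[score >= min_motifs, , drop = FALSE]
  out$motif_hits <- I(hits[score >= min_motifs])
  out$score <- score[score >= min_motifs]
  rownames(out) <- NULL
  out
}

# ungapped X-drop seed extension on a fixed diagonal of (xa, ya); 1-based
# exact seed (i, j, len k). Scored match +1 / mismatch -2; each direction
# stops once the running score falls `xdrop` below its maximum and the
# alignment ends at the maximum-scoring columns, so boundaries sit at the
# true edge of homology instead of drifting into random flanking sequence.
# N matches nothing. max_len caps total length (keeps direct copies disjoint).
extend_seed <- function(xa, ya, i, j, k, mismatch_penalty = 2, xdrop = 20,
                        max_len = Inf) {
  nx <- length(xa); ny <- length(ya)
  step_score <- function(cx, cy) {
    if (cx == cy && cx != "N") 1 else -mismatch_penalty
  }
  # right of the seed
  best_r <- 0L; sc <- 0; best_sc <- 0; t <- 0L
  while (i + k + t <= nx && j + k + t <= ny && k + t < max_len) {
    sc <- sc + step_score(xa[i + k + t], ya[j + k + t])
    t <- t + 1L
    if (sc > best_sc) { best_sc <- sc; best_r <- t }
    if (sc <= best_sc - xdrop) break
  }
  # left of the seed
  best_l <- 0L; sc <- 0; best_sc <- 0; t <- 0L
  while (i - t > 1L && j - t > 1L && k + best_r + t < max_len) {
    sc <- sc + step_score(xa[i - t - 1L], ya[j - t - 1L])
    t <- t + 1L
    if (sc > best_sc) { best_sc <- sc; best_l <- t }
    if (sc <= best_sc - xdrop) break
  }
  i <- i - best_l; j <- j - best_l
  len <- k + best_l + best_r
  mm <- sum(xa[i:(i + len - 1L)] != ya[j:(j + len - 1L)] |
              xa[i:(i + len - 1L)] == "N")
  list(i = i, j = j, len = len, mm = mm)
}

# seed positions (1-based) of exact k-mers without N
kmer_table <- function(s, k, max_occ = 100L) {
  n <- nchar(s)
  if (n < k) return(list())
  pos <- seq_len(n - k + 1L)
  km <- substring(s, pos, pos + k - 1L)
  ok <- !grepl("N", km, fixed = TRUE)
  tab <- split(pos[ok], km[ok])
  tab[lengths(tab) <= max_occ]
}

#' Find repeat pairs near an anchoring locus
#'
#' Seed-and-extend search for direct and inverted repeat pairs within
#' `window_bp` of an anchor (typically an RT candidate). Exact `seed_len`-mers
#' are extended ungapped in both directions with X-drop scoring (match +1,
#' mismatch -2), ending each alignment at its maximum-scoring columns so
#' that boundaries track the true extent of homology; alignments whose
#' overall mismatch fraction exceeds `max_mismatch_frac` are discarded.
#' Overlapping extensions on one diagonal are merged; self-trivial matches
#' are excluded. `N` matches nothing.
#'
#' @param record a `genome_record`.
#' @param anchor list or data.frame row with `start`, `end` (0-based
#'   half-open), e.g. an RT candidate from [scan_rt_candidates()].
#' @param window_bp search span on each side of the anchor.
#' @param min_repeat_len minimum aligned length to report.
#' @param seed_len exact seed length.
#' @param max_mismatch_frac maximum running mismatch fraction during
#'   extension.
#' @return data.frame of pairs sorted by `copyA_start`: `record_id`,
#'   `copyA_start`, `copyA_end`, `copyB_start`, `copyB_end` (0-based
#'   half-open, forward coordinates), `orientation` ("direct"/"inverted"),
#'   `aligned_len`, `n_mismatch`, and alignment strings `alnA`, `alnB`
#'   (`alnB` is the reverse complement of copyB for inverted pairs, so the
#'   two strings align column by column).
#' @export
find_repeat_pairs <- function(record, anchor, window_bp = 5000,
                              min_repeat_len = 50, seed_len = 12,
                              max_mismatch_frac = 0.25) {
  record <- as_record(record)
  stopifnot(window_bp > 0, min_repeat_len >= seed_len)
  L <- nchar(record$sequence)
  a_start <- anchor$start; a_end <- anchor$end
  if (is.null(a_start) || a_start < 0 || a_end > L) stop("anchor outside record bounds")
  w0 <- max(0L, as.integer(a_start) - as.integer(window_bp))
  w1 <- min(L, as.integer(a_end) + as.integer(window_bp))
  W <- substr0(record$sequence, w0, w1)
  n <- nchar(W)
  empty <- data.frame(record_id = character(0), copyA_start = integer(0),
                      copyA_end = integer(0), copyB_start = integer(0),
                      copyB_end = integer(0), orientation = character(0),
                      aligned_len = integer(0), n_mismatch = integer(0),
                      alnA = character(0), alnB = character(0),
                      stringsAsFactors = FALSE)
  if (n < 2L * min_repeat_len) return(empty)
  xa <- seq_chars(W)
  tab <- kmer_table(W, seed_len)
  rows <- list()

  add_row <- function(Ast, Alen, Bst, Blen, orient, alnA, alnB, mm) {
    rows[[length(rows) + 1L]] <<- data.frame(
      record_id = record$id,
      copyA_start = w0 + Ast - 1L, copyA_end = w0 + Ast - 1L + Alen,
      copyB_start = w0 + Bst - 1L, copyB_end = w0 + Bst - 1L + Blen,
      orientation = orient, aligned_len = Alen, n_mismatch = mm,
      alnA = alnA, alnB = alnB, stringsAsFactors = FALSE)
  }

  # direct repeats: W vs itself, diagonals d = j - i > 0; alignment length
  # capped at d so the two copies never overlap
  seen <- new.env(parent = emptyenv())
  for (ps in tab) {
    if (length(ps) < 2L) next
    for (u in seq_len(length(ps) - 1L)) {
      for (v in seq((u + 1L), length(ps))) {
        i <- ps[u]; j <- ps[v]; d <- j - i
        if (d == 0L) next
        key <- as.character(d)
        iv <- get0(key, envir = seen, ifnotfound = NULL)
        if (!is.null(iv) && i >= iv[1] && i < iv[2]) next
        e <- extend_seed(xa, xa, i, j, seed_len, max_len = d)
        assign(key, c(e$i, e$i + e$len), envir = seen)
        if (e$len >= min_repeat_len && e$mm / e$len <= max_mismatch_frac) {
          add_row(e$i, e$len, e$j, e$len, "direct",
                  substr(W, e$i, e$i + e$len - 1L), substr(W, e$j, e$j + e$len - 1L),
                  e$mm)
        }
      }
    }
  }

  # inverted repeats: W vs revcomp(W); a match of X[i..] with Y[j..] maps
  # copyB to forward interval [n - j - len + 2, n - j + 1] (1-based)
  Y <- revcomp(W)
  ya <- seq_chars(Y)
  tabY <- kmer_table(Y, seed_len)
  seenI <- new.env(parent = emptyenv())
  for (km in names(tab)) {
    psY <- tabY[[km]]
    if (is.null(psY)) next
    for (i in tab[[km]]) {
      for (j in psY) {
        key <- as.character(j - i)
        iv <- get0(key, envir = seenI, ifnotfound = NULL)
        if (!is.null(iv) && i >= iv[1] && i < iv[2]) next
        e <- extend_seed(xa, ya, i, j, seed_len)
        assign(key, c(e$i, e$i + e$len), envir = seenI)
        if (e$len < min_repeat_len || e$mm / e$len > max_mismatch_frac) next
        bs <- n - e$j - e$len + 2L            # 1-based forward start of copyB
        # exclude self-overlap (palindromes) and keep canonical order A < B
        if (e$i > bs) next
        if (e$i + e$len - 1L >= bs) next
        add_row(e$i, e$len, bs, e$len, "inverted",
                substr(W, e$i, e$i + e$len - 1L), substr(Y, e$j, e$j + e$len - 1L),
                e$mm)
      }
    }
  }

  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  # merge near-duplicates: same orientation with both copies overlapping an
  # already-kept (longer) pair
  out <- out[order(-out$aligned_len), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) for (j in seq(i + 1L, nrow(out))) {
      if (!keep[j] || out$orientation[j] != out$orientation[i]) next
      ovA <- out$copyA_start[j] < out$copyA_end[i] && out$copyA_end[j] > out$copyA_start[i]
      ovB <- out$copyB_start[j] < out$copyB_end[i] && out$copyB_end[j] > out$copyB_start[i]
      if (ovA && ovB) keep[j] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[out$copyA_end <= out$copyB_start | out$copyB_end <= out$copyA_start, , drop = FALSE]
  out <- out[order(out$copyA_start, out$copyB_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-column mismatch bookkeeping for an ungapped repeat alignment
mismatch_profile <- function(alnA, alnB) {
  a <- seq_chars(alnA); b <- seq_chars(alnB)
  stopifnot(length(a) == length(b))
  mm <- which(a != b | a == "N" | b == "N")
  positions <- data.frame(alignment_column = mm, baseA = a[mm], baseB = b[mm],
                          stringsAsFactors = FALSE)
  list(
    positions = positions,
    n_adenine_wrt_A = sum(a[mm] == "A"),
    n_other_wrt_A = length(mm) - sum(a[mm] == "A"),
    n_adenine_wrt_B = sum(b[mm] == "A"),
    n_other_wrt_B = length(mm) - sum(b[mm] == "A"),
    aligned_len = length(a)
  )
}

#' Classify a repeat pair as template/variable (TR/VR)
#'
#' Applies the adenine-specific variability rule: a copy qualifies as the
#' template (TR) when the alignment shows at least `min_adenine_mm` mismatch
#' columns where that copy carries an adenine, and at most
#' `max_other_per_100bp` non-adenine mismatches per 100 bp of aligned
#' sequence. Both copies are tested; if exactly one qualifies it becomes TR
#' and the other VR. If both qualify, the copy with more adenine-specific
#' mismatches wins (a tie is rejected as "ambiguous-template").
#'
#' @param pair one row of [find_repeat_pairs()] output (or an equivalent
#'   list with `alnA`, `alnB`, coordinate and orientation fields).
#' @param min_adenine_mm absolute minimum adenine-specific mismatch count.
#' @param max_other_per_100bp allowed non-adenine mismatches per 100 bp;
#'   scaled linearly with aligned length (real-valued threshold).
#' @return a `trvr_call` list: `tr`, `vr` (lists with `start`, `end`),
#'   `tr_copy` ("A"/"B"), `template_strand` ("+" for direct pairs, "-" for
#'   inverted), `profile`, `passed`, `reasons`, and the echoed `pair`.
#' @export
classify_tr_vr <- function(pair, min_adenine_mm = 10, max_other_per_100bp = 2) {
  if (is.data.frame(pair)) pair <- as.list(pair[1, ])
  prof <- mismatch_profile(pair$alnA, pair$alnB)
  allow_other <- max_other_per_100bp * prof$aligned_len / 100
  passA <- prof$n_adenine_wrt_A >= min_adenine_mm && prof$n_other_wrt_A <= allow_other
  passB <- prof$n_adenine_wrt_B >= min_adenine_mm && prof$n_other_wrt_B <= allow_other
  tr_copy <- NA_character_
  reasons <- character(0)
  if (passA && passB) {
    if (prof$n_adenine_wrt_A > prof$n_adenine_wrt_B) tr_copy <- "A"
    else if (prof$n_adenine_wrt_B > prof$n_adenine_wrt_A) tr_copy <- "B"
    else reasons <- "ambiguous-template"
  } else if (passA) tr_copy <- "A"
  else if (passB) tr_copy <- "B"
  else {
    if (max(prof$n_adenine_wrt_A, prof$n_adenine_wrt_B) < min_adenine_mm)
      reasons <- c(reasons, sprintf("adenine-mismatches<%d", min_adenine_mm))
    if (min(prof$n_other_wrt_A, prof$n_other_wrt_B) > allow_other)
      reasons <- c(reasons, "non-adenine-excess")
    if (length(reasons) == 0L) reasons <- "adenine-criterion-unmet"
  }
  passed <- !is.na(tr_copy)
  ivA <- list(start = pair$copyA_start, end = pair$copyA_end)
  ivB <- list(start = pair$copyB_start, end = pair$copyB_end)
  structure(list(
    tr = if (passed) (if (tr_copy == "A") ivA else ivB) else NULL,
    vr = if (passed) (if (tr_copy == "A") ivB else ivA) else NULL,
    tr_copy = tr_copy,
    template_strand = if (identical(pair$orientation, "inverted")) "-" else "+",
    orientation = pair$orientation %||% "direct",
    profile = prof,
    passed = passed,
    reasons = reasons,
    pair = pair
  ), class = "trvr_call")
}

# TR sequence read in the orientation that aligns with VR's forward-genomic
# reading (alignment strings already pair copyA with copyB-or-its-revcomp)
tr_aligned_to_vr <- function(call) {
  p <- call$pair
  if (call$tr_copy == "A") {
    # VR is copyB; alnB is VR forward for direct, revcomp(VR) for inverted
    if (call$orientation == "inverted") revcomp(p$alnA) else p$alnA
  } else {
    p$alnB  # already aligned column-wise to alnA == VR forward
  }
}

#' Assemble DGR cassettes from classified repeat pairs
#'
#' For each passing TR/VR call the target-protein (TP) gene is the ORF that
#' contains VR in frame (the longest such ORF when several qualify);
#' cassettes whose TR lies inside the chosen TP are rejected ("TR-coding");
#' cassettes sharing a VR interval are merged. When `find_cis = TRUE`, IMH /
#' IMH* motifs, the downstream stem-loop and Avd-like ORFs between RT and TP
#' are located and attached.
#'
#' @param record a `genome_record`.
#' @param rt RT candidate row (or `NULL` for anchor-free partial cassettes).
#' @param calls list of `trvr_call`s from [classify_tr_vr()].
#' @param orfs ORF data.frame for the record.
#' @param find_cis attach cis-element results?
#' @param imh_motif_pairs,imh_search_span passed to [find_imh()].
#' @return list of `dgr_cassette` lists with fields `record_id`, `rt`,
#'   `trvr`, `tp_orf`, `imh`, `hairpin`, `avd`, `complete`, `flags`.
#' @export
assemble_cassette <- function(record, rt, calls, orfs, find_cis = TRUE,
                              imh_motif_pairs = list(c("TGGGGT", "TGGAAT")),
                              imh_search_span = 40) {
  record <- as_record(record)
  L <- nchar(record$sequence)
  cassettes <- list()
  for (call in calls) {
    if (!inherits(call, "trvr_call") || !call$passed) next
    vr <- call$vr; tr <- call$tr
    flags <- character(0)
    # the target gene is the ORF containing VR; codons overlapping VR are
    # read in that ORF's frame (detected repeat boundaries carry bp-level
    # noise, so no codon-phase restriction is imposed on the VR start)
    cand <- orfs[orfs$start <= vr$start & orfs$end >= vr$end, , drop = FALSE]
    tp <- NULL
    if (nrow(cand) >= 1L) {
      if (nrow(cand) > 1L) flags <- c(flags, sprintf("multiple-TP-candidates:%d", nrow(cand)))
      tp <- as.list(cand[which.max(cand$end - cand$start), ])
    } else flags <- c(flags, "no-TP")
    if (!is.null(tp) && tr$start >= tp$start && tr$end <= tp$end) next  # TR-coding: reject
    imh <- NULL; hairpin <- NULL; avd <- NULL
    if (find_cis && !is.null(tp)) {
      tp_strand <- tp$strand
      if (tp_strand == "+") {
        fl_vr <- min(imh_search_span, L - vr$end)
        vr_fl <- substr0(record$sequence, vr$start, vr$end + fl_vr)
      } else {
        fl_vr <- min(imh_search_span, vr$start)
        vr_fl <- revcomp(substr0(record$sequence, vr$start - fl_vr, vr$end))
      }
      tr_strand <- if (call$template_strand == "+") tp_strand else setdiff(c("+", "-"), tp_strand)
      if (tr_strand == "+") {
        fl_tr <- min(imh_search_span, L - tr$end)
        tr_fl <- substr0(record$sequence, tr$start, tr$end + fl_tr)
      } else {
        fl_tr <- min(imh_search_span, tr$start)
        tr_fl <- revcomp(substr0(record$sequence, tr$start - fl_tr, tr$end))
      }
      imh <- find_imh(vr_fl, tr_fl, motif_pairs = imh_motif_pairs,
                      search_span = imh_search_span,
                      vr_flank_len = fl_vr, tr_flank_len = fl_tr)
      if (!is.null(imh)) {
        # map offsets (relative to the repeat 3' boundary) to genomic coords
        mlen <- nchar(imh$imh$motif)
        imh$imh$interval <- if (tp_strand == "+")
          list(start = vr$end + imh$imh$offset, end = vr$end + imh$imh$offset + mlen)
        else list(start = vr$start - imh$imh$offset - mlen, end = vr$start - imh$imh$offset)
        mlen2 <- nchar(imh$imh_star$motif)
        imh$imh_star$interval <- if (tr_strand == "+")
          list(start = tr$end + imh$imh_star$offset, end = tr$end + imh$imh_star$offset + mlen2)
        else list(start = tr$start - imh$imh_star$offset - mlen2, end = tr$start - imh$imh_star$offset)
      }
      # stem-loop inside the TP gene downstream of VR
      region <- if (tp_strand == "+") {
        list(seq = substr0(record$sequence, vr$end, tp$end), off = vr$end)
      } else {
        list(seq = revcomp(substr0(record$sequence, tp$start, vr$start)), off = NA)
      }
      if (nchar(region$seq) >= 11L) {
        hp <- find_hairpins(region$seq)
        if (nrow(hp) > 0L) {
          h <- as.list(hp[1, ])
          if (tp_strand == "+") {
            h$genomic_start <- region$off + h$start
            h$genomic_end <- region$off + h$end
          } else {
            h$genomic_start <- vr$start - h$end
            h$genomic_end <- vr$start - h$start
          }
          hairpin <- h
        }
      }
      if (!is.null(rt)) {
        gap_lo <- min(tp$end, rt$end); gap_hi <- max(tp$start, rt$start)
        between <- orfs[orfs$start >= gap_lo & orfs$end <= gap_hi, , drop = FALSE]
        between <- between[!(between$start == tp$start & between$end == tp$end), , drop = FALSE]
        avd_all <- find_avd_candidates(between)
        if (nrow(avd_all) > 0L) avd <- avd_all
      }
    }
    cassettes[[length(cassettes) + 1L]] <- structure(list(
      record_id = record$id,
      rt = if (is.null(rt)) NULL else as.list(rt),
      trvr = call,
      tp_orf = tp,
      imh = imh,
      hairpin = hairpin,
      avd = avd,
      complete = !is.null(rt) && call$passed,
      flags = if (is.null(rt)) c(flags, "partial-DGR") else flags
    ), class = "dgr_cassette")
  }
  # merge cassettes sharing a VR interval (keep the first)
  if (length(cassettes) > 1L) {
    key <- vapply(cassettes, function(cc) paste(cc$trvr$vr$start, cc$trvr$vr$end), character(1))
    cassettes <- cassettes[!duplicated(key)]
  }
  cassettes
}

#' Detect DGR cassettes in one genome record
#'
#' End-to-end per-record pipeline: six-frame ORF scan, RT candidate scan,
#' repeat-pair discovery around each anchor, TR/VR classification, and
#' cassette assembly with cis elements. User-supplied anchors (e.g. from a
#' BED file) can replace or supplement the motif scan.
#'
#' @param record a `genome_record` (or bare DNA string).
#' @param min_rt_protein_len minimum RT protein length (residues).
#' @param window_bp,min_repeat_len,seed_len,max_mismatch_frac see
#'   [find_repeat_pairs()].
#' @param min_adenine_mm,max_other_per_100bp see [classify_tr_vr()].
#' @param anchors optional data.frame of loci (`start`, `end`) used as
#'   anchors instead of the RT motif scan (each is still reported with any
#'   overlapping RT candidate).
#' @param genetic_code NCBI genetic code id.
#' @return list with `orfs`, `rt_candidates`, `pairs` (all repeat pairs),
#'   `calls` (all TR/VR calls, passing or not) and `cassettes`.
#' @export
detect_dgr <- function(record,
                       min_rt_protein_len = 100,
                       window_bp = 5000, min_repeat_len = 50, seed_len = 12,
                       max_mismatch_frac = 0.25,
                       min_adenine_mm = 10, max_other_per_100bp = 2,
                       anchors = NULL, genetic_code = 11) {
  record <- as_record(record)
  orfs <- find_orfs(record, min_protein_len = 30, genetic_code = genetic_code)
  rts <- scan_rt_candidates(orfs, min_protein_len = min_rt_protein_len)
  anchor_list <- list()
  if (!is.null(anchors)) {
    for (i in seq_len(nrow(anchors))) {
      anchor_list[[length(anchor_list) + 1L]] <-
        list(anchor = as.list(anchors[i, ]), rt = NULL)
    }
  }
  if (nrow(rts) > 0L) for (i in seq_len(nrow(rts))) {
    anchor_list[[length(anchor_list) + 1L]] <-
      list(anchor = as.list(rts[i, c("start", "end")]), rt = as.list(rts[i, ]))
  }
  pairs_all <- list(); calls_all <- list(); cassettes <- list()
  for (an in anchor_list) {
    pairs <- find_repeat_pairs(record, an$anchor, window_bp = window_bp,
                               min_repeat_len = min_repeat_len,
                               seed_len = seed_len,
                               max_mismatch_frac = max_mismatch_frac)
    if (nrow(pairs) > 0L) pairs_all[[length(pairs_all) + 1L]] <- pairs
    calls <- lapply(seq_len(nrow(pairs)), function(k)
      classify_tr_vr(pairs[k, ], min_adenine_mm = min_adenine_mm,
                     max_other_per_100bp = max_other_per_100bp))
    calls_all <- c(calls_all, calls)
    cassettes <- c(cassettes,
                   assemble_cassette(record, an$rt, calls, orfs))
  }
  if (length(cassettes) > 1L) {
    key <- vapply(cassettes, function(cc) paste(cc$trvr$vr$start, cc$trvr$vr$end), character(1))
    cassettes <- cassettes[!duplicated(key)]
  }
  pairs <- if (length(pairs_all)) unique(do.call(rbind, pairs_all)) else
    find_repeat_pairs(record, list(start = 0L, end = 0L), window_bp = 1)[0, ]
  list(orfs = orfs, rt_candidates = rts, pairs = pairs,
       calls = calls_all, cassettes = cassettes)
}

# nucleotide sequence of one named cassette feature, on its coding strand
cassette_feature_seq <- function(cassette, record, feature = c("TP", "VR", "TR", "RT")) {
  feature <- match.arg(feature)
  record <- as_record(record)
  iv <- switch(feature,
    TP = cassette$tp_orf,
    VR = cassette$trvr$vr,
    TR = cassette$trvr$tr,
    RT = cassette$rt)
  if (is.null(iv)) return(NA_character_)
  strand <- iv$strand %||% "+"
  extract_seq(record, iv$start, iv$end, strand)
}

#' Per-feature percent identity between two cassettes
#'
#' Globally aligns the nucleotide sequence of each shared feature (TP gene,
#' VR, TR, RT gene) with match +1, mismatch -1, linear gap -2 and reports
#' identity as matches / alignment columns x 100. Features absent from
#' either cassette are reported `NA`.
#'
#' @param c1,c2 `dgr_cassette` objects.
#' @param record1,record2 the records the cassettes were called on.
#' @return named numeric vector with entries `TP`, `VR`, `TR`, `RT` (percent
#'   identity or `NA`).
#' @export
cassette_identity <- function(c1, c2, record1, record2) {
  out <- c(TP = NA_real_, VR = NA_real_, TR = NA_real_, RT = NA_real_)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = TRUE)
  for (f in names(out)) {
    s1 <- cassette_feature_seq(c1, record1, f)
    s2 <- cassette_feature_seq(c2, record2, f)
    if (is.na(s1) || is.na(s2)) next
    aln <- Biostrings::pairwiseAlignment(s1, s2, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    a <- seq_chars(as.character(Biostrings::pattern(aln)))
    b <- seq_chars(as.character(Biostrings::subject(aln)))
    out[[f]] <- 100 * sum(a == b & a != "-") / length(a)
  }
  out
}
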