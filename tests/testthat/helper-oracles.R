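# Independent brute-force oracles used to freeze expected values.
# Each is written by direct enumeration, independent of the package's
# implementation path.

CODE11 <- Biostrings::getGeneticCode("11")

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# --- six-frame ORF oracle: direct enumeration over every frame/strand ------
# contract: per frame, ORF = first start (ATG/GTG/TTG) after the previous
# in-frame stop or N-broken codon, to the next in-frame stop (included);
# stop-less runs at the sequence end reported partial.
oracle_orfs <- function(seqstr, min_protein_len) {
  L <- nchar(seqstr)
  out <- list()
  rc <- dgrscope::revcomp(seqstr)
  for (strand in c("+", "-")) {
    sq <- if (strand == "+") seqstr else rc
    for (frame in 0:2) {
      i <- frame + 1L
      open_start <- NA  # codon start (1-based nt) of the current ORF
      while (i + 2L <= L) {
        cod <- substr(sq, i, i + 2L)
        aa <- if (grepl("[^ACGT]", cod)) NA_character_ else unname(CODE11[cod])
        if (is.na(open_start)) {
          if (!is.na(aa) && cod %in% c("ATG", "GTG", "TTG")) open_start <- i
        }
        if (!is.na(open_start)) {
          if (is.na(aa)) {
            open_start <- NA  # N breaks the frame, no stop seen: drop
          } else if (aa == "*") {
            n_aa <- (i - open_start) %/% 3L
            if (n_aa >= min_protein_len) {
              prot <- paste(vapply(seq(open_start, i - 1L, by = 3L),
                                   function(p) unname(CODE11[substr(sq, p, p + 2L)]),
                                   character(1)), collapse = "")
              s0 <- open_start - 1L; e0 <- i + 2L
              if (strand == "-") { tmp <- s0; s0 <- L - e0; e0 <- L - tmp }
              out[[length(out) + 1L]] <- data.frame(
                start = s0, end = e0, strand = strand, protein = prot,
                partial = FALSE, stringsAsFactors = FALSE)
            }
            open_start <- NA
          }
        }
        i <- i + 3L
      }
      if (!is.na(open_start)) {
        last <- open_start + 3L * ((L - open_start + 1L) %/% 3L) - 1L
        n_aa <- (last - open_start + 1L) %/% 3L
        if (n_aa >= min_protein_len) {
          prot <- paste(vapply(seq(open_start, last - 2L, by = 3L),
                               function(p) unname(CODE11[substr(sq, p, p + 2L)]),
                               character(1)), collapse = "")
          s0 <- open_start - 1L; e0 <- last
          if (strand == "-") { tmp <- s0; s0 <- L - e0; e0 <- L - tmp }
          out[[length(out) + 1L]] <- data.frame(
            start = s0, end = e0, strand = strand, protein = prot,
            partial = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0),
                                      strand = character(0), protein = character(0),
                                      partial = logical(0)))
  df <- do.call(rbind, out)
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

# --- exhaustive stem-loop oracle ------------------------------------------
# every (start, stem, loop) triple with exact reverse-complement arms,
# filtered to locally maximal ones under the same one-step growth rule
oracle_hairpins <- function(region, stem_min = 4, stem_max = 12,
                            loop_min = 3, loop_max = 8) {
  n <- nchar(region)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(region, "")[[1]]
  ok <- function(i, s, l) {
    if (i < 1 || i + 2 * s + l - 1 > n) return(FALSE)
    arm1 <- ch[i:(i + s - 1)]
    arm2 <- ch[(i + s + l):(i + 2 * s + l - 1)]
    if (any(!arm1 %in% names(comp)) || any(!arm2 %in% names(comp))) return(FALSE)
    all(unname(comp[arm1]) == rev(arm2))
  }
  rows <- list()
  for (i in seq_len(n)) for (s in stem_min:stem_max) for (l in loop_min:loop_max) {
    if (!ok(i, s, l)) next
    if (s < stem_max && ok(i - 1, s + 1, l)) next
    if (s < stem_max && l - 2 >= loop_min && ok(i, s + 1, l - 2)) next
    rows[[length(rows) + 1L]] <- data.frame(start = i - 1L, end = i + 2L * s + l - 1L,
                                            stem_len = s, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(start = integer(0), end = integer(0),
                                       stem_len = integer(0)))
  df <- unique(do.call(rbind, rows))
  df[order(-df$stem_len, df$start), , drop = FALSE]
}

# --- exhaustive protein-variant oracle ------------------------------------
# enumerates all 4^A nucleotide variants of the adenine positions, translates
# each full variant in the given frame, and counts the distinct proteins
# among stop-free variants (a variant with a nonsense codon encodes no
# protein) plus whether any variant reaches a stop
oracle_variants <- function(tr_segment, frame_offset = 0) {
  body <- substr(tr_segment, frame_offset + 1, nchar(tr_segment))
  ncod <- nchar(body) %/% 3
  body <- substr(body, 1, 3 * ncod)
  ch <- strsplit(body, "")[[1]]
  apos <- which(ch == "A")
  bases <- c("A", "C", "G", "T")
  k <- length(apos)
  n_var <- 4^k
  prots <- character(0)
  any_stop <- FALSE
  idx <- rep(1L, k)
  for (v in seq_len(n_var)) {
    vc <- ch
    if (k > 0) vc[apos] <- bases[idx]
    aa <- unname(CODE11[vapply(seq_len(ncod),
                               function(ci) paste(vc[(3 * ci - 2):(3 * ci)], collapse = ""),
                               character(1))])
    if (any(aa == "*")) any_stop <- TRUE
    else prots[length(prots) + 1L] <- paste(aa, collapse = "")
    # odometer increment
    j <- 1L
    while (j <= k) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= 4L) break
      idx[j] <- 1L; j <- j + 1L
    }
  }
  list(n_distinct = length(unique(prots)), stop_reachable = any_stop)
}

# --- independent pI oracle: uniroot on the same fixed pKa model ------------
oracle_pi <- function(protein) {
  pka_pos <- c(K = 10.8, R = 12.5, H = 6.5)
  pka_neg <- c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  aa <- strsplit(protein, "")[[1]]
  charge <- function(ph) {
    pos <- c(8.6, unname(pka_pos[aa[aa %in% names(pka_pos)]]))
    neg <- c(3.6, unname(pka_neg[aa[aa %in% names(pka_neg)]]))
    sum(1 / (1 + 10^(ph - pos))) - sum(1 / (1 + 10^(neg - ph)))
  }
  stats::uniroot(charge, c(0, 14), tol = 1e-9)$root
}
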