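# codons (as strings) for which a stop codon is reachable by substituting
# only the adenine positions; includes the stop codons themselves
stop_reachable_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases)[, 3:1], 1, paste, collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  reach <- vapply(all_codons, function(cod) {
    cc <- seq_chars(cod)
    any(vapply(stops, function(s) {
      ss <- seq_chars(s)
      all(cc == ss | cc == "A")
    }, logical(1)))
  }, logical(1))
  all_codons[reach]
}

# codon pools indexed by adenine count; safe pools exclude stop-reachable
codon_pools <- function(no_nonsense = TRUE) {
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases)[, 3:1], 1, paste, collapse = "")
  excl <- if (no_nonsense) stop_reachable_codons() else c("TAA", "TAG", "TGA")
  pool <- setdiff(all_codons, excl)
  acount <- vapply(pool, function(cod) sum(seq_chars(cod) == "A"), integer(1))
  split(pool, acount)
}

#' Simulation configuration for synthetic DGR genomes
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: a 50-kb background genome at GC 0.45 carrying one planted cassette
#' with a 114-bp TR/VR repeat pair whose template is 30% adenine, each
#' adenine independently rewritten in VR with probability 0.4 (uniformly
#' over the four bases, so 3/4 of rewrites change the base).
#'
#' @param genome_len genome length (bp).
#' @param gc background GC fraction.
#' @param n_cassettes number of planted cassettes (0 for negative controls).
#' @param repeat_len TR/VR length (bp, >= 50).
#' @param tr_adenine_frac fraction of TR positions that are adenine.
#' @param p_adenine_sub per-adenine probability of a uniform 4-base redraw
#'   in VR.
#' @param p_background_sub per-non-adenine probability of substitution.
#' @param plant_imh plant TGGGGT / TGGAAT at the VR / TR 3' ends?
#' @param plant_hairpin plant a stem-6, GAA-loop hairpin in the TP gene
#'   downstream of VR?
#' @param plant_avd plant a small basic Avd-like ORF between RT and TP?
#' @param plant_no_nonsense restrict TR codons so that no adenine
#'   substitution can create a stop codon?
#' @param seed RNG seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(genome_len = 50000, gc = 0.45, n_cassettes = 1,
                       repeat_len = 114, tr_adenine_frac = 0.30,
                       p_adenine_sub = 0.40, p_background_sub = 0,
                       plant_imh = TRUE, plant_hairpin = TRUE,
                       plant_avd = TRUE, plant_no_nonsense = TRUE,
                       seed = 1) {
  stopifnot(genome_len >= 1, gc > 0, gc < 1, n_cassettes >= 0,
            repeat_len >= 50,
            tr_adenine_frac >= 0, tr_adenine_frac <= 1,
            p_adenine_sub >= 0, p_adenine_sub <= 1,
            p_background_sub >= 0, p_background_sub <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Mutagenize a template repeat into a variable repeat
#'
#' Models adenine-directed mutagenesis: each adenine of the template is,
#' with probability `p_adenine_sub`, replaced by a uniform draw from
#' {A,C,G,T} (a draw of A is a silent no-change); each non-adenine position
#' is, with probability `p_background_sub`, replaced by a uniform draw from
#' the three other bases.
#'
#' @param tr_seq template DNA string over A/C/G/T.
#' @param p_adenine_sub,p_background_sub substitution probabilities.
#' @param seed optional seed (NULL uses the ambient RNG state).
#' @return list: `vr_seq`, `n_adenine_mm` (adenine positions actually
#'   changed), `n_other_mm`.
#' @export
mutate_vr <- function(tr_seq, p_adenine_sub = 0.40, p_background_sub = 0,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(!grepl("[^ACGT]", tr_seq))
  bases <- c("A", "C", "G", "T")
  v <- seq_chars(tr_seq)
  is_a <- v == "A"
  draw_a <- is_a & stats::runif(length(v)) < p_adenine_sub
  if (any(draw_a)) v[draw_a] <- sample(bases, sum(draw_a), replace = TRUE)
  draw_bg <- !is_a & stats::runif(length(v)) < p_background_sub
  if (any(draw_bg)) {
    orig <- v[draw_bg]
    v[draw_bg] <- vapply(orig, function(b) sample(setdiff(bases, b), 1), character(1))
  }
  tr <- seq_chars(tr_seq)
  list(vr_seq = paste(v, collapse = ""),
       n_adenine_mm = sum(tr != v & tr == "A"),
       n_other_mm = sum(tr != v & tr != "A"))
}

# random non-stop codons from the full coding pool
random_codons <- function(n) {
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases)[, 3:1], 1, paste, collapse = "")
  pool <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# template repeat with an exact adenine count and (optionally) no
# stop-reachable codons in the frame it will occupy inside the TP gene
build_tr <- function(repeat_len, tr_adenine_frac, no_nonsense = TRUE) {
  n_cod <- repeat_len %/% 3L
  rem <- repeat_len %% 3L
  target_a <- round(repeat_len * tr_adenine_frac)
  target_a <- min(target_a, 2L * n_cod)
  pools <- codon_pools(no_nonsense)
  max_per <- max(as.integer(names(pools)))
  # split target_a into per-codon counts bounded by the pool's max
  x_lo <- max(0L, target_a - n_cod)            # number of 2-adenine codons needed
  x_hi <- min(n_cod, target_a %/% 2L)
  stopifnot(max_per >= 2L, x_lo <= x_hi)
  x2 <- if (x_lo == x_hi) x_lo else sample(seq(x_lo, x_hi), 1)
  x1 <- target_a - 2L * x2
  counts <- sample(c(rep(2L, x2), rep(1L, x1), rep(0L, n_cod - x2 - x1)))
  codons <- vapply(counts, function(a) {
    p <- pools[[as.character(a)]]
    p[sample.int(length(p), 1)]
  }, character(1))
  tail_bases <- if (rem > 0) paste(sample(c("C", "G", "T"), rem, replace = TRUE), collapse = "") else ""
  paste0(paste(codons, collapse = ""), tail_bases)
}

# small basic protein in the Avd pI/MW window, returned as a coding sequence
build_avd_orf <- function(len_aa = 85) {
  neutral <- c("G", "A", "S", "T", "L", "V", "P", "N", "Q", "I", "F")
  aa <- sample(neutral, len_aa, replace = TRUE)
  aa[sample.int(len_aa, 12)] <- "K"
  aa[sample.int(len_aa, 2)] <- "D"
  prot <- paste(c("M", aa), collapse = "")
  for (i in 1:50) {
    pi <- protein_pi(prot)
    if (pi >= 8.2 && pi <= 9.8) break
    v <- seq_chars(prot)
    if (pi < 8.2) v[sample(which(v %in% neutral), 1)] <- "K"
    else v[sample(which(v == "K"), 1)] <- "A"
    prot <- paste(v, collapse = "")
  }
  codon_of <- c(A = "GCT", C = "TGC", D = "GAT", E = "GAA", F = "TTC", G = "GGT",
                H = "CAC", I = "ATC", K = "AAA", L = "CTG", M = "ATG", N = "AAC",
                P = "CCG", Q = "CAG", R = "CGT", S = "TCT", T = "ACC", V = "GTT",
                W = "TGG", Y = "TAC")
  paste0(paste(codon_of[seq_chars(prot)], collapse = ""), "TAA")
}

# RT-like coding sequence: random protein with the catalytic YADD box
build_rt_orf <- function(len_aa = 300, motif_at = 150) {
  aas <- names(RESIDUE_MASS)
  prot <- sample(aas, len_aa, replace = TRUE)
  prot[motif_at:(motif_at + 3L)] <- c("Y", "A", "D", "D")
  codon_of <- c(A = "GCA", C = "TGT", D = "GAC", E = "GAG", F = "TTT", G = "GGA",
                H = "CAT", I = "ATT", K = "AAG", L = "TTA", M = "ATG", N = "AAT",
                P = "CCA", Q = "CAA", R = "AGA", S = "AGT", T = "ACA", V = "GTC",
                W = "TGG", Y = "TAT")
  paste0("ATG", paste(codon_of[prot], collapse = ""), "TAA")
}

random_background <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")
}

# one cassette laid out on the forward strand in the order TP .. TR .. Avd .. RT;
# returns the sequence and truth offsets relative to the cassette start
build_cassette <- function(cfg) {
  tr <- build_tr(cfg$repeat_len, cfg$tr_adenine_frac, cfg$plant_no_nonsense)
  mut <- mutate_vr(tr, cfg$p_adenine_sub, cfg$p_background_sub)
  vr <- mut$vr_seq
  imh <- if (cfg$plant_imh) "TGGGGT" else ""
  imh_star <- if (cfg$plant_imh) "TGGAAT" else ""
  up <- random_codons(150)
  spacer <- random_codons(3)
  hairpin <- ""
  if (cfg$plant_hairpin) {
    repeat {
      stem <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE), collapse = "")
      hairpin <- paste0(stem, "GAA", revcomp(stem))
      cods <- substring(hairpin, seq(1, 13, 3), seq(3, 15, 3))
      if (!any(cods %in% c("TAA", "TAG", "TGA"))) break
    }
  }
  tail_cod <- random_codons(8)
  # pad VR to a codon boundary so downstream elements stay in frame
  vr_pad <- (3L - nchar(vr) %% 3L) %% 3L
  pad <- if (vr_pad > 0) paste(rep("C", vr_pad), collapse = "") else ""
  tp_seq <- paste0("ATG", up, vr, pad, imh, spacer, hairpin, tail_cod, "TAA")
  tp_start <- 0L
  vr_start <- 3L + nchar(up)
  gap1 <- random_background(200, cfg$gc)
  tr_start <- nchar(tp_seq) + nchar(gap1)
  tr_block <- paste0(tr, imh_star)
  gap2 <- random_background(150, cfg$gc)
  avd_seq <- if (cfg$plant_avd) build_avd_orf() else ""
  avd_start <- tr_start + nchar(tr_block) + nchar(gap2)
  gap3 <- random_background(150, cfg$gc)
  rt_seq <- build_rt_orf()
  rt_start <- avd_start + nchar(avd_seq) + nchar(gap3)
  seq <- paste0(tp_seq, gap1, tr_block, gap2, avd_seq, gap3, rt_seq)
  truth <- list(
    tp = list(start = tp_start, end = nchar(tp_seq), strand = "+"),
    tp_frame = 0L,
    vr = list(start = vr_start, end = vr_start + nchar(vr)),
    tr = list(start = tr_start, end = tr_start + nchar(tr)),
    imh = if (cfg$plant_imh) list(start = vr_start + nchar(vr) + vr_pad,
                                  end = vr_start + nchar(vr) + vr_pad + 6L) else NULL,
    imh_star = if (cfg$plant_imh) list(start = tr_start + nchar(tr),
                                       end = tr_start + nchar(tr) + 6L) else NULL,
    hairpin = if (cfg$plant_hairpin) {
      h0 <- vr_start + nchar(vr) + vr_pad + nchar(imh) + nchar(spacer)
      list(start = h0, end = h0 + 15L)
    } else NULL,
    avd = if (cfg$plant_avd) list(start = avd_start, end = avd_start + nchar(avd_seq)) else NULL,
    rt = list(start = rt_start, end = rt_start + nchar(rt_seq), strand = "+"),
    tr_seq = tr, vr_seq = vr,
    n_adenines_tr = sum(seq_chars(tr) == "A"),
    n_adenine_mm = mut$n_adenine_mm,
    n_other_mm = mut$n_other_mm
  )
  list(seq = seq, truth = truth)
}

shift_iv <- function(iv, off) {
  if (is.null(iv)) return(NULL)
  iv$start <- iv$start + off
  iv$end <- iv$end + off
  iv
}

#' Generate a synthetic genome with planted DGR cassettes
#'
#' Background bases are i.i.d. at the configured GC; each cassette occupies
#' a 10-kb span and carries, on the forward strand and in order: a TP gene
#' whose 3' region is VR (+ IMH and a GAA-loop hairpin), an intergenic TR
#' copy with IMH*, an optional Avd-like ORF, and an RT-like ORF containing
#' the YADD catalytic motif. VR derives from TR under the adenine-directed
#' substitution model. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list with `record` (a `genome_record`) and `truth` (list of
#'   per-cassette ground-truth interval/count lists, genome coordinates,
#'   0-based half-open).
#' @export
generate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  span <- 10000L
  if (config$n_cassettes * span > config$genome_len) {
    stop("cassettes do not fit: need ", config$n_cassettes * span,
         " bp, genome_len is ", config$genome_len)
  }
  genome <- random_background(config$genome_len, config$gc)
  truths <- list()
  if (config$n_cassettes > 0) {
    block <- config$genome_len %/% config$n_cassettes
    for (i in seq_len(config$n_cassettes)) {
      cass <- build_cassette(config)
      clen <- nchar(cass$seq)
      lo <- (i - 1L) * block
      off <- lo + sample.int(block - clen, 1)
      genome <- paste0(substr0(genome, 0L, off), cass$seq,
                       substr0(genome, off + clen, config$genome_len))
      tr <- cass$truth
      for (f in c("tp", "vr", "tr", "imh", "imh_star", "hairpin", "avd", "rt"))
        tr[[f]] <- shift_iv(tr[[f]], off)
      tr$cassette_span <- list(start = off, end = off + clen)
      truths[[i]] <- tr
    }
  }
  record <- structure(list(id = sprintf("synthetic_seed%d", config$seed),
                           sequence = genome, description = "synthetic genome with planted DGR cassettes",
                           topology = "linear"), class = "genome_record")
  list(record = record, truth = truths, config = config)
}

#' Simulate sequencing reads from a genome record
#'
#' Uniform start positions on both strands, substitution errors at
#' `error_rate`, Phred qualities drawn around `mean_q`, and an `N` injected
#' into a configurable fraction of reads (to exercise the QC filter).
#'
#' @param record a `genome_record`.
#' @param n number of reads.
#' @param read_len read length, a scalar or a c(min, max) range.
#' @param error_rate per-base substitution probability.
#' @param seed optional RNG seed.
#' @param mean_q,sd_q Phred quality distribution per read-base.
#' @param n_frac fraction of reads given one ambiguous base.
#' @return data.frame compatible with [qc_filter_reads()].
#' @export
generate_reads <- function(record, n, read_len = 100, error_rate = 0,
                           seed = NULL, mean_q = 30, sd_q = 3, n_frac = 0) {
  if (!is.null(seed)) set.seed(seed)
  record <- as_record(record)
  L <- nchar(record$sequence)
  stopifnot(max(read_len) <= L)
  if (n == 0) {
    return(data.frame(id = character(0), sequence = character(0),
                      qualities = I(list()), stringsAsFactors = FALSE))
  }
  lens <- if (length(read_len) == 2L) sample(seq(read_len[1], read_len[2]), n, replace = TRUE)
          else rep(as.integer(read_len), n)
  starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1), integer(1))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  seqs <- character(n)
  quals <- vector("list", n)
  with_n <- stats::runif(n) < n_frac
  for (i in seq_len(n)) {
    s <- substr(record$sequence, starts[i], starts[i] + lens[i] - 1L)
    if (strands[i] == "-") s <- revcomp(s)
    if (error_rate > 0) {
      v <- seq_chars(s)
      err <- stats::runif(lens[i]) < error_rate
      if (any(err)) v[err] <- vapply(v[err], function(b) sample(setdiff(bases, b), 1), character(1))
      s <- paste(v, collapse = "")
    }
    if (with_n[i]) {
      v <- seq_chars(s)
      v[sample.int(lens[i], 1)] <- "N"
      s <- paste(v, collapse = "")
    }
    seqs[i] <- s
    quals[[i]] <- pmin(40L, pmax(2L, as.integer(round(stats::rnorm(lens[i], mean_q, sd_q)))))
  }
  data.frame(id = sprintf("read_%d", seq_len(n)), sequence = seqs,
             qualities = I(quals), stringsAsFactors = FALSE)
}
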