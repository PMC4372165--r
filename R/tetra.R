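#' Sliding-window coordinates
#'
#' Windows start at 0, `step`, `2*step`, ...; a sequence shorter than
#' `window` yields no windows (with a warning).
#'
#' @param seq_or_len a DNA string or its length.
#' @param window window size in bp.
#' @param step step size in bp (`0 < step <= window`).
#' @return data.frame of `start`, `end` (0-based half-open).
#' @export
fragment_windows <- function(seq_or_len, window = 5000, step = 500) {
  stopifnot(window > 0, step > 0, step <= window)
  L <- if (is.character(seq_or_len)) nchar(seq_or_len) else as.integer(seq_or_len)
  if (L < window) {
    warning(sprintf("sequence length %d < window %d: no windows", L, window))
    return(data.frame(start = integer(0), end = integer(0)))
  }
  n <- (L - window) %/% step + 1L
  starts <- (seq_len(n) - 1L) * step
  data.frame(start = starts, end = starts + window)
}

#' Zero-order-Markov tetranucleotide odds ratios for one window
#'
#' Counts the 256 4-mers over the window (positions containing `N` are
#' skipped) and divides each observed count by its expectation under
#' independent mononucleotide frequencies computed from the window's non-N
#' bases: `expected(w) = L' * prod(freq(base))` with `L'` the number of
#' counted 4-mer positions. Entries with zero expectation (and necessarily
#' zero observation) are set to the neutral value 1. The observed and
#' expected totals both equal `L'` (conservation).
#'
#' @param window_seq DNA string over A/C/G/T/N with at least 4 non-N bases.
#' @return named numeric vector of 256 odds ratios in lexicographic 4-mer
#'   order (AAAA..TTTT).
#' @export
tetra_odds <- function(window_seq) {
  x <- Biostrings::DNAString(window_seq)
  mono <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  if (sum(mono) < 4) stop("window has fewer than 4 unambiguous bases")
  obs <- Biostrings::oligonucleotideFrequency(x, width = 4)
  Lp <- sum(obs)
  f <- as.numeric(mono) / sum(mono)
  expd <- Lp * as.vector(kronecker(f, kronecker(f, kronecker(f, f))))  # lexicographic
  odds <- ifelse(expd > 0, as.numeric(obs) / expd, 1)
  names(odds) <- names(obs)
  odds
}

#' Concatenate feature sequences and profile them in sliding windows
#'
#' Sequences are joined in input order with no spacer (emulating the
#' concatenation of dispersed cassette / gene sequences into one
#' composition sample), fragmented, and profiled with [tetra_odds()].
#'
#' @param feature_seqs character vector (or list) of DNA sequences.
#' @param label group label attached to every window (e.g. "DGR", "RT",
#'   "TP", "genome").
#' @param window,step sliding-window parameters.
#' @param source_id id recorded for the concatenated sequence.
#' @return a `tetra_profiles` object: list with `meta` (data.frame
#'   `source_id`, `window_start`, `window_end`, `group`) and `odds`
#'   (n x 256 matrix).
#' @export
concat_and_profile <- function(feature_seqs, label, window = 5000, step = 500,
                               source_id = label) {
  feature_seqs <- unlist(feature_seqs, use.names = FALSE)
  stopifnot(length(feature_seqs) >= 1L)
  cat_seq <- paste(feature_seqs, collapse = "")
  if (nchar(cat_seq) < window) {
    stop(sprintf("concatenation (%d bp) shorter than window (%d bp); use a smaller window",
                 nchar(cat_seq), window))
  }
  wins <- fragment_windows(cat_seq, window, step)
  odds <- t(vapply(seq_len(nrow(wins)),
                   function(i) tetra_odds(substr0(cat_seq, wins$start[i], wins$end[i])),
                   numeric(256)))
  structure(list(
    meta = data.frame(source_id = source_id, window_start = wins$start,
                      window_end = wins$end, group = label,
                      stringsAsFactors = FALSE),
    odds = odds
  ), class = "tetra_profiles")
}

#' Combine tetra profile sets
#' @param ... `tetra_profiles` objects.
#' @return a single `tetra_profiles` object.
#' @export
bind_profiles <- function(...) {
  ps <- list(...)
  structure(list(
    meta = do.call(rbind, lapply(ps, `[[`, "meta")),
    odds = do.call(rbind, lapply(ps, `[[`, "odds"))
  ), class = "tetra_profiles")
}

#' Non-metric multidimensional scaling of tetranucleotide profiles
#'
#' Euclidean distances between odds vectors are embedded by NMDS
#' (Kruskal stress-1, multiple random starts via [vegan::metaMDS()]);
#' the lowest-stress solution is returned with centered coordinates.
#' Deterministic for a fixed seed.
#'
#' @param profiles a `tetra_profiles` object, a numeric matrix of profile
#'   vectors (rows = windows), or a `dist` object.
#' @param k embedding dimension.
#' @param seed RNG seed.
#' @param n_starts random starts.
#' @param max_iter,tol convergence controls passed to the engine.
#' @return a `dgr_ordination` list: `coords` (n x k, column means 0),
#'   `stress` (Kruskal stress-1 in [0, 1]), `seed`, `n_starts`, and `meta`
#'   when available.
#' @export
nmds <- function(profiles, k = 2, seed = 1, n_starts = 20,
                 max_iter = 300, tol = 1e-7) {
  meta <- NULL
  if (inherits(profiles, "tetra_profiles")) {
    meta <- profiles$meta
    d <- stats::dist(profiles$odds)
  } else if (inherits(profiles, "dist")) {
    d <- profiles
  } else {
    d <- stats::dist(as.matrix(profiles))
  }
  n <- attr(d, "Size")
  if (n < k + 2) stop("need at least k + 2 points for NMDS")
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, trymax = n_starts, trace = 0,
                        autotransform = FALSE, wascores = FALSE,
                        maxit = max_iter, sfgrmin = tol)
  coords <- scale(fit$points, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  structure(list(coords = unclass(coords), stress = fit$stress,
                 seed = seed, n_starts = n_starts, meta = meta),
            class = "dgr_ordination")
}

#' 95% confidence ellipses for ordination groups
#'
#' Per group: center = coordinate mean; the 2x2 sample covariance is
#' eigendecomposed and semi-axis i = sqrt(eigenvalue_i * q) with q the
#' chi-square(2) quantile at `level` (5.991 at 0.95); the angle is that of
#' the leading eigenvector. Groups with fewer than 3 points are skipped with
#' a warning.
#'
#' @param coords n x 2 coordinate matrix (e.g. from [nmds()]).
#' @param group_labels length-n group labels.
#' @param level confidence level.
#' @return data.frame: `group`, `center_x`, `center_y`, `semi_axis1`,
#'   `semi_axis2`, `angle` (radians), `level`, `n`.
#' @export
confidence_ellipse <- function(coords, group_labels, level = 0.95) {
  stopifnot(ncol(coords) == 2, nrow(coords) == length(group_labels))
  q <- stats::qchisq(level, df = 2)
  rows <- list()
  for (g in unique(group_labels)) {
    m <- coords[group_labels == g, , drop = FALSE]
    if (nrow(m) < 3L) {
      warning(sprintf("group '%s' has %d < 3 points: skipped", g, nrow(m)))
      next
    }
    ctr <- colMeans(m)
    S <- stats::cov(m)
    ee <- eigen(S, symmetric = TRUE)
    semi <- sqrt(pmax(ee$values, 0) * q)
    ang <- atan2(ee$vectors[2, 1], ee$vectors[1, 1])
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, center_x = ctr[1], center_y = ctr[2],
      semi_axis1 = semi[1], semi_axis2 = semi[2],
      angle = ang, level = level, n = nrow(m), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(0), center_x = numeric(0), center_y = numeric(0),
               semi_axis1 = numeric(0), semi_axis2 = numeric(0),
               angle = numeric(0), level = numeric(0), n = integer(0))
  rownames(out) <- NULL
  out
}

#' Flag windows falling outside the genome core's confidence ellipse
#'
#' The "core" is defined by the windows of `genome_group_label`: their
#' coordinate mean and covariance define the `level` confidence ellipse
#' (Mahalanobis distance <= chi-square(2) quantile). Every window is flagged
#' in or out, and the flagged fraction is reported per group; feature groups
#' (e.g. concatenated RT genes) whose composition departs from the core
#' show elevated flagged fractions.
#'
#' @param ordination a `dgr_ordination` from [nmds()].
#' @param group_labels length-n labels (defaults to `meta$group`).
#' @param genome_group_label the label defining the core.
#' @param level confidence level of the core region.
#' @return list with `flags` (data.frame `group`, `outlier`) and
#'   `fraction_by_group` (named numeric).
#' @export
outlier_report <- function(ordination, group_labels = NULL,
                           genome_group_label = "genome", level = 0.95) {
  stopifnot(inherits(ordination, "dgr_ordination"))
  coords <- ordination$coords
  if (is.null(group_labels)) group_labels <- ordination$meta$group
  stopifnot(!is.null(group_labels), length(group_labels) == nrow(coords))
  core <- coords[group_labels == genome_group_label, , drop = FALSE]
  if (nrow(core) < 3L) stop("genome core group needs at least 3 points")
  ctr <- colMeans(core)
  S <- stats::cov(core)
  md <- stats::mahalanobis(coords, ctr, S)
  out <- md > stats::qchisq(level, df = 2)
  flags <- data.frame(group = group_labels, outlier = out, stringsAsFactors = FALSE)
  frac <- tapply(flags$outlier, flags$group, mean)
  list(flags = flags, fraction_by_group = frac)
}
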