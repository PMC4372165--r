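#' Default pipeline configuration
#'
#' All stage parameters with their operation-level defaults. Unknown keys in
#' `overrides` are rejected.
#'
#' @param overrides named list of values to change.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(
    min_rt_protein_len = 100,
    window_bp = 5000,
    min_repeat_len = 50,
    seed_len = 12,
    max_mismatch_frac = 0.25,
    min_adenine_mm = 10,
    max_other_per_100bp = 2,
    genetic_code = 11,
    tetra = FALSE,
    tetra_window = 5000,
    tetra_step = 500,
    nmds_starts = 20,
    seed = 1
  )
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

#' Run the full DGR discovery pipeline
#'
#' For every input record: RT candidate scan, repeat-pair discovery, TR/VR
#' classification (with failure reasons), cassette assembly with cis
#' elements, and a diversity summary per cassette with a TP frame. With
#' `config$tetra = TRUE` and at least one complete cassette, a
#' tetranucleotide ordination of genome windows versus concatenated
#' cassette / RT / TP sequences is added.
#'
#' @param inputs FASTA path(s), or a list of `genome_record`s.
#' @param config a [pipeline_config()].
#' @param anchors optional data.frame of user-supplied anchor loci with a
#'   `record_id` column (e.g. from [read_bed()]).
#' @return a `dgr_report` list: per-record results plus `config`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), anchors = NULL) {
  records <- if (is.character(inputs)) {
    do.call(c, lapply(inputs, read_fasta))
  } else if (inherits(inputs, "genome_record")) list(inputs) else inputs
  stopifnot(length(records) >= 1L)
  per_record <- list()
  for (rec in records) {
    rec_anchors <- NULL
    if (!is.null(anchors)) {
      rec_anchors <- anchors[anchors$record_id == rec$id, , drop = FALSE]
      if (nrow(rec_anchors) == 0L) rec_anchors <- NULL
    }
    det <- detect_dgr(rec,
                      min_rt_protein_len = config$min_rt_protein_len,
                      window_bp = config$window_bp,
                      min_repeat_len = config$min_repeat_len,
                      seed_len = config$seed_len,
                      max_mismatch_frac = config$max_mismatch_frac,
                      min_adenine_mm = config$min_adenine_mm,
                      max_other_per_100bp = config$max_other_per_100bp,
                      anchors = rec_anchors,
                      genetic_code = config$genetic_code)
    diversity <- lapply(det$cassettes, function(cc) {
      if (!is.null(cc$tp_orf)) {
        summarize_diversity(cc, genetic_code = config$genetic_code)
      } else NULL
    })
    tet <- NULL
    complete <- Filter(function(cc) cc$complete && !is.null(cc$tp_orf), det$cassettes)
    if (isTRUE(config$tetra) && length(complete) > 0L) {
      tet <- tryCatch(
        tetra_analysis(rec, complete, window = config$tetra_window,
                       step = config$tetra_step, seed = config$seed,
                       n_starts = config$nmds_starts),
        error = function(e) {
          warning("tetra stage skipped: ", conditionMessage(e))
          NULL
        })
    }
    per_record[[rec$id]] <- list(
      record_id = rec$id,
      record_length = nchar(rec$sequence),
      rt_candidates = det$rt_candidates,
      pairs = det$pairs,
      calls = det$calls,
      cassettes = det$cassettes,
      diversity = diversity,
      tetra = tet
    )
  }
  structure(list(records = per_record, config = config), class = "dgr_report")
}

# genome-versus-DGR-feature tetranucleotide ordination for one record
tetra_analysis <- function(record, cassettes, window = 5000, step = 500,
                           seed = 1, n_starts = 20) {
  record <- as_record(record)
  span_seq <- function(iv) extract_seq(record, iv$start, iv$end)
  genome_prof <- concat_and_profile(record$sequence, "genome", window, step,
                                    source_id = record$id)
  dgr_seqs <- vapply(cassettes, function(cc) {
    lo <- min(cc$tp_orf$start, cc$trvr$tr$start, cc$rt$start)
    hi <- max(cc$tp_orf$end, cc$trvr$tr$end, cc$rt$end)
    span_seq(list(start = lo, end = hi))
  }, character(1))
  profs <- list(genome_prof)
  dgr_cat <- paste(dgr_seqs, collapse = "")
  if (nchar(dgr_cat) >= window) {
    profs <- c(profs, list(concat_and_profile(dgr_seqs, "DGR", window, step)))
  }
  rt_cat <- paste(vapply(cassettes, function(cc) span_seq(cc$rt), character(1)), collapse = "")
  if (nchar(rt_cat) >= window) {
    profs <- c(profs, list(concat_and_profile(rt_cat, "RT", window, step)))
  }
  tp_cat <- paste(vapply(cassettes, function(cc) span_seq(cc$tp_orf), character(1)), collapse = "")
  if (nchar(tp_cat) >= window) {
    profs <- c(profs, list(concat_and_profile(tp_cat, "TP", window, step)))
  }
  all_prof <- do.call(bind_profiles, profs)
  ord <- nmds(all_prof, seed = seed, n_starts = n_starts)
  ell <- confidence_ellipse(ord$coords, all_prof$meta$group)
  outl <- outlier_report(ord, all_prof$meta$group, "genome")
  list(profiles = all_prof, ordination = ord, ellipses = ell, outliers = outl)
}

# serializable view of a cassette (exact big integers as strings)
cassette_row <- function(cc, div) {
  iv <- function(x) if (is.null(x)) c(NA_integer_, NA_integer_) else c(x$start, x$end)
  data.frame(
    record_id = cc$record_id,
    complete = cc$complete,
    rt_start = iv(cc$rt)[1], rt_end = iv(cc$rt)[2],
    tp_start = iv(cc$tp_orf)[1], tp_end = iv(cc$tp_orf)[2],
    tr_start = cc$trvr$tr$start, tr_end = cc$trvr$tr$end,
    vr_start = cc$trvr$vr$start, vr_end = cc$trvr$vr$end,
    orientation = cc$trvr$orientation,
    aligned_len = cc$trvr$profile$aligned_len,
    adenine_mm = max(cc$trvr$profile$n_adenine_wrt_A, cc$trvr$profile$n_adenine_wrt_B),
    has_imh = !is.null(cc$imh),
    has_hairpin = !is.null(cc$hairpin),
    n_avd_candidates = if (is.null(cc$avd)) 0L else nrow(cc$avd),
    n_adenines = if (is.null(div)) NA_integer_ else div$n_adenines,
    n_nt_variants = if (is.null(div)) NA_character_ else bigint_str(div$n_nt_variants),
    n_protein_variants = if (is.null(div)) NA_character_ else bigint_str(div$n_protein_variants),
    n_diversifiable_codons = if (is.null(div)) NA_integer_ else div$n_diversifiable_codons,
    n_aay_codons = if (is.null(div)) NA_integer_ else div$n_aay_codons,
    nonsense_risk = if (is.null(div)) NA else div$nonsense_risk,
    flags = paste(cc$flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Cassette summary table for a report
#' @param report a `dgr_report`.
#' @return data.frame, one row per cassette (variant counts as exact
#'   decimal strings).
#' @export
report_summary <- function(report) {
  rows <- list()
  for (rr in report$records) {
    for (i in seq_along(rr$cassettes)) {
      rows[[length(rows) + 1L]] <- cassette_row(rr$cassettes[[i]], rr$diversity[[i]])
    }
  }
  if (length(rows) == 0L) {
    cols <- c("record_id", "complete", "rt_start", "rt_end", "tp_start", "tp_end",
              "tr_start", "tr_end", "vr_start", "vr_end", "orientation",
              "aligned_len", "adenine_mm", "has_imh", "has_hairpin",
              "n_avd_candidates", "n_adenines", "n_nt_variants",
              "n_protein_variants", "n_diversifiable_codons", "n_aay_codons",
              "nonsense_risk", "flags")
    out <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# GFF3 feature table for all cassettes in a report
report_features <- function(report) {
  rows <- list()
  add <- function(record_id, iv, strand, type, id) {
    if (is.null(iv)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      record_id = record_id, start = iv$start, end = iv$end,
      strand = strand, type = type, id = id, stringsAsFactors = FALSE)
  }
  for (rr in report$records) {
    for (i in seq_along(rr$cassettes)) {
      cc <- rr$cassettes[[i]]
      base <- sprintf("%s_dgr%d", cc$record_id, i)
      st <- if (is.null(cc$tp_orf)) "+" else cc$tp_orf$strand
      add(cc$record_id, cc$rt, cc$rt$strand %||% "+", "DGR_RT", paste0(base, "_RT"))
      add(cc$record_id, cc$trvr$tr, st, "DGR_TR", paste0(base, "_TR"))
      add(cc$record_id, cc$trvr$vr, st, "DGR_VR", paste0(base, "_VR"))
      add(cc$record_id, cc$tp_orf, st, "DGR_TP", paste0(base, "_TP"))
      if (!is.null(cc$imh)) {
        add(cc$record_id, cc$imh$imh$interval, st, "DGR_IMH", paste0(base, "_IMH"))
        add(cc$record_id, cc$imh$imh_star$interval, st, "DGR_IMH", paste0(base, "_IMHstar"))
      }
      if (!is.null(cc$hairpin)) {
        add(cc$record_id, list(start = cc$hairpin$genomic_start, end = cc$hairpin$genomic_end),
            st, "DGR_hairpin", paste0(base, "_hairpin"))
      }
      if (!is.null(cc$avd)) for (k in seq_len(nrow(cc$avd))) {
        add(cc$record_id, list(start = cc$avd$start[k], end = cc$avd$end[k]),
            cc$avd$strand[k], "DGR_avd_candidate", sprintf("%s_avd%d", base, k))
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

#' Write a pipeline report to disk
#'
#' Emits `<prefix>.json` (full nesting, exact counts as decimal strings),
#' `<prefix>.gff3` (1-based inclusive coordinates) and `<prefix>.tsv`
#' (one row per cassette).
#'
#' @param report a `dgr_report`.
#' @param prefix output path prefix.
#' @param formats subset of c("json", "gff3", "tsv").
#' @return named character vector of written paths, invisibly.
#' @export
write_report <- function(report, prefix, formats = c("json", "gff3", "tsv")) {
  stopifnot(inherits(report, "dgr_report"))
  written <- character(0)
  summ <- report_summary(report)
  if ("tsv" %in% formats) {
    p <- paste0(prefix, ".tsv")
    utils::write.table(summ, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written["tsv"] <- p
  }
  if ("gff3" %in% formats) {
    p <- paste0(prefix, ".gff3")
    write_gff3(report_features(report), p)
    written["gff3"] <- p
  }
  if ("json" %in% formats) {
    p <- paste0(prefix, ".json")
    payload <- list(
      config = unclass(report$config),
      n_records = length(report$records),
      cassettes = summ,
      records = lapply(report$records, function(rr) list(
        record_id = rr$record_id,
        record_length = rr$record_length,
        n_rt_candidates = nrow(rr$rt_candidates),
        n_repeat_pairs = nrow(rr$pairs),
        n_cassettes = length(rr$cassettes),
        call_reasons = lapply(rr$calls, function(cl)
          list(passed = cl$passed, reasons = cl$reasons,
               adenine_mm = max(cl$profile$n_adenine_wrt_A, cl$profile$n_adenine_wrt_B),
               aligned_len = cl$profile$aligned_len))
      ))
    )
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA, null = "null")
    written["json"] <- p
  }
  invisible(written)
}
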