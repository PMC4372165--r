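#' Read genome records from a FASTA file
#'
#' Parses via [Biostrings::readBStringSet()], then validates and normalizes:
#' sequences are uppercased, RNA `U` is mapped to `T`, and IUPAC ambiguity
#' codes other than A/C/G/T are collapsed to `N` (the downstream repeat and
#' ORF machinery treats `N` as matching nothing).
#'
#' @param path path to a FASTA file.
#' @return a list of `genome_record` objects (fields `id`, `sequence`,
#'   `description`, `topology`), in file order.
#' @details The record `id` is the first whitespace-delimited token of the
#'   header; the remainder is kept as `description`. Duplicate ids and
#'   characters outside the IUPAC nucleotide alphabet are errors.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- vector("list", length(set))
  iupac <- "ACGTURYSWKMBDHVN"
  for (i in seq_along(set)) {
    s <- toupper(as.character(set[[i]]))
    bad <- regexpr(sprintf("[^%s]", iupac), s)
    if (bad > 0) {
      stop(sprintf("non-IUPAC character '%s' at position %d of record '%s'",
                   substr(s, bad, bad), bad, ids[i]))
    }
    s <- chartr("URYSWKMBDHV", "TNNNNNNNNNN", s)
    if (nchar(s) < 1L) stop("zero-length sequence in record '", ids[i], "'")
    out[[i]] <- structure(list(id = ids[i], sequence = s, description = descs[i],
                               topology = "linear"), class = "genome_record")
  }
  out
}

#' Write genome records to FASTA
#' @param records list of `genome_record`s.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", hdr), con)
    s <- r$sequence
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read sequencing reads from a FASTQ file (Sanger/Phred+33)
#'
#' @param path path to a FASTQ file.
#' @return a data.frame with columns `id`, `sequence` and a list-column
#'   `qualities` of per-base integer Phred scores.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")
  quals <- as(Biostrings::quality(set), "IntegerList")
  data.frame(
    id = sub("\\s.*$", "", names(set)),
    sequence = as.character(set),
    qualities = I(as.list(quals)),
    stringsAsFactors = FALSE
  )
}

#' Read candidate loci from a BED file
#'
#' Thin wrapper over [rtracklayer::import()] returning 0-based half-open
#' intervals compatible with the package's internal coordinates.
#'
#' @param path path to a BED file.
#' @return data.frame with `record_id`, `start`, `end` (0-based half-open),
#'   `name`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    record_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else rep(NA_character_, length(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

# features: data.frame(record_id, start, end, strand, type, id, parent?) in
# 0-based half-open coordinates; written as 1-based inclusive GFF3
write_gff3 <- function(features, path, source = "dgrscope") {
  if (is.null(features) || nrow(features) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  strand <- ifelse(features$strand %in% c("+", "-"), features$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = features$record_id,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = strand
  )
  gr$source <- source
  gr$type <- features$type
  gr$ID <- features$id
  if (!is.null(features$parent)) gr$Parent <- features$parent
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
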