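#' Reverse complement of a DNA string
#'
#' Complements over the alphabet A/C/G/T/N (N maps to N) and reverses.
#' Operates on plain character vectors; element-wise.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    s <- chartr("ACGTNacgtn", "TGCANtgcan", s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split a sequence into a character vector of single bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# 0-based half-open substring of a 1-based R string
substr0 <- function(s, start0, end0) substr(s, start0 + 1L, end0)

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce a genome record (list with id/sequence) or bare string
as_record <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    return(structure(list(id = "seq", sequence = toupper(x), description = "",
                          topology = "linear"), class = "genome_record"))
  }
  stopifnot(inherits(x, "genome_record") || (is.list(x) && !is.null(x$sequence)))
  x
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s, %d bp)\n", x$id, x$topology, nchar(x$sequence)))
  invisible(x)
}
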