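# Exact non-negative integer arithmetic on base-1e4 limb vectors.
# Variant counts scale as 4^A with A up to a few hundred adenines, far past
# 2^53, so counts are kept exact and only rendered to numeric on demand.

# limbs stored least-significant first, each in [0, 9999]
new_bigint <- function(limbs) structure(list(limbs = as.numeric(limbs)), class = "dgr_bigint")

#' Exact big integer from a small non-negative integer
#' @param x single non-negative number < 2^53.
#' @return a `dgr_bigint`.
#' @export
bigint <- function(x) {
  stopifnot(length(x) == 1L, is.finite(x), x >= 0, x == floor(x))
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, x %% 1e4)
    x <- floor(x / 1e4)
    if (x == 0) break
  }
  new_bigint(limbs)
}

# multiply by a small non-negative integer (< 2^40 or so)
bigint_mul_small <- function(b, m) {
  stopifnot(inherits(b, "dgr_bigint"), m >= 0, m == floor(m))
  if (m == 0) return(bigint(0))
  limbs <- b$limbs * m
  i <- 1L
  while (i <= length(limbs)) {
    if (limbs[i] >= 1e4) {
      carry <- floor(limbs[i] / 1e4)
      limbs[i] <- limbs[i] %% 1e4
      if (i == length(limbs)) limbs <- c(limbs, carry) else limbs[i + 1L] <- limbs[i + 1L] + carry
    }
    i <- i + 1L
  }
  new_bigint(limbs)
}

#' Exact power of a small base
#' @param base,exp non-negative integers; `base^exp` computed exactly.
#' @return a `dgr_bigint`.
#' @export
bigint_pow <- function(base, exp) {
  stopifnot(exp >= 0, exp == floor(exp))
  out <- bigint(1)
  for (i in seq_len(exp)) out <- bigint_mul_small(out, base)
  out
}

#' Exact product of a vector of small non-negative integers
#' @param xs numeric vector of non-negative integers.
#' @return a `dgr_bigint`.
#' @export
bigint_prod <- function(xs) {
  out <- bigint(1)
  for (x in xs) out <- bigint_mul_small(out, x)
  out
}

#' Render a big integer as an exact decimal string
#' @param b a `dgr_bigint`.
#' @return character scalar, no scientific notation.
#' @export
bigint_str <- function(b) {
  stopifnot(inherits(b, "dgr_bigint"))
  n <- length(b$limbs)
  parts <- sprintf("%04d", rev(b$limbs))
  parts[1] <- as.character(b$limbs[n])
  paste(parts, collapse = "")
}

#' Compare two big integers
#' @param a,b `dgr_bigint` objects.
#' @return -1, 0 or 1 as a <, ==, > b.
#' @export
bigint_cmp <- function(a, b) {
  la <- trim_limbs(a$limbs); lb <- trim_limbs(b$limbs)
  if (length(la) != length(lb)) return(sign(length(la) - length(lb)))
  for (i in rev(seq_along(la))) {
    if (la[i] != lb[i]) return(sign(la[i] - lb[i]))
  }
  0
}

trim_limbs <- function(l) {
  while (length(l) > 1L && l[length(l)] == 0) l <- l[-length(l)]
  l
}

#' Base-10 logarithm of a big integer
#' @param b a `dgr_bigint`; must be > 0.
#' @return numeric log10 (approximate for very large values).
#' @export
bigint_log10 <- function(b) {
  l <- trim_limbs(b$limbs)
  n <- length(l)
  top <- 0
  for (i in seq(n, max(1L, n - 3L))) top <- top * 1e4 + l[i]
  log10(top) + 4 * (max(1L, n - 3L) - 1L)
}

#' @export
format.dgr_bigint <- function(x, ...) bigint_str(x)

#' @export
print.dgr_bigint <- function(x, ...) {
  cat(bigint_str(x), "\n")
  invisible(x)
}

#' @export
as.character.dgr_bigint <- function(x, ...) bigint_str(x)
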