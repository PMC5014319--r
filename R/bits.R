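#' Coerce to a binary vector
#'
#' Binary patterns are plain integer vectors over \{0, 1\}. `as_bits()`
#' accepts integer/numeric/logical vectors and strings of `0`/`1` characters
#' (the on-disk and command-line representation of patterns).
#'
#' @param x An integer, numeric or logical vector, or a single string such as
#'   `"0110"`.
#' @return An integer vector with every element 0 or 1.
#' @examples
#' as_bits("1011")
#' as_bits(c(TRUE, FALSE, TRUE))
#' @export
as_bits <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    x <- as.integer(strsplit(x, "")[[1]])
  }
  if (is.logical(x)) x <- as.integer(x)
  if (is.double(x)) {
    xi <- as.integer(round(x))
    if (any(abs(x - xi) > 1e-9)) stop("non-binary input: values must be 0 or 1", call. = FALSE)
    x <- xi
  }
  if (!is.integer(x) || anyNA(x) || any(x != 0L & x != 1L)) {
    stop("non-binary input: values must be 0 or 1", call. = FALSE)
  }
  x
}

#' @rdname as_bits
#' @param bits A binary vector.
#' @export
bits_to_string <- function(bits) paste(as_bits(bits), collapse = "")

#' Hamming distance between two binary vectors
#'
#' The L1 distance between equal-length binary patterns: the number of
#' positions in which they differ. Used to score how far a backward-retrieved
#' address is from the presented cue.
#'
#' @param a,b Binary vectors of equal length.
#' @return A non-negative integer.
#' @examples
#' hamming_distance(c(1, 0, 1), c(1, 1, 1))
#' @export
hamming_distance <- function(a, b) {
  a <- as_bits(a)
  b <- as_bits(b)
  if (length(a) != length(b)) {
    stop("dimension mismatch: vectors have lengths ", length(a), " and ", length(b),
         call. = FALSE)
  }
  sum(a != b)
}

# run seeded code without disturbing the caller's RNG stream
local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}
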