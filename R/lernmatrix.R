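#' Learn binary pattern pairs into a Willshaw weight matrix
#'
#' Implements the clipped-Hebbian learning rule of the Lernmatrix: starting
#' from an all-zero synaptic matrix, an entry `w[i, j]` is set to 1 whenever
#' some stored pair has both the retrieved bit `y[i]` and the address bit
#' `x[j]` equal to 1. Entries never revert to 0, so learning is monotone and
#' order-independent. Storing a pattern with itself (`retrieved = addresses`,
#' the default) gives an auto-associative memory with a symmetric matrix.
#'
#' @param addresses Patterns presented as addresses: a list of binary vectors,
#'   or a matrix with one pattern per row.
#' @param retrieved Patterns to be retrieved, same shape as `addresses`.
#'   Defaults to `addresses` (auto-association).
#' @return An `n x m` integer 0/1 matrix of class `"lernmatrix"` with `n` the
#'   retrieved dimension and `m` the address dimension.
#' @examples
#' W <- learn_pairs(list(c(1, 0, 1)))
#' W
#' @export
learn_pairs <- function(addresses, retrieved = addresses) {
  X <- pattern_matrix(addresses, "address")
  Y <- pattern_matrix(retrieved, "retrieved")
  if (nrow(X) != nrow(Y)) {
    stop("dimension mismatch: ", nrow(X), " address vs ", nrow(Y), " retrieved patterns",
         call. = FALSE)
  }
  if (nrow(X) == 0L) stop("no pairs to learn", call. = FALSE)
  # OR of per-pair outer products y x^T, computed as a clipped cross product
  W <- matrix(as.integer(crossprod(Y, X) > 0), nrow = ncol(Y), ncol = ncol(X))
  new_lernmatrix(W)
}

new_lernmatrix <- function(W) {
  storage.mode(W) <- "integer"
  class(W) <- c("lernmatrix", class(W))
  W
}

# rows = patterns; validates binarity and a shared dimension
pattern_matrix <- function(patterns, what) {
  if (is.matrix(patterns)) {
    m <- patterns
    storage.mode(m) <- "integer"
  } else {
    if (!is.list(patterns)) patterns <- list(patterns)
    patterns <- lapply(patterns, as_bits)
    dims <- lengths(patterns)
    if (length(unique(dims)) > 1L) {
      stop("dimension mismatch across ", what, " patterns: ",
           paste(unique(dims), collapse = ", "), call. = FALSE)
    }
    m <- do.call(rbind, patterns)
  }
  if (anyNA(m) || any(m != 0L & m != 1L)) {
    stop("non-binary ", what, " pattern", call. = FALSE)
  }
  m
}

check_lernmatrix <- function(W) {
  if (!is.matrix(W) || anyNA(W) || any(W != 0 & W != 1)) {
    stop("weight matrix must be a binary 0/1 matrix", call. = FALSE)
  }
  W
}

#' One-step retrieval from a Lernmatrix
#'
#' Presents an address cue `x` and computes the dendritic sum of every unit,
#' `sums[i] = sum_j w[i, j] x[j]`. The firing threshold is set to the maximum
#' sum `T`, so exactly the maximally correlated units become active:
#' `y[i] = 1` iff `sums[i] >= T`. This one-step max-threshold rule is what
#' makes retrieval tolerant to partial or noisy cues.
#'
#' When the maximum sum is 0 (empty memory, or a cue disjoint from every
#' stored pattern) the literal rule would activate every unit; instead a
#' degenerate-retrieval error of class `"scenebind_degenerate_retrieval"` is
#' raised, since an all-ones answer carries no information. Callers that want
#' a soft failure can catch it and treat the cue as unfamiliar.
#'
#' @param W A binary weight matrix from [learn_pairs()].
#' @param x The address cue, a binary vector of length `ncol(W)`.
#' @return A list of class `"retrieval_result"` with elements `y` (the
#'   retrieved binary vector), `threshold_used` (`T`) and `sums`.
#' @examples
#' W <- learn_pairs(list(c(1, 0, 1)))
#' retrieve(W, c(1, 0, 0))$y
#' @export
retrieve <- function(W, x) {
  check_lernmatrix(W)
  x <- as_bits(x)
  if (length(x) != ncol(W)) {
    stop("dimension mismatch: cue has length ", length(x), ", expected ", ncol(W),
         call. = FALSE)
  }
  sums <- as.integer(W %*% x)
  T_max <- max(sums)
  if (T_max == 0L) stop_degenerate()
  structure(
    list(y = as.integer(sums >= T_max), threshold_used = T_max, sums = sums),
    class = "retrieval_result"
  )
}

stop_degenerate <- function() {
  stop(structure(
    class = c("scenebind_degenerate_retrieval", "error", "condition"),
    list(message = paste0(
      "degenerate retrieval: maximal dendritic sum is 0 ",
      "(empty memory or cue disjoint from every stored pattern)"
    ), call = NULL)
  ))
}

#' Backward projection through the transposed Lernmatrix
#'
#' Cues the memory with a retrieved vector `y` and projects through the
#' transposed matrix, recovering the best-matching stored address under the
#' same max-threshold rule as [retrieve()]. For a symmetric auto-associative
#' matrix this coincides with forward retrieval; for hetero-associations it is
#' the single backward pass of a bidirectional associative memory, used to
#' judge the reliability of an answer.
#'
#' @param W A binary weight matrix.
#' @param y A binary vector of length `nrow(W)`.
#' @return A `"retrieval_result"` whose `y` element is the back-projected
#'   address vector.
#' @export
backward_project <- function(W, y) {
  check_lernmatrix(W)
  y <- as_bits(y)
  if (length(y) != nrow(W)) {
    stop("dimension mismatch: cue has length ", length(y), ", expected ", nrow(W),
         call. = FALSE)
  }
  retrieve(new_lernmatrix(t(unclass(W))), y)
}

#' Quadratic-form activation and Hopfield energy of a cue
#'
#' `net_value()` evaluates the quadratic form `net = x' W x =
#' sum_ij w[i, j] x[i] x[j]` of an auto-associative memory; `energy()` returns
#' its negation `H = -net`, the Hopfield energy of the cue. A cue drawn from a
#' stored pattern yields a large `net` (low energy) because every active pair
#' of its bits is wired together.
#'
#' @param W A square auto-associative weight matrix.
#' @param x A binary cue of length `nrow(W)`.
#' @return A single number: `net_value()` is a non-negative integer, and
#'   `energy()` is its negation.
#' @examples
#' W <- learn_pairs(list(c(1, 0, 1)))
#' net_value(W, c(1, 0, 1))
#' energy(W, c(1, 0, 1))
#' @export
net_value <- function(W, x) {
  check_lernmatrix(W)
  if (nrow(W) != ncol(W)) {
    stop("net_value requires a square (auto-associative) weight matrix", call. = FALSE)
  }
  x <- as_bits(x)
  if (length(x) != ncol(W)) {
    stop("dimension mismatch: cue has length ", length(x), ", expected ", ncol(W),
         call. = FALSE)
  }
  as.numeric(crossprod(x, W %*% x))
}

#' @rdname net_value
#' @export
energy <- function(W, x) -net_value(W, x)

#' Familiarity discrimination
#'
#' Decides whether a cue `x` was stored in an auto-associative memory without
#' reconstructing the full answer. Two statistics are supported:
#'
#' * `mode = "net"`: the quadratic form `net = x' W x` is compared against a
#'   threshold `t`; `t = "auto"` sets `t = T / 2` where `T` is the maximal
#'   dendritic sum of this cue (the retrieval threshold).
#' * `mode = "cosine"`: the cosine between the cue and its one-step retrieval
#'   `y`, `cos = <x, y> / (|x| |y|)`, is compared against `t` in `[0, 1]`.
#'   This normalized statistic is the one a fractional threshold such as
#'   `t = 0.87` applies to, and it is the discriminative test used by the
#'   blockworld demonstration.
#'
#' In both modes `sim = 1` iff the statistic meets its threshold (`>=`).
#' The result also carries the Hamming distance between the cue and its
#' retrieval, and the Hopfield energy `-net`, for inspection.
#'
#' @param W A square auto-associative weight matrix.
#' @param x The binary cue.
#' @param mode `"cosine"` (default) or `"net"`.
#' @param t Threshold: a number, or `"auto"` for `T / 2` in net mode (cosine
#'   mode has no auto rule and requires a number in `[0, 1]`).
#' @return A list of class `"familiarity_result"` with elements `net`,
#'   `energy`, `hamming`, `cosine`, `sim`, `threshold_t`, `threshold_T` and
#'   `mode`.
#' @examples
#' W <- learn_pairs(list(c(1, 0, 1)))
#' familiarity(W, c(1, 0, 1), mode = "net", t = "auto")$sim
#' @export
familiarity <- function(W, x, mode = c("cosine", "net"), t = "auto") {
  mode <- match.arg(mode)
  check_lernmatrix(W)
  if (nrow(W) != ncol(W)) {
    stop("familiarity requires a square (auto-associative) weight matrix", call. = FALSE)
  }
  x <- as_bits(x)
  if (length(x) != ncol(W)) {
    stop("dimension mismatch: cue has length ", length(x), ", expected ", ncol(W),
         call. = FALSE)
  }
  n <- ncol(W)
  sums <- as.integer(W %*% x)
  T_max <- max(sums)
  net <- as.numeric(crossprod(x, sums))

  auto_t <- identical(t, "auto")
  if (!auto_t) {
    t <- as.numeric(t)
    lim <- if (mode == "net") c(0, n^2) else c(0, 1)
    if (is.na(t) || t < lim[1] || t > lim[2]) {
      stop("threshold t = ", t, " outside [", lim[1], ", ", lim[2], "] for mode ",
           mode, call. = FALSE)
    }
  }

  if (T_max == 0L && (mode == "cosine" || auto_t)) stop_degenerate()

  y <- if (T_max > 0L) as.integer(sums >= T_max) else NULL
  cosine <- if (!is.null(y)) sum(x * y) / (sqrt(sum(x)) * sqrt(sum(y))) else NA_real_
  hamming <- if (!is.null(y)) sum(x != y) else NA_integer_

  if (auto_t) t <- T_max / 2
  stat <- if (mode == "net") net else cosine
  structure(
    list(net = net, energy = -net, hamming = hamming, cosine = cosine,
         sim = as.integer(stat >= t), threshold_t = t, threshold_T = T_max,
         mode = mode),
    class = "familiarity_result"
  )
}

# Vectorized familiarity over candidate columns. X is an n x K 0/1 matrix.
# Degenerate columns (T = 0) get sim = 0 and NA cosine instead of an error:
# in a combinatorial screen an uninformative candidate is simply unfamiliar.
fam_stats <- function(W, X, mode = c("cosine", "net"), t = 0.87) {
  mode <- match.arg(mode)
  storage.mode(X) <- "double"
  S <- unclass(W) %*% X
  net <- colSums(X * S)
  T_max <- apply(S, 2, max)
  Y <- sweep(S, 2, pmax(T_max, 1), ">=") + 0
  wx <- colSums(X)
  wy <- colSums(Y)
  cosine <- ifelse(T_max > 0 & wx > 0, colSums(X * Y) / sqrt(wx * wy), NA_real_)
  stat <- if (mode == "net") net else cosine
  sim <- as.integer(!is.na(stat) & T_max > 0 & stat >= t)
  tibble::tibble(net = net, cosine = cosine, threshold_T = as.integer(T_max), sim = sim)
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat("One-step retrieval (T = ", x$threshold_used, ")\n", sep = "")
  cat("y: ", bits_to_string(x$y), "\n", sep = "")
  invisible(x)
}

#' @export
print.familiarity_result <- function(x, ...) {
  cat(sprintf("Familiarity (%s mode): sim = %d\n", x$mode, x$sim))
  cat(sprintf("  net = %g  energy = %g  cosine = %s  hamming = %s  t = %g\n",
              x$net, x$energy, format(x$cosine, digits = 4),
              format(x$hamming), x$threshold_t))
  invisible(x)
}

#' @export
print.lernmatrix <- function(x, ...) {
  cat(sprintf("Lernmatrix: %d x %d binary weights, %d set (density %.3f)\n",
              nrow(x), ncol(x), sum(x), mean(x)))
  invisible(x)
}

#' Tidy a familiarity result
#'
#' @param x A `"familiarity_result"`.
#' @param ... Unused.
#' @return A one-row tibble with the statistics and the decision bit.
#' @export
tidy.familiarity_result <- function(x, ...) {
  tibble::tibble(mode = x$mode, net = x$net, energy = x$energy,
                 cosine = x$cosine, hamming = x$hamming,
                 threshold_t = x$threshold_t, threshold_T = x$threshold_T,
                 sim = x$sim)
}

#' Read or write a weight matrix as whitespace-delimited text
#'
#' The format is a first line `"n m"` followed by `n` rows of `m` 0/1 values;
#' the round trip is lossless.
#'
#' @param W A binary weight matrix.
#' @param path File path.
#' @return `read_weight_matrix()` returns a `"lernmatrix"`;
#'   `write_weight_matrix()` returns `path` invisibly.
#' @export
write_weight_matrix <- function(W, path) {
  check_lernmatrix(W)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(W), ncol(W)), con)
  utils::write.table(unclass(W), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_matrix
#' @export
read_weight_matrix <- function(path) {
  header <- scan(path, what = integer(), n = 2, quiet = TRUE)
  vals <- scan(path, what = integer(), skip = 1, quiet = TRUE)
  if (length(vals) != header[1] * header[2]) {
    stop("weight matrix file is truncated: expected ", header[1] * header[2],
         " entries, found ", length(vals), call. = FALSE)
  }
  W <- matrix(vals, nrow = header[1], ncol = header[2], byrow = TRUE)
  new_lernmatrix(check_lernmatrix(W))
}
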