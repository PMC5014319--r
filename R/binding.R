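#' Combination-space counts
#'
#' `perm_count()` is the number of ordered `M`-tuples of distinct objects
#' from a scene of `N`, `Perm(N, M) = N! / (N - M)!` -- the number of
#' queries a naive classical screen must pose. `perm_rep_count()` is the
#' with-repetition relaxation `N^M` used by the quantum index space, which
#' strictly exceeds `Perm(N, M)` for `M >= 2`.
#'
#' Counts are exact integers represented as doubles; values beyond the
#' 2^53 exact-integer range raise an error rather than silently losing
#' precision.
#'
#' @param N Scene size (positive integer).
#' @param M Category size; `perm_count()` requires `1 <= M <= N`.
#' @return A single number (exact integer-valued double).
#' @examples
#' perm_count(7, 3)    # 210
#' perm_count(10, 3)   # 720
#' perm_rep_count(7, 3) # 343
#' @export
perm_count <- function(N, M) {
  check_count_args(N, M)
  if (M > N) stop("M must not exceed N in permutation mode", call. = FALSE)
  exact_prod(seq.int(N - M + 1, N))
}

#' @rdname perm_count
#' @export
perm_rep_count <- function(N, M) {
  check_count_args(N, M)
  exact_prod(rep(as.numeric(N), M))
}

check_count_args <- function(N, M) {
  if (!is.numeric(N) || !is.numeric(M) || length(N) != 1 || length(M) != 1 ||
      N < 1 || M < 1 || N != floor(N) || M != floor(M)) {
    stop("N and M must be positive integers", call. = FALSE)
  }
}

exact_prod <- function(xs) {
  out <- 1
  for (x in xs) {
    out <- out * x
    if (out > 2^53) {
      stop("count exceeds the exact integer range of doubles (2^53)", call. = FALSE)
    }
  }
  out
}

#' Enumerate candidate address tuples
#'
#' Lists the ordered address `M`-tuples over `1..N` in lexicographic order
#' (first address most significant): all `Perm(N, M)` tuples of distinct
#' addresses in `"perm"` mode, or all `N^M` tuples in `"perm_rep"` mode.
#'
#' @param N Number of addresses.
#' @param M Tuple length.
#' @param mode `"perm"` (no repeated address) or `"perm_rep"`.
#' @return An integer matrix with `M` columns, one tuple per row.
#' @export
enumerate_tuples <- function(N, M, mode = c("perm", "perm_rep")) {
  mode <- match.arg(mode)
  check_count_args(N, M)
  if (mode == "perm" && M > N) stop("M must not exceed N in permutation mode", call. = FALSE)
  grid <- do.call(expand.grid, rep(list(seq_len(N)), M))[, rev(seq_len(M)), drop = FALSE]
  tuples <- as.matrix(grid[do.call(order, as.data.frame(grid)), , drop = FALSE])
  dimnames(tuples) <- list(NULL, paste0("a", seq_len(M)))
  if (mode == "perm") {
    distinct <- apply(tuples, 1, function(r) !anyDuplicated(r))
    tuples <- tuples[distinct, , drop = FALSE]
  }
  tuples
}

# candidate matrix: column k is the concatenation of the entities addressed
# by tuple k (rows of `tuples`); addresses beyond scene$N give all-zero
# (waste) entities
candidate_matrix <- function(scene, tuples) {
  p <- scene$p
  ent <- vapply(scene$entities, function(e) e$bits, integer(p))
  ent <- cbind(ent, matrix(0L, nrow = p, ncol = max(0, max(tuples) - scene$N)))
  M <- ncol(tuples)
  X <- matrix(0L, nrow = M * p, ncol = nrow(tuples))
  for (s in seq_len(M)) {
    X[((s - 1) * p + 1):(s * p), ] <- ent[, tuples[, s]]
  }
  X
}

#' Enumerate candidate category vectors over a scene
#'
#' Forms every candidate address tuple (see [enumerate_tuples()]) and the
#' corresponding candidate vector, the concatenation of the addressed
#' entities in tuple order.
#'
#' @param scene A `"scene"`.
#' @param M Category size.
#' @inheritParams enumerate_tuples
#' @return A tibble with address columns `a1..aM` and a list column
#'   `candidate` of binary vectors of length `M * p`.
#' @export
enumerate_candidates <- function(scene, M, mode = c("perm", "perm_rep")) {
  mode <- match.arg(mode)
  tuples <- enumerate_tuples(scene$N, M, mode)
  X <- candidate_matrix(scene, tuples)
  out <- tibble::as_tibble(as.data.frame(tuples))
  out$candidate <- lapply(seq_len(ncol(X)), function(k) X[, k])
  out
}

#' Classical combinatorial binding
#'
#' The naive classical side of the binding search: every candidate tuple of
#' the scene is screened by familiarity discrimination against the learned
#' category memory. Candidates with `sim = 1` are matches; the best match
#' (highest statistic, ties broken by lexicographically smallest tuple) is
#' handed back to the memory, whose one-step retrieval returns the stored
#' noise-free category vector.
#'
#' @param scene A `"scene"`.
#' @param W The learned `"lernmatrix"` (dimension `M * p`).
#' @param M Category size.
#' @param mode Candidate space: `"perm"` (the `Perm(N, M)` distinct-address
#'   tuples) or `"perm_rep"` (`N^M`).
#' @param fam_mode Familiarity statistic, `"cosine"` (default) or `"net"`.
#' @param t Familiarity threshold (default 0.87, the demonstration value).
#' @param early_stop If `TRUE`, stop at the first match instead of screening
#'   the full space (not used by the reported counts).
#' @return A list of class `"bind_result"`: `matches` (tibble of passing
#'   tuples with their statistics), `best_tuple`, `recovered` (binary vector
#'   or `NULL`), `queries`, `mode`, `fam_mode`, `t`.
#' @export
classical_bind <- function(scene, W, M, mode = c("perm", "perm_rep"),
                           fam_mode = c("cosine", "net"), t = 0.87,
                           early_stop = FALSE) {
  mode <- match.arg(mode)
  fam_mode <- match.arg(fam_mode)
  if (M * scene$p != ncol(W)) {
    stop("dimension mismatch: candidates have ", M * scene$p,
         " bits but the memory expects ", ncol(W), call. = FALSE)
  }
  tuples <- enumerate_tuples(scene$N, M, mode)

  if (early_stop) {
    stats <- vector("list", nrow(tuples))
    queries <- 0L
    for (k in seq_len(nrow(tuples))) {
      Xk <- candidate_matrix(scene, tuples[k, , drop = FALSE])
      stats[[k]] <- fam_stats(W, Xk, fam_mode, t)
      queries <- queries + 1L
      if (stats[[k]]$sim == 1L) break
    }
    stats <- dplyr::bind_rows(stats[seq_len(queries)])
    tuples <- tuples[seq_len(queries), , drop = FALSE]
  } else {
    X <- candidate_matrix(scene, tuples)
    stats <- fam_stats(W, X, fam_mode, t)
    queries <- nrow(tuples)
  }

  res <- dplyr::bind_cols(tibble::as_tibble(as.data.frame(tuples)), stats)
  matches <- dplyr::filter(res, .data$sim == 1L)
  recovered <- NULL
  best_tuple <- NULL
  if (nrow(matches) > 0) {
    stat <- if (fam_mode == "net") matches$net else matches$cosine
    ord <- do.call(order, c(list(-stat), as.list(matches[, seq_len(M), drop = FALSE])))
    matches <- matches[ord, ]
    best_tuple <- as.integer(matches[1, seq_len(M)])
    Xb <- candidate_matrix(scene, matrix(best_tuple, nrow = 1))
    recovered <- retrieve(W, Xb[, 1])$y
  }
  structure(
    list(matches = matches, best_tuple = best_tuple, recovered = recovered,
         queries = queries, mode = mode, fam_mode = fam_mode, t = t),
    class = "bind_result"
  )
}

#' @export
print.bind_result <- function(x, ...) {
  cat(sprintf("Classical binding (%s mode, %s familiarity, t = %g)\n",
              x$mode, x$fam_mode, x$t))
  cat(sprintf("  %d queries, %d match(es)\n", x$queries, nrow(x$matches)))
  if (!is.null(x$best_tuple)) {
    cat("  best tuple: (", paste(x$best_tuple, collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' Tidy / summarize a binding result
#'
#' `tidy()` returns the match table (one row per accepted tuple);
#' `glance()` a one-row summary.
#'
#' @param x A `"bind_result"`.
#' @param ... Unused.
#' @export
tidy.bind_result <- function(x, ...) x$matches

#' @rdname tidy.bind_result
#' @export
glance.bind_result <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, fam_mode = x$fam_mode, t = x$t, queries = x$queries,
    n_matches = nrow(x$matches), recovered = !is.null(x$recovered)
  )
}
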