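#' Power-of-two padding of the address space
#'
#' The quantum index register holds `nu = 2^ceiling(log2(N))` addresses, the
#' smallest power of two at least `N`; addresses `N+1 .. nu` refer to
#' all-zero waste objects, which can never be marked at any threshold
#' `t >= 1`.
#'
#' @param N Scene size (positive integer).
#' @return The padded address-space size `nu`.
#' @examples
#' nu_pad(10) # 16
#' @export
nu_pad <- function(N) {
  if (!is.numeric(N) || length(N) != 1 || N < 1 || N != floor(N)) {
    stop("N must be a positive integer", call. = FALSE)
  }
  2^ceiling(log2(N))
}

#' Uniform superposition over the combination-index space
#'
#' The simulated search state lives on the `P' = nu^M` ordered address
#' tuples `(a1, ..., aM)` with each `a` in `1..nu`: a real amplitude vector
#' indexed lexicographically (first address most significant), initialized
#' uniform at `1 / sqrt(nu^M)`. Amplitudes over the full loaded bit-space
#' are unnecessary because the oracle is a basis permutation plus a flag,
#' so the index-level simulation is exact.
#'
#' @param nu Padded address-space size (a power of two).
#' @param M Tuple length.
#' @return A list of class `"index_state"` with `amplitudes`, `nu`, `M`.
#' @export
init_index_state <- function(nu, M) {
  if (nu < 1 || nu != 2^round(log2(nu))) {
    stop("nu must be a power of two", call. = FALSE)
  }
  if (M < 1 || M != floor(M)) stop("M must be a positive integer", call. = FALSE)
  P <- nu^M
  structure(
    list(amplitudes = rep(1 / sqrt(P), P), nu = nu, M = M),
    class = "index_state"
  )
}

#' Convert between address tuples and state indices
#'
#' Tuples are 1-based addresses in `1..nu`; indices are 1-based positions in
#' the lexicographic enumeration of `{1..nu}^M` (first address most
#' significant).
#'
#' @param tuples An integer matrix with `M` columns (or a single tuple).
#' @param idx Integer state indices.
#' @param nu,M Space parameters.
#' @return `tuple_to_index()` an integer vector; `index_to_tuple()` an
#'   integer matrix with `M` columns.
#' @export
tuple_to_index <- function(tuples, nu) {
  if (!is.matrix(tuples)) tuples <- matrix(tuples, nrow = 1)
  M <- ncol(tuples)
  as.integer((tuples - 1) %*% nu^((M - 1):0) + 1)
}

#' @rdname tuple_to_index
#' @export
index_to_tuple <- function(idx, nu, M) {
  out <- matrix(0L, nrow = length(idx), ncol = M)
  v <- idx - 1
  for (s in M:1) {
    out[, s] <- as.integer(v %% nu) + 1L
    v <- v %/% nu
  }
  colnames(out) <- paste0("a", seq_len(M))
  out
}

#' One Grover iteration
#'
#' Applies the oracle phase flip (amplitudes of marked tuples change sign)
#' followed by inversion about the mean (the diffusion operator). The norm
#' is preserved exactly up to floating-point rounding.
#'
#' @param state An `"index_state"`.
#' @param marked Marked tuples: an integer matrix of address tuples, or a
#'   vector of state indices.
#' @return The updated `"index_state"`.
#' @export
grover_iterate <- function(state, marked) {
  if (length(state$amplitudes) == 0) stop("empty state", call. = FALSE)
  idx <- marked_indices(state, marked)
  a <- state$amplitudes
  a[idx] <- -a[idx]
  state$amplitudes <- 2 * mean(a) - a
  state
}

marked_indices <- function(state, marked) {
  if (is.matrix(marked) || (is.data.frame(marked))) {
    tuple_to_index(as.matrix(marked), state$nu)
  } else {
    as.integer(marked)
  }
}

#' @rdname grover_iterate
#' @param k Number of iterations.
#' @export
grover_run_iterations <- function(state, marked, k) {
  idx <- marked_indices(state, marked)
  for (i in seq_len(k)) state <- grover_iterate(state, idx)
  state
}

#' Probability mass on the marked set
#'
#' @inheritParams grover_iterate
#' @return The summed squared amplitude over the marked tuples.
#' @export
marked_probability <- function(state, marked) {
  sum(state$amplitudes[marked_indices(state, marked)]^2)
}

#' Grover iteration schedule and closed-form success probability
#'
#' `optimal_iterations()` is the standard schedule
#' `floor((pi / 4) sqrt(P' / r))` for `r` solutions in a space of size `P'`;
#' `grover_success_prob()` the closed-form success probability
#' `sin^2((2 k + 1) theta)` with `theta = arcsin(sqrt(r / P'))` after `k`
#' iterations from the uniform state.
#'
#' @param P_space Search-space size `P'`.
#' @param r Number of solutions, `1 <= r <= P'`.
#' @param k Iteration count.
#' @return An integer (`optimal_iterations`) or a probability in `[0, 1]`.
#' @examples
#' optimal_iterations(4096, 1) # 50
#' grover_success_prob(4, 1, 1) # exactly 1
#' @export
optimal_iterations <- function(P_space, r) {
  if (r < 1 || r > P_space) stop("need 1 <= r <= P'", call. = FALSE)
  as.integer(floor(pi / 4 * sqrt(P_space / r)))
}

#' @rdname optimal_iterations
#' @export
grover_success_prob <- function(P_space, r, k) {
  theta <- asin(sqrt(r / P_space))
  sin((2 * k + 1) * theta)^2
}

#' Sample measurements from an index state
#'
#' Draws `n` address tuples from the Born distribution `|amplitude|^2`.
#'
#' @param state An `"index_state"`.
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return An integer matrix of sampled tuples (`n` rows, `M` columns).
#' @export
measure_state <- function(state, n = 1, seed = NULL) {
  probs <- state$amplitudes^2
  idx <- local_seed(seed,
    sample.int(length(probs), n, replace = TRUE, prob = probs))
  index_to_tuple(idx, state$nu, state$M)
}

#' Precompute the oracle's marked set
#'
#' Evaluates the familiarity oracle classically for every tuple of the
#' `nu^M` index space (the simulation device that replaces per-iteration
#' circuit evaluation: the oracle acts on basis states, so its marked set
#' fully determines the dynamics). Tuples addressing waste objects
#' (`> scene$N`) produce all-zero candidate slots and are never marked at a
#' positive threshold.
#'
#' @param scene A `"scene"`.
#' @param W Learned weight matrix of dimension `M * p`.
#' @param M Category size.
#' @param fam_mode Familiarity statistic, `"cosine"` or `"net"`.
#' @param t Threshold (fraction for cosine mode, integer for net mode).
#' @param nu Padded address-space size (default `nu_pad(scene$N)`).
#' @return A tibble of marked tuples (columns `a1..aM`) with their `net` and
#'   `cosine` statistics; the full space size is in attribute `P_space`.
#' @export
mark_set <- function(scene, W, M, fam_mode = c("cosine", "net"), t = 0.87,
                     nu = NULL) {
  fam_mode <- match.arg(fam_mode)
  if (is.null(nu)) nu <- nu_pad(scene$N)
  if (M * scene$p != ncol(W)) {
    stop("dimension mismatch between scene entities and memory", call. = FALSE)
  }
  tuples <- enumerate_tuples(nu, M, "perm_rep")
  X <- candidate_matrix(scene, tuples)
  stats <- fam_stats(W, X, fam_mode, t)
  out <- dplyr::bind_cols(tibble::as_tibble(as.data.frame(tuples)), stats)
  out <- dplyr::filter(out, .data$sim == 1L)
  attr(out, "P_space") <- nrow(tuples)
  attr(out, "nu") <- nu
  out
}

#' Hybrid Grover search over a scene
#'
#' Simulates the full hybrid loop: a uniform superposition over the `nu^M`
#' address tuples is amplified for `floor((pi / 4) sqrt(P' / r))` Grover
#' iterations against the familiarity oracle, a tuple is measured, and every
#' distinct marked tuple found is handed back to the classical memory, whose
#' one-step retrieval returns the stored noise-free category. Measurement
#' repeats (re-preparing the same amplified state) until `r` distinct marked
#' tuples have been seen or the repeat budget is exhausted.
#'
#' @param scene A `"scene"`.
#' @param W Learned weight matrix.
#' @param M Category size.
#' @param r Assumed number of solutions (solution counting is outside this
#'   simulator; tests obtain `r` from the generator's ground truth).
#' @param fam_mode,t Familiarity configuration (see [mark_set()]).
#' @param seed Integer seed for the measurements.
#' @param repeats Measurement repeat budget.
#' @param marks Optional precomputed [mark_set()] (avoids rescreening the
#'   index space when many replicate searches share one fixture).
#' @return A list of class `"grover_search"`: `found` (tibble of distinct
#'   marked tuples in discovery order), `recovered` (list of retrieved
#'   category vectors), `measurements` (all sampled tuples), `oracle_calls`
#'   (`k * repeats_used`), `plan` (`P_space`, `nu`, `r`, `k`,
#'   `predicted_success`), `status` (`"complete"` or `"partial"`).
#' @export
run_search <- function(scene, W, M, r = 1, fam_mode = c("cosine", "net"),
                       t = 0.87, seed = NULL, repeats = 100, marks = NULL) {
  fam_mode <- match.arg(fam_mode)
  if (r < 1) stop("r must be at least 1", call. = FALSE)
  if (is.null(marks)) marks <- mark_set(scene, W, M, fam_mode, t)
  nu <- attr(marks, "nu")
  P_space <- attr(marks, "P_space")
  k <- optimal_iterations(P_space, r)
  marked_idx <- if (nrow(marks) > 0) {
    tuple_to_index(as.matrix(marks[, seq_len(M)]), nu)
  } else integer(0)

  state <- init_index_state(nu, M)
  state <- grover_run_iterations(state, marked_idx, k)

  found <- integer(0)
  samples <- matrix(0L, nrow = 0, ncol = M)
  used <- 0L
  local_seed(seed, {
    for (rep in seq_len(repeats)) {
      used <- rep
      tup <- measure_state(state, 1)
      samples <- rbind(samples, tup)
      idx <- tuple_to_index(tup, nu)
      if (idx %in% marked_idx && !idx %in% found) found <- c(found, idx)
      if (length(found) >= r) break
    }
  })

  found_tuples <- index_to_tuple(found, nu, M)
  recovered <- lapply(seq_len(nrow(found_tuples)), function(i) {
    Xc <- candidate_matrix(scene, found_tuples[i, , drop = FALSE])
    retrieve(W, Xc[, 1])$y
  })
  status <- if (length(found) >= r) "complete" else "partial"
  if (status == "partial") {
    warning("repeat budget exhausted: found ", length(found), " of ", r,
            " solutions", call. = FALSE)
  }
  structure(
    list(found = tibble::as_tibble(as.data.frame(found_tuples)),
         recovered = recovered,
         measurements = tibble::as_tibble(as.data.frame(samples)),
         oracle_calls = k * used,
         plan = list(P_space = P_space, nu = nu, r = r, k = k,
                     predicted_success = grover_success_prob(P_space,
                                                             max(1, nrow(marks)),
                                                             k)),
         n_marked = nrow(marks), status = status,
         fam_mode = fam_mode, t = t),
    class = "grover_search"
  )
}

#' @export
print.grover_search <- function(x, ...) {
  cat(sprintf("Grover search: P' = %d, k = %d iterations, %d marked, status %s\n",
              x$plan$P_space, x$plan$k, x$n_marked, x$status))
  if (nrow(x$found) > 0) {
    cat("found tuples:\n")
    print(x$found)
  }
  cat(sprintf("oracle calls: %d, predicted success %.4f\n",
              x$oracle_calls, x$plan$predicted_success))
  invisible(x)
}

#' @rdname tidy.bind_result
#' @export
glance.grover_search <- function(x, ...) {
  tibble::tibble(
    P_space = x$plan$P_space, k = x$plan$k, r = x$plan$r,
    n_marked = x$n_marked, n_found = nrow(x$found),
    oracle_calls = x$oracle_calls,
    predicted_success = x$plan$predicted_success,
    status = x$status
  )
}

#' Classical versus quantum cost accounting
#'
#' Collects the combination-space sizes and gate counts of the hybrid
#' algorithm for given scene and category sizes: the query counts
#' `L = Perm(N, M)` and `P = N^M`, the padded quantum space `P' = nu^M`, the
#' Grover schedule `floor((pi / 4) sqrt(P' / r))`, the reversible-load gate
#' count `N (N - 1) p`, the familiarity-circuit gate count
#' `4 n^2 = 4 (p M)^2`, the state-preparation cost `N * M`, and the ordering
#' check `sqrt(P') < L < P` that expresses the quadratic advantage regime
#' (`M >= 2`; for `M = 1` the chain collapses to `L = P = N`).
#'
#' @param N Scene size.
#' @param M Category size.
#' @param p Bits per cognitive entity (default 300).
#' @param r Assumed number of solutions.
#' @return A list of class `"cost_report"`.
#' @examples
#' cost_report(7, 3)$ordering_check # sqrt(512) < 210 < 343
#' @export
cost_report <- function(N, M, p = 300, r = 1) {
  L <- perm_count(N, M)
  P <- perm_rep_count(N, M)
  nu <- nu_pad(N)
  P_space <- nu^M
  structure(
    list(N = N, M = M, p = p, r = r,
         L = L, P = P, nu = nu, P_space = P_space,
         sqrt_P_space = sqrt(P_space),
         k_grover = optimal_iterations(P_space, r),
         load_gates = N * (N - 1) * p,
         familiarity_gates = 4 * (p * M)^2,
         prep_cost = N * M,
         classical_cost = P,
         quantum_cost = sqrt(P) + N * M,
         ordering_check = M >= 2 && sqrt(P_space) < L && L < P),
    class = "cost_report"
  )
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf("Cost report (N = %d, M = %d, p = %d, r = %d)\n", x$N, x$M, x$p, x$r))
  cat(sprintf("  L = Perm(N, M) = %s, P = N^M = %s, P' = nu^M = %s (nu = %d)\n",
              format(x$L, big.mark = " "), format(x$P, big.mark = " "),
              format(x$P_space, big.mark = " "), x$nu))
  cat(sprintf("  sqrt(P') = %.2f, Grover iterations k = %d\n",
              x$sqrt_P_space, x$k_grover))
  cat(sprintf("  load gates N(N-1)p = %s, familiarity gates 4(pM)^2 = %s\n",
              format(x$load_gates, big.mark = " "),
              format(x$familiarity_gates, big.mark = " ")))
  cat(sprintf("  ordering sqrt(P') < L < P: %s\n", x$ordering_check))
  invisible(x)
}

#' @rdname tidy.bind_result
#' @export
tidy.cost_report <- function(x, ...) {
  tibble::tibble(
    quantity = c("L", "P", "nu", "P_space", "sqrt_P_space", "k_grover",
                 "load_gates", "familiarity_gates", "prep_cost"),
    value = c(x$L, x$P, x$nu, x$P_space, x$sqrt_P_space, x$k_grover,
              x$load_gates, x$familiarity_gates, x$prep_cost)
  )
}
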