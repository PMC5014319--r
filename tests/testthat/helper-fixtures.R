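# shared fixtures, all generated in code

# random sparse binary pattern of length n with m ones
random_pattern <- function(n, m) {
  b <- integer(n)
  b[sample.int(n, m)] <- 1L
  b
}

# a small-p scene of random entities plus an embedded two-slot category
# (the last two entities in slot order, repeated for N < 2); returns scene,
# memory and ground truth
small_circuit_fixture <- function(N = 3, p = 6, seed = 7) {
  withr::with_seed(seed, {
    pats <- lapply(seq_len(N), function(i) random_pattern(p, max(2, p %/% 2)))
    scene <- bit_scene(pats)
    planted <- if (N >= 3) c(2L, 3L) else c(1L, min(2L, N))
    cat_vec <- c(pats[[planted[1]]], pats[[planted[2]]])
    list(scene = scene, W = learn_pairs(list(cat_vec)),
         category = cat_vec, planted = planted)
  })
}

# the full blockworld study fixture (memoised per seed within a test file)
tower_fixture <- local({
  cache <- list()
  function(seed = 5) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      world <- generate_blockworld(seed = seed)
      mem <- learn_category_positions(world$template, world$positions)
      cache[[key]] <<- list(world = world, mem = mem)
    }
    cache[[key]]
  }
})

# brute-force net by the defining double loop (independent of the
# matrix-algebra path in net_value)
net_double_loop <- function(W, x) {
  n <- length(x)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- acc + W[i, j] * x[i] * x[j]
    }
  }
  acc
}

# exhaustive bijectivity check of a circuit over its full (small) bit-space
is_bijective <- function(circuit) {
  w <- circuit$width
  stopifnot(w <= 16)
  seen <- character(0)
  for (v in 0:(2^w - 1)) {
    bits <- as.integer(intToBits(v)[seq_len(w)])
    out <- paste(evaluate_circuit(circuit, state = bits), collapse = "")
    seen <- c(seen, out)
  }
  !anyDuplicated(seen)
}
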