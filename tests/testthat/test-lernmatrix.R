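test_that("clipped-Hebbian learning sets exactly the co-active outer-product entries", {
  W <- learn_pairs(list(c(1, 0, 1)))
  expect_equal(unclass(W),
               matrix(c(1, 0, 1, 0, 0, 0, 1, 0, 1), 3, 3, byrow = TRUE),
               ignore_attr = TRUE)

  expect_equal(sum(learn_pairs(list(c(0, 0, 0)))), 0)

  once <- learn_pairs(list(c(1, 1, 0)))
  twice <- learn_pairs(list(c(1, 1, 0), c(1, 1, 0)))
  expect_identical(unclass(once), unclass(twice))
})

test_that("learning rejects dimension mismatches and non-binary input", {
  expect_error(learn_pairs(list(c(1, 0), c(1, 0, 1))), "dimension mismatch")
  expect_error(learn_pairs(list(c(1, 2, 0))), "non-binary")
  expect_error(learn_pairs(list(c(1, 0)), list(c(1, 0), c(0, 1))), "dimension mismatch")
})

test_that("max-threshold retrieval completes exact and partial cues", {
  W <- learn_pairs(list(c(1, 0, 1)))

  r <- retrieve(W, c(1, 0, 1))
  expect_equal(r$sums, c(2L, 0L, 2L))
  expect_equal(r$threshold_used, 2L)
  expect_equal(r$y, c(1L, 0L, 1L))

  r2 <- retrieve(W, c(1, 0, 0))
  expect_equal(r2$sums, c(1L, 0L, 1L))
  expect_equal(r2$threshold_used, 1L)
  expect_equal(r2$y, c(1L, 0L, 1L))
})

test_that("a zero maximal dendritic sum raises the degenerate-retrieval error", {
  W0 <- new_empty <- learn_pairs(list(c(0, 0, 0)))
  expect_error(retrieve(W0, c(1, 1, 1)), class = "scenebind_degenerate_retrieval")
  W <- learn_pairs(list(c(1, 0, 1)))
  expect_error(retrieve(W, c(0, 1, 0)), class = "scenebind_degenerate_retrieval")
  expect_error(backward_project(W, c(0, 1, 0)),
               class = "scenebind_degenerate_retrieval")
})

test_that("backward projection transposes the forward projection", {
  # hetero pair x = (1,1,0), y = (0,1): backward of y recovers x
  Wh <- learn_pairs(list(c(1, 1, 0)), list(c(0, 1)))
  b <- backward_project(Wh, c(0, 1))
  expect_equal(b$y, c(1L, 1L, 0L))

  # symmetric auto-associative memory: backward equals forward
  W <- learn_pairs(list(c(1, 0, 1, 1), c(0, 1, 1, 0)))
  cue <- c(1, 0, 0, 1)
  expect_identical(backward_project(W, cue)$y, retrieve(W, cue)$y)
})

test_that("hamming distance counts differing positions", {
  expect_equal(hamming_distance(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(hamming_distance(c(1, 0, 1), c(0, 1, 0)), 3)
  expect_equal(hamming_distance(c(1, 0, 1), c(1, 1, 1)), 1)
  expect_error(hamming_distance(c(1, 0), c(1, 0, 1)), "dimension mismatch")
})

test_that("quadratic form and energy follow the definition", {
  W <- learn_pairs(list(c(1, 0, 1)))
  expect_equal(net_value(W, c(1, 0, 1)), 4)
  expect_equal(energy(W, c(1, 0, 1)), -4)
  expect_equal(net_value(W, c(0, 0, 0)), 0)
  expect_error(net_value(learn_pairs(list(c(1, 0)), list(c(1, 0, 1))), c(1, 0)),
               "square")
})

test_that("net by the double loop equals the matrix-vector form on random instances", {
  withr::with_seed(11, {
    for (rep in 1:100) {
      n <- sample(2:10, 1)
      W <- learn_pairs(lapply(1:2, function(i) random_pattern(n, sample.int(n, 1))))
      x <- random_pattern(n, sample.int(n, 1))
      expect_equal(net_value(W, x), net_double_loop(W, x))
    }
  })
})

test_that("energy is non-increasing as bits of a stored pattern are added to a cue", {
  # brute force over all sub-patterns of a stored pattern: adding any stored
  # bit can only add non-negative terms to net, so H = -net cannot rise
  stored <- c(1, 1, 0, 1, 1)
  W <- learn_pairs(list(stored))
  on <- which(stored == 1)
  for (v in 0:(2^length(on) - 1)) {
    sub <- integer(length(stored))
    sub[on[as.logical(intToBits(v)[seq_along(on)])]] <- 1L
    for (add in setdiff(on, which(sub == 1))) {
      grown <- sub
      grown[add] <- 1L
      expect_lte(energy(W, grown), energy(W, sub))
    }
  }
})

test_that("familiarity with auto threshold accepts a stored cue", {
  W <- learn_pairs(list(c(1, 0, 1)))
  f <- familiarity(W, c(1, 0, 1), mode = "net", t = "auto")
  expect_equal(f$threshold_T, 2L)
  expect_equal(f$threshold_t, 1)
  expect_equal(f$net, 4)
  expect_equal(f$sim, 1L)
  expect_equal(f$energy, -4)
  expect_equal(f$hamming, 0L)
})

test_that("familiarity rejects the zero cue at any positive threshold", {
  W <- learn_pairs(list(c(1, 0, 1)))
  expect_equal(familiarity(W, c(0, 0, 0), mode = "net", t = 1)$sim, 0L)
  expect_error(familiarity(W, c(0, 0, 0), mode = "cosine", t = 0.5),
               class = "scenebind_degenerate_retrieval")
})

test_that("a stored cue has cosine 1 and passes any cosine threshold", {
  W <- learn_pairs(list(c(1, 0, 1, 1)))
  f <- familiarity(W, c(1, 0, 1, 1), mode = "cosine", t = 1)
  expect_equal(f$cosine, 1)
  expect_equal(f$sim, 1L)
})

test_that("familiarity validates its threshold range per mode", {
  W <- learn_pairs(list(c(1, 0, 1)))
  expect_error(familiarity(W, c(1, 0, 1), mode = "cosine", t = 1.5), "outside")
  expect_error(familiarity(W, c(1, 0, 1), mode = "net", t = 10), "outside")
  expect_error(familiarity(W, c(1, 0, 1), mode = "net", t = -1), "outside")
})

test_that("learning is monotone, order-independent and symmetric for auto-association", {
  withr::with_seed(23, {
    for (rep in 1:25) {
      n <- sample(2:8, 1)
      pats <- lapply(1:sample(1:4, 1), function(i) random_pattern(n, sample.int(n, 1)))
      W <- learn_pairs(pats)
      # OR of per-pair outer products
      expected <- Reduce(function(acc, p) pmax(acc, p %o% p), pats,
                         accumulate = FALSE, init = matrix(0L, n, n))
      expect_equal(unclass(W), expected, ignore_attr = TRUE)
      # permutation invariance
      W2 <- learn_pairs(pats[sample(seq_along(pats))])
      expect_identical(unclass(W), unclass(W2))
      # symmetry
      expect_identical(unclass(W), t(unclass(W)))
    }
  })
})

test_that("no stored pattern misses itself and a lone pattern retrieves exactly", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      n <- sample(3:12, 1)
      pats <- lapply(1:sample(1:3, 1), function(i) random_pattern(n, sample(2:n, 1)))
      W <- learn_pairs(pats)
      for (p in pats) {
        r <- retrieve(W, p)
        # every unit of the stored pattern reaches the maximal sum |p| = T
        expect_true(all(r$y[p == 1] == 1L))
        expect_equal(r$threshold_used, sum(p))
      }
      if (length(pats) == 1) {
        expect_identical(retrieve(W, pats[[1]])$y, pats[[1]])
      }
    }
  })
})

test_that("mutually disjoint stored patterns are all familiar at the auto threshold", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      n <- sample(10:32, 1)
      k <- sample(2:5, 1)
      slots <- split(sample.int(n), cut(seq_len(n), k, labels = FALSE))
      pats <- lapply(slots, function(idx) {
        p <- integer(n)
        p[idx[seq_len(max(1, length(idx) - 1))]] <- 1L
        p
      })
      W <- learn_pairs(pats)
      for (p in pats) {
        expect_equal(familiarity(W, p, mode = "net", t = "auto")$sim, 1L)
      }
    }
  })
})

test_that("weight matrices round-trip through the text format", {
  withr::with_seed(53, {
    W <- learn_pairs(lapply(1:3, function(i) random_pattern(7, 3)),
                     lapply(1:3, function(i) random_pattern(5, 2)))
    path <- withr::local_tempfile()
    write_weight_matrix(W, path)
    expect_identical(unclass(read_weight_matrix(path)), unclass(W))
    header <- scan(path, what = integer(), n = 2, quiet = TRUE)
    expect_equal(header, c(5L, 7L))
  })
})
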