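test_that("the address space pads to the next power of two", {
  expect_equal(nu_pad(7), 8)
  expect_equal(nu_pad(16), 16)
  expect_equal(nu_pad(10), 16)
  expect_equal(nu_pad(1), 1)
  expect_error(nu_pad(0), "positive")
})

test_that("the initial index state is uniform and normalized", {
  s <- init_index_state(2, 1)
  expect_equal(s$amplitudes, rep(1 / sqrt(2), 2))
  s2 <- init_index_state(4, 2)
  expect_equal(s2$amplitudes, rep(1 / 4, 16))
  for (nu in c(2, 4, 8, 16)) {
    for (M in 1:3) {
      st <- init_index_state(nu, M)
      expect_equal(sum(st$amplitudes^2), 1, tolerance = 1e-12)
    }
  }
  expect_error(init_index_state(3, 1), "power of two")
})

test_that("tuple/index conversion is a lexicographic bijection", {
  nu <- 4; M <- 3
  idx <- seq_len(nu^M)
  tuples <- index_to_tuple(idx, nu, M)
  expect_equal(tuple_to_index(tuples, nu), idx)
  expect_equal(unname(tuples[1, ]), c(1L, 1L, 1L))
  expect_equal(unname(tuples[nu^M, ]), c(4L, 4L, 4L))
  # first address most significant
  expect_equal(unname(tuples[nu^2 + 1, ]), c(2L, 1L, 1L))
})

test_that("one iteration on a 4-state space with one solution succeeds exactly", {
  s <- init_index_state(4, 1)
  s <- grover_iterate(s, 3L)
  expect_equal(marked_probability(s, 3L), 1, tolerance = 1e-12)
})

test_that("with no marked tuples the state is unchanged up to global sign", {
  s <- init_index_state(8, 1)
  s2 <- grover_iterate(s, integer(0))
  expect_equal(abs(s2$amplitudes), abs(s$amplitudes), tolerance = 1e-12)
})

test_that("simulated success equals the closed form across space sizes and solution counts", {
  for (P in c(4, 64, 1024, 4096)) {
    for (r in c(1, 2, 4)) {
      s <- init_index_state(P, 1)
      marked <- seq_len(r)
      k <- optimal_iterations(P, r)
      s <- grover_run_iterations(s, marked, k)
      expect_equal(marked_probability(s, marked),
                   grover_success_prob(P, r, k),
                   tolerance = 1e-9)
    }
  }
})

test_that("the norm survives a thousand iterations", {
  s <- init_index_state(64, 1)
  for (i in 1:1000) s <- grover_iterate(s, 5L)
  expect_equal(sum(s$amplitudes^2), 1, tolerance = 1e-12)
})

test_that("the iteration schedule follows floor((pi/4) sqrt(P'/r))", {
  expect_equal(optimal_iterations(4, 1), 1)
  expect_equal(optimal_iterations(4096, 1), 50)
  expect_equal(optimal_iterations(4096, 4), 25)
  expect_equal(optimal_iterations(64, 1), 6)
  expect_error(optimal_iterations(16, 0), "r")
})

test_that("measurement frequencies follow the Born rule", {
  s <- init_index_state(16, 1)
  s <- grover_run_iterations(s, c(3L, 11L), 1)
  probs <- s$amplitudes^2
  n <- 10000
  draws <- measure_state(s, n, seed = 5)
  idx <- tuple_to_index(draws, 16)
  for (i in seq_len(16)) {
    got <- sum(idx == i)
    sigma <- sqrt(n * probs[i] * (1 - probs[i]))
    expect_lt(abs(got - n * probs[i]), 3 * sigma + 1e-9)
  }
})

test_that("the marked set equals the brute-force classical screen", {
  withr::with_seed(47, {
    for (rep in 1:3) {
      N <- sample(3:4, 1); p <- 8; M <- 2
      pats <- lapply(seq_len(N), function(i) random_pattern(p, 3))
      scene <- bit_scene(pats)
      W <- learn_pairs(list(c(pats[[1]], pats[[2]])))
      # above the largest single-slot net (3 ones -> 9), so tuples with an
      # all-zero waste slot cannot pass on their real slot alone
      t <- 10
      marks <- mark_set(scene, W, M, fam_mode = "net", t = t)
      nu <- attr(marks, "nu")
      tuples <- enumerate_tuples(nu, M, "perm_rep")
      brute <- apply(tuples, 1, function(tp) {
        Xc <- scenebind:::candidate_matrix(scene, matrix(tp, nrow = 1))
        as.integer(net_value(W, Xc[, 1]) >= t)
      })
      got <- apply(as.matrix(marks[, 1:2]), 1, paste, collapse = ",")
      want <- apply(tuples[brute == 1L, , drop = FALSE], 1, paste, collapse = ",")
      expect_setequal(got, want)
      # waste addresses are never marked
      expect_true(all(as.matrix(marks[, 1:2]) <= N))
    }
  })
})

test_that("an untrained memory marks nothing", {
  pats <- list(c(1, 0, 1, 0), c(0, 1, 0, 1))
  scene <- bit_scene(pats)
  W0 <- learn_pairs(list(rep(0L, 8)))
  marks <- mark_set(scene, W0, 2, fam_mode = "net", t = 1)
  expect_equal(nrow(marks), 0)
})

test_that("the hybrid search finds the planted tower and hands off to exact retrieval", {
  fix <- tower_fixture()
  world <- fix$world; mem <- fix$mem
  marks <- mark_set(world$scene, mem$W, 3)
  expect_equal(nrow(marks), 1)
  expect_equal(unname(as.integer(marks[1, 1:3])), world$planted_addresses)
  expect_equal(attr(marks, "P_space"), 4096)

  gs <- run_search(world$scene, mem$W, 3, r = 1, seed = 77, marks = marks)
  expect_equal(gs$plan$k, 50)
  expect_equal(gs$status, "complete")
  expect_equal(unname(as.integer(gs$found[1, ])), world$planted_addresses)
  expect_identical(gs$recovered[[1]], as.integer(mem$stored[world$planted_index, ]))
  expect_equal(gs$oracle_calls, 50 * nrow(gs$measurements))
})

test_that("the search reports a partial result when the budget is too small", {
  # two disjoint planted categories in a small scene, budget 1
  withr::with_seed(59, {
    pats <- lapply(1:4, function(i) random_pattern(10, 3))
    scene <- bit_scene(pats)
    W <- learn_pairs(list(c(pats[[1]], pats[[2]]), c(pats[[3]], pats[[4]])))
    marks <- mark_set(scene, W, 2, fam_mode = "cosine", t = 0.99)
    expect_gte(nrow(marks), 2)
    expect_warning(
      gs <- run_search(scene, W, 2, r = nrow(marks) + 5, seed = 3, repeats = 1,
                       marks = marks),
      "budget"
    )
    expect_equal(gs$status, "partial")
  })
})

test_that("search results agree with the classical screen on accepted tuples", {
  fix <- tower_fixture()
  world <- fix$world; mem <- fix$mem
  marks <- mark_set(world$scene, mem$W, 3)
  bind <- classical_bind(world$scene, mem$W, 3, mode = "perm_rep")
  a <- apply(as.matrix(marks[, 1:3]), 1, paste, collapse = ",")
  b <- apply(as.matrix(bind$matches[, 1:3]), 1, paste, collapse = ",")
  expect_setequal(a, b)
})

test_that("the cost report reproduces the quadratic-advantage ordering", {
  cr <- cost_report(7, 3, p = 300)
  expect_equal(cr$L, 210)
  expect_equal(cr$P, 343)
  expect_equal(cr$P_space, 512)
  expect_equal(cr$sqrt_P_space, sqrt(512))
  expect_true(cr$ordering_check)

  cr10 <- cost_report(10, 3, p = 300)
  expect_equal(cr10$load_gates, 27000)
  expect_equal(cr10$familiarity_gates, 3240000)

  cr1 <- cost_report(5, 1, p = 20)
  expect_equal(cr1$L, 5)
  expect_equal(cr1$P, 5)
  expect_equal(cr1$P_space, 8)
  expect_false(cr1$ordering_check)

  td <- tidy(cr)
  expect_equal(td$value[td$quantity == "load_gates"], 7 * 6 * 300)
})
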