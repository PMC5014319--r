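test_that("the Peres gate computes the full-adder truth table on all operand triples", {
  for (v in 0:7) {
    x <- as.integer(intToBits(v)[1:3])
    out <- peres_full_adder(x[1], x[2], x[3], 0)
    total <- x[1] + x[2] + x[3]
    expect_equal(unname(out[1]), x[1])         # first operand passes through
    expect_equal(unname(out[3]), total %% 2)   # sum
    expect_equal(unname(out[4]), total %/% 2)  # carry
  }
  expect_equal(unname(peres_full_adder(1, 1, 0, 0)), c(1L, 0L, 0L, 1L))
  expect_equal(unname(peres_full_adder(1, 0, 1, 0)), c(1L, 1L, 0L, 1L))
  expect_equal(unname(peres_full_adder(0, 0, 0, 0)), c(0L, 0L, 0L, 0L))
})

test_that("the full subtractor computes difference and borrow on all operand triples", {
  for (v in 0:7) {
    x <- as.integer(intToBits(v)[1:3])
    out <- full_subtractor(x[1], x[2], x[3], 0)
    d <- x[1] - x[2] - x[3]
    expect_equal(unname(out[3]), ((d %% 2) + 2) %% 2)     # difference bit
    expect_equal(unname(out[4]), as.integer(d < 0))       # borrow out
  }
  expect_equal(unname(full_subtractor(0, 1, 0, 0)), c(0L, 1L, 1L, 1L))
  expect_equal(unname(full_subtractor(1, 1, 0, 0)), c(1L, 0L, 0L, 0L))
})

test_that("gate primitives are bijections on their wires", {
  for (kind in c("PERES", "FULL_SUB")) {
    outs <- vapply(0:15, function(v) {
      bits <- as.integer(intToBits(v)[1:4])
      circ <- structure(list(width = 4L, registers = list(all = 1:4),
                             init = integer(4),
                             gates = list(scenebind:::new_gate(kind, 1:4))),
                        class = "oracle_circuit")
      paste(evaluate_circuit(circ, state = bits), collapse = "")
    }, character(1))
    expect_equal(anyDuplicated(outs), 0)
  }
})

test_that("random small circuits invert exactly", {
  withr::with_seed(61, {
    for (rep in 1:20) {
      w <- 8L
      gates <- lapply(1:15, function(i) {
        kind <- sample(c("NOT", "CNOT", "TOFFOLI", "PERES", "FULL_SUB"), 1)
        nw <- c(NOT = 1, CNOT = 2, TOFFOLI = 3, PERES = 4, FULL_SUB = 4)[[kind]]
        scenebind:::new_gate(kind, sample.int(w, nw))
      })
      circ <- structure(list(width = w, registers = list(all = 1:w),
                             init = integer(w), gates = gates),
                        class = "oracle_circuit")
      inv <- invert_circuit(circ)
      for (i in 1:50) {
        b <- sample(0:1, w, replace = TRUE)
        expect_identical(evaluate_circuit(inv, state = evaluate_circuit(circ, state = b)), b)
      }
      expect_true(is_bijective(circ))
    }
  })
})

test_that("the empty circuit is the identity and a CNOT flips its target", {
  empty <- structure(list(width = 3L, registers = list(all = 1:3),
                          init = integer(3), gates = list()),
                     class = "oracle_circuit")
  expect_identical(evaluate_circuit(empty, state = c(1L, 0L, 1L)), c(1L, 0L, 1L))
  cnot <- structure(list(width = 2L, registers = list(all = 1:2),
                         init = integer(2),
                         gates = list(scenebind:::new_gate("CNOT", 1:2))),
                    class = "oracle_circuit")
  expect_identical(evaluate_circuit(cnot, state = c(1L, 0L)), c(1L, 1L))
  expect_identical(evaluate_circuit(cnot, state = c(0L, 1L)), c(0L, 1L))
})

test_that("the load multiplexer fetches every addressed entity exactly", {
  for (N in 2:4) {
    fix <- small_circuit_fixture(N = N, p = 4, seed = 70 + N)
    circ <- build_load_circuit(fix$scene)
    expect_equal(circ$gate_count, N * (N - 1) * 4)
    nu <- circ$nu
    for (alpha in seq_len(nu)) {
      got <- load_entity(fix$scene, alpha, circ)
      want <- if (alpha <= N) fix$scene$entities[[alpha]]$bits else integer(4)
      expect_identical(got, want)
    }
    # scene register must be untouched by the load
    st <- evaluate_circuit(circ, list(addr = scenebind:::int_to_bits(0L, length(circ$registers$addr))))
    expect_identical(st[circ$registers$scene], circ$init[circ$registers$scene])
  }
})

test_that("a single-entity scene loads its only object", {
  fix <- small_circuit_fixture(N = 1, p = 5, seed = 81)
  circ <- build_load_circuit(fix$scene)
  expect_equal(circ$gate_count, 0) # N (N - 1) p with N = 1
  expect_identical(load_entity(fix$scene, 1, circ), fix$scene$entities[[1]]$bits)
})

test_that("the familiarity circuit reports the stated gate accounting", {
  W <- learn_pairs(list(c(1, 0, 1, 1, 0)))
  circ <- build_familiarity_circuit(W, t = 3)
  expect_equal(circ$gate_count, 100) # 4 n^2, n = 5
  expect_equal(circ$gate_breakdown$gates, c(50, 25, 25))
  expect_error(build_familiarity_circuit(W, t = -1), "non-negative")
  expect_error(build_familiarity_circuit(W, t = 26), "outside")
})

test_that("the familiarity circuit's borrow bit equals the classical net decision", {
  withr::with_seed(91, {
    for (rep in 1:10) {
      n <- sample(3:6, 1)
      W <- learn_pairs(lapply(1:2, function(i) random_pattern(n, sample(2:n, 1))))
      t <- sample(0:(n^2), 1)
      circ <- build_familiarity_circuit(W, t)
      for (i in 1:8) {
        x <- sample(0:1, n, replace = TRUE)
        st <- evaluate_circuit(circ, list(x = x))
        classical <- as.integer(net_value(W, x) >= t)
        expect_identical(st[circ$sim_wire], classical)
      }
    }
  })
})

test_that("zero weights never pass a positive threshold through the circuit", {
  W0 <- learn_pairs(list(c(0, 0, 0)))
  circ <- build_familiarity_circuit(W0, t = 1)
  for (v in 0:7) {
    x <- as.integer(intToBits(v)[1:3])
    expect_equal(evaluate_circuit(circ, list(x = x))[circ$sim_wire], 0L)
  }
})

test_that("the composed oracle agrees with classical familiarity exhaustively and uncomputes", {
  for (N in 2:4) {
    for (M in 1:2) {
      fix <- small_circuit_fixture(N = N, p = 6, seed = 100 + 10 * N + M)
      cat_vec <- unlist(lapply(seq_len(M), function(s) fix$scene$entities[[min(s + 1, N)]]$bits))
      W <- learn_pairs(list(cat_vec))
      t <- 5L
      circ <- build_oracle_circuit(fix$scene, W, t, M)
      tuples <- enumerate_tuples(circ$nu, M, "perm_rep")
      for (k in seq_len(nrow(tuples))) {
        run <- oracle_run(fix$scene, W, t, tuples[k, ], circuit = circ)
        Xc <- scenebind:::candidate_matrix(fix$scene, tuples[k, , drop = FALSE])
        expect_identical(run$sim, as.integer(net_value(W, Xc[, 1]) >= t))
        expect_true(run$restored)
      }
    }
  }
})

test_that("the oracle accepts the planted tuple and rejects unrelated ones", {
  fix <- small_circuit_fixture(N = 4, p = 6, seed = 131)
  t <- as.integer(sum(fix$category)^2 %/% 2)
  circ <- build_oracle_circuit(fix$scene, fix$W, t, 2)
  expect_equal(oracle_bit(fix$scene, fix$W, t, fix$planted, circuit = circ), 1L)
  # waste addresses load all-zero objects: never familiar at t >= 1
  expect_equal(oracle_bit(fix$scene, fix$W, t, c(circ$nu, circ$nu), circuit = circ), 0L)
})

test_that("circuit dumps list registers and one gate per line", {
  fix <- small_circuit_fixture(N = 2, p = 3, seed = 141)
  circ <- build_load_circuit(fix$scene)
  lines <- format_circuit(circ)
  expect_true(any(grepl("^# register obj:", lines)))
  body <- lines[!grepl("^#", lines)]
  expect_equal(length(body), circ$n_gates_actual)
  expect_true(all(grepl("^(NOT|CNOT|TOFFOLI|PERES|PERES_INV|FULL_SUB|FULL_SUB_INV)( \\d+)+$",
                        body)))
  path <- withr::local_tempfile()
  write_circuit(circ, path)
  expect_identical(readLines(path), lines)
})
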