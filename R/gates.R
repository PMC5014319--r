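#' Reversible gate primitives
#'
#' `peres_full_adder()` is the Peres gate, a reversible full adder on four
#' wires: with the ancilla `x4 = 0`, the third output is the sum
#' `x1 + x2 + x3 (mod 2)` and the fourth the carry; the first operand passes
#' through unchanged. `full_subtractor()` is the analogous reversible full
#' subtractor: minuend `x1`, subtrahend `x2`, borrow-in `x3`; the third
#' output is the difference bit and the fourth the borrow-out (XOR-ed onto
#' the ancilla so the gate stays a bijection).
#'
#' @param x1,x2,x3,x4 Bits (0 or 1); `x4` is the ancilla, normally 0.
#' @return A named integer vector `c(y1, y2, y3, y4)`.
#' @examples
#' peres_full_adder(1, 1, 0, 0) # sum 0, carry 1
#' full_subtractor(0, 1, 0, 0)  # 0 - 1: difference 1, borrow 1
#' @export
peres_full_adder <- function(x1, x2, x3, x4 = 0) {
  b <- as_bits(c(x1, x2, x3, x4))
  out <- peres_map(b)
  names(out) <- paste0("y", 1:4)
  out
}

#' @rdname peres_full_adder
#' @export
full_subtractor <- function(x1, x2, x3, x4 = 0) {
  b <- as_bits(c(x1, x2, x3, x4))
  out <- fullsub_map(b)
  names(out) <- paste0("y", 1:4)
  out
}

peres_map <- function(x) {
  s <- xor(x[1] == 1, x[2] == 1)
  c(x[1], as.integer(s), as.integer(xor(s, x[3] == 1)),
    as.integer(xor(xor(s & x[3] == 1, x[1] == 1 & x[2] == 1), x[4] == 1)))
}

fullsub_map <- function(x) {
  s <- xor(x[1] == 1, x[2] == 1)
  borrow <- (x[1] == 0 & (x[2] == 1 | x[3] == 1)) | (x[2] == 1 & x[3] == 1)
  c(x[1], as.integer(s), as.integer(xor(s, x[3] == 1)),
    as.integer(xor(borrow, x[4] == 1)))
}

# 16 x 4 truth tables (row = 1 + sum(x_k 2^(k-1))) and their inverses
make_table <- function(fun) {
  t(vapply(0:15, function(v) fun(as.integer(intToBits(v)[1:4])), integer(4)))
}
invert_table <- function(tab) {
  idx <- tab %*% c(1L, 2L, 4L, 8L) + 1L
  inv <- tab
  inv[idx, ] <- t(vapply(0:15, function(v) as.integer(intToBits(v)[1:4]), integer(4)))
  inv
}

.peres_table <- make_table(peres_map)
.peres_inv_table <- invert_table(.peres_table)
.fullsub_table <- make_table(fullsub_map)
.fullsub_inv_table <- invert_table(.fullsub_table)

.gate_kinds <- c("NOT", "CNOT", "TOFFOLI", "PERES", "PERES_INV",
                 "FULL_SUB", "FULL_SUB_INV")
gate_code <- function(kind) match(kind, .gate_kinds)
# inverse gate kind by code: NOT/CNOT/TOFFOLI self-inverse, PERES <-> PERES_INV
.gate_inverse_code <- c(1L, 2L, 3L, 5L, 4L, 7L, 6L)

new_gate <- function(kind, wires) {
  wires <- as.integer(wires)
  if (anyDuplicated(wires)) stop("gate wires must be distinct", call. = FALSE)
  list(kind = gate_code(kind), wires = wires)
}

apply_gate <- function(state, g) {
  w <- g$wires
  switch(g$kind,
    { state[w] <- 1L - state[w]; state },                                   # NOT
    { if (state[w[1]] == 1L) state[w[2]] <- 1L - state[w[2]]; state },      # CNOT
    { if (state[w[1]] == 1L && state[w[2]] == 1L)
        state[w[3]] <- 1L - state[w[3]]
      state },                                                              # TOFFOLI
    { state[w] <- .peres_table[bits_index(state[w]), ]; state },            # PERES
    { state[w] <- .peres_inv_table[bits_index(state[w]), ]; state },        # PERES_INV
    { state[w] <- .fullsub_table[bits_index(state[w]), ]; state },          # FULL_SUB
    { state[w] <- .fullsub_inv_table[bits_index(state[w]), ]; state }       # FULL_SUB_INV
  )
}

bits_index <- function(b) b[1] + 2L * b[2] + 4L * b[3] + 8L * b[4] + 1L

invert_gates <- function(gates) {
  lapply(rev(gates), function(g) {
    list(kind = .gate_inverse_code[g$kind], wires = g$wires)
  })
}

#' Evaluate a reversible circuit on a basis state
#'
#' Applies the circuit's gates in order to a classical basis assignment.
#' The starting state is the circuit's built-in initialization (constant
#' registers such as the scene, weight and threshold bits) overridden by any
#' register assignments in `inputs`, or a full `state` vector.
#'
#' @param circuit An `"oracle_circuit"`.
#' @param inputs A named list of binary vectors, one per register to set.
#' @param state Optionally a full width-length state vector (overrides
#'   `inputs` and the initialization).
#' @return The output basis state: an integer 0/1 vector of length
#'   `circuit$width`.
#' @export
evaluate_circuit <- function(circuit, inputs = list(), state = NULL) {
  if (is.null(state)) {
    state <- circuit$init
    for (nm in names(inputs)) {
      wires <- circuit$registers[[nm]]
      if (is.null(wires)) stop("unknown register: ", nm, call. = FALSE)
      bits <- as_bits(inputs[[nm]])
      if (length(bits) != length(wires)) {
        stop("register ", nm, " expects ", length(wires), " bits, got ",
             length(bits), call. = FALSE)
      }
      state[wires] <- bits
    }
  } else {
    state <- as_bits(state)
    if (length(state) != circuit$width) {
      stop("state must cover all ", circuit$width, " wires", call. = FALSE)
    }
  }
  for (g in circuit$gates) state <- apply_gate(state, g)
  state
}

#' Invert a reversible circuit
#'
#' Returns the mirror circuit: the gate list reversed with every gate
#' replaced by its inverse, so that evaluating the inverse on the output of
#' the original restores the input exactly.
#'
#' @param circuit An `"oracle_circuit"`.
#' @return An `"oracle_circuit"` computing the inverse bijection.
#' @export
invert_circuit <- function(circuit) {
  circuit$gates <- invert_gates(circuit$gates)
  circuit
}

#' Write a circuit as plain text
#'
#' One gate per line, `KIND w1 w2 ...`, preceded by a register-map header in
#' `#` comments -- a stable, inspectable dump for golden tests.
#'
#' @param circuit An `"oracle_circuit"`.
#' @param path File path for `write_circuit()`.
#' @return `format_circuit()` returns a character vector of lines;
#'   `write_circuit()` writes them and returns `path` invisibly.
#' @export
format_circuit <- function(circuit) {
  header <- c(
    sprintf("# width %d", circuit$width),
    vapply(names(circuit$registers), function(nm) {
      sprintf("# register %s: %s", nm,
              paste(circuit$registers[[nm]], collapse = " "))
    }, character(1), USE.NAMES = FALSE)
  )
  body <- vapply(circuit$gates, function(g) {
    paste(c(.gate_kinds[g$kind], g$wires), collapse = " ")
  }, character(1))
  c(header, body)
}

#' @rdname format_circuit
#' @export
write_circuit <- function(circuit, path) {
  writeLines(format_circuit(circuit), path)
  invisible(path)
}
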