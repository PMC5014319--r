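# --- wire allocator -------------------------------------------------------
# A tiny mutable builder: wires are integer ids, registers named wire
# ranges, gates appended in order. Constant registers (scene, weights,
# threshold) carry their bits in `init`.

new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$width <- 0L
  env$registers <- list()
  env$init <- integer(0)
  env$gates <- list()
  env$n_gates <- 0L
  env
}

cb_alloc <- function(cb, n, name = NULL, init = integer(n)) {
  if (n == 0L) {
    if (!is.null(name)) cb$registers[[name]] <- integer(0)
    return(integer(0))
  }
  wires <- cb$width + seq_len(n)
  cb$width <- cb$width + as.integer(n)
  cb$init <- c(cb$init, as.integer(init))
  if (!is.null(name)) cb$registers[[name]] <- wires
  wires
}

cb_gate <- function(cb, kind, wires) {
  cb$n_gates <- cb$n_gates + 1L
  cb$gates[[cb$n_gates]] <- new_gate(kind, wires)
  invisible(cb)
}

cb_circuit <- function(cb, gate_count, meta = list()) {
  structure(
    c(list(width = cb$width, registers = cb$registers, init = cb$init,
           gates = cb$gates, gate_count = gate_count,
           n_gates_actual = cb$n_gates),
      meta),
    class = "oracle_circuit"
  )
}

#' @export
print.oracle_circuit <- function(x, ...) {
  cat(sprintf("Reversible circuit: %d wires, %d gates (reported gate count %s)\n",
              x$width, x$n_gates_actual,
              format(x$gate_count, big.mark = " ")))
  cat("registers:", paste(sprintf("%s[%d]", names(x$registers),
                                  lengths(x$registers)), collapse = " "), "\n")
  invisible(x)
}

# multi-controlled flag: flag ^= AND(controls); chain ancillas are fresh
# zero wires allocated in `anc_reg`
cb_multi_and <- function(cb, controls, target, anc_reg) {
  a <- length(controls)
  if (a == 0L) {
    cb_gate(cb, "NOT", target)
  } else if (a == 1L) {
    cb_gate(cb, "CNOT", c(controls, target))
  } else if (a == 2L) {
    cb_gate(cb, "TOFFOLI", c(controls, target))
  } else {
    acc <- cb_alloc(cb, 1L, NULL)
    cb$registers[[anc_reg]] <- c(cb$registers[[anc_reg]], acc)
    cb_gate(cb, "TOFFOLI", c(controls[1], controls[2], acc))
    for (k in 3:(a - 1)) {
      nxt <- cb_alloc(cb, 1L, NULL)
      cb$registers[[anc_reg]] <- c(cb$registers[[anc_reg]], nxt)
      cb_gate(cb, "TOFFOLI", c(acc, controls[k], nxt))
      acc <- nxt
    }
    cb_gate(cb, "TOFFOLI", c(acc, controls[a], target))
  }
  invisible(cb)
}

int_to_bits <- function(v, width) as.integer(intToBits(v)[seq_len(width)])
bits_to_int <- function(b) sum(b * 2^(seq_along(b) - 1))

# append the load multiplexer for one slot: computes flag_k = [addr == k-1]
# for every k and copies the addressed entity onto the object register.
# Flags and chain ancillas remain set (waste bits of the load).
append_load <- function(cb, ent_bits, nu, p, addr, obj, flag_reg, anc_reg) {
  flags <- cb_alloc(cb, nu, flag_reg)
  cb$registers[[anc_reg]] <- integer(0)
  a <- length(addr)
  for (k in seq_len(nu)) {
    pat <- int_to_bits(k - 1L, a)
    zeros <- addr[pat == 0L]
    for (wz in zeros) cb_gate(cb, "NOT", wz)
    cb_multi_and(cb, addr, flags[k], anc_reg)
    for (wz in zeros) cb_gate(cb, "NOT", wz)
    scene_wires <- cb$registers$scene[((k - 1) * p + 1):(k * p)]
    for (j in seq_len(p)) {
      cb_gate(cb, "TOFFOLI", c(flags[k], scene_wires[j], obj[j]))
    }
  }
  invisible(cb)
}

scene_register_init <- function(scene, nu) {
  ent <- unlist(lapply(scene$entities, function(e) e$bits), use.names = FALSE)
  c(ent, integer((nu - scene$N) * scene$p))
}

#' Build the reversible load multiplexer for a scene
#'
#' Constructs the reversible circuit that, given an address register holding
#' `alpha`, copies the `alpha`-th entity of the scene register onto the
#' (initially zero) object register: for every address value a flag bit is
#' computed by an equality test on the address bits (NOTs plus a Toffoli
#' chain) and the flagged entity's bits are Toffoli-copied out. Flags and
#' chain ancillas remain set as the load's waste bits. The scene is padded
#' with all-zero waste objects up to `nu`, the next power of two.
#'
#' The reported `gate_count` follows the stated accounting for the load,
#' `N (N - 1) p`; the concrete multiplexer construction differs (any correct
#' multiplexer is admissible) and its literal gate list length is kept in
#' `n_gates_actual`.
#'
#' @param scene A `"scene"` with `N` entities of `p` bits.
#' @param nu Padded address-space size; default `nu_pad(scene$N)`.
#' @return An `"oracle_circuit"` with registers `obj`, `addr`, `scene`,
#'   `flags`, `anc`. Evaluate with `inputs = list(addr = bits)` where the
#'   address bits encode `alpha - 1` least-significant first.
#' @examples
#' sc <- new_scene(data.frame(shape = c("cube", "pyramid"),
#'                            x0 = c(0, 20), y0 = c(0, 20),
#'                            width = 10, height = 10))
#' circ <- build_load_circuit(sc)
#' circ$gate_count # N (N - 1) p
#' @export
build_load_circuit <- function(scene, nu = NULL) {
  if (is.null(nu)) nu <- nu_pad(scene$N)
  p <- scene$p
  N <- scene$N
  if (anyDuplicated(scene$objects$address)) stop("duplicate addresses", call. = FALSE)
  a <- as.integer(round(log2(nu)))
  cb <- new_builder()
  obj <- cb_alloc(cb, p, "obj")
  addr <- cb_alloc(cb, a, "addr")
  cb_alloc(cb, nu * p, "scene", init = scene_register_init(scene, nu))
  append_load(cb, NULL, nu, p, addr, obj, "flags", "anc")
  cb_circuit(cb, gate_count = N * (N - 1) * p,
             meta = list(nu = nu, p = p, N = N))
}

#' Load an entity through the reversible multiplexer
#'
#' Convenience evaluator: runs [build_load_circuit()]'s circuit (or a
#' prebuilt one) on address `alpha` and returns the object-register bits.
#'
#' @param scene A `"scene"`.
#' @param alpha Address in `1..nu` (values above `scene$N` hit all-zero
#'   waste objects).
#' @param circuit Optional prebuilt load circuit.
#' @return The loaded entity bits (integer vector of length `p`).
#' @export
load_entity <- function(scene, alpha, circuit = NULL) {
  if (is.null(circuit)) circuit <- build_load_circuit(scene)
  a <- length(circuit$registers$addr)
  state <- evaluate_circuit(circuit, list(addr = int_to_bits(alpha - 1L, a)))
  state[circuit$registers$obj]
}

# append the familiarity core (U_Sim): AND terms, Peres ripple accumulation
# and the threshold subtraction; returns the wire carrying the borrow bit
# (the sim source). All ancillas are collected in the `result` register.
append_usim <- function(cb, x_wires, t) {
  n <- length(x_wires)
  W_wires <- cb$registers$w
  b <- max(1L, ceiling(log2(n^2 + 1)))
  acc <- cb_alloc(cb, b, NULL)
  result <- acc
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      t1 <- cb_alloc(cb, 1L, NULL)
      t2 <- cb_alloc(cb, 1L, NULL)
      result <- c(result, t1, t2)
      if (i == j) {
        cb_gate(cb, "CNOT", c(x_wires[i], t1))
      } else {
        cb_gate(cb, "TOFFOLI", c(x_wires[i], x_wires[j], t1))
      }
      cb_gate(cb, "TOFFOLI", c(t1, W_wires[(i - 1) * n + j], t2))
      carry <- t2
      for (k in seq_len(b)) {
        z <- cb_alloc(cb, 2L, NULL)
        result <- c(result, z)
        cb_gate(cb, "PERES", c(carry, z[1], acc[k], z[2]))
        carry <- z[2]
      }
    }
  }
  if (t == 0) {
    # net >= 0 always holds: sim source is a constant-1 wire
    sim_src <- cb_alloc(cb, 1L, NULL)
    result <- c(result, sim_src)
    cb_gate(cb, "NOT", sim_src)
  } else {
    thr <- cb_alloc(cb, b, "thr", init = int_to_bits(t - 1L, b))
    borrow <- cb_alloc(cb, 1L, NULL)
    result <- c(result, borrow)
    for (k in seq_len(b)) {
      bo <- cb_alloc(cb, 1L, NULL)
      result <- c(result, bo)
      cb_gate(cb, "FULL_SUB", c(thr[k], acc[k], borrow, bo))
      borrow <- bo
    }
    sim_src <- borrow
  }
  cb$registers$result <- result
  list(sim_src = sim_src, acc = acc, b = b)
}

#' Build the reversible familiarity circuit
#'
#' Realizes familiarity discrimination as a reversible circuit: the
#' quadratic form `net = sum_ij w[i, j] & x[i] & x[j]` is accumulated by AND
#' (Toffoli) gates feeding a Peres-adder ripple, and the threshold test
#' `net >= t` is decided by a full-subtractor ripple computing
#' `(t - 1) - net`, whose final borrow bit is the familiarity bit `sim`.
#' Register widths are `ceiling(log2(n^2 + 1))` bits, enough to hold any
#' `net` without overflow.
#'
#' The reported `gate_count` follows the stated accounting, `4 n^2`
#' (`2 n^2` ANDs, `n^2` adders, `n^2` subtractors, itemized in
#' `gate_breakdown`); the literal gate-list length is in `n_gates_actual`.
#'
#' @param W A square binary auto-associative weight matrix.
#' @param t Integer threshold, `0 <= t <= n^2`.
#' @return An `"oracle_circuit"` with registers `x`, `w`, `thr`, `result`
#'   and a `sim_wire` element naming the borrow wire that carries the
#'   decision. Evaluate with `inputs = list(x = cue_bits)`.
#' @export
build_familiarity_circuit <- function(W, t) {
  check_lernmatrix(W)
  n <- ncol(W)
  if (nrow(W) != n) stop("weight matrix must be square", call. = FALSE)
  t <- as.integer(t)
  if (is.na(t) || t < 0) stop("threshold t must be a non-negative integer", call. = FALSE)
  if (t > n^2) stop("threshold t = ", t, " outside [0, ", n^2, "]", call. = FALSE)
  cb <- new_builder()
  x <- cb_alloc(cb, n, "x")
  cb_alloc(cb, n * n, "w", init = as.integer(t(unclass(W))))
  us <- append_usim(cb, x, t)
  circ <- cb_circuit(cb, gate_count = as.integer(4 * n * n),
                     meta = list(
                       sim_wire = us$sim_src, n = n, t = t,
                       gate_breakdown = tibble::tibble(
                         component = c("and", "adder", "subtractor"),
                         gates = c(2L * n^2, n^2, n^2)
                       )
                     ))
  circ
}

#' Compose the full familiarity oracle over a scene
#'
#' Builds the complete reversible oracle for a candidate address tuple:
#' `M` load multiplexers place the addressed entities into object registers
#' whose concatenation is the candidate vector; the familiarity circuit
#' (`U_Sim`) computes the thresholded quadratic form; a CNOT copies the
#' decision borrow bit into the dedicated `sim` wire; and the mirror inverse
#' of `U_Sim` uncomputes every intermediate result, restoring the whole
#' `result` register to zero. Only `sim`, the loaded candidate registers and
#' their load waste bits differ from the pre-oracle state.
#'
#' @param scene A `"scene"`.
#' @param W The learned weight matrix of dimension `M * p`.
#' @param t Integer familiarity threshold.
#' @param M Category size.
#' @param nu Padded address-space size (default `nu_pad(scene$N)`).
#' @return An `"oracle_circuit"` with registers `obj1..objM`,
#'   `addr1..addrM`, `scene`, `w`, `thr`, `result`, `sim`.
#' @export
build_oracle_circuit <- function(scene, W, t, M, nu = NULL) {
  check_lernmatrix(W)
  if (is.null(nu)) nu <- nu_pad(scene$N)
  p <- scene$p
  n <- M * p
  if (ncol(W) != n || nrow(W) != n) {
    stop("weight matrix must be ", n, " x ", n, " for M = ", M, call. = FALSE)
  }
  t <- as.integer(t)
  if (is.na(t) || t < 0 || t > n^2) {
    stop("threshold t must be an integer in [0, ", n^2, "]", call. = FALSE)
  }
  a <- as.integer(round(log2(nu)))
  cb <- new_builder()
  objs <- lapply(seq_len(M), function(s) cb_alloc(cb, p, paste0("obj", s)))
  addrs <- lapply(seq_len(M), function(s) cb_alloc(cb, a, paste0("addr", s)))
  cb_alloc(cb, nu * p, "scene", init = scene_register_init(scene, nu))
  cb_alloc(cb, n * n, "w", init = as.integer(t(unclass(W))))
  sim <- cb_alloc(cb, 1L, "sim")
  for (s in seq_len(M)) {
    append_load(cb, NULL, nu, p, addrs[[s]], objs[[s]],
                paste0("flags", s), paste0("anc", s))
  }
  usim_start <- cb$n_gates + 1L
  us <- append_usim(cb, unlist(objs), t)
  usim_gates <- cb$gates[usim_start:cb$n_gates]
  cb_gate(cb, "CNOT", c(us$sim_src, sim))
  for (g in invert_gates(usim_gates)) {
    cb$n_gates <- cb$n_gates + 1L
    cb$gates[[cb$n_gates]] <- g
  }
  cb_circuit(cb, gate_count = M * scene$N * (scene$N - 1) * p + 2L * 4L * n^2 + 1L,
             meta = list(nu = nu, p = p, N = scene$N, M = M, t = t, n = n,
                         sim_wire = sim))
}

#' Evaluate the familiarity oracle on an address tuple
#'
#' `oracle_run()` evaluates the composed oracle circuit on a basis state
#' encoding the tuple and reports the sim bit together with the uncompute
#' check (whether every `result` wire returned to its initial value);
#' `oracle_bit()` returns just the bit. The result equals the classical
#' [familiarity()] decision in net mode with integer threshold `t` on the
#' concatenated candidate.
#'
#' @param scene A `"scene"`.
#' @param W Learned weight matrix (`M * p` square).
#' @param t Integer threshold.
#' @param tuple Integer address tuple of length `M` (addresses `1..nu`).
#' @param circuit Optional prebuilt circuit from [build_oracle_circuit()]
#'   (build once when screening many tuples).
#' @return `oracle_run()`: a list with `sim`, `restored` (logical),
#'   `state` and `circuit`. `oracle_bit()`: the bit as an integer.
#' @export
oracle_run <- function(scene, W, t, tuple, circuit = NULL) {
  if (is.null(circuit)) {
    circuit <- build_oracle_circuit(scene, W, t, M = length(tuple))
  }
  M <- circuit$M
  if (length(tuple) != M) stop("tuple must have length ", M, call. = FALSE)
  if (any(tuple < 1 | tuple > circuit$nu)) {
    stop("addresses must lie in 1..", circuit$nu, call. = FALSE)
  }
  a <- length(circuit$registers$addr1)
  inputs <- stats::setNames(
    lapply(tuple, function(al) int_to_bits(al - 1L, a)),
    paste0("addr", seq_len(M))
  )
  state <- evaluate_circuit(circuit, inputs)
  rw <- circuit$registers$result
  restored <- all(state[rw] == circuit$init[rw])
  list(sim = state[circuit$registers$sim], restored = restored,
       state = state, circuit = circuit)
}

#' @rdname oracle_run
#' @export
oracle_bit <- function(scene, W, t, tuple, circuit = NULL) {
  oracle_run(scene, W, t, tuple, circuit)$sim
}
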