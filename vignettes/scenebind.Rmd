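---
title: "Binding visual categories with a Willshaw memory and simulated Grover search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding visual categories with a Willshaw memory and simulated Grover search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenebind)
```

## The problem

A visual scene is represented sub-symbolically: each recognized object is a
binary pattern, and a *category* (such as a tower of blocks) is the
concatenation of `M` object patterns stored in an associative memory. The
binding — deciding *which* `M` of the scene's `N` objects, in which order,
instantiate a stored category — is combinatorial: `L = Perm(N, M)` ordered
candidates without address repetition, `P = N^M` with repetition. The
package implements the classical screen over this space, and a simulated
quantum search that amplifies the solutions over a padded index space of
`P' = nu^M` tuples, `nu = 2^ceiling(log2 N)`.

Segmentation is assumed solved: objects arrive as (shape, bounding box)
records, and the package never attempts to find objects in pixels.

## The memory model

`learn_pairs()` implements the Lernmatrix rule: starting from zero weights,
`w[i, j] <- 1` whenever a stored pair has `y[i] = x[j] = 1`. Weights are
binary and never decay, so learning is monotone and order-independent, and
auto-association (the only mode the pipeline uses) yields a symmetric
matrix. `retrieve()` performs one-step recall at the maximum-sum threshold
`T = max_i sum_j w[i, j] x[j]`: exactly the maximally correlated units fire.
This rule tolerates partial and noisy cues but, with dense or overlapping
stored patterns, crosstalk can pull the threshold above the units of the
sought pattern — a behaviour the demonstration actually exploits (below).

When `T = 0` the literal rule would set *every* unit active. The package
raises a classed error (`scenebind_degenerate_retrieval`) instead, because
an all-ones answer carries no information; the combinatorial screens catch
it internally and score such candidates as unfamiliar. For the same reason
`familiarity(t = "auto")` refuses a degenerate cue in both modes: the auto
threshold `t = T / 2` is meaningless at `T = 0`.

### Familiarity

Two statistics decide whether a cue was stored, without reconstructing the
answer:

* **net mode:** `net = x' W x`, the quadratic form (the negated Hopfield
  energy), against a threshold `t`; `t = "auto"` uses `t = T / 2` computed
  on the cue. This is the statistic the reversible circuit computes, so the
  circuit path accepts integer thresholds only.
* **cosine mode (default):** the cosine between the cue and its one-step
  retrieval. This normalized statistic is what a fractional threshold such
  as the demonstration's `t = 0.87` applies to, and it is far more
  selective than net mode: with saturating binary weights, `net` grows with
  the square of the cue weight and any partially overlapping cue passes
  `t = T / 2`, whereas the cosine penalizes every bit the retrieval does
  not explain.

The decision boundary is `sim = 1` iff the statistic is `>= t` in both the
classical and the circuit path. The circuit realizes it by computing the
borrow of `(t - 1) - net`, which is 1 exactly when `net >= t` for integer
`t >= 1`; `t = 0` is accepted unconditionally via a constant wire, since
`net >= 0` always holds.

## Scene coding

Each object encodes into a *cognitive entity* of three associative fields:

* an **identity field**: the shape's bitmap normalized to 10 × 10 pixels
  (nearest-neighbour scaling; orientation normalization is a no-op for the
  axis-aligned blockworld), flattened row-major to 100 bits;
* an **abscissa field**: a bar of 1s over the half-open pixel interval
  `[x0, x0 + width)` on a vector of length `canvas width`;
* an **ordinate field**: likewise for `[y0, y0 + height)`.

With the default 100 × 100 canvas this gives `p = 100 + 100 + 100 = 300`
bits per entity and `M p = 900` bits per three-slot category; the identity
dimension of 100 is the only allocation consistent with those totals.
Coordinates are 0-based with the origin at the top-left, scene addresses
are 1-based, and candidate tuples are enumerated lexicographically — all
three conventions are arbitrary but must be fixed for bit-exact tests.

Shapes are drawn as **outlines** (the cube is the border of its square, the
pyramid a triangle outline over a full base row). Outlines keep the
identity fields sparse — roughly 30 of 100 bits instead of 55–100 for
filled figures — which keeps the 900 × 900 weight matrix far from
saturation after ten stored positions (density ≈ 0.17 rather than ≈ 0.7)
and materially widens the familiarity margin between the planted tuple and
its near-duplicates.

## The blockworld generator

`generate_blockworld()` emulates the demonstration conditions: `N = 10`
objects on a 100 × 100 pictogram, one instance of the tower category
(pyramid above two cubes, slot order top-to-bottom) planted at one of ten
learned anchor positions, the remaining objects random non-overlapping
distractor blocks, and salt-and-pepper pixel noise. Everything is
deterministic under a seed, and the ground truth (planted addresses in slot
order, anchor, learned positions) is returned for testing.

Three design choices deserve explanation:

* **Noise enters through the pictogram, and therefore only the identity
  fields.** The default rate is 0.05 (about 500 flipped pixels). Because
  segmentation is assumed solved, position bars are exact while identity
  fields are re-extracted from the noisy pixels. Spurious pixels land on
  bits that no stored pattern uses (the stored identity bits are the same
  shape bitmaps at every learned position), so noise only *deletes* evidence
  uniformly across a stored pattern's units. That is precisely the regime
  in which max-threshold retrieval returns the stored vector bit for bit —
  the exact-recovery property the demonstration asserts.
* **The ten learned positions form a deterministic ladder**
  `(x0, y0) = (8(k-1), 7(k-1))`, and the category is planted at the middle
  rung. Neighbouring stored instances overlap in their position bars, and
  this crosstalk is what *rejects* near-duplicate candidates: a tuple that
  repeats the middle cube for the bottom slot, or swaps two slots, differs
  from the planted candidate only in one or two 10-bit ordinate bars; its
  stray bar bits are covered by neighbouring stored instances, so retrieval
  collapses onto the identity-only unit set and the cosine drops to about
  0.79 — well under 0.87 — instead of the 0.93+ a naive overlap argument
  would suggest.
* **Distractors may not coincide exactly with any learned slot box**, so
  the generator's `r = 1` ground truth is true by construction (a random
  distractor cube sitting exactly where a stored instance expects one would
  silently plant a second solution).

The generator does *not* emulate real image statistics: objects are rigid
10 × 10 blocks, noise is i.i.d. salt-and-pepper, and there is no occlusion,
scale or rotation variation. Passing tests therefore demonstrate the
binding machinery, not robustness of the coding scheme to natural images.

## The threshold t = 0.87

The demonstration threshold must separate three populations of candidates:
the planted tuple (cosine ≈ 0.93–0.96 at 5% noise), near-duplicates
rejected through crosstalk (≈ 0.79), and candidates missing a slot
entirely. The last group is bounded structurally: a candidate with one
all-zero slot can reach cosine at most `sqrt((M-1)/M) ≈ 0.816 < 0.87`, so
tuples that address padding ("waste") objects can never pass in cosine
mode. In net mode that guarantee holds only when `t` exceeds the largest
single-slot quadratic form — a boundary worth remembering when choosing
integer thresholds for the circuit path.

## The reversible oracle

`build_familiarity_circuit()` compiles the net-mode test into gates: each
term `w[i, j] & x[i] & x[j]` costs two Toffoli ANDs, a Peres-adder ripple
accumulates the sum into a register of `ceiling(log2(n^2 + 1))` bits (wide
enough that overflow is impossible), and a full-subtractor ripple computes
`(t - 1) - net`, whose final borrow is the decision bit. The composed
oracle (`build_oracle_circuit()`) places `M` reversible load multiplexers
in front — each computes an address-equality flag per scene slot and
Toffoli-copies the flagged entity onto an object register — copies the
borrow out with a single CNOT, and then runs the familiarity block's mirror
inverse, restoring every intermediate wire ("uncomputation"). Evaluation is
classical, on basis states: the oracle is a bijection, verified by
property tests, and its bit agrees exhaustively with `familiarity()` on
every tuple of every small test scene.

Two accounting conventions follow the cost analysis rather than the
literal gate list: the familiarity circuit reports `4 n^2` gates
(`2 n^2` ANDs, `n^2` adders, `n^2` subtractors) and the load multiplexer
reports `N (N - 1) p`, while the honest constructed-gate tallies are kept
separately in `n_gates_actual`. The printed formulas treat each ∧/∨ and
each multi-bit adder stage as one gate; any correct multiplexer
construction is admissible, so the reported formula — not the
implementation detail — is the stable quantity.

## The Grover simulation

Amplitudes live only on the `nu^M` address tuples. This index-level
simulation is exact, not an approximation: the loaded-object, result and
waste registers are computed and uncomputed deterministically per basis
state, so the full state is always a product of the index register with
fixed registers, and the oracle acts as a phase flip on marked indices. A
full bit-level amplitude simulation (900+ qubits for the demonstration)
would be impossible and would add nothing.

`mark_set()` precomputes the oracle's accepted tuples with `P'` classical
familiarity evaluations — a simulation device, clearly not a quantum cost;
`run_search()` still accounts oracle calls Grover-style as
`k × repeats`. The iteration schedule is the standard
`k = floor((pi/4) sqrt(P'/r))`; the solution count `r` is an input (the
package does not implement quantum counting), and tests obtain it from the
generator's ground truth. Amplitudes are real throughout, since both the
oracle flip and the inversion about the mean are real operators. The
simulated success probability matches the closed form
`sin^2((2k+1) arcsin(sqrt(r/P')))` to 1e-9 across all tested space sizes,
and the norm drifts by less than 1e-12 over a thousand iterations.

For the demonstration fixture (`nu = 16`, `M = 3`, `P' = 4096`, one marked
tuple, `k = 50`) the predicted success is `sin^2(101 theta) ≈ 0.99995`, so
one hundred seeded single-measurement replicates are expected to find the
planted tuple essentially every time.

## Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `canvas` | 100 × 100 px | pictogram extent; fixes bar dimensions |
| `n_objects` (`N`) | 10 | scene size; `L = 720` candidate tuples |
| `M` | 3 | category slots; `n = M p = 900` |
| `n_positions` | 10 | learned tower anchors on the ladder |
| `noise_rate` | 0.05 | pixel flip probability on the pictogram |
| `fam_mode`, `t` | cosine, 0.87 | demonstration familiarity test |
| `r` | 1 | assumed solution count for the Grover plan |
| `seed` | 42 | master seed; stages use derived child seeds |

## Problem sizes in the test suite

Exhaustive circuit checks run on scenes of `N = 2..4` entities of `p = 4..6`
bits with `M = 1..2` (oracle widths of a few thousand wires, all `nu^M`
tuples per scene); Grover fidelity covers `P' ∈ {4, 64, 1024, 4096}` and
`r ∈ {1, 2, 4}`; the Born-rule check draws 10^4 samples on `P' = 16`; the
hybrid acceptance replicates 100 seeded searches on the full 4096-tuple
fixture. The full suite runs in well under a minute.

## Known limitations

* The Willshaw memory is used far above its sparse-coding capacity regime
  (stored patterns activate ~18% of units); retrieval still works here
  because only ten strongly structured patterns are stored, but the
  familiarity margins would degrade with many categories or positions.
* `perm_rep` candidate tuples with repeated addresses are deliberately not
  filtered; they are rejected by the familiarity threshold alone, which is
  guaranteed for this fixture but not for arbitrary geometries.
* Counts are exact only up to 2^53 (`perm_rep_count()` errors beyond rather
  than rounding silently); no arbitrary-precision arithmetic is used.
* Quantum counting of `r`, amplitude estimation, unlearning of recognized
  categories, and any claim about physical hardware are out of scope.
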