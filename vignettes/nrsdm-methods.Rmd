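---
title: "Nested repeated sequence decomposition: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested repeated sequence decomposition: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrsdm)
```

## The model

`nrsdm` treats a one-dimensional process as a text `T = c_0 c_1 ... c_{L-1}`
over a finite alphabet and describes it by the exact sequences that repeat in
it. A *symbol* is a character sequence of length at least 2 that occurs at
least `rq` times without overlap; everything not covered by a symbol is
*noise*. The flat (depth-0) decomposition extracts symbols greedily, longest
first; the nested decomposition applies the same extraction inside every
symbol found, recursively, until symbols contain no internal repeats. The
result is a tree: the root is the whole text, each node's children are the
symbols that describe it, and each node carries the characters left
unexplained as noise.

Three quantities summarize a node with length `l`, in-parent count `g`, and
effective count `r` (the product of in-parent counts along its ancestor
chain):

* coverage probability `Q = r·l/L0`, the fraction of the *original* text the
  node's instances occupy (for depth-1 nodes this is the plain `g·l/L0`);
* nested pattern complexity `NPC = Σᵢ (nᵢ/N) log_d(N/nᵢ)`, the base-`d`
  entropy of the node's census (its `d` child-symbol and grouped-noise types
  with counts `nᵢ`, `N = Σᵢ nᵢ`), which is 0 for a single-type description and
  1 for a perfectly balanced one;
* the tree-level multiscale integral complexity `MSIC = Σ NPC` over non-leaf
  nodes, an integral of description complexity across observation scales.

Two views render the tree on log–log axes: the MSIR aggregates coverage by
sequence length across depths, the NPR keeps one point per node with bubble
size decreasing in depth. Because `Q = r·l/L0` exactly, every point sits on
the band of its repetition count; band lines are drawn as visual guides.

### Assumptions

The method assumes exact symbol matches: two segments either repeat or they
do not. All tolerance for "nearly equal" values must therefore be put into the
discretization resolution, not the search. It also assumes a stationary
alphabet — the scale is fitted once on the whole series, so regime changes in
the value distribution shift bin occupancy rather than bin edges.

## The greedy search, precisely

Candidate lengths run from `floor(L/rq)` down to `min_len = 2`. At a given
length, every window that touches no locked position is a candidate; a
candidate qualifies if its greedy left-to-right set of non-overlapping,
unlocked occurrences has at least `rq` members (greedy selection is optimal in
count for a fixed pattern). Among qualifying candidates of the same length the
one whose first counted occurrence starts leftmost wins; a residual tie goes
to the lexicographically smallest sequence — the search is silent on
preference, and determinism is required for reproducible trees. After an
extraction all counted occurrences are locked and the *same* length is
re-scanned before descending.

Two internal accelerations leave the output bit-identical to that
specification, which a brute-force reference implementation checks on over a
thousand random texts in the test suite:

* the qualifying-length predicate is monotone — if a length-`l` sequence
  qualifies, its length-`l−1` prefix qualifies too — so the next extraction
  length can be found by binary search rather than a linear descent;
* identical sequences are always decomposed identically (`rq` is constant
  across depths), so subtrees are memoized by sequence; the logical model
  still keeps one node per parent-child relation, with per-instance depths and
  effective counts annotated afterwards.

Single characters are never symbols: a length-1 "repeat" carries no
arrangement information, and keeping it as per-position noise makes the
census-based NPC well defined.

## Discretization scales

A scale is written `"<T|H|L>: <s>/<inflect>/<param>"`. All three types share
the bin semantics: `s + 1` strictly increasing boundaries, infinite at both
ends, half-open bins with the lower edge inclusive, and an ordered
single-character alphabet (`a`–`z`, then `A`–`Z`; resolutions beyond 52
continue into Unicode letters so that every symbol stays one character).

* **linear** — equal-width bins over the observed range `[min, max]`.
* **tangential** — with `v_c` the series value at quantile
  `(inflect + 0.5)/s` and `W = max − min`, interior boundaries are
  `b_k = v_c + λ·W·tan(π(k/s − (inflect + 0.5)/s))`. Resolution is finest at
  the inflection character and falls off toward the tails; smaller `λ` means
  a sharper concentration.
* **hyperbolic** — the same construction with
  `sinh(γ(k/s − (inflect+0.5)/s))/sinh(γ/2)`, `γ = 1/λ`, a milder warp.

These closed forms are this package's own: they were chosen to give the
stated qualitative behavior (one parameter controlling how strongly
resolution concentrates at an inflection index) while parsing the compact
`Type: Res/Inflect/Param` notation directly. Note a consequence worth knowing:
at small `λ` the finite boundaries cover only a narrow band around `v_c`, so
values far from the inflection collapse into the two extreme characters. That
is intended — it is what "absorbing" a nonlinearity means here — but it makes
reachable repeat lengths sensitive to the exact warp, which matters when
comparing against results produced by other scale constructions (see
*Limitations*).

Degenerate inputs are defined, not errors: a constant series maps every value
to the inflection character, and boundary-exact values go to the upper bin.

`optimize_scale()` picks the candidate scale whose text has the highest
negentropy `h = 1 − Σ pᵢ log_s(1/pᵢ)`; ties break toward the simpler scale
(linear, then tangential, then hyperbolic, then smaller `λ`), and the full
`(candidate, h)` grid is attached for audit. If every candidate collapses the
text to one character the best-effort winner is returned with a warning.

## Parameters that matter

| parameter | default | meaning and why |
|---|---|---|
| `rq` | 2 | minimum occurrence count; 2 is the weakest notion of "repeated", larger values tolerate noise and shrink runtime (shorter top candidate length) |
| `min_len` | 2 | symbols must be at least 2 characters; 1-character symbols are definitionally noise |
| `s` (resolution) | 20 | alphabet size; finer scales separate more states but lengthen transients and shorten exact repeats |
| inflection | `s/2` | 0-based character index where resolution concentrates |
| `λ` (param) | 0.01 | nonlinearity strength; tangential/hyperbolic only |

## The N convention in NPC

The census count `N` is taken to be `Σᵢ nᵢ`. The complexity formula needs a
concrete `N` to be evaluable, and this choice is the only one under which NPC
is a proper normalized entropy on `[0, 1]` with its extremes meaning what they
should (0 = single-type description, 1 = balanced description). Noise
characters enter the census grouped by identity — two noise `D`s are one type
with count 2 — so the description stays exhaustive without inflating
diversity. A consequence: numerical NPC/MSIC values from other conventions are
comparable only qualitatively.

## What the simulators emulate — and what they do not

`may_map()` is the exact logistic recursion; `lorenz_system()` integrates the
classic three-parameter system with fixed-step RK4 (`deSolve`), defaulting to
`σ = 10, ρ = 28, β = 8/3`, `Δt = 0.005`, start `(1, 1, 1)` — the standard
chaotic, two-lobe configuration, adopted here because the experiments they
support do not fix these values any more precisely. `nested_periodic_text()`
plants a known hierarchy (motif × inner reps + spacer, repeated outer-reps
times, optional out-of-alphabet corruption) and returns the ground truth for
recovery tests.

Passing tests on these generators show that the search recovers *planted or
dynamical* exact structure under controlled noise. They do not show that
real-world series (market data, measured signals) have such structure: real
data reach the method only through discretization, where measurement noise,
drift and non-stationarity blur exact repeats. For drifting series the useful
transformation is differencing before discretization, which the reader should
apply upstream; the package does not do it implicitly.

`detect_period()` reports the smallest `p` with `suffix[i] = suffix[i+p]`
after a burn-in (default: the first half, a deliberately generous transient
allowance), with `p` capped at half the suffix so a "period" is witnessed at
least twice.

## Problem sizes and determinism

The test suite exercises the oracle equivalence on 1000+ random texts of
length up to 60 over alphabets of 2–6 characters; the logistic-map experiments
use 1001 samples (2501 in the chaotic regime); the Lorenz runs use 10,000
steps per axis. These sizes keep the whole suite in the minutes range on one
CPU while covering every code path; the search itself handles texts of a few
tens of thousands of characters, with the usual cubic-order caveat for
pathological inputs. Every decomposition is deterministic: same text, same
`rq`, same tree, same SHA-256 structural digest (the digest serializes each
node's sequence, noise and sorted child digests, so it is invariant to child
discovery order but sensitive to any structural change). The digest
implementation is pure R, verified against the published SHA-256 test
vectors.

## Limitations

* **Exact matching in floating point.** Repeat lengths in discretized
  simulations depend on when (and whether) the float orbit becomes exactly
  periodic. At ρ = 3.5 the double-precision logistic orbit locks onto its
  4-cycle within ~60 steps, so almost the whole 1001-sample text is exactly
  periodic and the longest non-overlapping repeat is structurally close to
  `floor(L/2)`; at ρ = 3.9 the double-precision orbit stays aperiodic over
  2501 steps and longest repeats are short. Results produced at other
  precisions, or with other scale warps, can differ by large factors for
  these reasons alone — the acceptance script reports what this package
  computes under its stated conditions.
* **No approximate matching.** Fuzzy or gapped repeats, and
  reverse-complement awareness for nucleic-acid texts, are out of scope.
* **Cost.** The search is worst-case cubic in text length; tens of thousands
  of characters are practical, millions are not. Raising `rq` is the
  intended lever for long texts.
* **MSIC bounds.** The bound `1 < MSIC < #branch nodes` applies to
  multi-level trees whose branch censuses are non-degenerate (`d ≥ 2`); a
  perfectly tiled text produces single-type censuses with NPC 0 and can sit
  below 1.

## A complete small run

```{r example}
gen <- nested_periodic_text("ab", 4, 5, spacer = "xz")
fit <- nrsdm(gen$text, rq = 2)
fit
tree_nodes(fit)[, c("depth", "sequence", "count_in_parent", "q", "npc")]
msir_table(fit)
```
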