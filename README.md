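# nrsdm: nested repeated sequence decomposition

`nrsdm` characterizes one-dimensional processes — chaotic maps, continuous
dynamical systems, any real-valued series — by the exact repeated sequences in
their symbolic transcriptions. It is aimed at users who need structure out of
oscillatory but non-periodic signals where Fourier-style decompositions give
little purchase: instead of frequencies, it reports *which* state sequences
repeat, *how often*, and *how deeply they nest inside one another*.

The pipeline has three stages:

1. **Discretization.** A numeric series is mapped onto an ordered alphabet of
   `s` characters through a scale — linear, tangential or hyperbolic — written
   in the compact notation `"T: 20/10/0.01"` (type, resolution, inflection
   index, nonlinearity parameter). Nonlinear scales concentrate resolution
   around the inflection character. Scale parameters can be chosen
   automatically by maximizing the text's negentropy
   `h = 1 − Σᵢ pᵢ log_s(1/pᵢ)`, the information the discretization makes
   extractable.
2. **Decomposition.** A greedy longest-first search extracts non-overlapping
   sequences appearing at least `rq` times, locking each find and re-scanning,
   down to length 2; the remainder is noise. Each extracted symbol is then
   decomposed the same way, recursively, producing a tree: depth-1 symbols
   explain the text, depth-2 symbols explain the depth-1 symbols, and so on.
   A node with effective count `r` (its in-parent count multiplied along the
   ancestor chain) and length `l` covers the fraction `Q = r·l/L` of the
   original text.
3. **Characterization.** Each node's description (child symbols plus grouped
   noise characters, `d` types, counts `nᵢ`, `N = Σnᵢ`) gets a nested pattern
   complexity `NPC = Σᵢ (nᵢ/N) log_d(N/nᵢ) ∈ [0, 1]`; the multiscale integral
   complexity `MSIC` sums NPC over all non-leaf nodes. Two log–log
   probability-versus-length views summarize the tree: the MSIR (aggregated
   over depth) and the NPR (one bubble per node, size decreasing with depth),
   both aligned on the equal-repetition bands `Q = r·l/L`.

Simulators for the logistic map, the Lorenz system (RK4) and planted
nested-periodic texts are included for experimentation and testing.

## Worked example

The 42-character text below decomposes into two depth-1 symbols; the repeated
pair `CA` turns out to be nested three levels deep.

```r
library(nrsdm)
fit <- nrsdm("CADCADCCACAECCACACEDDCADCABCCACAECCACACEDD", rq = 2)
fit
#> Nested repeated sequence decomposition (rq = 2)
#>   text length 42, 2 depth-0 symbol(s), noise fraction 0.0476
#>   tree: 6 node(s), max depth 3, 2 leaf/leaves
#>   Complexity: MSIC/NPC = 3.771/0.9591
```

`CCACAECCACACEDD` (×2) and `CADCA` (×2) explain all but two characters of the
text (`residuals(fit)` returns the noise, `D` at position 5 and `B` at 26).
Inside the 15-mer sits `CCACA` (×2), and inside both `CCACA` and `CADCA` sits
`CA`, whose effective counts are 8 and 4:

```r
tree_nodes(fit)[, c("depth", "sequence", "count_in_parent", "effective_count", "q")]
#>   depth                                   sequence count_in_parent effective_count         q
#> 1     0 CADCADCCACAECCACACEDDCADCABCCACAECCACACEDD               1               1 1.0000000
#> 2     1                            CCACAECCACACEDD               2               2 0.7142857
#> 3     2                                      CCACA               2               4 0.4761905
#> 4     3                                         CA               2               8 0.3809524
#> 5     1                                      CADCA               2               2 0.2380952
#> 6     2                                         CA               2               4 0.1904762
```

The root NPC is 0.9591 (its census {15-mer: 2, CADCA: 2, D: 1, B: 1} is nearly
uniform) and MSIC sums the four branch nodes to 3.771 — between 1 and the
branch-node count, as it must be for a multi-level tree. `plot(fit, "npr")`
draws the coverage-versus-length bubbles on their repetition bands.

A numeric series goes through the same interface via a scale:

```r
x <- may_map(3.5, 1001)                    # logistic map, 4-cycle regime
fit <- nrsdm(x, scale = "T: 20/10/0.01", rq = 2)
detect_period(fit$text, burn_in = 500)
#> [1] 4
```

## Command line

A thin launcher wraps the same functions:

```sh
cli=$(Rscript -e 'cat(system.file("scripts", "nrsdm", package = "nrsdm"))')
$cli simulate may --rho 3.5 --n 1001 --out may.csv
$cli run --input may.csv --scale "T: 20/10/0.01" --rq 2 --out-prefix out --plot
```

Subcommands: `discretize`, `decompose`, `complexity`, `represent`, `simulate`,
`run`. Logs go to stderr; data to files; every run writes a YAML sidecar with
its full configuration and the tree's structural hash.

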