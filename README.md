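# synergynet

Higher-order (synergistic) associations among binary signs and diseases that
pairwise association networks cannot see.

## The scientific problem

Association networks for survey or clinical data are usually built from
pairwise statistics. But pairwise statistics are structurally blind to
*synergy*: if a disease is driven by an interaction of signs — the canonical
case being `Y = XOR(A, B)` with balanced, independent inputs — then every
pairwise mutual information `I(A; Y)`, `I(B; Y)`, `I(A; B)` is exactly **0
bits** while the joint `I({A, B}; Y)` is a full **1 bit**. A pairwise network
draws no edge at all around a mechanism that is in fact deterministic.

`synergynet` provides:

* **A world model.** Binary Bayesian networks with conditional probability
  table (CPT) edges, exact inference by joint-table enumeration (≤ 20
  nodes), and vectorized ancestral sampling that retains each realization's
  exogenous noises `u_i` (node `i` is 1 iff `u_i < P(node = 1 | parents)`),
  so individual-level counterfactuals are well defined.
* **Information measures** (all in bits, exact and plug-in estimators):
  entropy `H`, mutual information between variable sets, total correlation
  `TC = Σ H(X_i) − H(X)`, dual total correlation
  `DTC = (1 − n) H(X) + Σ H(X_{−i})`, the O-information
  `Ω = TC − DTC` (`Ω < 0`: synergy-dominated; `Ω > 0`: redundancy-dominated),
  and whole-minus-sum synergy
  `WMS = I({P1, P2}; T) − I(P1; T) − I(P2; T)`.
* **Interventions.** Population-level soft nudges of a root prior with exact
  propagation of `Δ log-odds = logit(post) − logit(baseline)`, and hard
  `do()` interventions on individual realizations that clamp nodes and
  recompute descendants reusing the recorded noises.
* **A screening pipeline.** `scan_synergy()` keeps triples whose pairwise
  MIs are all small (the triangle filter — exactly the triples a pairwise
  network dismisses), scores them with plug-in `Ω`, attaches one-sided
  permutation p-values (margin-preserving null drawn in O(1) per permutation
  via hypergeometric contingency tables), and controls the false discovery
  rate by Benjamini-Hochberg.
* **Generators with ground truth.** A nine-node reference network with two
  planted synergistic gates and OR-gate diseases, plus survey-style
  generators (default 587 × 51) with planted XOR triplets, noisy-copy pairs,
  OR-gate diseases, a ground-truth manifest, and matched null surveys.

See the methods vignette (`vignettes/methods.Rmd`) for the model,
parameter defaults and their rationale, and limitations.

## Worked example

```r
library(synergynet)

net <- build_reference_network("optimized")
glance(net)
#> # A tibble: 1 × 4
#>   n_nodes n_edges n_roots max_parents
#>     <int>   <int>   <int>       <int>
#> 1       9      10       3           2
```

Six signs `S1..S6`, three diseases `D1..D3`. `S4` is a synergistic child of
`{S1, S2}` and `S6` of `{S2, S3}`; `D1 = OR(S1, S4)`, `D2 = OR(S5, S6)`.
Simulate 100,000 subjects and look at what a pairwise analysis sees:

```r
data <- generate_reference_dataset(net, 100000, seed = 42)
m <- mi_matrix(data)
round(m[c("S1", "S2", "S3"), c("S4", "S6", "D1")], 4)
#>        S4    S6     D1
#> S1 0.0106 0e+00 0.5302
#> S2 0.0095 6e-04 0.0303
#> S3 0.0060 1e-03 0.0177
```

Every parent-to-gate MI is ~0.01 bits — pairwise noise level — yet the
parents jointly carry the gate:

```r
mutual_information(data, c("S1", "S2"), "S4")
#> 0.3223 bits
```

Thresholding the pairwise MI graph at 0.05 bits splits the nine variables
into three components; the synergistic edges are simply absent:

```r
mi_graph_components(m, 0.05)
#> [[1]] "D1" "S1" "S4"
#> [[2]] "D2" "S5" "S6"
#> [[3]] "D3" "S2" "S3"
```

The scan recovers the hidden structure. The top hit is the planted gate
`{S1, S2} → S4`, with the strongest (most negative) O-information:

```r
scan <- scan_synergy(data, permutations = 1000, seed = 42)
head(scan, 3)
#>   var_a var_b var_c o_information_bits  p_value q_value significant
#> 1    S1    S2    S4             -0.302 0.000999   0.003        TRUE
#> 2    S1    S3    S4             -0.162 0.000999   0.003        TRUE
#> 3    D3    S1    S4             -0.128 0.000999   0.003        TRUE
```

(Rows 2-3 are real, weaker synergies inherited through the `S2 → S3` link.)

A population-level nudge of `S2` by +0.2 propagates only to `S2`'s
descendants — `S1` and `S5` are exactly unmoved:

```r
population_effect(net, "S2", 0.2)
#>   node baseline  post delta_log_odds boundary
#> 1   S1    0.406 0.406         0.0000    FALSE
#> 2   S2    0.449 0.649         0.8193    FALSE
#> 3   S3    0.450 0.606         0.6312    FALSE
#> 4   D3    0.455 0.595         0.5668    FALSE
#> 5   S4    0.278 0.300         0.1035    FALSE
#> 6   D1    0.545 0.505        -0.1634    FALSE
#> 7   S5    0.529 0.529         0.0000    FALSE
#> 8   S6    0.891 0.887        -0.0405    FALSE
#> 9   D2    0.949 0.947        -0.0380    FALSE
```

And an individual-level counterfactual: take a subject with everything
active and ask what `do(S2 = 0)` would have changed, holding their exogenous
noises fixed. The synergistic gates `S4` and `S6` switch off (and with them
`S3` and `D3`), while `D1` and `D2` stay on through their other OR inputs:

```r
s <- sample_network(net, 1000, seed = 7)
r <- realization(s, which(s$S2 == 1 & s$S4 == 1 & s$S6 == 1)[1])
r$states
#> S1 S2 S3 D3 S4 D1 S5 S6 D2
#>  1  1  1  1  1  1  1  1  1
do_intervention(net, r, c(S2 = 0))$states
#> S1 S2 S3 D3 S4 D1 S5 S6 D2
#>  1  0  0  0  0  1  1  1  1
```

`autoplot()` methods exist for MI matrices, effect reports and scans;
`tidy()`/`glance()` methods for networks, joint tables, MI matrices and
scans. A command-line interface covering the whole pipeline is installed at
`inst/cli/synergynet.R` (subcommands `build-network`, `simulate`,
`mi-matrix`, `nudge`, `do`, `scan`, `gen-survey`, `pipeline`).

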