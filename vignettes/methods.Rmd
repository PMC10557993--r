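---
title: "Methods: detecting higher-order synergy in binary sign-disease data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting higher-order synergy in binary sign-disease data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergynet)
```

## The problem

Association networks built from pairwise statistics (correlation, dyadic
mutual information) are structurally blind to *synergistic* dependence. The
canonical example is the XOR gate: if `Y = XOR(A, B)` with fair, independent
inputs, then every pairwise mutual information involving `Y` is exactly zero,
while `A` and `B` jointly determine `Y` completely. In clinical survey data,
a disease driven by an interaction of signs can therefore be invisible to any
pairwise sign-disease network. This package provides (a) a generative world
model in which such structure exists by construction, (b) estimators that can
see it, and (c) a screening pipeline with calibrated error control.

## World model

The generative model is a Bayesian network over binary nodes. Each node
carries a conditional probability table (CPT) giving `P(node = 1)` per joint
parent state; CPT rows are keyed by the parent bitstring with the **first
parent as the most significant bit** (`"00"`, `"01"`, `"10"`, `"11"` for two
parents). Exact inference enumerates the full joint table (capped at 20
nodes, i.e. at most `2^20` states); larger networks must be sampled.

Sampling uses the exogenous-noise representation: node `i` is set to 1 iff an
independent uniform noise `u_i` is below the CPT probability for its parents'
realized state. The noises are retained with every sample, which makes
individual-level counterfactuals well defined: `do_intervention()` clamps
nodes and recomputes descendants *reusing the same noises* — the same
individual, identical in every exogenous respect, under the intervention.
Population-level soft interventions (`nudge()`) instead shift a root's prior
by a fixed mass and propagate exactly; effects are reported as
`logit(post) - logit(baseline)` in natural-log units.

### The reference network

`build_reference_network()` returns a nine-node network — six signs `S1..S6`,
three diseases `D1..D3` — built so that pairwise analysis provably
misses part of the structure:

* `S1`, `S2`, `S5` are roots with priors drawn uniformly from `[0.3, 0.7]`
  (moderate prevalences keep the synergistic gates near their
  pairwise-invisible regime; the draw is fixed by the `seed` argument,
  default 1).
* `S3` depends on `S2` with spontaneous rate 0.10 and penetrance 0.88. The
  asymmetry is deliberate: with a perfectly symmetric noisy copy and an
  XNOR-like child, `P(S6 = 1)` is *exactly* invariant to shifts of `S2`'s
  prior, an uninformative knife-edge we avoid by construction.
* `S4` and `S6` are synergistic children of `{S1, S2}` and `{S2, S3}`. In the
  `"optimized"` variant their CPTs come from `optimize_synergistic_cpt()`
  (below); the `"figure1b"` variant instead uses a fixed literal table for
  `S4` whose `(S1=0, S2=0)` row is 0.028 and whose `(S1=1, S2=0)` row is 1,
  so that clamping `S2` to 0 forces `S4` off whenever `S1` is on.
* `D1 = OR(S1, S4)` and `D2 = OR(S5, S6)` are deterministic OR gates;
  `D3` depends on `S3` alone (0.05 / 0.95).

### Designing synergistic CPTs

`optimize_synergistic_cpt()` maximizes the whole-minus-sum (WMS) synergy of a
child `T` given its parents' joint distribution:

`WMS = I({P1, P2}; T) - I(P1; T) - I(P2; T)`

over the four CPT probabilities (parameterized by logits, multi-start
Nelder-Mead, default 50 restarts). Two soft constraints enter as penalties
(weight 60 per bit of excess):

* `pairwise_cap` (default 0.01 bits) bounds each single-parent MI, keeping
  the gate invisible to dyadic screens;
* `or_leak_cap` (optional) bounds the MI between `OR(P1, T)` and `P2`. This
  matters when `T` feeds a deterministic OR-gate disease: a *perfectly*
  deterministic XOR/XNOR child leaks substantial association from the
  co-parent into the disease, which would fuse otherwise separate components
  of the pairwise-MI graph. Zero pairwise MI, a deterministic OR disease, and
  clean component separation are jointly unachievable, so the reference
  network trades a little determinism (cap 0.03 bits) for separation, while
  keeping the joint MI above 0.3 bits.

Candidates are polished by rounding near-boundary probabilities and oriented
canonically so that `P(T = 1 | both parents on) >= 0.5`; complementing every
row is an MI-preserving relabeling, so optima come in equivalent pairs and
the orientation only fixes a representative.

## Information measures

All measures are in **bits** (base-2 logarithms) and have plug-in (empirical
frequency) and exact (joint-table) estimators with a common interface:
entropy, mutual information between arbitrary disjoint sets, total
correlation `TC`, dual total correlation `DTC`, and the O-information

`Omega = TC - DTC`,

whose sign separates redundancy-dominated (`Omega > 0`) from
synergy-dominated (`Omega < 0`) triplets; the XOR triplet attains exactly
−1 bit and three perfect copies of one bit attain exactly +1 bit (both are
verified exactly in the test suite, and to within 0.01 bits from
100,000-sample plug-in estimates). Plug-in entropies are biased downward at
finite `n`; an optional Miller-Madow correction is provided, but the scan
below relies on permutation calibration rather than bias correction.

## The scanning pipeline

`scan_synergy()` implements a three-stage screen:

1. **Triangle filter.** Keep every unordered triple whose three pairwise MIs
   are all below `mi_threshold` (default 0.05 bits) — precisely the triples a
   pairwise network dismisses.
2. **Permutation test.** For each candidate, the observed plug-in
   O-information is compared to a null in which the three columns are
   independently row-shuffled (margins preserved, all dependence destroyed).
   Rather than shuffling `n`-vectors, the default engine draws the null
   2×2×2 contingency table directly by sequential hypergeometric sampling
   given the fixed column totals — an exactly equivalent null at O(1) cost
   per permutation. (An explicit shuffle engine is retained and tested as a
   cross-check.) The one-sided p-value is
   `(1 + #\{Omega_null <= Omega_obs\}) / (B + 1)` with `B = 1000` by default;
   the `+1` smoothing keeps the test valid at finite `B`. Each triplet's RNG
   stream is derived from the seed and the *sorted* triplet labels, so
   results are independent of scan order.
3. **FDR control.** Benjamini-Hochberg adjustment over the candidate set
   (delegated to `stats::p.adjust`, cross-checked against a brute-force
   step-up oracle in the tests); triplets with `q <= fdr_q` (default 0.15)
   are flagged significant.

Because the filter and the test use the same data, the FDR guarantee over the
post-selection candidate set is approximate; the package therefore ships a
matched null generator and calibration tests rather than relying on the
nominal level alone.

## Synthetic survey generator

`generate_survey()` emulates the *shape* of a cross-sectional geriatric
screening survey: by default 587 subjects, 37 binary signs, and 14 binary
disease indicators. Background signs are independent Bernoulli draws with
prevalences from `[0.05, 0.4]` (skewed, like real sign prevalences, so power
estimates are not flattered by fair coins). Planted synergistic triplets set
one sign to the XOR of two others, flipped with probability `flip_noise`
(default 0.05); their *input* prevalences are drawn from `[0.4, 0.6]`
instead, because a noisy XOR of strongly skewed inputs leaks pairwise MI and
would be removed by the pipeline's own triangle filter before testing —
near-balanced inputs are the regime in which pure synergy exists at all.
Planted pairs are noisy copies; diseases are OR gates of one to three random
signs plus flip noise. Every planted mechanism is recorded in a ground-truth
manifest (`score_recovery()` benchmarks a scan against it), and
`generate_null_survey()` produces a column-independent control with the same
layout.

The generator emulates structure, not content: it does not reproduce any
real instrument's item wording, missing-data patterns, ordinal-scale
binarization, or empirical prevalence tables.

## Numerical choices

* Base-2 logarithms throughout; `0 log 0 = 0` by convention.
* Exact enumeration is vectorized over all `2^k` states and refuses `k > 20`.
* Ancestral sampling is vectorized over observations; per-node noises are
  stored alongside the data for counterfactual reuse.
* Effects with `|delta log-odds| < 1e-9` are treated as exactly zero in the
  locality tests (exact inference makes true zeros exact up to floating
  error).
* The permutation null uses integer contingency tables, so its Omega values
  are exact given the drawn tables; p-values are deterministic given the
  seed.

## Limitations

* Only **triplets** are scanned; higher-order (4-way and up) interactions
  are out of scope, though the information measures accept larger sets.
* Plug-in estimation needs cell counts; with 2×2×2 tables and `n` in the
  thousands this is unproblematic, but the measures are not corrected for
  small-sample bias by default.
* The triangle filter's threshold trades power for candidate-set size;
  synergistic triplets with substantial *pairwise* leakage are excluded by
  design.
* FDR control is approximate under filter-test dependence (see above).
* The world model is binary and acyclic; ordinal severities, feedback, and
  longitudinal dynamics are not represented.
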