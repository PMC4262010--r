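---
title: "Comparing quantitative host-parasitoid webs: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing quantitative host-parasitoid webs: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantweb)
```

`quantweb` implements a complete workflow for asking whether the
structure of quantitative host–parasitoid webs varies with latitude or
host guild once sampling artefacts are removed. This vignette explains
the models behind each step, the tunable parameters and why their
defaults are what they are, the numerical choices inside the heuristic
components, and what the synthetic-data tests do and do not demonstrate
about real webs.

## The data model

A web is a non-negative matrix `a` (hosts × parasitoids) of interaction
counts, carrying a study identifier, a signed latitude and a host-guild
label. Two asymmetries are built in, reflecting how rearing-based webs
are collected:

- **Hosts** are chosen by the researcher, so a host can legitimately be
  present with no parasitism — all-zero rows are kept, and they count
  towards the species total `S` used by weighted connectance.
- **Parasitoids** exist in the data only through reared events — an
  all-zero column is rejected at ingest.

A cell sum `m` (the *matrix size*) is the package's measure of sampling
effort. Whether all cells are integers is detected exactly at ingest
(tolerance 0 for integer storage, relative 1e-9 for doubles) because it
gates H2′ and event subsampling, which are only meaningful for counts.

## Shannon-based metrics and H2′

Generality, vulnerability, linkage density and weighted connectance are
the classical effective-number descriptors; entropies are computed in
nats and converted through `exp()`, which makes the logarithm base
irrelevant, and `0·log 0 ≡ 0` throughout.

H2′ needs the extreme entropies reachable by an integer matrix with the
observed marginal totals. Both extremes are NP-hard to obtain exactly
in general, so heuristics are used and checked against an exhaustive
enumeration oracle (`h2_bounds_exact()`, every integer matrix with the
given marginals):

- **Maximum** (closest to independence): largest-remainder rounding of
  `A_i·A_·j/m`, marginal repair by entropy-maximising unit moves, then
  steepest-entropy unit moves along 2×2 cycles until no move improves.
- **Minimum** (most concentrated): greedy packing — place
  `min(remaining row, remaining column)` into the cell of the currently
  largest marginals, ties broken towards the lowest index — plus a
  second deterministic variant that gives priority to *perfect fits*
  (a remaining row total exactly equal to a remaining column total),
  both refined by entropy-decreasing full transfers along 2×2 cycles;
  the more concentrated result wins. The perfect-fit variant exists
  because pure greedy packing can lodge in a local optimum (e.g.
  marginals (5,4) × (3,4,2)).

Both bound matrices are built from sorted marginals, which makes the
bounds — and hence H2′ — exactly invariant under row/column
permutation. When `H2max − H2min` is numerically zero the marginals
leave no freedom and H2′ is defined as 0; otherwise the ratio is
clipped to `[0, 1]` to absorb residual heuristic slack. On the full
small-matrix suite (`m ≤ 10`, up to 3×3) the heuristic H2′ stays within
0.02 of the oracle.

One idealisation worth knowing: H2′ is *not* exactly invariant under
multiplying an integer web by a constant, because the bound lattice
refines with `m`; the effect is a few hundredths at small `m` and
vanishes as webs grow. The test suite asserts it at 0.05 absolute.

## Modularity

The objective is the weighted bipartite (Barber-style) modularity; the
trivial single-module partition scores exactly 0 and unparasitised
hosts contribute nothing wherever they are placed. The optimiser is
simulated annealing over three move types (node reassignment 80%,
module merge 10%, random-bisection split 10%) with the initial
temperature set from the mean |ΔQ| of probe moves so that a typical
uphill-equivalent move is accepted about half the time, geometric
cooling of 0.995 per sweep, and chain termination after 2000 moves
without improvement; the best of several independent restarts is
returned and a partition worse than the trivial one is never reported.
Per-chain seeds derive from the master seed by a counter scheme, so
results are exactly reproducible. Against the exhaustive-search oracle
(all set partitions, feasible to 10 nodes) the annealer reaches at
least 99% of the optimum across seeds on the small-web suite; on larger
webs no optimality guarantee exists, which is one reason replicate
means (50 for modularity) are used wherever modularity enters the
rarefaction machinery.

## Taxonomic diversity Δ

Δ is the abundance-weighted mean taxonomic path distance between pairs
of host individuals: `Δ = Σ_{i<j} ω_ij x_i x_j / (N(N−1)/2)`. Distances
`ω` use equal step lengths per rank, scaled so that the maximum
possible distance is 100, after dropping ranks that carry no
information (a single value overall, or one value per species) — the
same convention as the standard equal-step implementation in community
ecology, against which the test suite cross-checks. Abundances `x_i`
default to host marginal totals (so unparasitised hosts carry zero
weight); a presence mode (`x_i = 1`) is available because the choice is
not dictated by the method, only logged. Presence-mode Δ is exactly
invariant to uniform count rescaling; abundance-mode Δ changes only
through the finite-`N` denominator.

## Rarefaction and standardisation

An integer web of `m` events is expanded into its event multiset and
subsampled *without replacement* (hypergeometric), which guarantees
that drawing all `m` events returns the original web bit-for-bit — the
anchor for all downstream identities. Two species-handling conventions
are exposed, and they matter only for connectance:

- `subsample()` keeps the full host roster (unsampled hosts become
  empty rows), matching the ingest convention.
- `rarefaction_curve()` / `standardise_collection()` default to
  `hosts = "observed"`: each subsample is treated as a web in its own
  right containing only the species its events touch, because that is
  how real lower-effort webs present themselves, and it is the regime
  in which connectance falls with effort while the effective-number
  metrics rise. With the roster convention `S` is pinned and
  connectance instead *rises* with effort; both behaviours are
  legitimate, but cross-web comparisons should use one convention
  consistently.

Default grids are geometric with at most 25 points between 2 and `m`
(the full integer grid is available); replicate counts default to 100,
and 50 for modularity. Per-(network, size, replicate) seeds are hashed
from the master seed, so curves are reproducible and independent of
evaluation order. Standardisation subsamples every eligible web to a
common size — default 65 events, the second tercile of the empirical
size distribution in the compiled literature; `empirical_tercile()`
computes terciles of any collection via the interpolated
empirical-distribution quantile (type 4), under which sizes
{30, 65, 200} indeed give 65.

## The five analysis stages

All stages share one engine: `lme4` fits with study (or network nested
in study) as the grouping factor; the random structure (intercept vs
intercept + slope) is chosen by AIC — AICc where samples are small
(stages 3 and 5) — keeping the simpler model unless the richer one wins
by more than 1; fixed effects are tested by likelihood-ratio tests of
ML fits only (a REML fit is refused); backward simplification removes
the least significant droppable term at `p ≥ 0.05`, never dropping a
main effect while its interaction survives, and the minimum adequate
model is refitted with REML for reporting. Singular or non-converged
fits are flagged in the output rather than hidden. AICc uses
`AIC + 2k(k+1)/(n−k−1)` with `k` the full parameter count.

Response transforms follow the structure of each stage: metrics are
log-transformed except H2′ (stage 1 and the residual-producing
regressions), except H2′ and modularity (stages 2–3, where modularity
can be near zero in subsamples), and except H2′ and connectance
(stage 4). Non-positive values under a log transform are dropped with a
warning rather than silently shifted. In stage 4 the generality model
uses a random slope *on Δ* — the stage's predictor — which is the
natural reading of a random-slope structure in a Δ-only model.

Stage 5 regresses each metric's size-corrected residuals on guild,
absolute latitude (the hypothesis is equator-to-pole, hemispheres
pooled), Δ and their two-way interactions, with a random study
intercept. The residuals are **marginal** (observed minus fixed-effect
prediction): latitude and guild are constant within a study, so
conditional residuals — which subtract the fitted study intercepts —
would remove exactly the between-study variation those covariates could
explain; with conditional residuals the latitude test's power collapses
to near its size. Conditional residuals remain available by argument
for within-study questions.

## The synthetic generator

`generate_collection()` emulates a literature compilation: by default
28 studies, each with 1–15 webs, five guilds, latitudes uniform over
34.6° S–74.5° N, and matrix sizes log-uniform over 10–10⁴ (three orders
of magnitude). Each web draws host availability weights and parasitoid
abundance weights from lognormals with sd 2 — insect samples are
strongly right-skewed, and this guarantees rare species and singletons
at every effort level, which is what makes species keep accumulating
under subsampling (and connectance decline with effort) as in real
webs. Each parasitoid's host preferences are Dirichlet with
concentration θ (default 0.5), sampled in log space so that near-one-hot
preferences at tiny θ do not underflow; θ is the specialisation dial —
median H2′ falls monotonically as θ rises. Cell probabilities are
`∝ w_i v_j q_ij` and the matrix is one multinomial draw of exactly `m`
events, so matrix size is exact (a requirement of the rarefaction
contracts). Study heterogeneity enters as Gaussian random effects on
`log θ`; taxonomies are balanced trees from configurable branching
factors; an optional bias clusters preferences within host genera for
Δ-coupling experiments and is off by default so the null generator
stays null.

Latitude and guild effects are deliberately *not* wired into the
network mechanics: they are recorded in a truth ledger and added to the
metric table afterwards (`apply_injected_effects()`), so recovery tests
know the injected truth exactly instead of estimating it through the
generator's nonlinearities.

What passing tests show — and what they do not: the synthetic webs
reproduce the qualitative machinery (size dependence of the
effective-number metrics, its disappearance after standardisation,
null latitude/guild structure when none is injected, calibrated and
powered latitude tests at the 28-study scale), but they are
multinomially sampled from smooth abundance models. Real webs carry
phenology, spatial structure, misidentification and non-independent
rearing batches, none of which the generator emulates; a green suite
here validates the implementation, not any claim about nature.

## Problem sizes and runtime choices

The shipped tests run the oracle comparisons over every integer matrix
with `m ≤ 10` up to 3×3 (via their ~600 marginal classes), the
annealer against the exhaustive oracle on webs of up to 8 nodes × 5
seeds, rarefaction signs on 20 webs of 1000 events (12-point geometric
grids, 100 replicates), standardisation nulls on 60 webs, slope
recovery at 30 studies × 5 webs, type-I error over 200 simulated
collections at the 28-study scale and power over 50. These sizes keep
the whole suite in the tens of minutes on one core while leaving every
assertion at the scale stated with it.

## Known limitations

- The H2′ bounds and the annealed Q are heuristics outside the
  enumeration range; both are deterministic given seeds, and Q is
  reported as the best found, not a certified optimum.
- Backward simplification tests many hypotheses along its path; the
  per-term retention threshold is 0.05 without multiplicity correction,
  matching standard minimum-adequate-model practice.
- Δ assumes equal step lengths between ranks; branch lengths
  proportional to taxonomic distinctness variation are out of scope.
- The mixed models are Gaussian on the (possibly log) metric scale;
  non-Gaussian GLMMs and spatial autocorrelation are out of scope.
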