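---
title: "Cancer-niche dynamics under cluster-variation free energies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cancer-niche dynamics under cluster-variation free energies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvmniche)
```

## The model

`cvmniche` treats a tissue as a closed 2D Ising-like system: an `H x W`
lattice of binary cells, 0 healthy and 1 cancerous, with open (non-periodic)
boundaries. The Hamiltonian is a sum over nearest-neighbour pairs with zero
activation energy; the single convention `u(1,1) = -eps_in`, all other pair
energies 0, covers both regimes the scenarios need — positive `eps_in`
rewards cancer–cancer contacts (niche construction), negative `eps_in`
rewards breaking them up (apoptosis). The inverse temperature is fixed at 1
and not exposed: the Boltzmann weights are used only to *define* an energy
scale, so a temperature dial would be redundant with `eps_in`.

Exact evaluation of the free energy `F_H = -ln Z` needs `2^N` terms, so the
package evaluates variational free energies `F = U(Q) - S(Q)` over cluster
marginals at orders d = 1 (mean field), d = 2 (Bethe, pair clusters),
d = 3 (triangle clusters) and `full` (the exact limit, feasible to 16
sites). The d = 3 decomposition tiles every unit square with two right
triangles sharing the anti-diagonal; regions are the triangles, their
pairwise intersections, and intersections of intersections, weighted by
Möbius overcounting numbers `c_r = 1 - sum over super-regions of c_s`. On a
two-row, three-column patch this yields exactly four triangles minus three
shared pairs — the worked configuration the test suite pins term by term.
The counting numbers satisfy the exact-counting condition
(`sum of c_r over regions containing any site = 1`), which the suite checks
on a battery of small lattices including corners and edges; it is why
independent-site distributions give identical entropies at every order.

Two geometric conventions were genuinely open and are fixed as follows.
The triangle orientation follows the worked two-row example rather than the
(typographically inconsistent) general index pattern of the source
formulation, because the worked example is exactly reproducible. At open
boundaries only fully in-bounds clusters are regions; the Möbius recursion
then restores exact counting automatically, with boundary sites simply
having fewer super-regions. Coordinates in the API are 1-based `(row, col)`,
and site ids are row-major, matching a row-by-row numbering of the lattice.

## Marginals: empirical, translation-homogeneous

The marginal `Q_r` of a region is estimated as the relative frequency of
each binary configuration across *all translated instances* of the region's
shape in the current grid — one table per shape class (site, horizontal /
vertical / anti-diagonal pair, two triangle orientations). This is the
classical cluster-variation treatment; it makes energy and entropy
well-defined lattice totals (per-shape expectation times instance count) and
an evaluation O(N). The normalisation constraint is satisfied by
construction, so no Lagrange-multiplier machinery is needed; `0 log 0 = 0`,
and no pseudo-count smoothing is applied by default (an additive
pseudo-count is available in `empirical_marginals()` for robustness
experiments). A consequence worth knowing: entropies of *empirical* tables
are mixture entropies across instances, and region-weighted sums can be
negative (the Bethe entropy of a checkerboard is `-48 ln 2` on an 8 x 8
grid); only the full-order entropy is guaranteed non-negative.

Free energies are reported as lattice totals in natural units. The
mean-field evaluator (`order_d = 1`) uses the shared site marginal
`Q(1) = cancer_fraction` with product-form pair expectations, so its
internal energy is `n_pairs * (-eps_in * p^2)` and its entropy
`N * h(p)` — the closed forms the tests assert.

## Dynamics

The four scenario hyperparameters, with units and defaults:

* **tolerance** `tol in [0,1]` — sets the flip target (cancer if
  `tol > 0.5`, healthy otherwise; the 0.5 boundary goes healthy) and caps
  the cancer fraction that cancer-adding flips may reach. It does not evict
  pre-existing cancer: an apoptosis run starting above `tol` simply may not
  add more.
* **interaction** `eps_in` — natural units per pair, used verbatim from the
  scenario table (2.77259, 1.88001, −1.42670); no closed-form
  interpretation is assumed.
* **growth rate** `alpha` — percent of the lattice proposed per trial;
  `J = max(1, round(alpha/100 * N))`. The floor matters: the metastasis
  ramp starts at `alpha = 0.00061`, i.e. J ≈ 0.1, and clamping to one
  proposal per trial keeps the ramp meaningful.
* **noise** `n_t in [0,1]` — probability that a proposal is *global*
  (uniform over all eligible sites) rather than *local* (uniform over
  eligible sites adjacent to the target-state cluster, falling back to the
  nearest sites by Manhattan distance, then to global if no target-state
  site exists).

The noise reading deserves a note. The source transition rule compares an
auxiliary Bernoulli(ρ) variable against the noise, but under that literal
reading noise 0 and noise 0.25 behave identically whenever the Bernoulli
draw is 1, which contradicts the documented distinction between localised
(noise 0) and dispersive (noise 0.25) growth and makes the metastasis decay
schedule inert. The default mode therefore treats the noise directly as the
global-proposal probability, which reproduces all three phenomenologies;
the literal Bernoulli comparison is retained behind
`proposal_mode = "literal"` (ρ defaults to 0.2 and is consumed only there).

Acceptance is greedy and per flip: a proposed flip is evaluated by the
change in the d = 3 cluster-variation free energy and retained iff
`delta F <= 0` (ties accepted, so exactly-neutral early moves — a first
seed-adjacent flip on a cold lattice — do not deadlock) and the tolerance
cap holds. Batch acceptance semantics would need an unstated batch-revert
rule and are not offered. Because the free energy depends on the grid only
through the per-class configuration counts, a flip touches at most six
triangles plus the incident pairs and site, and the incremental update is
O(1); the suite verifies incremental against full re-evaluation to 1e-9.
Free energies (Kikuchi and mean-field) are recorded once per trial.

Per flip the RNG is consumed in a documented order — proposal-type draw,
then site draw — so a fixed seed reproduces a trajectory bitwise.

## Scenarios and the synthetic initial states

The presets encode the study conditions on the default 128 x 128 lattice,
100 trials, ρ = 0.2: local growth (tol 0.6, eps 2.77259, alpha 0.00610,
noise 0.25 dispersive / 0.00 localised, single centre seed), metastasis
(tol 0.6, eps 1.88001, alpha 0.00061→0.00610, noise 0.30→0.25, block
primary site), apoptosis (tol 1e-5, eps −1.42670, alpha 0.00610, noise
0.25, blobs of 41 and 172 cells). Choices the source leaves open, fixed
once here: the single seed sits at the grid centre; the primary site is a
12 x 12 interior block at rows/cols 21–32 ("small" relative to the lattice,
fully interior, configurable); blob seeds grow by deterministic
breadth-first accretion (ring order, row-major within rings) so a given
count always yields the same connected cluster. The large apoptosis niche
uses the printed figure of 172 cells even though it is nearer 1.05% than 1%
of the lattice. Schedules interpolate linearly from the first to the last
trial.

What the generator emulates — and does not. Initial states are idealised
geometric niches (a cell, a block, a compact blob) on an otherwise healthy
lattice; real tissue has irregular niche boundaries, cell-type heterogeneity
beyond a binary state, and open-system exchanges, none of which are
modelled. Passing trajectories therefore demonstrate the internal
consistency of the free-energy formulation (descent, cap, phenomenology),
not calibration to tumour data.

## Numerical choices and problem sizes

Tolerances: entropy/energy equivalences are asserted to 1e-9; marginal
normalisation to 1e-12. Degenerate inputs: grids must be at least 2 x 2 (a
triangle tiling needs one full unit square); exact enumeration refuses more
than 16 sites; saturation (no site left to flip towards the target) ends a
trial early and later trials record zero proposals.

The test suite runs the full-size 128 x 128 presets for the descent and cap
properties (J = 1 flip per trial makes each run take about a second) and
uses 64 x 64 grids, 60 trials and 10 seeds for the stochastic
phenomenology checks, with the seed niches scaled to the same lattice
fractions (10- and 43-cell blobs, 6 x 6 block). The explicit region-graph
enumeration is quadratic-ish in region count and is intended for the small
worked examples; full-size evaluation goes through the closed-form
per-class counting totals, which the suite equates with the explicit
enumeration on a battery of small shapes.

## Known limitations

The mean-field comparison trace is computed from the same trajectory that
descends the Kikuchi free energy — the system is never *driven* by the
mean-field functional. Kikuchi-vs-mean-field free-energy gaps are therefore
diagnostic, not a bound (with overlapping clusters no global distribution
consistent with the cluster marginals need exist, and the cluster free
energy need not upper-bound `F_H`; the variational bound is only asserted,
and tested, for explicit normalised distributions on tiny systems).
Proposals flip only towards the tolerance target, so a growth run never
removes cancer and an apoptosis run never adds it; metastatic "movement" is
not a paired removal+insertion but global colonisation that persists only
when it lowers the free energy. No belief propagation, no temperature
schedule, no cell agency.
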