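---
title: "Community flux balance analysis and cross-feeding inference with steadycross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community flux balance analysis and cross-feeding inference with steadycross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steadycross)
```

## The model

`steadycross` analyzes two-member (or, generically, K-member) microbial
communities growing on a dietary fiber under the balanced-growth community
FBA formulation (SteadyCom). Every member k grows at the common community
rate $\mu$ (h$^{-1}$), holds a biomass fraction $X_k \ge 0$ with
$\sum_k X_k = 1$, and carries absolute fluxes $V_k$ (mmol/h per unit total
community biomass) constrained by

$$S_k V_k = 0, \qquad LB_{jk} X_k \le V_{jk} \le UB_{jk} X_k, \qquad
  V_{\mathrm{bio},k} = \mu X_k .$$

Members interact only through a shared extracellular pool: each member
exchange reaction transfers its metabolite to the pool, and every pool
metabolite $p$ has a community exchange flux $e_p$ (negative = uptake from
the medium, positive = export) closing the balance
$\sum_k V_{\mathrm{ex}(k,p)} = e_p$. A member with $X_k = 0$ is forced to
$V_k = 0$ by the scaled bounds, so vanishing members are permitted.

Key assumptions inherited from the formulation:

* **Balanced growth** — all members share one growth rate. This matches
  mid-exponential co-culture where composition is stationary; it does not
  describe succession or lag phases.
* **Steady state** — no metabolite accumulation inside members; the pool
  only accumulates what the community exchanges export.
* **Linear capacity scaling** — per-gDW flux capacities scale with
  abundance.

For fixed $\mu$ the constraint set is a convex polytope, which is what makes
the downstream variability analysis and Monte Carlo sampling well-defined.

## The pipeline and its tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `mu_exp` | scenario-specific (0.35 for the inulin-like default) | h$^{-1}$ | experimentally observed community growth rate imposed on the model |
| `suboptimality_factor` | 0.05 | — | fiber budget grants (1+ε)-times faster growth |
| `total_abundance` | 1 | — | abundances are relative fractions |
| `mu_tolerance` | 1e-6 | h$^{-1}$ | bisection convergence width |
| `excess_value` | 1000 | mmol/gDW/h | "in excess" uptake for carbon-free nutrients |
| `growth_epsilon`, `flux_epsilon` | 1e-6 | h$^{-1}$, mmol/gDW/h | positivity thresholds in phenotype tests |
| `fraction_of_optimum` | 0.9 | — | growth enforced during product-formation tests |
| `n_samples`, `thinning` | 200000, 100 | — | reference sampler configuration |
| `alpha` | 0.01 | — | significance level for produced/consumed calls |

**Maximum balanced growth** is found by bisection on $\mu$ over the
feasibility LP (bracket $[0, 10]$ h$^{-1}$, tolerance `mu_tolerance`). The
LP layer is a dense two-phase tableau simplex with Bland's smallest-index
rule; community models activate many scaled-bound rows simultaneously, and
Bland's rule guarantees termination under that degeneracy. A defensive
residual check rejects near-feasible phase-1 endpoints, so bisection cannot
be fooled by a marginally infeasible growth rate.

**Minimal fiber uptake at fixed growth** maximizes the (negative) community
fiber exchange at $\mu = \mu_{\exp}$. The two problems are dual in the sense
that re-maximizing growth under the minimized uptake recovers
$\mu_{\exp}$ — an identity the test suite checks on every fixture.

**Degeneracy at the optimum.** The flux distribution at the optimal point of
either problem is generally not unique. The reported witness additionally
minimizes the sum of absolute member exchange fluxes, a parsimony rule that
selects a single representative distribution. The pin that fixes the primary
optimum is imposed as a width-$2\times10^{-7}$ box rather than an equality:
pinning exactly on the optimal face makes the simplex tableau maximally
degenerate. The primary objective value itself is always reported from the
primary LP, not from the refined witness.

**Suboptimal relaxation.** The fiber budget $u'$ is the minimal uptake at
$(1+\varepsilon)\mu_{\exp}$; all variability analyses then run at
$\mu_{\exp}$ with fiber uptake $\le u'$ (an inequality, not pinned — the
relaxation is a budget the community may leave unused). In a community with
linear yield chains, $u' = (1+\varepsilon)\,u_{\min}$ exactly, which the
tests exploit.

**FVA** solves two LPs per requested quantity (abundances, member exchange
fluxes, community exchanges) over the budget-constrained polytope.

## Monte Carlo sampling

The sampler is an artificial-centering hit-and-run chain run in the null
space of the equality constraints, where the polytope is full-dimensional:

* Warmup: extreme points along $\pm$ each null-space basis direction
  (2 per sampled dimension, capped at 2000), plus further randomized LP
  objectives if requested, plus their centroid as the interior start.
* Directions: a uniformly chosen warmup point minus the running center of
  all visited states; chords by ratio tests on the inequality rows; the
  next state uniform on the chord. Every `thinning`-th state is retained.
* The core is compiled (Rcpp) and uses R's RNG, so a fixed `seed` gives
  bit-identical matrices. The incremental chord bookkeeping is refreshed
  every 8192 steps to cap floating-point drift; retained samples satisfy all
  constraints to ~1e-9 in the test fixtures.
* Degenerate case: if every sampled direction has chord width below the
  tolerance, the sampler stops with an error suggesting dimension reduction
  rather than silently returning a frozen chain.

Abundances are sampled as free variables within their feasibility ranges,
consistent with reporting abundance ranges alongside exchange ranges; a
scenario may pin them via `fixed_abundances` when a known composition should
be imposed.

The reference configuration (200,000 retained points, thinning 100) is the
package default. The test suite and the acceptance script run the same code
at reduced size (hundreds to 20,000 points, thinning preserved at up to
100), sizes chosen so the full suite completes in well under a minute of
sampling time; the chain's split-half consistency and unit-box calibration
are themselves part of the suite.

## Classification and coupling

A member's exchanged metabolite is *produced* if the sampled flux
distribution's median is significantly greater than zero at `alpha`
(default 0.01), *consumed* if significantly smaller, *indeterminate*
otherwise. Two statistical choices deserve justification:

* **Signed-rank, not rank-sum.** The question is one-sample (is the median
  of one flux distribution zero?), for which the one-sample Wilcoxon
  signed-rank test is the appropriate rank test; a two-sample rank-sum test
  has no natural second sample here. `stats::wilcox.test(x, mu = 0)` is
  used with the normal approximation.
* **Raw p-values.** No multiple-testing correction is applied; the raw
  p < alpha rule is the classification contract. Thinned Markov-chain
  samples remain autocorrelated, which inflates nominal significance — the
  p-values should be read as classification thresholds, not calibrated
  error rates (the report notes this caveat).

Coupling is Pearson correlation across samples (Spearman available via
`method`). When a shared metabolite has no community exchange — no
environmental sink or source — its pool balance forces producer flux =
−consumer flux in every feasible point, so the pair's coefficient is −1
up to the ~1e-12 arithmetic of the null-space reconstruction; the suite
asserts this identity at 1e-9. Constant columns are excluded from the
matrix and recorded.

## The synthetic community generator

`make_toy_degrader_butyrogen()` emulates the topology of a fiber-degrading /
butyrate-producing pair:

* the **degrader** hydrolyzes a DP-`average_dp` polymer (default 25 monomer
  units of 6 carbons — a fructan-like chain), grows with
  `monomer_per_biomass` = 10, and its biomass reaction co-secretes 4
  lactate, 1 succinate and 2 acetate per unit biomass (obligate mixed-acid
  fermentation: growth forces acid secretion);
* the **butyrogen** grows on lactate (3 per biomass) and acetate (6 per
  biomass) and vents surplus lactate carbon as butyrate
  (2 lactate → butyrate + acetate, carbon-exact);
* lactate cannot leave the shared environment (its community export is
  closed), so all lactate carbon flows through the butyrogen.

These choices give the fixture its scientific character: the degrader
*needs* the butyrogen (its obligate lactate secretion has no other sink), so
the community optimum is interior rather than single-member; no butyrate is
made at the growth optimum, while the suboptimal budget opens a butyrate
flux; and the lactate exchange pair is perfectly anticorrelated. The default
experimental growth rate is 0.35 h$^{-1}$ with a 5% suboptimality factor,
the conditions of a fast inulin-like fermentation; an alternative
0.09 h$^{-1}$-style slow-fiber scenario is a one-argument change.

Because every flow is a linear yield chain, the generator emits a
closed-form answer sheet (maximum growth $\mu^* = \mathrm{DP}\cdot
c_F/a_M$, minimal uptake, budget, abundance FVA bounds), and the test suite
certifies the LP machinery against it — the oracles are independent of the
code paths they check (grid search for bisection, vertex enumeration for
FVA, known uniform moments for the sampler).

What the toy does **not** emulate: realistic network size (AGORA-scale
models have ~2000 reactions; the toys have ≤ 15 per member), redundant
pathways and futile cycles, cofactor and ATP bookkeeping, thermodynamic
constraints, and noisy experimental truth tables. Passing tests therefore
certify the *algorithms* — optimization, sampling, statistics — not the
biological fidelity of any particular genome-scale reconstruction.

`make_coupled_pair()` is the minimal balance-coupling fixture (one shared
metabolite, no sink, pinned abundances, a one-dimensional exchange
polytope), and `make_phenotype_fixture()` builds a network plus truth table
whose confusion counts are known by construction (exactly
`round(error_rate * n_rows)` rows disagree with model behavior).

## Media, carbon closure and fiber normalization

A medium lists permitted uptakes as positive magnitudes; applying it sets
the exchange lower bound to the negated magnitude (COBRA sign convention:
negative flux = uptake). Every *carbon-containing* exchange the medium does
not list is closed to uptake, so the named carbon source is the only bulk
carbon entering; carbon-free exchanges (minerals, ions, vitamins) default
to `excess_value`. Carbon is counted by parsing element counts from
metabolite formula strings; metabolites without formulas are treated as
carbon-free and reported in the `"no_formula"` attribute so silent leaks are
visible. Media may also bound or close exports (`export_bounds`), an
extension used to model metabolites that cannot leave the community
environment.

Fiber polymers are normalized on carbon: one fiber unit carries
`average_dp × carbon_per_monomer` carbons and must hydrolyze to exactly
`average_dp` monomer equivalents, with the degradation reaction's carbon
balance checked exactly. This makes growth on fibers of different chain
length comparable per unit carbon.

## Numerical choices

* LP: dense two-phase tableau simplex, Bland's rule, pivot tolerance 1e-9,
  right-hand sides sign-normalized, variables shifted to the nonnegative
  orthant; infinite bounds replaced by a 1e4 box (community fluxes are
  bounded by 1000 · abundance by construction). A post-solve residual check
  converts any surviving constraint violation above 1e-6 (relative) into an
  infeasibility verdict.
* Bisection bracket $[0, 10]$ h$^{-1}$; feasibility at the top of the
  bracket is reported as "growth not limited" (a missing uptake bound).
* Curation edits apply atomically with an audit log carrying each edit's
  inverse; `invert_edits()` replays them most-recent-first.
* JSON model writing is canonical (fixed key order, model-order entries,
  full-precision numbers), so read → write → read is a fixed point and
  outputs are diffable.
* The SBML writer tags exchange reactions with SBO:0000627 and the biomass
  reaction with SBO:0000629 so both designations survive a round trip; the
  test suite cross-checks the export against an independent SBML parser.

## Limitations

* LP sizes beyond a few hundred variables (e.g. unreduced genome-scale
  community models) will be slow through the dense tableau; the design
  targets curated or reduced models and synthetic fixtures.
* The sampler assumes the fixed-growth polytope is bounded; unbounded
  directions must be closed by medium or capacity bounds first.
* Produced/consumed calls inherit the autocorrelation caveat above;
  effective sample sizes are not estimated.
* Exact reproduction of any published community study requires that study's
  curated models and media; without them the package's guarantees are the
  property-based ones its test suite states.
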