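---
title: "Models and design choices in reefdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in reefdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefdiv)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the tunable parameters that matter, what
the synthetic-data generators emulate (and do not), and the numerical and
design choices that were genuinely open.

## Time conventions

Two clocks are used consistently. An **age** is measured in Myr before the
present — the axis on which users state divergence thresholds, breakpoints
and sea-level intervals. **t** is time since the root, `t = root_age − age`,
the direction in which likelihood integrals run. A chronogram must be
ultrametric; the constructor tolerates a relative root-to-tip discrepancy
of `1e-6` by default (`tol` argument) because trees from dating software
carry rounding noise. Divergence between two species is the age of their
most recent common ancestor — not twice that age — so a 5-Myr threshold
means "lineages that split less than 5 Myr ago".

The lineage count `N(t)` is right-continuous: an event at time `t` counts
from `t` onward. This convention is not cosmetic — it makes the identity
`∫ N(t) dt = Σ branch lengths` exact, which the piecewise likelihoods rely
on and the tests assert at `1e-9`. Multifurcating nodes are accepted; a
node of out-degree `m` contributes `m − 1` tied branching events.

## The time-dependent pure-birth likelihood

The diversification model is a pure-birth process whose per-lineage
speciation rate λ(t) comes from one of four families: constant; piecewise
constant with breakpoint ages; logistic
`λ(t) = 1/(1 + exp(−(a t + b)))`; or a two-rate sea-level covariate model
(one rate during high-stand age intervals, another elsewhere). Extinction
is deliberately absent: on reconstructed phylogenies of extant species
extinction rates are notoriously hard to estimate, and the constant-rate
birth–death fit (provided for exactly this check) tends to drive the
extinction rate to its zero boundary on such data, which the acceptance
experiments reproduce.

Conditioning on the root split, the log-likelihood is

$$\log L = \sum_{i} \log \lambda(t_i) \;-\; \int_0^{T} N(t)\,\lambda(t)\,dt
\;+\; \log\,(n-1)!$$

with the sum over the `n − 2` non-root branching events. The labelled-
histories constant `log (n−1)!` is included so absolute values match the
convention of the `ape` fitters (`ape::yule`, `ape::birthdeath`), which the
tests use as independent cross-checks; AIC differences are invariant to it.
If any event falls where λ = 0 the likelihood is `−∞`.

All integrals are exact. For the step families the rate is constant
between the union of branching times and epoch boundaries, so the integral
is a finite sum of rate × lineage-time products; the logistic sigmoid has
antiderivative `softplus(a t + b)/a`, applied segment by segment between
events. No quadrature error enters any fit.

Epoch boundaries are half-open: an event exactly on a breakpoint age
belongs to the **younger** epoch, a deterministic tie-break that matters
only on measure-zero sets for real data. The same rule classifies ages on
the younger edge of a sea-level interval as low-stand. Epochs and their
rates are always indexed oldest-first.

## Fitting and model comparison

* **Constant Yule**: closed form `λ̂ = (n−2)/X` (X = total branch length),
  standard error `λ̂/√(n−2)` (Poisson information). The report's SE method
  for multi-parameter fits is the observed information (numerical Hessian);
  per-epoch rates get the analytic `λ̂_j/√e_j`.
* **Birth–death**: the standard reconstructed-process likelihood in terms
  of net rate `r = λ − μ` and turnover `a = μ/λ`, conditioned on the root
  split and survival. The optimiser runs Nelder–Mead on
  `(log r, logit a)` from three starts, then an L-BFGS-B polish in
  `(r, a)` with box constraints so the pure-birth boundary `μ = 0` is
  attainable, plus one start pinned at that boundary.
* **Logistic**: Nelder–Mead plus BFGS polish over `(a, b)` from five
  starts (one at the constant-rate plateau `a = 0`,
  `b = logit(λ̂)`; four seeded perturbations). With `t` measured from the
  root, a negative slope means a rate declining toward the present — the
  direction in which a fitted slowdown is expressed; parameterising on age
  instead would flip the sign.
* **Piecewise (rate-shift)**: for fixed breakpoints every epoch rate has
  the analytic MLE `events/lineage-time`, so breakpoints are profiled by
  exhaustive search. The profile likelihood is piecewise in the breakpoints
  with jumps at branching times, which defeats continuous optimisers; the
  default candidate grid is every midpoint between consecutive distinct
  branching ages plus a uniform 0.1-Myr grid, deduplicated.
* `AIC = −2 log L + 2k` with `k` = 1 (constant), 2 (birth–death, logistic,
  covariate), `2m − 1` (piecewise with `m` epochs). The best model is the
  minimum, ties broken toward fewer parameters; no AIC weights.

### The epoch-occupancy floor

Profiling a breakpoint over a dense grid consumes more effective degrees
of freedom than the single parameter AIC charges for it. Left
unconstrained, the search happily places a breakpoint just past the
youngest branching event, declaring a zero-event "epoch" spanning the gap
to the present (or a near-empty epoch at the root, where only two lineages
exist). On single-rate simulations this inflates the two-epoch log-
likelihood by about 2.7 on average — enough to beat AIC's penalty and
select a spurious rate shift on most replicates. This is precisely the
minimum-segment problem of changepoint inference, and the package adopts
the standard remedy: during the search every epoch must contain at least
`min_events = 5` branching events (so each epoch rate carries a relative
standard error of at most `1/√5 ≈ 45%`); the floor shrinks automatically
on trees with fewer than `5m` events, and user-supplied fixed breakpoints
are never constrained. With the floor in place, AIC selects the constant
model on a clear majority of single-rate simulations while still detecting
a strong simulated shift (0.15 → 0.05 at 10 Ma) essentially always, with
median breakpoint error well under 1 Myr.

## LTT curves, envelopes and window rates

`ltt_curve()` is the cumulative event count. `ltt_envelope()` simulates
replicate trees from a fitted model **conditioned on the observed tip
count and root age** (rejection sampling) and reports pointwise 2.5/97.5
percentiles on a shared time grid — the right reference distribution for
asking whether the observed accumulation is unusual for a tree of this
size and depth. `window_rates()` is the non-parametric companion: fixed
age windows (default 10 Myr, youngest window containing the present),
rate = events/lineage-time per window, with zero-lineage-time windows
reported as missing rather than zero.

## Π_ST and partial randomizations

Given a binary species × site table and a divergence threshold `T`, only
unordered pairs of distinct species with divergence `< T` qualify.
`Δᴾ_S` averages qualifying divergences over all (site, co-occurring pair)
instances pooled across sites; `Δᴾ_T` averages them over the pooled
species set of the analysis; `Π_ST = (Δᴾ_T − Δᴾ_S)/Δᴾ_T`. Positive values
mean co-occurring species are *more* closely related than the pool
(clustering); negative values mean dispersion.

Two definitional points were genuinely open and are exposed as switches
rather than silently resolved:

* `delta_t_mode`: the total mean is computed over the pooled species set
  (default) or restricted to pairs observable in two different sites
  (`"between_sites"`). The two readings disagree between the report
  tables' caption and the defining text; the pooled reading is consistent
  with the worked numbers.
* `delta_s_mode`: within-site instances are pooled with equal weight per
  instance (default) or per-site means are averaged (`"site_mean"`). The
  worked-example arithmetic is insensitive to this weighting.

The null model shuffles species identities **uniformly within each clade
younger than the threshold**, leaving deeper structure fixed
(`null_mode = "within_blocks"`); because maximal sub-threshold clades are
exactly the connected components of the sub-threshold pair graph, pairs
crossing blocks never qualify and the test isolates structure attributable
to recent divergences. The alternative reading — shuffle the whole tree
and merely truncate the pair set — is available as
`null_mode = "truncate_only"`. P-values use the add-one permutation
convention `(count + 1)/(R + 1)` with ties counted as extreme, one-sided
in both directions; the interval bounds are empirical 2.5/97.5 percentiles
(linear interpolation). The default replicate count is 999 (the source
analyses do not state theirs). When no block has two members the null is
degenerate and the result is flagged `untestable` instead of returning
arithmetic on nothing. Report tables round to three decimals, half away
from zero; worked examples recomputed from printed (already rounded)
inputs can therefore differ by ±0.001 from re-derived values.

Full-enumeration nulls on ≤ 6-species trees back the Monte-Carlo
implementation in the tests: on the three-species toy the exact null mean
is 0 and `P(Π ≥ 0.1) = 2/3`, which the sampler reproduces within
Monte-Carlo error.

## The synthetic-data generators

The generators define the conditions under which the estimators are
exercised; their defaults mirror the study system's scale.

* **Trees**: forward pure-birth simulation from two lineages. Step-rate
  families use exponential waiting times restarted at epoch boundaries;
  the logistic family uses Ogata thinning with the per-segment supremum of
  the monotone sigmoid (globally bounded by 1). A duration stop fixes the
  root age; a tip-count stop runs to the time of the next untaken event,
  which makes `X ~ Gamma(n−1, λ)` under a constant rate and hence
  `E[(n−2)/X] = λ` exactly — the estimator is unbiased by construction,
  not approximately. Age-keyed families need a known root age and
  therefore require the duration stop. Rates of 0.067–0.15
  events/lineage/Myr and root ages of 35–50 Myr reproduce the tip counts
  (tens to ~150) and depths of the study clades.
* **Communities**: `neutral` samples uniformly without replacement
  (the calibration reference); `filtered` evolves a unit-rate Brownian
  trait on the tree (root value 0 — only relative distances matter) and
  samples with weight `exp(−strength·|trait − optimum|)` toward a
  per-site optimum, producing clustering; `dispersed` adds species in
  random order rejecting candidates within `strength` Myr of a resident
  (limiting similarity); `recent_allopatry` confines the members of every
  cherry younger than `strength` Myr to disjoint island groups and fills
  the rest neutrally, emulating young allopatric sister species with
  non-overlapping ranges. Sites split into two islands with alternating
  inner-reef/outer-slope habitats so both analysis scales are exercised.
* **Sea levels**: a fixed two-interval toy table, and a random
  "cenozoic-like" style alternating high/low spans over the last 30 Myr
  (older ages stay low-stand, reflecting how sparse the lineage record is
  before 30 Ma).

One calibration note: the strength of a limiting-similarity treatment must
be judged against the tree's divergence distribution. On a 40-tip,
λ = 0.067 tree most species pairs diverge by more than 25 Myr, so an
exclusion radius of a few Myr barely constrains assembly and yields a
near-null test; the dispersion power experiment therefore uses a 25-Myr
radius, under which ten species per site remain feasible.

What the generators do **not** emulate: dating error and topological
uncertainty in the chronogram; extinction; abundance (samples are species
lists); spatial autocorrelation among sites; and observation error in the
occurrence records. Passing tests therefore demonstrate correctness of the
statistics and calibration of the permutation test under idealised
assembly, not robustness to phylogenetic error on real data.

## Problem sizes and reproducibility

The experiment sizes used by the test suite are the package's chosen
study conditions: constant-rate recovery over 500 trees of 100 tips;
breakpoint and covariate recovery over 50 trees of ~150 tips; null
calibration over 200 neutral datasets with 199 randomizations each
(two-sided rejection tracked at nominal 5%, accepted in [1%, 11%]);
the allopatry signature over 100 replicates of a 60-species,
6-site system. Every stochastic function takes a `seed`; multi-part
computations derive per-part seeds deterministically, and the RNG state of
the caller is always restored, so any table — including the full
`run_analysis()` bundle — reruns byte-identically from its manifest.

## Known limitations

* The breakpoint search is exhaustive over a grid; with more than two
  breakpoints the combinatorics grow quickly and a coarser
  `grid_resolution` is needed. Breakpoint standard errors are not reported
  (the profile is piecewise-flat, so a Hessian there is meaningless).
* The logistic rate is bounded in (0, 1) events/lineage/Myr by
  construction; clades diversifying faster than one event per lineage per
  Myr need a rescaled time unit.
* Π_ST inherits the assumption that phylogenetic distance proxies
  ecological similarity (niche conservatism); the package measures
  structure, it cannot validate that assumption.
* The permutation null conditions on the observed occupancy pattern;
  gradients in richness across sites are therefore part of the conditioning,
  not part of what is tested.
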