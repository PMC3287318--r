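# reefdiv

Diversification rates and phylogenetic community structure for coral-reef
fish assemblages (or any clade with a dated phylogeny and presence/absence
community samples).

Highly diverse reef-fish communities sit at the centre of a long-running
argument between niche-based and neutral views of species coexistence. The
two views leave different fingerprints in data that can be read off a
chronogram and a species × site occurrence table:

* **Diversification through time.** Under a niche view, speciation should
  slow as ecological space fills; under a neutral view it should not.
  `reefdiv` fits a family of pure-birth (Yule) models with time-varying
  speciation rate λ(t) — constant, piecewise with breakpoints, logistic,
  and a sea-level covariate model — by maximum likelihood and compares
  them with AIC, alongside the constant-rate birth–death model,
  lineage-through-time (LTT) curves with simulation envelopes, and
  per-window rate estimates.
* **Phylogenetic community structure.** If co-occurring species are more
  closely related than a random draw from the regional pool the community
  is phylogenetically *clustered* (habitat filtering); if less related,
  *dispersed* (limiting similarity, or allopatric speciation at regional
  scales). `reefdiv` measures this with the Π_ST statistic and tests it
  against *partial randomizations* that shuffle species only within clades
  younger than a divergence threshold, so the signal can be traced through
  time.

## The statistics

For a chronogram with `n` tips, root age `T` (Myr) and lineage count
`N(t)`, the time-dependent pure-birth log-likelihood conditioned on the
root split is

    log L = Σ_i log λ(t_i)  −  ∫₀ᵀ N(t) λ(t) dt  +  log (n−1)!

with the sum over the `n − 2` non-root branching events. The constant-rate
MLE is the closed form `λ̂ = (n−2)/X` with `X` the total branch length;
piecewise and sea-level models have analytic per-epoch MLEs
(events / lineage-time), with breakpoints profiled over a grid; models are
ranked by `AIC = −2 log L + 2k`.

For an occurrence matrix and a divergence threshold, `Δᴾ_S` is the mean
divergence (MRCA age) of co-occurring species pairs diverged by less than
the threshold, `Δᴾ_T` the same mean over the pooled species set, and

    Π_ST = (Δᴾ_T − Δᴾ_S) / Δᴾ_T

is positive under clustering and negative under dispersion. Significance
comes from permutation nulls restricted to the sub-threshold clades, with
add-one one-sided p-values and empirical 95% bounds.

A synthetic-data module simulates chronograms under every rate family
(exponential waiting times / Ogata thinning) and assembles communities
under neutral, habitat-filtered, limiting-similarity and recent-allopatry
rules, so the whole pipeline is testable end to end without external data.

## Worked example

Simulate a chronogram whose speciation rate drops from 0.15 to 0.05
events/lineage/Myr at 10 Ma, then ask the model suite what happened:

```r
library(reefdiv)
tree <- simulate_yule_tree(rate_piecewise(c(0.15, 0.05), breakpoints = 10),
                           duration = 35, seed = 5)   # 135 tips
tab <- model_comparison(tree)
tab[, c("model", "logL", "k", "AIC", "best")]
#>           model   logL k     AIC  best
#> 1          yule 55.486 1 -108.97 FALSE
#> 2   birth_death 55.486 2 -106.97 FALSE
#> 3      logistic 73.706 2 -143.41 FALSE
#> 4 breakpoints_1 80.542 3 -155.08  TRUE
#> 5 breakpoints_2 81.403 5 -152.81 FALSE
attr(tab, "fits")$breakpoints_1
#> Diversification fit (piecewise): logL = 80.5419, k = 3, AIC = -155.0837
#>   lambda_1 = 0.1499 ± 0.0163, lambda_2 = 0.04319 ± 0.00623, tau_1 = 10.1
```

AIC picks the one-breakpoint model and recovers the simulated rates and
shift age (0.1499 and 0.0432 around a breakpoint at 10.1 Ma). The same
slowdown is visible non-parametrically in `window_rates(tree, 10)`.

Communities assembled under recent allopatry — young sister species
confined to different islands — leave the characteristic threshold
signature in Π_ST: dispersion (negative values) among recently diverged
species, fading to nothing at the full-tree threshold:

```r
com_tree <- simulate_yule_tree(rate_constant(0.067), n_tips = 60, seed = 81)
occ <- simulate_communities(com_tree, n_sites = 6, richness_per_site = 20,
                            mode = "recent_allopatry", strength = 5, seed = 8)
pist_profile(occ, com_tree, thresholds = c(5, 10, 25, 50),
             reps = 999, seed = 9)[, c("threshold", "pi_st")]
#>   threshold   pi_st
#> 1         5 -0.2005
#> 2        10 -0.2028
#> 3        25 -0.0228
#> 4        50 -0.0249
```

`run_analysis()` (or `inst/cli/reefdiv.R run`) chains every stage — model
table, LTT envelope, window rates, regional and local Π_ST profiles,
community summary — and writes the tables plus a JSON manifest that fully
records seeds and parameters.

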