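# epochsse

Epoch-sliced, state-dependent diversification analysis for time-calibrated
phylogenies, built around the question of how the absence of megaherbivores
between the end-Cretaceous extinction (66 Ma) and the Late Eocene rise of
giant mammals (~40 Ma) reshaped the evolution of associated plant traits —
megafaunal fruits (≥ 4 cm) and spiny armature — and the diversification of
the lineages carrying them.

The package is aimed at macroevolutionary biologists who have (i) a
time-calibrated tree (or a posterior sample of trees), (ii) a species table
with a continuous trait and/or binary defence traits, and optionally (iii) a
fossil size table, and who want to ask whether rates shifted inside a fixed
geological interval.

## What it computes

* **Epoch-sliced BiSSE likelihood.** The binary-state speciation–extinction
  model with per-epoch rates λ₀, λ₁, μ₀, μ₁, q₀₁, q₁₀ (events/lineage/Myr),
  integrating the standard BiSSE equations
  dE_i/da = μ_i − (λ_i+μ_i+q_ij)E_i + λ_iE_i² + q_ijE_j and
  dD_i/da = −(λ_i+μ_i+q_ij)D_i + q_ijD_j + 2λ_iE_iD_i
  branch-wise in C++, with rates switching at epoch boundaries (default
  66 and 40 Ma), state-specific sampling fractions, unknown tip states, and
  survival conditioning at the root.
* **Model ladder + stepwise selection.** Up to 18 nested models (rates tied
  or free across states; constant, gap-shifted or fully time-varying),
  compared by likelihood-ratio tests: parameters are kept only when they
  significantly improve fit.
* **MCMC.** Slice sampling of the selected model's rates, pooled across a
  posterior sample of trees; epoch-wise medians, 95% credibility intervals,
  net diversification r = λ − μ per draw, and contrast probabilities such as
  P(λ_gap < λ_pre).
* **Ancestral fruit size.** Re-rooting ML reconstruction of log fruit length
  under Brownian motion with CIs, traitgram coordinates, fossil overlays at
  epoch midpoints, and exact fossil constraints via zero-length pseudo-tips.
* **Stochastic character maps.** ML Mk fits and exact conditional sampling
  of binary-trait histories (uniformization), node posterior probabilities,
  and counts of independent trait origins.
* **Simulators.** Forward Gillespie state/epoch-dependent birth–death trees
  with full character histories, neutral binary traits, Brownian traits and
  toy fossil tables — every stage runs without external data.

## Worked example

```r
library(epochsse)

# a three-epoch toy clade whose speciation halves in the middle epoch
grid  <- epoch_grid(c(20, 10))
rates <- rate_set(lambda0 = c(0.3, 0.15, 0.3), lambda1 = c(0.3, 0.15, 0.3),
                  mu0 = 0.05, q01 = 0.05, grid = grid)
cfg <- sim_config(rates, grid = grid, origin_age = 30, root_state = 0,
                  tip_window = c(150, 400))
sim <- simulate_bisse_tree(cfg, seed = 1)

spec <- model_spec(lambda = c("tied", "shift"), grid = grid)  # 4 parameters
fit  <- fit_ml(spec, sim$phy, sim$tip_states, seed = 1)
post <- sample_posterior(fit, sim$phy, sim$tip_states, n_gen = 500, seed = 2)
su   <- pool_and_summarize(post)

epoch_interval(su, "lambda0", epoch = 2)
#>        lo    median        hi
#> 0.1024783 0.2184053 0.4098049
contrast_prob(su, "lambda0", epoch_a = 1, epoch_b = 2)
#> [1] 0.9711111
```

On this single 241-tip tree the mid-epoch speciation interval
(0.10–0.41/Myr) brackets the generating value of 0.15/Myr, and 97% of the
posterior draws put speciation inside the gap below the pre-gap rate — the
signature the analysis is designed to detect. Pooling over a posterior
sample of trees (as `analysis/04_mcmc_rates.R` does) tightens these
summaries. (Numbers are the output of this exact code.)

The `analysis/` directory holds the full study as numbered drivers —
`01_simulate_data.R` through `07_neutral_robustness.R` (simulation,
classification, model selection, MCMC, fruit-size reconstruction with
fossil constraints, stochastic mapping, neutral-trait robustness) — each a
thin script over the package functions that prints what it found and writes
its tables under `results/`.

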