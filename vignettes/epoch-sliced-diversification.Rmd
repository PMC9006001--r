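---
title: "Epoch-sliced, state-dependent diversification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epoch-sliced, state-dependent diversification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Large herbivores shape vegetation, disperse very large ("megafaunal", here
fruits at least 4 cm long) fruits, and select for physical defences such as
spines and prickles (armature). Between the end-Cretaceous extinction of the
non-avian dinosaurs (66 Ma) and the rise of megaherbivorous mammals in the
Late Eocene (about 40 Ma), terrestrial ecosystems lacked herbivores above a
tonne. If such a gap changed the selective regime for associated plant
clades, it should be visible in time-calibrated phylogenies as shifts, at
those two boundary ages, in speciation, extinction, and the rates at which
the associated traits were gained and lost.

`epochsse` implements the full analysis chain needed to ask that question of
any clade: a binary-state speciation–extinction (BiSSE) likelihood whose
rates are piecewise-constant across geological epochs, a nested ladder of
constrained models compared by likelihood-ratio tests, slice-sampling MCMC
pooled over a posterior sample of trees, Brownian-motion ancestral
reconstruction of a continuous trait with fossil constraints (traitgrams),
stochastic character maps of binary defence traits, and forward simulators
that generate every input the pipeline consumes.

# The epoch-sliced BiSSE model

A binary character with states 0/1 influences diversification through six
rates per epoch: speciation $\lambda_0, \lambda_1$, extinction
$\mu_0, \mu_1$ and transitions $q_{01}, q_{10}$ (all in events per lineage
per Myr). Ages are measured before present, tips at 0; an epoch grid is a
strictly decreasing vector of boundary ages, by default $(66, 40)$, giving
epochs $(\text{root}, 66]$, $(66, 40]$ (the megaherbivore gap) and
$(40, 0]$. An age exactly on a boundary belongs to the older epoch.

Along a branch the standard BiSSE ordinary differential equations are
integrated backward in age $a$,

$$\frac{dE_i}{da} = \mu_i - (\lambda_i + \mu_i + q_{ij})E_i
  + \lambda_i E_i^2 + q_{ij}E_j,$$
$$\frac{dD_i}{da} = -(\lambda_i + \mu_i + q_{ij})D_i + q_{ij}D_j
  + 2\lambda_i E_i D_i,$$

with the rates switching at epoch boundaries; boundaries are mandatory mesh
points, so a rate discontinuity never straddles an integrator step. A tip
observed in state $i$ starts with $D_i = f_i$, $D_j = 0$,
$E_i(0) = 1 - f_i$, where $f_i$ is the state-specific sampling fraction; a
tip of unknown state starts with $D_i = f_i$ for both states, so species
lacking trait data may be kept. At an internal node
$D_i \leftarrow D_i^{L} D_i^{R} \lambda_i$ using the $\lambda$ of the epoch
containing the node age (the root node included). At the root the states
are combined with weights $w$ ("obs": proportional to $D$; alternatives:
flat or a fixed state), and by default the likelihood is conditioned on the
survival of both root lineages by dividing by
$\sum_i w_i \lambda_i (1 - E_i)^2$.

## Numerical choices

The four-variable system is integrated by an adaptive Cash–Karp
Runge–Kutta scheme written in C++ (the same design choice the established
diversification packages make). Default tolerances are absolute $10^{-12}$
and relative $10^{-10}$: tight enough that inserting an epoch boundary with
identical rates on both sides moves a 50-tip log-likelihood by less than
$10^{-8}$, which we treat as a correctness invariant. Optimization and MCMC
use $10^{-9}/10^{-7}$, which changes log-likelihoods by $\sim 10^{-8}$ and
halves the cost. $(D_0, D_1)$ are renormalized into a log accumulator at
every node and whenever they leave $[10^{-12}, 10^{12}]$, keeping the ODE
linear in $D$ rather than integrating in log space. $E$ is clamped to
$[0,1]$ and $D$ to non-negative values against roundoff; without the
clamp, extreme rate proposals (e.g. $\lambda$ near the upper bound) can
push $D$ to $-10^{-300}$ and poison the root weighting.

# The model ladder and stepwise selection

A `model_spec` assigns each of the $6 \times$ epochs rate cells to a free
parameter; cells sharing a parameter are constrained equal. Each rate class
($\lambda$, $\mu$, $q$) has a state mode (tied or free) and a time mode:
tied, *shift* (the middle epoch differs, the flanking epochs share a
value — the megaherbivore-gap shift), or free. The programmatic ladder holds
the $2^3$ state combinations at constant rates, time-dependent extensions
of the state-free model (each class gaining a shift or full time freedom,
plus shift combinations), and the fully free model — exactly 18 models from
3 to 18 parameters, every one nested in the fully free model. The exact
membership of the original 18-model set is not recoverable from the main
text of the study this package generalizes, so the ladder is generated from
this symmetric cross and is user-overridable.

Fits maximize the likelihood over log rates (bounds $10^{-8}$–$10$/Myr)
from jittered restarts around a Yule-rate heuristic. Stepwise selection
starts at the fewest-parameter model and moves to a richer nested model
only when the likelihood-ratio test rejects at level $\alpha = 0.05$
(configurable), i.e. extra parameters are kept only when they significantly
improve fit; as $\alpha \to 0$ nothing rejects and the simplest model
stands, at $\alpha = 1$ the search walks to the fully free model. Ties
among equally parameterized candidates go to the higher log-likelihood,
then ladder order.

A calibration caveat surfaced while validating the test: the $\chi^2_1$
null of the state-dependence LRT is only nominal when both state-specific
rates are well identified, which at 100–300 tips requires an even state
mix at the tips (transition rates around 0.1/Myr on these tree depths).
With rare transitions one $\lambda$ is informed by a handful of tips and
the test over-rejects by a few percent. The calibration studies in the test
suite therefore simulate with $q = 0.1$; empirical analyses with very
unbalanced traits should expect mild anticonservatism.

# MCMC and pooling across trees

The posterior of the selected model's rates is sampled by univariate slice
sampling (stepping-out and shrinkage) over log rates, starting at the ML
point, with independent exponential priors on the natural rates (mean
$2\times$ the ML rate of the fully constrained model by default — the prior
the cited tooling constructs — and user-overridable; the Jacobian of the
log transform is included). Step widths adapt during an initial phase that
is kept in the stored chain; the first 10% of each chain is discarded at
summary time only. Chains from different trees are pooled by concatenation
with equal draws per tree. Summaries report, per epoch and state, the
posterior median and 95% interval of every rate and of net diversification
$r = \lambda - \mu$ computed per draw, plus contrast probabilities such as
$P(\lambda_{\text{gap}} < \lambda_{\text{pre}})$ as the fraction of pooled
draws satisfying the inequality. Quantiles are ECDF-based (type 2), so
pooling identical chains is exactly idempotent.

# Ancestral reconstruction and traitgrams

For log fruit length the ancestral estimate at each internal node is the
Brownian-motion ML root state of the tree re-rooted at that node, computed
by Felsenstein pruning (equivalently the GLS estimate; the test suite
checks it against the exact joint-ML linear-system solution and against an
independent implementation). $\sigma^2$ is the ML estimate
($\text{RSS}/n$, not REML), and node variances are the re-rooted root
variance scaled by $\hat\sigma^2$, with 95% CIs at $\pm 1.96$ standard
errors; an independent implementation that scales by $n/(n-1)$ matches
after rescaling. Edge states are linearly interpolated (20 samples per
edge by default) to draw traitgrams: the tree projected into (age, trait)
space.

Fossil constraints are implemented as zero-length pendant pseudo-tips
grafted onto the constrained lineage at the fossil age: exact (the node is
pinned to the value), and reusing the unconstrained machinery. Fossils are
overlaid on the traitgram at the midpoint of their epoch's age interval,
log-transformed like the tips; seed measurements are flagged as minimum
size estimates and never enter a likelihood.

# Stochastic character mapping

Armature is modelled by a 2-state Markov process; gain and loss rates are
fit by ML (ARD by default, since the scientific question distinguishes
gains from losses), with the root prior defaulting to the stationary
distribution of the fitted matrix. Maps are drawn exactly: node states from
their conditional distributions (root from prior times partial likelihoods,
then pre-order draws), and within-branch paths conditional on endpoints by
uniformization, which bounds runtime on long branches with low rates. Node
posterior probabilities are frequencies across maps (2000 maps put them
within 0.05 of the exact re-rooting marginals on 50-tip trees; the default
of 500 maps mirrors common practice). Independent origins of a state are
counted as change points into it across all branches — a root already in
the state contributes no origin — and summarized as the min/median/mode
across maps.

# The synthetic-data generator

`simulate_bisse_tree` is a forward-time Gillespie simulation of the exact
generating model of the likelihood: per-lineage exponential waiting times
at the current epoch's total rate, events chosen proportionally, rates
switching at boundaries, extinct subtrees pruned, and the full character
history retained (it is returned as the same validated `character_history`
object the mapping code produces). Crown simulations condition on both
crown lineages surviving, matching the likelihood's survival conditioning;
acceptance is by rejection until the surviving tip count enters a window.
Window conditioning is not part of the likelihood, so very narrow windows
distort calibration studies slightly; the suite uses generous windows.
Neutral traits, Brownian tip values and toy fossil tables complete the
inputs, so every stage of the pipeline runs without any external data.

What the generator does *not* emulate: phylogenetic error and incomplete
taxon sampling structure beyond per-state fractions, among-lineage rate
heterogeneity (hidden states), diversified sampling, or fossilized
ancestors. Green tests therefore demonstrate correctness of the machinery
under the model's own assumptions, not robustness of the science to their
violation.

# Study scales used in the checks

The heavy calibration studies are sized for a single CPU: state-dependent
rate recovery uses 30 trees of roughly 280–600 tips grown from a state-1
crown over 22 Myr at $(\lambda_0, \lambda_1, \mu, q) =
(0.1, 0.3, 0.05, 0.01)$, with 250-generation slice chains per tree; LRT
calibration uses 200 null trees of 70–150 tips (a window centred on 100
tips — wider windows admit very small trees whose finite-sample null is
visibly inflated); the neutral-trait robustness check runs 50 replicates
against a two-model ladder, each on a freshly simulated 100–220-tip tree.
The fresh tree per replicate matters: the selection rate conditional on one
fixed tree shape varies widely around the nominal level (we observed
per-tree rates from ~2% to ~20%), which is itself the artefact the
robustness check exists to expose — on empirical data the check reports the
rate for *your* tree, while the calibration study here establishes that the
procedure is honest on average over tree shapes. The acceptance script
reruns a condensed version of each study. Chain lengths are short because slice sampling decorrelates
these low-dimensional posteriors within a few sweeps; interval estimates
at these lengths are coarse but unbiased.

# Known limitations

* Two states only; no hidden-state (HiSSE-style) or multi-state extensions,
  so "state-dependence" here can reflect correlates of the focal trait.
* Piecewise-constant time dependence with user-fixed boundaries; the
  boundary ages are inputs, not estimated.
* The LRT compares fixed nested pairs; no parametric-bootstrap null.
* Rejection-window tree simulation (not GSA); fine for calibration suites,
  mildly biased for very narrow windows.
* Posterior summaries report no convergence diagnostics beyond what the
  chains expose; the intended use pools many short chains across trees.
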