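---
title: "Pollen-host traits and bee diversification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pollen-host traits and bee diversification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollendiv)
```

## The scientific problem

Bees depend on floral pollen, and flowers differ sharply in how they offer
it: some present pollen openly on exposed anthers (*accessible* rewards,
typical of Asteraceae, Malvaceae or Cucurbitaceae), while "bee-flowers"
such as many Fabaceae and Lamiaceae conceal it inside keel flowers or
narrow tubes (*restricted* rewards) so that only behaviourally or
morphologically specialised visitors can extract it. `pollendiv`
implements a complete inference chain for asking whether lineages that
exploit restricted pollen diversify at different rates from lineages on
accessible pollen:

1. **Trait coding** — turn quantitative per-sample pollen-load counts
   into binary species-level characters.
2. **Ancestral-state reconstruction** — a two-state Markov (Mk) model
   with Bayesian rate integration and per-node Bayes-factor tests.
3. **State-dependent diversification** — BiSSE/HiSSE-style likelihoods
   with hidden states and incomplete sampling, fitted by multi-start
   maximum likelihood (six-model ladder, AIC comparison) and by Bayesian
   MCMC (posterior contrast of net diversification).
4. **Simulation machinery** — forward simulators of trees, characters and
   pollen tables, plus orchestrated power / false-positive / sensitivity
   studies.

Throughout, state 0 is *accessible* (A) and state 1 *restricted* (R); for
the host-specificity partition, 0 is *specialist* (oligolectic) and 1
*generalist* (polylectic). Branch lengths are absolute time (Myr); all
rates are per lineage per Myr.

## Trait coding from pollen loads

A pollen sample is the scopal load of one female: percentages over pollen
types plus a load-size weight recorded before the pollen was removed.
Coding proceeds in three steps, each mirroring standard quantitative
pollen-analysis practice:

* **Contamination filter.** Within each sample, types below 5% of the
  load are excluded and the rest renormalised. The filter is applied *per
  sample*, before any pooling, so that a contaminant can never be rescued
  by averaging across many samples. It is strict ("less than 5%"), so a
  type at exactly 5% is kept.
* **Load-weighted aggregation.** Samples are combined as a weighted mean
  with weights proportional to load size; literature records without load
  sizes default to weight 1. Types whose aggregate share still falls
  below the threshold are dropped, so every retained type exceeds it.
* **Classification.** A species is coded `A` if only accessible types
  remain, `R` if only restricted ones, and polymorphic `AR` when both
  categories persist, each with total share above the same 5% level. The
  5% level is reused here because it is the one contamination threshold
  the protocol defines; a separate polymorphism threshold would be an
  extra free parameter with no empirical anchor. Species whose retained
  types cannot be resolved against the catalog are `data_deficient`. A
  species is a *specialist* when at least 95% of its pollen comes from
  one plant family (inclusive at the boundary; genus-level available via
  `level = "genus"`).

Four binary partitions feed the diversification analyses, differing in
how `AR` is resolved: `PA1` scores it restricted, `PA2` ambiguous, `PA3`
accessible, and `PS` codes specialist (0) versus generalist (1).
`data_deficient` species are missing in every partition. The orderings
imply a useful invariant checked in the tests: per species, the `PA1`
state always dominates the `PA3` state under `0 < 1`.

## Ancestral states: Mk model, marginals, node Bayes factors

The two-state Mk likelihood uses the closed-form `2x2` transition
probabilities and Felsenstein pruning. Ambiguous, polymorphic and missing
tips all enter as `(1, 1)` partials — the standard Mk treatment of
polymorphism when the polymorphic state itself is not modelled. The root
prior defaults to uniform; a stationary prior is available where the rates
make it well defined.

`asr_marginal_posteriors()` integrates over the two rates by
coordinate-wise slice sampling under independent exponential priors. The
prior mean is set from the data scale: Fitch parsimony changes divided by
total tree length, floored at 0.01 — a tuning-free analogue of the usual
"rates on the order of a few changes per tree" heuristic. Per retained
draw, marginal node probabilities come from the exact down-pass/up-pass
recursion (validated in the tests against clamped-likelihood ratios), and
their posterior means are reported.

Node support uses the fossilisation device: the node is clamped to each
state in turn, each constrained marginal likelihood is estimated by
stepping-stone sampling (10 power posteriors, inverse temperatures at
quantiles of Beta(0.3, 1) — the standard geometric-path schedule; the
harmonic-mean estimator was rejected as unstable), and
`BF = 2 (ln mL_best − ln mL_other)`. A node is called significant when
`BF > 5`, strictly; a clamp with zero likelihood reports an infinite,
flagged BF.

## The SSE likelihood engine

The core is the coupled D/E system of state-dependent birth-death
models. Per combined state `i` (observed x hidden; ordering
`(A,h1), (R,h1), (A,h2), ...`):

```
dE_i/dt = mu_i − (lambda_i + mu_i) E_i + sum_j Q_ij E_j + lambda_i E_i^2
dD_i/dt = −(lambda_i + mu_i) D_i + sum_j Q_ij D_j + 2 lambda_i E_i D_i
```

`E_i` is the probability that a lineage in state `i` leaves no sampled
descendant; `D_i` the density of the observed subtree. Tips start at
`E = 1 − rho` and `D = rho` on the compatible states (all states for
ambiguous/missing tips): sampling fractions act only at the tips, the
standard treatment of incomplete taxon sampling. Branches are integrated
with an adaptive Dormand–Prince 5(4) scheme in compiled code
(`rtol = 1e-8`, `atol = 1e-10` by default, matching the precision of the
established SSE implementations and configurable throughout), with `D`
log-rescaled at nodes and on underflow — double precision fails on
~90-tip trees with small rates otherwise. At internal nodes
`D = lambda_i D_left D_right`; at the root, terms are combined either
with equal weights or weights proportional to the root `D`
(the default, following common SSE practice), and survival conditioning
divides each root term by `lambda_i (1 − E_i)^2`. Both choices are
exposed as flags because published analyses rarely state them; the
defaults are `condition_on_survival = TRUE`,
`root_weighting = "observed_weighted"`.

Three exact properties anchor the implementation and are enforced in the
test suite:

* a survival-conditioned cherry with `mu = q = 0` has
  `lnL = −2 lambda t` exactly;
* with state-independent rates the likelihood factorizes into a
  constant-rate birth-death term plus the Mk character likelihood
  (using equal root weights and a uniform Mk root prior — the weighted
  root treatment deliberately breaks this factorization);
* tying all rates across hidden states collapses the likelihood onto the
  observed-state-only model, for any hidden transition rate.

The collapse property has a practical corollary: in models whose rates do
not vary across hidden states (Mase, Mas, M0), the hidden channel is
*inert* — the likelihood does not depend on `q_hidden` at all. `fit_ml()`
therefore evaluates those models on the observed-state space (an exact,
tested reduction), and `q_hidden` remains a formal free parameter of the
specification that the data cannot identify.

## The six-model ladder and its fitting strategy

All six models share three transition rates (`q01`, `q10` between
observed states; one `qh` between hidden states; simultaneous
observed-and-hidden changes are barred). The ladder pairs each
state-dependent model with a null of matching parameter richness, so AIC
comparisons cannot favour state dependence merely through flexibility:

| model | lambda, mu vary by | hidden | free parameters |
|-------|--------------------|--------|-----------------|
| Mase  | observed state     | 2      | 7  |
| Mas   | observed lambda, single mu | 2 | 6 |
| Mahse | observed x hidden  | 2      | 11 |
| M0    | nothing            | 2      | 5  |
| M0h2  | hidden state only  | 2      | 7  |
| M0h4  | hidden state only  | 4      | 11 |

One genuinely open reading of the model descriptions is whether Mase and
Mas carry a hidden channel at all ("analogous to BiSSE" suggests none;
"each with two or four hidden states" suggests two). We give them two
hidden states with rates tied across them: this realises the uniform
three-transition-rate structure, and by the collapse property it is
likelihood-equivalent to the plain BiSSE reading, so nothing hinges on
the choice beyond the bookkeeping of `q_hidden`.

Fitting is Nelder–Mead on log-parameters (positivity for free; stopping
at relative tolerance `1e-10` or 5000 iterations). Start 1 combines a
character-independent birth-death fit with the parsimony transition-rate
guess; starts 2–5 jitter it with lognormal(0, 0.5^2) noise. Each start
gets a short exploratory run and the best is polished to convergence —
the best-of-five-starts strategy standard for these multimodal surfaces.
Model support uses the conventional AIC margin of 2 against the best
null; ties rank the more parsimonious model first. Net diversification
is reported per observed state, averaging over hidden states with equal
weights.

## Bayesian contrast of net diversification

`run_mcmc()` targets prior x likelihood for a five-parameter model
(state-dependent speciation, shared extinction, free transition rates)
or full BiSSE (state-dependent extinction too), on the two-state space.
Priors are independent exponentials; each mean defaults to twice the
character-independent net-diversification estimate — the convention of
the established Bayesian SSE tool. The sampler is coordinate-wise slice
sampling (tuning-free; widths adapted from the sample spread during
burn-in), run for 10,000 generations with 20% burn-in by default, and is
exactly reproducible given a seed. The headline summary is
`PP(d_R > d_A)`: the fraction of retained samples in which the
restricted state's net diversification `d = lambda − mu` exceeds the
accessible state's (strict inequality; exact ties would count against
the hypothesis). The difference and ratio sample sets are exposed for
violin plots; note the ratio is unstable whenever `d_A` has posterior
mass near zero, so the difference is the contrast we test against.

## Simulators and the synthetic study conditions

`simulate_bisse_tree()` is an exact Gillespie simulation from a crown
pair sharing a root state drawn from the stationary distribution of the
transition process. Stopping is either at a fixed extant count (the tree
is cut at the moment the count is reached) or at a fixed crown age;
extinct lineages are pruned, and crown extinction triggers resimulation
on a fresh seed stream (acceptance-rejection, attempt count recorded) so
the stopping rule stays exact. `apply_incomplete_sampling()` prunes tips
uniformly and derives state-specific sampling fractions from `f`, the
assumed share of accessible-state species among the unsampled:
`rho_0 = n0/(n0 + f N_unsampled)`, `rho_1 = n1/(n1 + (1−f) N_unsampled)`.

The synthetic pollen generator draws, per species, 1–22 replicate
samples (the replicate range of the motivating survey), Dirichlet
proportions over that species' preferred host types (mixed species carry
both categories with shares of at least 0.25 before contamination), and
contaminant types whose total share is capped at 4.9% — strictly below
the 5% filter, so coding recovery of the true state is guaranteed by
construction, and the end-to-end recovery test is a check of the
pipeline's bookkeeping, not a statistical gamble. What the generator does
*not* emulate: identification error in pollen typing, spatial structure
among localities, within-species niche variation broader than the
Dirichlet, or genuinely borderline polymorphism — so passing recovery
says nothing about those failure modes on real data.

## Study sizes and numerical choices

The packaged simulation studies use conditions mirroring the motivating
system: birth rates around 0.1–0.2, extinction 0.03, transition rates
0.01–0.05, trees of 300 tips for power/false-positive work, and an
empirical-scale configuration of 89 species sampled from a richness of
397 (global sampling fraction 89/397). Decision rules are
`PP > 0.975` (two-sided 5%) for the Bayesian contrast and a
2-point AIC margin for ML; both configurable. For the replicated
simulation studies the Bayesian chains default to 800 generations with
20% burn-in and a slightly looser integration tolerance (`1e-7`): across
replicates the Monte-Carlo error these leave is far below the
between-replicate variation being measured, while the single-dataset
default remains 10,000 generations at `1e-8`. The false-positive study
uses 40 replicates; parameter-recovery, 100. Degenerate inputs are
handled explicitly: zero-length branches are legal (their transition
matrix is the identity), impossible data return `-Inf` rather than
erroring, and a likelihood that is zero for one node fixation yields an
infinite flagged Bayes factor.

## Known limitations

* Only binary observed characters; no multistate or quantitative-state
  models, no cladogenetic (GeoSSE-style) transitions, no time-varying
  rates.
* The Mk model treats polymorphic terminals as ambiguous rather than
  modelling the polymorphic state.
* Net-diversification ratios are reported but, as noted, ill-behaved
  when the denominator straddles zero.
* Stepping-stone marginal likelihoods use short chains per rung by
  default; node Bayes factors near the threshold deserve longer runs.
* The trait-associated sequence-rate asymmetry test sometimes paired
  with these analyses is out of scope here.
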