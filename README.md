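# pollendiv

Tools for linking quantitative pollen-load data to macroevolutionary
diversification in bees.

Many flowers present pollen openly ("accessible" rewards: Asteraceae,
Malvaceae, Cucurbitaceae, ...), while structurally complex "bee-flowers"
(many Fabaceae, Lamiaceae, Boraginaceae) conceal it so that only
specialised bees can extract it ("restricted" rewards). `pollendiv`
implements the full inference chain for testing whether bee lineages
exploiting restricted pollen diversify at different rates:

- **Trait coding** — per-sample pollen percentages with load-size
  weights are filtered (types under 5% of a sample are treated as
  contamination), aggregated, and coded into binary characters under
  four partitions: `PA1`/`PA2`/`PA3` (accessible = 0 vs restricted = 1,
  with polymorphic species scored restricted / ambiguous / accessible
  respectively) and `PS` (specialist = 0 vs generalist = 1, using the
  inclusive 95% single-family rule).
- **Ancestral states** — a two-state Markov model with Bayesian rate
  integration (slice-sampling MCMC under exponential priors), exact
  marginal node probabilities, and per-node Bayes factors from
  stepping-stone marginal likelihoods with the node's state fossilised
  (`BF = 2 Δ ln mL`, significant when `BF > 5`).
- **State-dependent diversification** — a compiled BiSSE/HiSSE-style
  D/E likelihood engine over observed x hidden state spaces with
  per-state sampling fractions:

  ```
  dE_i/dt = mu_i − (lambda_i + mu_i) E_i + Σ_j Q_ij E_j + lambda_i E_i²
  dD_i/dt = −(lambda_i + mu_i) D_i + Σ_j Q_ij D_j + 2 lambda_i E_i D_i
  ```

  fitted two ways: a six-model maximum-likelihood ladder
  (`Mase`, `Mas`, `Mahse`, `M0`, `M0h2`, `M0h4`; all with three
  transition rates; 7, 6, 11, 5, 7, 11 free parameters) compared by AIC,
  and Bayesian MCMC reporting `PP(d_R > d_A)`, the posterior probability
  that the restricted state's net diversification `d = λ − μ` exceeds
  the accessible state's.
- **Simulation machinery** — Gillespie tree+character simulation,
  trait-only simulation on fixed trees, incomplete-sampling with
  state-specific sampling fractions derived from the assumed unsampled
  composition `f`, a synthetic pollen-table generator with known truth,
  and orchestrated power / false-positive / `f`-sensitivity studies.

## Worked example

Simulate a 120-species clade in which restricted-pollen lineages
speciate twice as fast, generate a matching synthetic pollen survey,
code it, and run both inference routes:

```r
library(pollendiv)
set.seed(1)
rep <- simulate_bisse_tree(lambda = c(0.1, 0.2), mu = c(0.03, 0.03),
                           q = c(0.02, 0.02), stop_n = 120, seed = 7)
truth <- ifelse(rep$tip_states == 0, "A", "R")
truth[sample(which(truth == "R"), 6)] <- "AR"   # some polymorphic species
pollen <- generate_synthetic_pollen_dataset(truth, seed = 8)
coding <- code_pollen_dataset(pollen$samples, pollen$catalog)
head(coding, 3)
#>   species n_samples accessibility specificity
#> 1     t10         9             A  specialist
#> 2    t105        11             A  specialist
#> 3    t107        12             R  specialist

pa1 <- build_character_matrix(
  setNames(coding$accessibility, coding$species), "PA1",
  tip_labels = rep$tree$tip.label)

fits <- lapply(c("Mase", "Mas", "M0"), function(m)
  fit_ml(rep$tree, pa1, m, seed = 9))
compare_aic(fits)
#>   model k    lnL   AIC     d_A    d_R delta_AIC supported_over_null
#> 1   Mas 6 -327.3 666.7 0.03443 0.2166     0.000                TRUE
#> 2  Mase 7 -327.3 668.6 0.03446 0.2058     1.913                TRUE
#> 3    M0 5 -332.6 675.1 0.19134 0.1913     8.460               FALSE

trace <- run_mcmc(rep$tree, pa1, model = "five_param_equal_mu",
                  n_iter = 2000, seed = 10)
summarize_diversification(trace)
#> PP(d1 > d0) = 0.9988
#> d1 - d0: median 0.1826, 95% CI [0.0828, 0.2589]
#> d1 / d0: median 3.1757, 95% CI [-70.3326, 74.4914]
```

Both routes recover the built-in effect: the state-dependent models beat
the null by more than 2 AIC points, the estimated net diversification of
the restricted state is far above the accessible state's, and the
posterior probability of `d_R > d_A` is ~0.999. (The wild credible
interval on the *ratio* is the expected pathology when the denominator
`d_A` has posterior mass near zero — use the difference.)

The methods vignette
(`vignettes/pollen-diversification-methods.Rmd`) documents the models,
their assumptions, every tunable threshold, and the design decisions.

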