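#' Bayesian MCMC over BiSSE parameters
#'
#' Slice-sampling MCMC targeting the product of independent exponential
#' priors and the 2-state SSE likelihood (no hidden states).  Two model
#' forms are supported: `five_param_equal_mu` (state-dependent speciation,
#' a single extinction rate, unequal transition rates: `lambda0, lambda1,
#' mu, q01, q10`) and `full_bisse` (state-dependent extinction as well:
#' `lambda0, lambda1, mu0, mu1, q01, q10`).
#'
#' Each rate's exponential prior mean defaults to twice the
#' character-independent net-diversification estimate for the tree, the
#' convention of the standard Bayesian SSE implementation.  Slice widths
#' are tuned per parameter during burn-in; the chain is deterministic given
#' `seed`.
#'
#' @param tree An ultrametric `phylo`.
#' @param chars A `character_matrix` or named tip-state vector.
#' @param model `"five_param_equal_mu"` (default) or `"full_bisse"`.
#' @param sampling Sampling fractions (scalar or per observed state).
#' @param priors Optional numeric vector of exponential prior *rates*
#'   (1/mean), one per parameter.
#' @param n_iter Total generations (default 10000).
#' @param burn_in_frac Fraction discarded as burn-in (default 0.2).
#' @param seed Optional integer seed.
#' @param prior_only Sample the prior alone (constant likelihood);
#'   a sanity diagnostic for the sampler.
#' @param condition_on_survival,root_weighting,rtol,atol Passed to
#'   [sse_loglik()].
#' @return A `posterior_trace`: list with `samples` (all iterations,
#'   parameters plus `lnL` and `lnpost`), `retained` (post-burn-in row
#'   indices), `model`, `n_iter`, `burn_in_frac`, `seed`, `prior_rates`.
#' @export
run_mcmc <- function(tree, chars, model = c("five_param_equal_mu",
                                            "full_bisse"),
                     sampling = 1, priors = NULL, n_iter = 10000,
                     burn_in_frac = 0.2, seed = NULL, prior_only = FALSE,
                     condition_on_survival = TRUE,
                     root_weighting = "observed_weighted",
                     rtol = 1e-8, atol = 1e-10) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  states <- as_tip_states(chars, tree)
  par_names <- if (model == "five_param_equal_mu") {
    c("lambda0", "lambda1", "mu", "q01", "q10")
  } else {
    c("lambda0", "lambda1", "mu0", "mu1", "q01", "q10")
  }
  d <- length(par_names)
  space <- sse_state_space(1)
  if (is.null(priors)) {
    ntip <- ape::Ntip(tree)
    r0 <- max(log(ntip / 2) / tree_root_age(tree), 0.01)
    priors <- rep(1 / (2 * r0), d)
  }
  stopifnot(length(priors) == d, all(priors > 0))
  lik <- make_sse_lik(tree, states, space, sampling,
                      condition_on_survival, root_weighting, rtol, atol)
  lnl <- function(p) {
    if (prior_only) return(0)
    np <- length(p)
    q01 <- p[np - 1L]
    q10 <- p[np]
    Q <- matrix(c(-q01, q10, q01, -q10), 2, 2)
    lam <- p[1:2]
    mu <- if (model == "five_param_equal_mu") c(p[3], p[3]) else p[3:4]
    tryCatch(lik(lam, mu, Q), error = function(e) -Inf)
  }
  logpost <- function(p) {
    lp <- sum(stats::dexp(p, priors, log = TRUE))
    ll <- lnl(p)
    if (!is.finite(ll)) return(-Inf)
    lp + ll
  }
  init <- NULL
  for (try in seq_len(20)) {
    cand <- stats::rexp(d, priors)
    if (is.finite(logpost(cand))) {
      init <- cand
      break
    }
  }
  if (is.null(init)) {
    stop("could not find a finite-likelihood initial point in 20 draws",
         call. = FALSE)
  }
  burn <- round(n_iter * burn_in_frac)
  run <- mcmc_slice(logpost, init, n_iter, widths = 1 / priors,
                    adapt_iter = burn)
  samples <- as.data.frame(run$samples)
  names(samples) <- par_names
  samples$lnpost <- run$logpost
  samples$lnL <- if (prior_only) 0 else
    samples$lnpost - rowSums(mapply(function(col, r)
      stats::dexp(samples[[col]], r, log = TRUE), par_names, priors))
  structure(list(samples = samples,
                 retained = seq.int(burn + 1L, n_iter),
                 model = model, n_iter = n_iter,
                 burn_in_frac = burn_in_frac, seed = seed,
                 prior_rates = stats::setNames(priors, par_names),
                 par_names = par_names),
            class = "posterior_trace")
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat("posterior trace:", x$model, "-", x$n_iter, "generations,",
      length(x$retained), "retained\n")
  print(signif(vapply(x$samples[x$retained, x$par_names], stats::median, 0),
               4))
  invisible(x)
}

#' Posterior summary of the net-diversification contrast
#'
#' From the retained samples of a [run_mcmc()] trace, computes per-state
#' net diversification `d = lambda - mu` and summarizes the contrast
#' between state 1 (restricted/generalist) and state 0
#' (accessible/specialist): the posterior probability `PP(d1 > d0)` (strict
#' inequality), and the full sample sets of the difference `d1 - d0` and
#' ratio `d1 / d0`.
#'
#' @param trace A `posterior_trace`.
#' @return A `diversification_summary`: list with `pp_greater`,
#'   `diff_samples`, `ratio_samples`, `d_samples` (two-column matrix), and
#'   posterior medians / 95% credible intervals of both contrasts.
#' @export
summarize_diversification <- function(trace) {
  stopifnot(inherits(trace, "posterior_trace"))
  s <- trace$samples[trace$retained, , drop = FALSE]
  if (nrow(s) == 0L) stop("input error: zero retained samples",
                          call. = FALSE)
  mu0 <- if (trace$model == "five_param_equal_mu") s$mu else s$mu0
  mu1 <- if (trace$model == "five_param_equal_mu") s$mu else s$mu1
  d0 <- s$lambda0 - mu0
  d1 <- s$lambda1 - mu1
  dif <- d1 - d0
  rat <- d1 / d0
  structure(list(pp_greater = mean(d1 > d0),
                 diff_samples = dif,
                 ratio_samples = rat,
                 d_samples = cbind(d0 = d0, d1 = d1),
                 diff_median = stats::median(dif),
                 diff_ci = stats::quantile(dif, c(0.025, 0.975),
                                           names = FALSE),
                 ratio_median = stats::median(rat),
                 ratio_ci = stats::quantile(rat, c(0.025, 0.975),
                                            names = FALSE)),
            class = "diversification_summary")
}

#' @export
print.diversification_summary <- function(x, ...) {
  cat(sprintf("PP(d1 > d0) = %.4f\n", x$pp_greater))
  cat(sprintf("d1 - d0: median %.4f, 95%% CI [%.4f, %.4f]\n",
              x$diff_median, x$diff_ci[1], x$diff_ci[2]))
  cat(sprintf("d1 / d0: median %.4f, 95%% CI [%.4f, %.4f]\n",
              x$ratio_median, x$ratio_ci[1], x$ratio_ci[2]))
  invisible(x)
}

#' Long-format contrast samples for violin plots
#'
#' @param summary A `diversification_summary`.
#' @param label Optional label column value (e.g. the partition).
#' @return Data frame with columns `label`, `quantity`
#'   (`"difference"`/`"ratio"`), `value`.
#' @export
contrast_long <- function(summary, label = "") {
  stopifnot(inherits(summary, "diversification_summary"))
  data.frame(label = label,
             quantity = rep(c("difference", "ratio"),
                            each = length(summary$diff_samples)),
             value = c(summary$diff_samples, summary$ratio_samples),
             stringsAsFactors = FALSE)
}
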