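#' Build one of the six named diversification model specifications
#'
#' The model ladder spans state-dependent and null models, all sharing the
#' three-transition-rate structure (`q01`, `q10` between observed states,
#' `qh` between hidden states):
#' \describe{
#'   \item{Mase}{speciation and extinction vary by observed state only
#'     (2 lambda + 2 mu + 3 q = 7 free parameters); the BiSSE-like model,
#'     carried on 2 hidden states with rates tied across them.}
#'   \item{Mas}{as Mase with a single extinction rate (6).}
#'   \item{Mahse}{speciation and extinction free over all observed x hidden
#'     combinations with 2 hidden states (11); the HiSSE-like model.}
#'   \item{M0}{single speciation and extinction rate (5); the
#'     character-independent null.}
#'   \item{M0h2}{rates vary by hidden state only, 2 hidden states (7);
#'     matches Mase in parameter richness.}
#'   \item{M0h4}{rates vary by hidden state only, 4 hidden states (11);
#'     matches Mahse in parameter richness.}
#' }
#'
#' In Mase, Mas and M0 the hidden channel is inert: because lambda and mu
#' are tied across hidden states and tips are uninformative about them, the
#' likelihood is independent of `qh` and equals the corresponding
#' observed-state-only model.  `fit_ml()` exploits this for speed; `qh`
#' still counts as a free parameter of the specification.
#'
#' @param name One of `"Mase"`, `"Mas"`, `"Mahse"`, `"M0"`, `"M0h2"`,
#'   `"M0h4"`.
#' @return An `sse_model_spec`: list with `name`, `n_hidden`,
#'   `free_parameters` (ordered labels), `k`, `inert_hidden`, and
#'   `expand(free)` mapping a free-parameter vector to [sse_parameters()].
#' @export
build_model_spec <- function(name) {
  specs <- list(
    Mase = list(n_hidden = 2L,
                free = c("lambdaA", "lambdaR", "muA", "muR",
                         "q01", "q10", "qh"),
                lam = function(p, sp) p[c("lambdaA", "lambdaR")][sp$obs_index + 1],
                mu = function(p, sp) p[c("muA", "muR")][sp$obs_index + 1],
                inert = TRUE),
    Mas = list(n_hidden = 2L,
               free = c("lambdaA", "lambdaR", "mu", "q01", "q10", "qh"),
               lam = function(p, sp) p[c("lambdaA", "lambdaR")][sp$obs_index + 1],
               mu = function(p, sp) rep(p["mu"], sp$n_states),
               inert = TRUE),
    Mahse = list(n_hidden = 2L,
                 free = c("lambdaA1", "lambdaR1", "lambdaA2", "lambdaR2",
                          "muA1", "muR1", "muA2", "muR2",
                          "q01", "q10", "qh"),
                 lam = function(p, sp) p[paste0("lambda",
                                               c("A", "R")[sp$obs_index + 1],
                                               sp$hidden_index)],
                 mu = function(p, sp) p[paste0("mu",
                                              c("A", "R")[sp$obs_index + 1],
                                              sp$hidden_index)],
                 inert = FALSE),
    M0 = list(n_hidden = 2L,
              free = c("lambda", "mu", "q01", "q10", "qh"),
              lam = function(p, sp) rep(p["lambda"], sp$n_states),
              mu = function(p, sp) rep(p["mu"], sp$n_states),
              inert = TRUE),
    M0h2 = list(n_hidden = 2L,
                free = c("lambda1", "lambda2", "mu1", "mu2",
                         "q01", "q10", "qh"),
                lam = function(p, sp) p[paste0("lambda", sp$hidden_index)],
                mu = function(p, sp) p[paste0("mu", sp$hidden_index)],
                inert = FALSE),
    M0h4 = list(n_hidden = 4L,
                free = c(paste0("lambda", 1:4), paste0("mu", 1:4),
                         "q01", "q10", "qh"),
                lam = function(p, sp) p[paste0("lambda", sp$hidden_index)],
                mu = function(p, sp) p[paste0("mu", sp$hidden_index)],
                inert = FALSE))
  if (!name %in% names(specs)) {
    stop("input error: unknown model name '", name, "'", call. = FALSE)
  }
  s <- specs[[name]]
  space <- sse_state_space(s$n_hidden)
  expand <- function(free) {
    stopifnot(length(free) == length(s$free))
    names(free) <- s$free
    sse_parameters(unname(s$lam(free, space)), unname(s$mu(free, space)),
                   list(q01 = unname(free["q01"]),
                        q10 = unname(free["q10"]),
                        qh = unname(free["qh"])),
                   space)
  }
  structure(list(name = name, n_hidden = s$n_hidden,
                 free_parameters = s$free, k = length(s$free),
                 inert_hidden = s$inert, space = space, expand = expand),
            class = "sse_model_spec")
}

#' @export
print.sse_model_spec <- function(x, ...) {
  cat("SSE model", x$name, "-", x$k, "free parameters,",
      x$n_hidden, "hidden states\n")
  cat("  ", paste(x$free_parameters, collapse = ", "), "\n")
  invisible(x)
}

# A 1-hidden-state reduction of an inert-hidden model's parameters:
# identical likelihood, cheaper ODE system.
reduce_params_inert <- function(spec, free) {
  names(free) <- spec$free_parameters
  space1 <- sse_state_space(1)
  full <- spec$expand(free)
  sse_parameters(full$lambda[1:2], full$mu[1:2],
                 list(q01 = unname(free["q01"]), q10 = unname(free["q10"]),
                      qh = 0),
                 space1)
}

# Character-independent starting point: a crown-based net-diversification
# estimate refined by a constant-rate birth-death fit, plus a parsimony
# transition-rate guess.
bd_start_rates <- function(tree, chars) {
  ntip <- ape::Ntip(tree)
  age <- tree_root_age(tree)
  r0 <- max(log(ntip / 2) / age, 0.01)
  lam <- r0
  mu <- r0 / 10
  fit <- tryCatch(ape::birthdeath(tree), error = function(e) NULL)
  if (!is.null(fit)) {
    r <- fit$para["b-d"]
    a <- min(max(fit$para["d/b"], 0), 0.95)
    if (is.finite(r) && r > 0) {
      lam <- as.numeric(r / (1 - a))
      mu <- as.numeric(lam * a)
    }
  }
  q <- parsimony_rate_guess(tree, chars)
  c(lambda = max(lam, 1e-4), mu = max(mu, 1e-5), q = max(q, 1e-4))
}

start_vector <- function(spec, base) {
  p <- numeric(spec$k)
  names(p) <- spec$free_parameters
  p[grepl("^lambda", names(p))] <- base["lambda"]
  p[grepl("^mu", names(p))] <- base["mu"]
  p[c("q01", "q10", "qh")] <- base["q"]
  p
}

#' Fit an SSE model by multi-start simplex maximum likelihood
#'
#' Runs Nelder-Mead on log-scale parameters from `n_starts` initial
#' vectors: the first is built from a character-independent birth-death fit
#' and a parsimony transition-rate guess; the rest perturb it with
#' lognormal noise.  Each start gets a short exploratory run; the best
#' start is then optimized to convergence, mirroring the
#' pick-the-best-of-five-starts strategy standard for these likelihood
#' surfaces.
#'
#' @param tree An ultrametric `phylo`.
#' @param chars A `character_matrix` or named tip-state vector.
#' @param spec An [build_model_spec()] specification (or model name).
#' @param sampling Sampling fractions (scalar or per observed state).
#' @param n_starts Number of starting points (default 5).
#' @param seed Optional seed for the start jitter.
#' @param condition_on_survival,root_weighting,rtol,atol Passed to
#'   [sse_loglik()].
#' @param reduce_inert Use the exact observed-state-only reduction for
#'   models whose hidden channel is inert (default `TRUE`).
#' @param stage1_maxit,stage2_maxit Simplex iteration budgets for the
#'   exploratory and final runs.
#' @return A `fit_result`: list with `model`, `mle` (natural scale), `lnL`,
#'   `AIC = 2k - 2 lnL`, `n_starts_converged`, `start_lnL`,
#'   `net_diversification` (per observed state, hidden states averaged
#'   equally), and `data_id`.
#' @export
fit_ml <- function(tree, chars, spec, sampling = 1, n_starts = 5,
                   seed = NULL, condition_on_survival = TRUE,
                   root_weighting = "observed_weighted",
                   rtol = 1e-8, atol = 1e-10, reduce_inert = TRUE,
                   stage1_maxit = 300, stage2_maxit = 5000) {
  if (is.character(spec)) spec <- build_model_spec(spec)
  stopifnot(inherits(spec, "sse_model_spec"))
  if (!is.null(seed)) set.seed(seed)
  states <- as_tip_states(chars, tree)
  use_reduced <- reduce_inert && spec$inert_hidden
  space_used <- if (use_reduced) sse_state_space(1) else spec$space
  lik <- make_sse_lik(tree, states, space_used, sampling,
                      condition_on_survival, root_weighting, rtol, atol)
  objective <- function(logp) {
    free <- exp(logp)
    par <- tryCatch(
      if (use_reduced) reduce_params_inert(spec, free)
      else spec$expand(free),
      error = function(e) NULL)
    if (is.null(par)) return(1e10)
    ll <- tryCatch(lik(par$lambda, par$mu, par$Q),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  base <- bd_start_rates(tree, states)
  p0 <- start_vector(spec, base)
  starts <- vector("list", n_starts)
  starts[[1]] <- log(p0)
  if (n_starts > 1) {
    for (i in 2:n_starts) {
      starts[[i]] <- log(p0) + stats::rnorm(spec$k, 0, 0.5)
    }
  }
  stage1 <- lapply(starts, function(s) {
    stats::optim(s, objective, method = "Nelder-Mead",
                 control = list(maxit = stage1_maxit, reltol = 1e-8))
  })
  vals <- vapply(stage1, function(f) f$value, 0)
  if (all(vals >= 1e10)) {
    stop("fit failure: no start produced a finite likelihood; starts:\n",
         paste(vapply(starts, function(s)
           paste(signif(exp(s), 3), collapse = " "), ""), collapse = "\n"),
         call. = FALSE)
  }
  best <- stage1[[which.min(vals)]]
  final <- stats::optim(best$par, objective, method = "Nelder-Mead",
                        control = list(maxit = stage2_maxit,
                                       reltol = 1e-10))
  mle <- stats::setNames(exp(final$par), spec$free_parameters)
  lnL <- -final$value
  params <- spec$expand(mle)
  d_obs <- vapply(0:1, function(s) {
    sel <- params$space$obs_index == s
    mean(params$lambda[sel] - params$mu[sel])
  }, 0)
  structure(list(model = spec,
                 mle = mle,
                 lnL = lnL,
                 AIC = 2 * spec$k - 2 * lnL,
                 n_starts_converged = sum(vals < 1e10),
                 start_lnL = -vals,
                 net_diversification = stats::setNames(d_obs, c("A", "R")),
                 data_id = data_fingerprint(tree, states)),
            class = "fit_result")
}

data_fingerprint <- function(tree, states) {
  paste(ape::Ntip(tree), signif(sum(tree$edge.length), 12),
        paste(states, collapse = ""), sep = "|")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, k = %d, AIC = %.4f\n",
              x$model$name, x$lnL, x$model$k, x$AIC))
  print(signif(x$mle, 4))
  cat("net diversification: d_A =",
      signif(x$net_diversification["A"], 4),
      ", d_R =", signif(x$net_diversification["R"], 4), "\n")
  invisible(x)
}

#' Rank SSE model fits by AIC
#'
#' Sorts fits by AIC (ties broken toward fewer parameters) and flags models
#' supported over the null: AIC at least 2 points below the best null model
#' (`M0`, `M0h2`, `M0h4`) in the set.
#'
#' @param fits A list of `fit_result` objects fitted to identical data.
#' @param delta_aic_support Support margin (default 2).
#' @return Data frame with `model`, `k`, `lnL`, `AIC`, `delta_AIC`,
#'   `d_A`, `d_R`, `supported_over_null`.
#' @export
compare_aic <- function(fits, delta_aic_support = 2) {
  stopifnot(length(fits) >= 2)
  ids <- vapply(fits, function(f) f$data_id, "")
  if (length(unique(ids)) != 1L) {
    stop("input error: fits are not on identical data", call. = FALSE)
  }
  tab <- data.frame(
    model = vapply(fits, function(f) f$model$name, ""),
    k = vapply(fits, function(f) f$model$k, 0L),
    lnL = vapply(fits, function(f) f$lnL, 0),
    AIC = vapply(fits, function(f) f$AIC, 0),
    d_A = vapply(fits, function(f) f$net_diversification["A"], 0),
    d_R = vapply(fits, function(f) f$net_diversification["R"], 0),
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC, tab$k), ]
  tab$delta_AIC <- tab$AIC - min(tab$AIC)
  nulls <- tab$model %in% c("M0", "M0h2", "M0h4")
  best_null <- if (any(nulls)) min(tab$AIC[nulls]) else NA_real_
  tab$supported_over_null <- if (is.na(best_null)) NA else
    tab$AIC <= best_null - delta_aic_support
  rownames(tab) <- NULL
  tab
}
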