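#' Two-state Markov (Mk) transition probabilities
#'
#' Closed form for the 2x2 transition probability matrix `P(t) = exp(Qt)`
#' of a binary continuous-time Markov chain with rates `q01` (0 to 1) and
#' `q10` (1 to 0).
#'
#' @param q01,q10 Non-negative transition rates (per Myr).
#' @param t Elapsed time (>= 0).
#' @return 2x2 matrix, rows = starting state (0, 1).
#' @export
mk_transition_matrix <- function(q01, q10, t) {
  stopifnot(q01 >= 0, q10 >= 0, t >= 0)
  r <- q01 + q10
  if (r == 0) return(diag(2))
  p1 <- q01 / r
  p0 <- q10 / r
  e <- exp(-r * t)
  matrix(c(p0 + p1 * e, p1 * (1 - e),
           p0 * (1 - e), p1 + p0 * e),
         2, 2, byrow = TRUE)
}

mk_tip_partial <- function(state) {
  switch(state,
         "0" = c(1, 0),
         "1" = c(0, 1),
         c(1, 1)) # ambiguous / missing / polymorphic
}

mk_root_prior <- function(root_prior, q01, q10) {
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == 2, all(root_prior >= 0))
    return(root_prior / sum(root_prior))
  }
  switch(match.arg(root_prior, c("uniform", "stationary")),
         uniform = c(0.5, 0.5),
         stationary = {
           if (q01 + q10 <= 0) {
             stop("stationary root prior undefined when q01 + q10 = 0",
                  call. = FALSE)
           }
           c(q10, q01) / (q01 + q10)
         })
}

# Post-order partials for the 2-state Mk model.  Returns the per-node
# conditional likelihoods ("down" partials) with per-node log scale factors,
# on the post-ordered tree.  fix_node (ape node id) clamps an internal node
# to fix_state (0/1).
mk_down_pass <- function(tree, states, q01, q10,
                         fix_node = NULL, fix_state = NULL) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(po)
  nn <- ntip + po$Nnode
  L <- matrix(1, nn, 2)
  logscale <- numeric(nn)
  for (i in seq_len(ntip)) L[i, ] <- mk_tip_partial(states[i])
  edge <- po$edge
  elen <- po$edge.length
  acc <- matrix(1, nn, 2) # running product of child contributions
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]
    ch <- edge[e, 2]
    if (ch > ntip) {
      L[ch, ] <- acc[ch, ]
      if (!is.null(fix_node) && ch == fix_node) {
        L[ch, 2 - fix_state] <- 0 # zero the non-fixed state
      }
      m <- max(L[ch, ])
      if (m == 0) return(list(loglik = -Inf))
      L[ch, ] <- L[ch, ] / m
      logscale[ch] <- logscale[ch] + log(m)
    }
    P <- mk_transition_matrix(q01, q10, elen[e])
    top <- as.numeric(P %*% L[ch, ])
    acc[par, ] <- acc[par, ] * top
    logscale[par] <- logscale[par] + logscale[ch]
  }
  root <- ntip + 1L
  L[root, ] <- acc[root, ]
  if (!is.null(fix_node) && root == fix_node) {
    L[root, 2 - fix_state] <- 0
  }
  m <- max(L[root, ])
  if (m == 0) return(list(loglik = -Inf))
  L[root, ] <- L[root, ] / m
  logscale[root] <- logscale[root] + log(m)
  list(po = po, L = L, logscale = logscale, ntip = ntip, root = root)
}

#' Mk model log-likelihood by Felsenstein pruning
#'
#' Likelihood of binary tip states on a tree under a two-rate Markov model.
#' Ambiguous, polymorphic and missing tips enter with partials `(1, 1)`.
#' An internal node can be clamped ("fossilized") to a state, which is how
#' the per-node Bayes factors are computed.
#'
#' @param tree A validated `phylo`.
#' @param chars A `character_matrix` or named tip-state vector.
#' @param q01,q10 Transition rates (>= 0, per Myr).
#' @param root_prior `"uniform"` (default), `"stationary"`, or a length-2
#'   probability vector.
#' @param fix_node Optional internal node id (ape numbering) to clamp.
#' @param fix_state State (0 or 1) to clamp `fix_node` to.
#' @return Log-likelihood; `-Inf` when the data are impossible.
#' @export
mk_loglik <- function(tree, chars, q01, q10, root_prior = "uniform",
                      fix_node = NULL, fix_state = NULL) {
  if (q01 < 0 || q10 < 0) stop("input error: rates must be >= 0",
                               call. = FALSE)
  states <- as_tip_states(chars, tree)
  down <- mk_down_pass(tree, states, q01, q10, fix_node, fix_state)
  if (!is.null(down$loglik)) return(down$loglik)
  prior <- mk_root_prior(root_prior, q01, q10)
  val <- sum(prior * down$L[down$root, ])
  if (val <= 0) return(-Inf)
  log(val) + down$logscale[down$root]
}

# Marginal ancestral state probabilities at fixed rates, by the standard
# down-pass / up-pass recursion.  Returns a (Nnode x 2) matrix of
# P(state | data) for internal nodes, rows named by ape node id.
asr_marginal_fixed <- function(tree, chars, q01, q10,
                               root_prior = "uniform") {
  states <- as_tip_states(chars, tree)
  down <- mk_down_pass(tree, states, q01, q10)
  if (!is.null(down$loglik)) {
    stop("data impossible under the supplied rates", call. = FALSE)
  }
  po <- down$po
  ntip <- down$ntip
  root <- down$root
  prior <- mk_root_prior(root_prior, q01, q10)
  nn <- ntip + po$Nnode
  edge <- po$edge
  elen <- po$edge.length
  # children of each internal node, and the edge index leading to each child
  kids <- vector("list", nn)
  kedge <- vector("list", nn)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]
    kids[[p]] <- c(kids[[p]], edge[e, 2])
    kedge[[p]] <- c(kedge[[p]], e)
  }
  up <- matrix(NA_real_, nn, 2) # outside-subtree partial, prior included
  up[root, ] <- prior
  # preorder: edges in reverse post-order give parent before child
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1]
    ch <- edge[e, 2]
    sibs <- setdiff(kids[[p]], ch)
    contrib <- up[p, ]
    for (b in sibs) {
      eb <- kedge[[p]][match(b, kids[[p]])]
      Pb <- mk_transition_matrix(q01, q10, elen[eb])
      contrib <- contrib * as.numeric(Pb %*% down$L[b, ])
    }
    Pn <- mk_transition_matrix(q01, q10, elen[e])
    up[ch, ] <- as.numeric(t(Pn) %*% contrib)
    s <- sum(up[ch, ])
    if (s > 0) up[ch, ] <- up[ch, ] / s # marginals only need ratios
  }
  nodes <- (ntip + 1L):nn
  marg <- up[nodes, , drop = FALSE] * down$L[nodes, , drop = FALSE]
  marg <- marg / rowSums(marg)
  rownames(marg) <- nodes
  colnames(marg) <- c("P0", "P1")
  marg
}

#' Parsimony-informed rate scale for a binary character
#'
#' Fitch parsimony change count divided by total tree length, floored at
#' 0.01, used to centre rate priors and optimizer starting points on the
#' scale the data suggest.
#'
#' @param tree A `phylo`.
#' @param chars A `character_matrix` or named tip-state vector.
#' @return A positive rate (changes per Myr).
#' @export
parsimony_rate_guess <- function(tree, chars) {
  st <- as_tip_states(chars, tree)
  code <- ifelse(st == "0", "0", ifelse(st == "1", "1", "?"))
  dat <- phangorn::phyDat(matrix(code, ncol = 1,
                                 dimnames = list(names(st), NULL)),
                          type = "USER", levels = c("0", "1"),
                          ambiguity = "?")
  changes <- phangorn::parsimony(tree, dat)
  max(changes / sum(tree$edge.length), 0.01)
}

#' Bayesian marginal ancestral-state reconstruction
#'
#' MCMC over the two transition rates under independent exponential priors;
#' for each retained draw the marginal state probabilities at every internal
#' node are computed by the down/up pruning recursion, and their posterior
#' means returned.  Reproducible given `seed`.
#'
#' @param tree A validated `phylo`.
#' @param chars A `character_matrix` or named tip-state vector.
#' @param n_iter Total MCMC iterations (default 2000).
#' @param burn_in_frac Fraction discarded as burn-in (default 0.2).
#' @param seed Optional integer seed.
#' @param rate_prior_mean Mean of the exponential prior on each rate;
#'   defaults to [parsimony_rate_guess()].
#' @param root_prior Root state prior (see [mk_loglik()]).
#' @return An `asr_result`: list with `node_posterior` (internal nodes x 2,
#'   posterior mean state probabilities), `rate_samples` (retained draws of
#'   `q01`, `q10`), and the run settings.
#' @export
asr_marginal_posteriors <- function(tree, chars, n_iter = 2000,
                                    burn_in_frac = 0.2, seed = NULL,
                                    rate_prior_mean = NULL,
                                    root_prior = "uniform") {
  if (!is.null(seed)) set.seed(seed)
  states <- as_tip_states(chars, tree)
  obs <- states[states %in% c("0", "1")]
  if (length(unique(obs)) < 2L) {
    warning("fewer than 2 distinct observed states; rates identified ",
            "only through the prior")
  }
  if (is.null(rate_prior_mean)) {
    rate_prior_mean <- parsimony_rate_guess(tree, chars)
  }
  prate <- 1 / rate_prior_mean
  logpost <- function(q) {
    sum(stats::dexp(q, prate, log = TRUE)) +
      mk_loglik(tree, states, q[1], q[2], root_prior)
  }
  init <- rep(rate_prior_mean, 2)
  burn <- round(n_iter * burn_in_frac)
  run <- mcmc_slice(logpost, init, n_iter,
                    widths = rep(rate_prior_mean, 2), adapt_iter = burn)
  keep <- seq.int(burn + 1L, n_iter)
  nodes <- (ape::Ntip(tree) + 1L):(ape::Ntip(tree) + tree$Nnode)
  post <- matrix(0, length(nodes), 2,
                 dimnames = list(nodes, c("P0", "P1")))
  for (i in keep) {
    post <- post + asr_marginal_fixed(tree, states, run$samples[i, 1],
                                      run$samples[i, 2], root_prior)
  }
  post <- post / length(keep)
  # slice sampling moves essentially every iteration; a chain that stays
  # put signals a degenerate target
  move_frac <- mean(diff(run$samples[, 1]) != 0)
  if (move_frac < 0.01) {
    warning("rate chain shows poor mixing (move fraction ",
            signif(move_frac, 3), ")")
  }
  structure(list(node_posterior = post,
                 rate_samples = run$samples[keep, , drop = FALSE],
                 n_iter = n_iter, burn_in_frac = burn_in_frac, seed = seed,
                 rate_prior_mean = rate_prior_mean,
                 root_prior = root_prior),
            class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat("Bayesian ancestral state reconstruction:",
      nrow(x$node_posterior), "internal nodes,",
      nrow(x$rate_samples), "retained draws\n")
  cat("rate posterior means: q01 =", signif(mean(x$rate_samples[, 1]), 4),
      ", q10 =", signif(mean(x$rate_samples[, 2]), 4), "\n")
  invisible(x)
}

# Stepping-stone estimate of the log marginal likelihood of the Mk model
# with an optional node clamped.  K power posteriors with inverse
# temperatures at quantiles of Beta(0.3, 1).
mk_stepping_stone <- function(tree, states, rate_prior_mean, root_prior,
                              fix_node = NULL, fix_state = NULL,
                              n_rungs = 10, n_iter = 200,
                              burn_frac = 0.25) {
  prate <- 1 / rate_prior_mean
  betas <- stats::qbeta(seq(0, 1, length.out = n_rungs + 1), 0.3, 1)
  lnl <- function(q) mk_loglik(tree, states, q[1], q[2], root_prior,
                               fix_node, fix_state)
  lprior <- function(q) sum(stats::dexp(q, prate, log = TRUE))
  x <- rep(rate_prior_mean, 2)
  total <- 0
  burn <- ceiling(n_iter * burn_frac)
  for (k in seq_len(n_rungs)) {
    bk <- betas[k]
    bk1 <- betas[k + 1]
    logpost <- function(q) {
      ll <- lnl(q)
      if (!is.finite(ll) && bk == 0) ll <- -1e10 # prior rung tolerates -Inf
      lprior(q) + bk * ll
    }
    # re-draw a starting point if the previous rung left us somewhere flat
    if (!is.finite(logpost(x))) x <- rep(rate_prior_mean, 2)
    run <- mcmc_slice(logpost, x, n_iter,
                      widths = rep(rate_prior_mean, 2), adapt_iter = burn)
    keep <- seq.int(burn + 1L, n_iter)
    lls <- apply(run$samples[keep, , drop = FALSE], 1, lnl)
    if (all(!is.finite(lls))) return(-Inf)
    total <- total + (logsumexp((bk1 - bk) * lls) - log(length(lls)))
    x <- run$samples[n_iter, ]
  }
  total
}

#' Per-node Bayes factor for the ancestral state
#'
#' Tests which state is supported at an internal node by running two
#' constrained reconstructions with the node's state fixed ("fossilized")
#' to 0 and to 1, estimating each log marginal likelihood by
#' stepping-stone sampling, and reporting
#' `BF = 2 * (ln mL_best - ln mL_other)`.  Following the convention used
#' for these node tests, a node is called significant when `BF > 5`
#' (strict inequality).
#'
#' @inheritParams asr_marginal_posteriors
#' @param node Internal node id (ape numbering: `Ntip + 1` is the root).
#' @param n_rungs Number of stepping-stone power posteriors (default 10).
#' @param n_iter Iterations per rung (default 200).
#' @param bf_threshold Significance threshold (default 5, strict).
#' @return A `node_bf`: list with `node`, `bayes_factor`, `preferred_state`,
#'   `significant`, `log_ml` (both fixations), `infinite` flag.
#' @export
node_bayes_factor <- function(tree, chars, node, n_rungs = 10, n_iter = 200,
                              seed = NULL, rate_prior_mean = NULL,
                              root_prior = "uniform", bf_threshold = 5) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  if (node <= ntip || node > ntip + tree$Nnode) {
    stop("node must be an internal node id", call. = FALSE)
  }
  states <- as_tip_states(chars, tree)
  if (is.null(rate_prior_mean)) {
    rate_prior_mean <- parsimony_rate_guess(tree, chars)
  }
  lml <- vapply(0:1, function(s) {
    mk_stepping_stone(tree, states, rate_prior_mean, root_prior,
                      fix_node = node, fix_state = s,
                      n_rungs = n_rungs, n_iter = n_iter)
  }, 0)
  best <- which.max(lml) - 1L
  bf <- 2 * (max(lml) - min(lml))
  structure(list(node = node,
                 bayes_factor = bf,
                 preferred_state = best,
                 significant = is.finite(bf) && bf > bf_threshold ||
                   is.infinite(bf),
                 log_ml = stats::setNames(lml, c("state0", "state1")),
                 infinite = is.infinite(bf)),
            class = "node_bf")
}

#' @export
print.node_bf <- function(x, ...) {
  cat(sprintf("node %d: BF = %.3f, preferred state %d, %ssignificant\n",
              x$node, x$bayes_factor, x$preferred_state,
              if (x$significant) "" else "not "))
  invisible(x)
}
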