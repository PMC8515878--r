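#' Combined observed-by-hidden state space
#'
#' The SSE engine works on the product of the two observed pollen states
#' (`A` = 0, accessible; `R` = 1, restricted) and `n_hidden` hidden states.
#' Combined states are ordered with the observed state varying fastest:
#' `(A,h1), (R,h1), (A,h2), (R,h2), ...`.  This ordering is relied on by all
#' parameter constructors and is part of the package contract.
#'
#' @param n_hidden Number of hidden states: 1, 2 or 4.
#' @return An `sse_state_space`: list with `observed_states`, `n_hidden`,
#'   `n_states`, `obs_index` (observed state, 0/1, of each combined state)
#'   and `hidden_index`.
#' @export
sse_state_space <- function(n_hidden = 1) {
  if (!n_hidden %in% c(1L, 2L, 4L)) {
    stop("n_hidden must be 1, 2 or 4", call. = FALSE)
  }
  n_hidden <- as.integer(n_hidden)
  n <- 2L * n_hidden
  structure(list(observed_states = c("A", "R"),
                 n_hidden = n_hidden,
                 n_states = n,
                 obs_index = rep(0:1, n_hidden),
                 hidden_index = rep(seq_len(n_hidden), each = 2L)),
            class = "sse_state_space")
}

#' SSE rate parameters over a combined state space
#'
#' Bundles per-combined-state speciation and extinction rates with a
#' transition-rate matrix.  Dual transitions (simultaneous observed and
#' hidden change) must have rate zero; this is enforced at construction.
#'
#' @param lambda Speciation rates (events/lineage/Myr), one per combined
#'   state.
#' @param mu Extinction rates, one per combined state.
#' @param Q Transition-rate matrix over combined states: off-diagonals
#'   >= 0, rows summing to zero.  When a named list
#'   `list(q01 = , q10 = , qh = )` is given instead, the standard
#'   three-rate matrix is built: `q01`/`q10` between observed states within
#'   a hidden state, `qh` between every pair of hidden states within an
#'   observed state, zero elsewhere.
#' @param space An [sse_state_space()]; inferred from `length(lambda)` if
#'   missing.
#' @return An `sse_parameters` object.
#' @export
sse_parameters <- function(lambda, mu, Q, space = NULL) {
  if (is.null(space)) space <- sse_state_space(length(lambda) / 2L)
  n <- space$n_states
  stopifnot(length(lambda) == n, length(mu) == n)
  if (any(!is.finite(lambda)) || any(lambda < 0) ||
      any(!is.finite(mu)) || any(mu < 0)) {
    stop("lambda and mu must be finite and >= 0", call. = FALSE)
  }
  if (is.list(Q)) {
    Q <- build_three_rate_q(Q$q01, Q$q10, if (is.null(Q$qh)) 0 else Q$qh,
                            space)
  }
  stopifnot(is.matrix(Q), nrow(Q) == n, ncol(Q) == n)
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0", call. = FALSE)
  if (any(abs(rowSums(Q)) > 1e-10)) {
    stop("Q rows must sum to zero", call. = FALSE)
  }
  dual <- (outer(space$obs_index, space$obs_index, "!=") &
             outer(space$hidden_index, space$hidden_index, "!="))
  if (any(off[dual] != 0)) {
    stop("dual transitions (observed and hidden change together) must be 0",
         call. = FALSE)
  }
  structure(list(lambda = unname(lambda), mu = unname(mu), Q = unname(Q),
                 space = space),
            class = "sse_parameters")
}

#' @export
print.sse_parameters <- function(x, ...) {
  cat("SSE parameters over", x$space$n_states, "combined states (",
      x$space$n_hidden, "hidden )\n")
  cat("  lambda:", paste(signif(x$lambda, 4), collapse = " "), "\n")
  cat("  mu:    ", paste(signif(x$mu, 4), collapse = " "), "\n")
  invisible(x)
}

# The three-transition-rate structure: two rates between observed states,
# one rate between hidden states, dual transitions zero.
build_three_rate_q <- function(q01, q10, qh, space) {
  n <- space$n_states
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      same_h <- space$hidden_index[i] == space$hidden_index[j]
      same_o <- space$obs_index[i] == space$obs_index[j]
      if (same_h && !same_o) {
        Q[i, j] <- if (space$obs_index[i] == 0) q01 else q10
      } else if (same_o && !same_h) {
        Q[i, j] <- qh
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Sampling fractions over the combined state space
#'
#' The probability that an extant species in each state is included in the
#' tree.  A single number gives the global fraction (the study design here
#' uses 89/397 for the empirical clade); a length-2 vector gives
#' state-specific fractions for observed states A and R, replicated across
#' hidden states.
#'
#' @param rho Scalar, length-2 (per observed state), or per-combined-state
#'   vector in (0, 1].
#' @param space An [sse_state_space()].
#' @return Numeric vector of per-combined-state sampling probabilities.
#' @export
sampling_fractions <- function(rho = 1, space = sse_state_space(1)) {
  n <- space$n_states
  if (length(rho) == 1L) rho <- rep(rho, n)
  else if (length(rho) == 2L) rho <- rho[space$obs_index + 1L]
  stopifnot(length(rho) == n)
  if (any(rho <= 0) || any(rho > 1)) {
    stop("input error: rho must be in (0, 1]", call. = FALSE)
  }
  rho
}

# Coerce tip character data to a named vector over the tree's tips with
# values "0", "1", "ambiguous", "missing".
as_tip_states <- function(chars, tree) {
  if (inherits(chars, "character_matrix")) chars <- chars$states
  if (is.numeric(chars)) chars <- as.character(chars)
  stopifnot(!is.null(names(chars)))
  miss <- setdiff(tree$tip.label, names(chars))
  if (length(miss)) {
    stop("tips without character data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  st <- chars[tree$tip.label]
  ok <- c("0", "1", "ambiguous", "missing")
  if (!all(st %in% ok)) {
    stop("tip states must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  st
}

#' Tip initial conditions for the SSE likelihood
#'
#' For a tip observed in state `s`, `D` is the sampling fraction on every
#' combined state whose observed part is `s` and zero elsewhere; ambiguous
#' and missing tips get `D = rho` on all combined states.  `E` starts at
#' `1 - rho` everywhere (the probability of an extant lineage being
#' unsampled).
#'
#' @param chars A `character_matrix` or named state vector.
#' @param tree The phylogeny whose tip order the matrices follow.
#' @param space An [sse_state_space()].
#' @param sampling Output of [sampling_fractions()] (or its `rho` input).
#' @return List with matrices `E` and `D` (tips x combined states).
#' @export
initialize_tips <- function(chars, tree, space = sse_state_space(1),
                            sampling = 1) {
  rho <- sampling_fractions(sampling, space)
  st <- as_tip_states(chars, tree)
  ntip <- length(st)
  n <- space$n_states
  D <- matrix(0, ntip, n)
  E <- matrix(rep(1 - rho, each = ntip), ntip, n)
  for (i in seq_len(ntip)) {
    if (st[i] %in% c("ambiguous", "missing")) {
      D[i, ] <- rho
    } else {
      s <- as.integer(st[i])
      sel <- space$obs_index == s
      D[i, sel] <- rho[sel]
    }
  }
  list(E = E, D = D)
}

#' Integrate the D/E system along one branch
#'
#' Propagates a per-state likelihood state rootward over a duration `t`
#' under constant rates, by adaptive Dormand-Prince integration of the
#' coupled extinction (`E`) and clade-likelihood (`D`) ODEs.
#'
#' @param state List with numeric vectors `E` and `D` (one entry per
#'   combined state) and optionally `logcomp`.
#' @param params An [sse_parameters()] object.
#' @param t Branch duration (Myr, >= 0).
#' @param rtol,atol Integration tolerances.
#' @return A list like `state`, with `logcomp` accumulating any log scale
#'   factored out of `D`.
#' @export
integrate_branch <- function(state, params, t, rtol = 1e-8, atol = 1e-10) {
  stopifnot(t >= 0, inherits(params, "sse_parameters"))
  lc0 <- if (is.null(state$logcomp)) 0 else state$logcomp
  if (t == 0) return(list(E = state$E, D = state$D, logcomp = lc0))
  out <- sse_branch_cpp(state$E, state$D, params$lambda, params$mu,
                        params$Q, t, rtol, atol)
  list(E = out$E, D = out$D, logcomp = lc0 + out$logcomp)
}

#' State-dependent speciation-extinction log-likelihood
#'
#' Joint likelihood of an ultrametric tree and binary tip states under a
#' BiSSE/HiSSE-style model: tip conditions from [initialize_tips()], branch
#' propagation by the compiled ODE integrator, `D` combined at each internal
#' node as `lambda_i * D_left,i * D_right,i`, and the root assembled with
#' either equal weights or weights proportional to the root `D` values.
#' With `condition_on_survival` each root term is divided by
#' `lambda_i * (1 - E_i)^2`, conditioning on the two crown lineages having
#' sampled descendants.
#'
#' @param tree A validated ultrametric `phylo`.
#' @param chars A `character_matrix` or named tip-state vector.
#' @param params An [sse_parameters()] object.
#' @param sampling Sampling fractions (scalar, per observed state, or per
#'   combined state).
#' @param condition_on_survival Logical (default `TRUE`).
#' @param root_weighting `"observed_weighted"` (weights proportional to the
#'   root `D`; default) or `"equal"`.
#' @param rtol,atol Integration tolerances.
#' @return Log-likelihood (scalar; `-Inf` for impossible data).
#' @examples
#' tr <- read_tree("(A:10,B:10);")
#' ch <- c(A = "0", B = "0")
#' p <- sse_parameters(lambda = c(0.1, 0.1), mu = c(0, 0),
#'                     Q = list(q01 = 0, q10 = 0))
#' sse_loglik(tr, ch, p)  # -2 under survival conditioning
#' @export
sse_loglik <- function(tree, chars, params, sampling = 1,
                       condition_on_survival = TRUE,
                       root_weighting = c("observed_weighted", "equal"),
                       rtol = 1e-8, atol = 1e-10) {
  root_weighting <- match.arg(root_weighting)
  stopifnot(inherits(params, "sse_parameters"))
  lik <- make_sse_lik(tree, chars, params$space, sampling,
                      condition_on_survival, root_weighting, rtol, atol)
  lik(params$lambda, params$mu, params$Q)
}

# Prepared likelihood closure: tree reordering and tip conditioning are
# computed once, so optimizers and samplers pay only for the ODE pass.
make_sse_lik <- function(tree, chars, space, sampling = 1,
                         condition_on_survival = TRUE,
                         root_weighting = "observed_weighted",
                         rtol = 1e-8, atol = 1e-10) {
  tip <- initialize_tips(chars, tree, space, sampling)
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(po)
  equal_w <- root_weighting == "equal"
  function(lambda, mu, Q) {
    res <- sse_tree_cpp(po$edge, po$edge.length, ntip, tip$E, tip$D,
                        lambda, mu, Q, rtol, atol)
    if (!is.finite(res$logcomp)) return(-Inf)
    D <- res$D
    E <- res$E
    w <- if (equal_w || sum(D) <= 0) rep(1 / length(D), length(D))
         else D / sum(D)
    terms <- D
    if (condition_on_survival) {
      denom <- lambda * (1 - E)^2
      terms <- ifelse(D > 0 & denom > 0, D / denom, 0)
    }
    val <- sum(w * terms)
    if (val <= 0) return(-Inf)
    ll <- log(val) + res$logcomp
    if (is.nan(ll)) -Inf else ll
  }
}

#' Serialize SSE parameters to and from YAML
#'
#' @param params An [sse_parameters()] object.
#' @param file Path to write; `NULL` returns the YAML string.
#' @return `params_to_yaml`: the path (or string) invisibly;
#'   `params_from_yaml`: an `sse_parameters` object.
#' @export
params_to_yaml <- function(params, file = NULL) {
  stopifnot(inherits(params, "sse_parameters"))
  obj <- list(n_hidden = params$space$n_hidden,
              lambda = as.numeric(params$lambda),
              mu = as.numeric(params$mu),
              Q = apply(params$Q, 1, as.numeric, simplify = FALSE))
  txt <- yaml::as.yaml(obj)
  if (is.null(file)) return(invisible(txt))
  writeLines(txt, file)
  invisible(file)
}

#' @rdname params_to_yaml
#' @param x YAML string or path to a YAML file.
#' @export
params_from_yaml <- function(x) {
  obj <- if (file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(x)
  space <- sse_state_space(obj$n_hidden)
  Q <- do.call(rbind, lapply(obj$Q, as.numeric))
  sse_parameters(as.numeric(obj$lambda), as.numeric(obj$mu), Q, space)
}
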