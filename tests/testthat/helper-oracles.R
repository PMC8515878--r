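# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately brute-force / closed-form, written
# without reference to the package's own pruning or ODE code paths.

# All rooted binary shapes (with labelled tips) on 2-4 tips, as Newick.
small_tree_set <- function() {
  c(two = "(A:1.2,B:1.2);",
    three = "((A:1,B:1):0.8,C:1.8);",
    four_balanced = "((A:1,B:1):1,(C:0.6,D:0.6):1.4);",
    four_pectinate = "(((A:0.5,B:0.5):0.7,C:1.2):0.8,D:2);")
}

# Brute-force Mk likelihood: enumerate all internal-node state
# assignments, multiplying matrix-exponential transition probabilities.
brute_mk_loglik <- function(tree, states, q01, q10,
                            prior = c(0.5, 0.5)) {
  Q <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE)
  P <- function(t) ape::matexpo(Q * t)
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  tip_sets <- lapply(states[tree$tip.label], function(s) {
    if (s == "0") 0L else if (s == "1") 1L else 0:1
  })
  internal <- (ntip + 1L):nn
  grid <- expand.grid(rep(list(0:1), length(internal)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign_internal <- as.integer(grid[g, ])
    names(assign_internal) <- internal
    tipgrid <- expand.grid(tip_sets)
    for (tg in seq_len(nrow(tipgrid))) {
      node_state <- integer(nn)
      node_state[internal] <- assign_internal
      node_state[seq_len(ntip)] <- as.integer(tipgrid[tg, ])
      pr <- prior[node_state[ntip + 1L] + 1L]
      for (e in seq_len(nrow(tree$edge))) {
        a <- node_state[tree$edge[e, 1]]
        b <- node_state[tree$edge[e, 2]]
        pr <- pr * P(tree$edge.length[e])[a + 1L, b + 1L]
      }
      total <- total + pr
    }
  }
  log(total)
}

# Constant-rate birth-death log-likelihood via deSolve (1-state D/E
# system), conditioned on survival of both crown lineages; complete
# sampling.  Independent of the compiled integrator.
desolve_bd_loglik <- function(tree, lambda, mu) {
  po <- ape::reorder.phylo(tree, "postorder")
  rhs <- function(t, y, parms) {
    list(c(mu - (lambda + mu) * y[1] + lambda * y[1]^2,
           -(lambda + mu) * y[2] + 2 * lambda * y[1] * y[2]))
  }
  nn <- ape::Ntip(po) + po$Nnode
  E <- rep(NA_real_, nn)
  Dacc <- rep(1, nn)
  for (e in seq_len(nrow(po$edge))) {
    ch <- po$edge[e, 2]
    par <- po$edge[e, 1]
    y0 <- if (ch <= ape::Ntip(po)) c(0, 1) else c(E[ch], lambda * Dacc[ch])
    yT <- deSolve::ode(y0, c(0, po$edge.length[e]), rhs, NULL,
                       rtol = 1e-10, atol = 1e-12)[2, 2:3]
    Dacc[par] <- Dacc[par] * yT[2]
    E[par] <- yT[1]
  }
  root <- ape::Ntip(po) + 1L
  log(lambda * Dacc[root] / (lambda * (1 - E[root])^2))
}

# Random ultrametric tree scaled to a given crown age.
random_ultra_tree <- function(n, age = 10) {
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length * age / max(ape::node.depth.edgelength(tr))
  tr
}

random_states <- function(tree) {
  stats::setNames(sample(c("0", "1"), ape::Ntip(tree), replace = TRUE),
                  tree$tip.label)
}

make_sample <- function(species, id, comp, w = 1) {
  pollen_sample(species, id, comp, load_weight = w)
}

tiny_catalog <- function() {
  pollen_catalog(data.frame(
    pollen_type = c("AstA", "MalA", "FabR", "LamR", "UnknownType"),
    plant_family = c("Asteraceae", "Malvaceae", "Fabaceae", "Lamiaceae",
                     ""),
    plant_genus = c("Centaurea", "Malva", "Vicia", "Salvia", ""),
    accessibility = c("accessible", "accessible", "restricted",
                      "restricted", "unknown"),
    stringsAsFactors = FALSE))
}
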