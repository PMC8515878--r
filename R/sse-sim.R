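#' Simulate a tree and binary character under state-dependent birth-death
#'
#' Gillespie (exact event-driven) forward simulation starting from a crown
#' pair of lineages sharing the root state.  Each lineage in state `s`
#' speciates at rate `lambda[s+1]`, goes extinct at rate `mu[s+1]`, and
#' flips state at rate `q01`/`q10`.  Extinct lineages are pruned from the
#' returned tree, which is ultrametric by construction.  Simulations whose
#' crown dies out (or that fall short of `min_surviving_tips` under a time
#' stop) are rejected and re-run on a fresh seed stream, up to
#' `max_attempts`.
#'
#' @param lambda Length-2 speciation rates (states 0, 1).
#' @param mu Length-2 extinction rates.
#' @param q Length-2 transition rates `c(q01, q10)`.
#' @param stop_n Stop when this many lineages are extant (exclusive with
#'   `stop_time`).
#' @param stop_time Stop at this crown age.
#' @param root_state Starting state (0/1); drawn from the stationary
#'   distribution of the transition process when `NULL`.
#' @param min_surviving_tips Minimum surviving tips for a time-stopped
#'   simulation to be accepted (default 2).
#' @param seed Optional integer seed.
#' @param max_attempts Rejection budget before aborting (default 1000).
#' @return A `sim_replicate`: list with `tree` (pruned, extant-only
#'   `phylo`), `tip_states` (named 0/1 vector), `true_params`,
#'   `root_state`, `n_attempts`, `seed`.
#' @export
simulate_bisse_tree <- function(lambda, mu, q, stop_n = NULL,
                                stop_time = NULL, root_state = NULL,
                                min_surviving_tips = 2, seed = NULL,
                                max_attempts = 1000) {
  stopifnot(length(lambda) == 2, length(mu) == 2, length(q) == 2,
            all(lambda >= 0), all(mu >= 0), all(q >= 0))
  if (is.null(stop_n) == is.null(stop_time)) {
    stop("give exactly one of stop_n or stop_time", call. = FALSE)
  }
  if (!is.null(stop_n) && stop_n < 2) stop("stop_n must be >= 2",
                                           call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    rs <- root_state
    if (is.null(rs)) {
      rs <- if (sum(q) > 0) stats::rbinom(1, 1, q[1] / sum(q)) else 0L
    }
    sim <- gillespie_bisse_once(lambda, mu, q, stop_n, stop_time, rs)
    if (is.null(sim)) next
    n_surv <- length(sim$tip_states)
    ok <- if (!is.null(stop_n)) n_surv == stop_n else TRUE
    if (ok && n_surv >= min_surviving_tips) {
      return(structure(list(tree = sim$tree,
                            tip_states = sim$tip_states,
                            true_params = list(lambda = lambda, mu = mu,
                                               q = q),
                            root_state = rs,
                            n_attempts = attempt, seed = seed),
                       class = "sim_replicate"))
    }
  }
  stop("simulation aborted: no surviving replicate in ", max_attempts,
       " attempts (survival probability too low for this regime)",
       call. = FALSE)
}

# One unconditioned forward pass; NULL if the crown dies out.
gillespie_bisse_once <- function(lambda, mu, q, stop_n, stop_time, rs) {
  cap <- 16L
  parent <- integer(cap)
  t_start <- numeric(cap)
  t_end <- numeric(cap)
  state <- integer(cap)
  extinct <- logical(cap)
  n_lin <- 2L
  parent[1:2] <- 0L
  t_start[1:2] <- 0
  state[1:2] <- rs
  active <- c(1L, 2L)
  t <- 0
  repeat {
    st <- state[active]
    per <- lambda[st + 1] + mu[st + 1] + ifelse(st == 0, q[1], q[2])
    total <- sum(per)
    if (total <= 0) {
      t_next <- Inf
    } else {
      t_next <- t + stats::rexp(1, total)
    }
    if (!is.null(stop_time) && t_next > stop_time) {
      t <- stop_time
      break
    }
    if (is.infinite(t_next)) break
    t <- t_next
    i <- active[sample.int(length(active), 1, prob = per)]
    s <- state[i]
    ev <- sample.int(3, 1, prob = c(lambda[s + 1], mu[s + 1],
                                    if (s == 0) q[1] else q[2]))
    if (ev == 1L) { # speciation
      if (n_lin + 2L > cap) {
        cap <- cap * 2L
        length(parent) <- cap
        length(t_start) <- cap
        length(t_end) <- cap
        length(state) <- cap
        extinct <- c(extinct, logical(cap - length(extinct)))
      }
      kids <- n_lin + 1:2
      parent[kids] <- i
      t_start[kids] <- t
      state[kids] <- s
      extinct[kids] <- FALSE
      t_end[i] <- t
      n_lin <- n_lin + 2L
      active <- c(setdiff(active, i), kids)
      if (!is.null(stop_n) && length(active) == stop_n) break
    } else if (ev == 2L) { # extinction
      t_end[i] <- t
      extinct[i] <- TRUE
      active <- setdiff(active, i)
      if (length(active) == 0L) return(NULL)
    } else { # state flip
      state[i] <- 1L - s
    }
  }
  if (length(active) < 1L) return(NULL)
  t_end[active] <- t
  is_tip <- rep(TRUE, n_lin)
  is_tip[parent[seq_len(n_lin)][parent[seq_len(n_lin)] > 0]] <- FALSE
  # assemble newick bottom-up: children always have larger ids
  labels <- character(n_lin)
  child_of <- vector("list", n_lin)
  for (i in seq_len(n_lin)) {
    if (parent[i] > 0L) {
      child_of[[parent[i]]] <- c(child_of[[parent[i]]], i)
    }
  }
  nwk <- character(n_lin)
  tipno <- 0L
  tip_ids <- integer(0)
  for (i in n_lin:1) {
    len <- t_end[i] - t_start[i]
    if (is.null(child_of[[i]])) {
      tipno <- tipno + 1L
      labels[i] <- paste0("t", i)
      tip_ids <- c(tip_ids, i)
      nwk[i] <- sprintf("%s:%.12g", labels[i], len)
    } else {
      nwk[i] <- sprintf("(%s,%s):%.12g", nwk[child_of[[i]][1]],
                        nwk[child_of[[i]][2]], len)
    }
  }
  txt <- sprintf("(%s,%s);", nwk[1], nwk[2])
  tree <- ape::read.tree(text = txt)
  ext_labels <- labels[tip_ids][extinct[tip_ids]]
  if (length(ext_labels)) {
    if (length(ext_labels) >= ape::Ntip(tree) - 1L) return(NULL)
    tree <- ape::drop.tip(tree, ext_labels)
    if (is.null(tree) || ape::Ntip(tree) < 2L) return(NULL)
  }
  surv <- tip_ids[!extinct[tip_ids]]
  ts <- stats::setNames(state[surv], labels[surv])
  list(tree = tree, tip_states = ts[tree$tip.label])
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat("simulated replicate:", ape::Ntip(x$tree), "extant tips, root state",
      x$root_state, sprintf("(%d attempt%s)\n", x$n_attempts,
                            if (x$n_attempts > 1) "s" else ""))
  print(table(x$tip_states))
  invisible(x)
}

#' Simulate a binary character on a fixed tree
#'
#' Forward simulation of a two-state Markov chain along the branches of an
#' existing tree; used for trait-only null scenarios where the phylogeny is
#' held fixed.
#'
#' @param tree A validated `phylo`.
#' @param q01,q10 Transition rates.
#' @param root_state 0/1, or `NULL` to draw from the stationary
#'   distribution.
#' @param seed Optional integer seed.
#' @return Named integer vector of tip states.
#' @export
simulate_mk_traits <- function(tree, q01, q10, root_state = NULL,
                               seed = NULL) {
  validate_tree(tree)
  stopifnot(q01 >= 0, q10 >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(root_state)) {
    root_state <- if (q01 + q10 > 0) {
      stats::rbinom(1, 1, q01 / (q01 + q10))
    } else 0L
  }
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  node_state <- integer(nn)
  node_state[ntip + 1L] <- root_state
  po <- ape::reorder.phylo(tree, "postorder")
  rates <- c(q01, q10)
  for (e in rev(seq_len(nrow(po$edge)))) { # preorder
    s <- node_state[po$edge[e, 1]]
    rem <- po$edge.length[e]
    repeat {
      r <- rates[s + 1]
      if (r <= 0) break
      w <- stats::rexp(1, r)
      if (w > rem) break
      rem <- rem - w
      s <- 1L - s
    }
    node_state[po$edge[e, 2]] <- s
  }
  stats::setNames(node_state[seq_len(ntip)], tree$tip.label)
}

#' Subsample a simulated clade and derive state-specific sampling fractions
#'
#' Mimics incomplete taxon sampling: the replicate is pruned uniformly at
#' random down to `n_keep` tips, and the per-state sampling fractions are
#' derived from an assumption about the unsampled species.  With
#' `N_unsampled = total_richness - n_keep` and `f` the fraction of the
#' unsampled species in state 0 (accessible),
#' `rho_0 = n0_kept / (n0_kept + f * N_unsampled)` and
#' `rho_1 = n1_kept / (n1_kept + (1 - f) * N_unsampled)`.
#'
#' @param rep A `sim_replicate` (or list with `tree`, `tip_states`).
#' @param total_richness True number of extant species in the clade.
#' @param f Assumed fraction of state 0 among the unsampled species.
#' @param n_keep Tips to retain (default: all, i.e. no pruning).
#' @param seed Optional integer seed for the subsample.
#' @return List with `tree`, `tip_states` (pruned), `rho` (length 2,
#'   states 0/1), `n_kept` (per state), `f`, `total_richness`.
#' @export
apply_incomplete_sampling <- function(rep, total_richness, f,
                                      n_keep = NULL, seed = NULL) {
  stopifnot(f >= 0, f <= 1)
  tree <- rep$tree
  states <- rep$tip_states
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_keep)) n_keep <- ape::Ntip(tree)
  if (n_keep > ape::Ntip(tree)) {
    stop("infeasible sampling: n_keep exceeds simulated tips",
         call. = FALSE)
  }
  if (n_keep < ape::Ntip(tree)) {
    keep <- sample(tree$tip.label, n_keep)
    tree <- ape::keep.tip(tree, keep)
    states <- states[tree$tip.label]
  }
  if (total_richness < n_keep) {
    stop("infeasible sampling: total_richness below kept tip count",
         call. = FALSE)
  }
  n_uns <- total_richness - n_keep
  n0 <- sum(states == 0)
  n1 <- sum(states == 1)
  if ((n0 == 0 && f > 0) || (n1 == 0 && f < 1)) {
    stop("infeasible sampling: a state absent from the kept tips would ",
         "need unsampled members", call. = FALSE)
  }
  rho0 <- if (n0 + f * n_uns > 0) n0 / (n0 + f * n_uns) else 1
  rho1 <- if (n1 + (1 - f) * n_uns > 0) n1 / (n1 + (1 - f) * n_uns) else 1
  list(tree = tree, tip_states = states,
       rho = c(rho0, rho1), n_kept = c(`0` = n0, `1` = n1),
       f = f, total_richness = total_richness)
}

#' Built-in synthetic pollen-type catalog
#'
#' A small catalog of pollen types from families with accessible rewards
#' (Asteraceae, Malvaceae, Cucurbitaceae, Convolvulaceae, Dipsacaceae) and
#' restricted, bee-flower rewards (Fabaceae, Lamiaceae, Boraginaceae,
#' Ericaceae), two types per family, used by the synthetic pollen
#' generator.
#'
#' @return A `pollen_catalog`.
#' @export
default_pollen_catalog <- function() {
  fams <- data.frame(
    plant_family = c("Asteraceae", "Malvaceae", "Cucurbitaceae",
                     "Convolvulaceae", "Dipsacaceae",
                     "Fabaceae", "Lamiaceae", "Boraginaceae", "Ericaceae"),
    accessibility = c(rep("accessible", 5), rep("restricted", 4)),
    stringsAsFactors = FALSE)
  genera <- c(Asteraceae = "Centaurea", Malvaceae = "Malva",
              Cucurbitaceae = "Cucurbita", Convolvulaceae = "Ipomoea",
              Dipsacaceae = "Scabiosa", Fabaceae = "Vicia",
              Lamiaceae = "Salvia", Boraginaceae = "Echium",
              Ericaceae = "Erica")
  out <- do.call(rbind, lapply(seq_len(nrow(fams)), function(i) {
    data.frame(pollen_type = paste0(fams$plant_family[i], "_t", 1:2),
               plant_family = fams$plant_family[i],
               plant_genus = paste0(genera[fams$plant_family[i]], 1:2),
               accessibility = fams$accessibility[i],
               stringsAsFactors = FALSE)
  }))
  pollen_catalog(out)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), alpha)
  g / sum(g)
}

#' Generate a synthetic pollen dataset with known true states
#'
#' Emulates the structure of a quantitative pollen-load survey: per species
#' a number of replicate samples drawn uniformly from `n_samples_range`,
#' each with Dirichlet-distributed proportions over pollen types consistent
#' with the species' true accessibility state (pure accessible, pure
#' restricted, or mixed for `AR` with both category shares at least 0.25
#' before contamination), plus occasional contaminant types whose total
#' share never reaches the 5% exclusion threshold
#' (`contamination_max = 0.049` by default), and integer load-size
#' weights.  By construction, the coding pipeline recovers the true state
#' of every species.
#'
#' @param true_states Named character vector: species to `"A"`, `"R"` or
#'   `"AR"`.
#' @param n_samples_range Inclusive range of replicate counts per species
#'   (default `c(1, 22)`).
#' @param contamination_max Upper bound on a sample's total contaminant
#'   share (default 0.049, strictly below the 5% filter).
#' @param seed Optional integer seed.
#' @param catalog A `pollen_catalog` with at least two accessible and two
#'   restricted families (default [default_pollen_catalog()]).
#' @return List with `samples` (list of [pollen_sample()]) and `catalog`.
#' @export
generate_synthetic_pollen_dataset <- function(true_states,
                                              n_samples_range = c(1, 22),
                                              contamination_max = 0.049,
                                              seed = NULL,
                                              catalog = default_pollen_catalog()) {
  stopifnot(!is.null(names(true_states)),
            all(true_states %in% c("A", "R", "AR")))
  if (!is.null(seed)) set.seed(seed)
  acc_types <- catalog$pollen_type[catalog$accessibility == "accessible"]
  res_types <- catalog$pollen_type[catalog$accessibility == "restricted"]
  if (length(unique(catalog$plant_family[catalog$accessibility ==
                                         "accessible"])) < 2 ||
      length(unique(catalog$plant_family[catalog$accessibility ==
                                         "restricted"])) < 2) {
    stop("catalog needs >= 2 accessible and >= 2 restricted families",
         call. = FALSE)
  }
  samples <- list()
  for (sp in names(true_states)) {
    truth <- true_states[[sp]]
    n_s <- sample(seq(n_samples_range[1], n_samples_range[2]), 1)
    # a species keeps a preferred host set across its samples
    main_acc <- sample(acc_types, sample(1:2, 1))
    main_res <- sample(res_types, sample(1:2, 1))
    for (j in seq_len(n_s)) {
      comp <- switch(truth,
        A = stats::setNames(rdirichlet1(rep(8, length(main_acc))),
                            main_acc),
        R = stats::setNames(rdirichlet1(rep(8, length(main_res))),
                            main_res),
        AR = {
          u <- stats::runif(1, 0.3, 0.7)
          c(stats::setNames(u * rdirichlet1(rep(8, length(main_acc))),
                            main_acc),
            stats::setNames((1 - u) * rdirichlet1(rep(8, length(main_res))),
                            main_res))
        })
      if (stats::runif(1) < 0.7) {
        pool <- setdiff(catalog$pollen_type, names(comp))
        contam <- sample(pool, sample(1:2, 1))
        c_tot <- stats::runif(1, 0.005, contamination_max)
        shares <- c_tot * rdirichlet1(rep(1, length(contam)))
        comp <- c(comp * (1 - c_tot), stats::setNames(shares, contam))
      }
      samples[[length(samples) + 1L]] <-
        pollen_sample(sp, sprintf("%s_s%02d", sp, j), 100 * comp,
                      load_weight = sample(1:3, 1))
    }
  }
  list(samples = samples, catalog = catalog)
}

#' Write pollen samples to a long-format CSV
#'
#' @param samples List of [pollen_sample()] objects.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pollen_table <- function(samples, file) {
  rows <- do.call(rbind, lapply(samples, function(s) {
    data.frame(species = s$species, sample_id = s$sample_id,
               load_weight = s$load_weight,
               pollen_type = names(s$composition),
               percent = unname(s$composition),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}
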