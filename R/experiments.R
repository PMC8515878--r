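#' Simulation study of power, false-positive rate and estimator accuracy
#'
#' For each condition, simulates trees and binary characters under known
#' rates, runs the configured inference (Bayesian MCMC contrast and/or the
#' ML model ladder), and tabulates the fraction of replicates calling a
#' diversification-rate difference together with bias and RMSE of the rate
#' estimates.  A condition with equal speciation rates measures the
#' false-positive rate; conditions with unequal rates measure power.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{conditions}{list of condition lists: `name`, `lambda` (length
#'       2), `mu` (length 2), `q` (length 2), `n_tips`, `n_reps`.}
#'     \item{method}{`"mcmc"`, `"ml"`, or `c("mcmc", "ml")`.}
#'     \item{mcmc}{list: `n_iter`, `burn_in_frac`, `model` (default
#'       `five_param_equal_mu`).}
#'     \item{ml}{list: `models` (default `c("Mase", "M0")`), `n_starts`.}
#'     \item{pp_threshold}{MCMC decision threshold (default 0.975).}
#'     \item{delta_aic}{ML support margin (default 2).}
#'     \item{rho}{sampling fraction applied to all replicates (default 1).}
#'     \item{seed}{integer master seed.}
#'   }
#' @return A `study_report`: list with `summary` (per condition x method),
#'   `replicates` (per-replicate decisions and estimates, each traceable to
#'   its seed), and `failures`.
#' @export
run_power_study <- function(config) {
  stopifnot(is.list(config), length(config$conditions) >= 1)
  method <- config$method %||% "mcmc"
  mcmc_cfg <- config$mcmc %||% list()
  ml_cfg <- config$ml %||% list()
  pp_thr <- config$pp_threshold %||% 0.975
  daic <- config$delta_aic %||% 2
  rho <- config$rho %||% 1
  seed <- config$seed %||% 1
  set.seed(seed)
  rep_rows <- list()
  failures <- list()
  for (cond in config$conditions) {
    stopifnot(cond$n_reps >= 1)
    rep_seeds <- sample.int(.Machine$integer.max - 1, cond$n_reps)
    for (r in seq_len(cond$n_reps)) {
      row <- tryCatch(
        power_study_one(cond, method, mcmc_cfg, ml_cfg, pp_thr, daic, rho,
                        rep_seeds[r]),
        error = function(e) e)
      if (inherits(row, "error")) {
        failures[[length(failures) + 1L]] <-
          list(condition = cond$name, rep = r, seed = rep_seeds[r],
               message = conditionMessage(row))
      } else {
        row$condition <- cond$name
        row$rep <- r
        rep_rows[[length(rep_rows) + 1L]] <- row
      }
    }
  }
  reps <- do.call(rbind, rep_rows)
  summary <- NULL
  if (!is.null(reps)) {
    for (cname in unique(reps$condition)) {
      sub <- reps[reps$condition == cname, , drop = FALSE]
      cond <- Filter(function(cc) cc$name == cname, config$conditions)[[1]]
      true_d <- cond$lambda - cond$mu
      srow <- data.frame(condition = cname, n_reps = nrow(sub))
      if ("pp_greater" %in% names(sub)) {
        srow$mcmc_positive_rate <- mean(sub$pp_greater > pp_thr)
      }
      if ("delta_aic_vs_null" %in% names(sub)) {
        srow$ml_positive_rate <- mean(sub$delta_aic_vs_null >= daic)
      }
      for (nm in c("d0_hat", "d1_hat")) {
        if (nm %in% names(sub)) {
          truth <- true_d[if (nm == "d0_hat") 1 else 2]
          srow[[paste0(nm, "_bias")]] <- mean(sub[[nm]] - truth)
          srow[[paste0(nm, "_rmse")]] <- sqrt(mean((sub[[nm]] - truth)^2))
        }
      }
      if (all(c("d0_hat", "d1_hat") %in% names(sub))) {
        srow$sign_match_rate <-
          mean(sign(sub$d1_hat - sub$d0_hat) == sign(true_d[2] - true_d[1]))
      }
      n_fail <- sum(vapply(failures, function(f)
        identical(f$condition, cname), TRUE))
      srow$n_failures <- n_fail
      srow$flagged <- n_fail > 0.2 * cond$n_reps
      summary <- rbind(summary, srow)
    }
  }
  structure(list(summary = summary, replicates = reps, failures = failures,
                 config = config),
            class = "study_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

power_study_one <- function(cond, method, mcmc_cfg, ml_cfg, pp_thr, daic,
                            rho, rep_seed) {
  rep <- simulate_bisse_tree(cond$lambda, cond$mu, cond$q,
                             stop_n = cond$n_tips, seed = rep_seed)
  chars <- stats::setNames(as.character(rep$tip_states),
                           names(rep$tip_states))
  out <- data.frame(seed = rep_seed)
  if ("mcmc" %in% method) {
    tr <- run_mcmc(rep$tree, chars,
                   model = mcmc_cfg$model %||% "five_param_equal_mu",
                   sampling = rho,
                   n_iter = mcmc_cfg$n_iter %||% 800,
                   burn_in_frac = mcmc_cfg$burn_in_frac %||% 0.2,
                   seed = rep_seed + 1L,
                   rtol = mcmc_cfg$rtol %||% 1e-7,
                   atol = mcmc_cfg$atol %||% 1e-9)
    ds <- summarize_diversification(tr)
    out$pp_greater <- ds$pp_greater
    med <- vapply(tr$samples[tr$retained, tr$par_names], stats::median, 0)
    mu0 <- if (tr$model == "five_param_equal_mu") med["mu"] else med["mu0"]
    mu1 <- if (tr$model == "five_param_equal_mu") med["mu"] else med["mu1"]
    out$d0_hat <- unname(med["lambda0"] - mu0)
    out$d1_hat <- unname(med["lambda1"] - mu1)
    out$lambda0_hat <- unname(med["lambda0"])
    out$lambda1_hat <- unname(med["lambda1"])
  }
  if ("ml" %in% method) {
    models <- ml_cfg$models %||% c("Mase", "M0")
    fits <- lapply(models, function(m)
      fit_ml(rep$tree, chars, m, sampling = rho,
             n_starts = ml_cfg$n_starts %||% 5, seed = rep_seed + 2L))
    names(fits) <- models
    aics <- vapply(fits, function(f) f$AIC, 0)
    nulls <- intersect(models, c("M0", "M0h2", "M0h4"))
    alts <- setdiff(models, nulls)
    out$delta_aic_vs_null <- if (length(nulls) && length(alts)) {
      min(aics[nulls]) - min(aics[alts])
    } else NA_real_
    bestalt <- fits[[alts[which.min(aics[alts])]]]
    if (!("d0_hat" %in% names(out))) {
      out$d0_hat <- unname(bestalt$net_diversification["A"])
      out$d1_hat <- unname(bestalt$net_diversification["R"])
      out$lambda0_hat <- unname(bestalt$mle[grepl("^lambda", names(bestalt$mle))][1])
      out$lambda1_hat <- unname(bestalt$mle[grepl("^lambda", names(bestalt$mle))][2])
    }
    out$ml_lambda_ratio <-
      unname(bestalt$mle["lambdaR"] / bestalt$mle["lambdaA"])
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("simulation study report\n")
  print(x$summary)
  if (length(x$failures)) {
    cat(length(x$failures), "replicate failure(s) recorded\n")
  }
  invisible(x)
}

#' Sensitivity of the diversification contrast to unsampled-state
#' assumptions
#'
#' For each value of `f` (the assumed fraction of state-0/accessible
#' species among the unsampled members of the clade), derives
#' state-specific sampling fractions from the observed state counts and
#' the clade's total richness, reruns the Bayesian contrast, and collects
#' `PP(d1 > d0)`.
#'
#' @param tree An ultrametric `phylo` of the sampled species.
#' @param chars A `character_matrix` or named tip-state vector.
#' @param total_richness Total extant species in the clade.
#' @param f_grid Values of `f` in `[0, 1]` (default `seq(0.1, 0.9, 0.1)`).
#' @param mcmc List of [run_mcmc()] settings (`n_iter`, `burn_in_frac`,
#'   `model`).
#' @param seed Integer master seed.
#' @return Data frame with one row per `f`: `f`, `rho0`, `rho1`,
#'   `pp_greater`, `diff_median`, `ratio_median`, `feasible`.
#' @export
run_sensitivity_f <- function(tree, chars, total_richness,
                              f_grid = seq(0.1, 0.9, by = 0.1),
                              mcmc = list(), seed = 1) {
  stopifnot(all(f_grid >= 0), all(f_grid <= 1))
  st <- as_tip_states(chars, tree)
  n0 <- sum(st == "0")
  n1 <- sum(st == "1")
  n_uns <- total_richness - ape::Ntip(tree)
  if (n_uns < 0) stop("total_richness below the number of tips",
                      call. = FALSE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, length(f_grid))
  rows <- lapply(seq_along(f_grid), function(i) {
    f <- f_grid[i]
    if ((n0 == 0 && f > 0) || (n1 == 0 && f < 1)) {
      return(data.frame(f = f, rho0 = NA, rho1 = NA, pp_greater = NA,
                        diff_median = NA, ratio_median = NA,
                        feasible = FALSE))
    }
    rho0 <- n0 / (n0 + f * n_uns)
    rho1 <- n1 / (n1 + (1 - f) * n_uns)
    tr <- run_mcmc(tree, st, model = mcmc$model %||% "five_param_equal_mu",
                   sampling = c(rho0, rho1),
                   n_iter = mcmc$n_iter %||% 2000,
                   burn_in_frac = mcmc$burn_in_frac %||% 0.2,
                   seed = seeds[i])
    ds <- summarize_diversification(tr)
    data.frame(f = f, rho0 = rho0, rho1 = rho1,
               pp_greater = ds$pp_greater,
               diff_median = ds$diff_median,
               ratio_median = ds$ratio_median, feasible = TRUE)
  })
  do.call(rbind, rows)
}

#' Full empirical-style analysis pipeline
#'
#' Runs the whole inference chain on one dataset: pollen coding into the
#' four partitions (PA1/PA2/PA3/PS), Bayesian ancestral-state
#' reconstruction with node Bayes factors on the partitions requested, the
#' six-model ML ladder with AIC comparison per partition, and the Bayesian
#' MCMC diversification contrast under both MCMC model forms per
#' partition.  Every stage is seeded so a rerun with the same config
#' reproduces the numbers exactly.
#'
#' @param tree An ultrametric `phylo`.
#' @param samples List of [pollen_sample()] objects covering (a subset of)
#'   the tree's tips.
#' @param catalog A `pollen_catalog`.
#' @param config List: `partitions` (default all four), `rho` (sampling
#'   fraction, default 1), `ml_models` (default all six),
#'   `mcmc` (settings list), `asr` (settings list: `n_iter`, `run_bf`,
#'   `bf_nodes`), `seed`.
#' @param out_dir Optional directory; when given, coded matrices, model
#'   tables, ASR tables and MCMC summaries are written as CSV.
#' @return A `pipeline_report`: list with `coding`, `matrices`, `asr`,
#'   `ml_tables`, `mcmc_summaries`, `config`.
#' @export
run_empirical_pipeline <- function(tree, samples, catalog, config = list(),
                                   out_dir = NULL) {
  partitions <- config$partitions %||% c("PA1", "PA2", "PA3", "PS")
  rho <- config$rho %||% 1
  ml_models <- config$ml_models %||%
    c("Mase", "Mas", "Mahse", "M0", "M0h2", "M0h4")
  mcmc_cfg <- config$mcmc %||% list()
  asr_cfg <- config$asr %||% list()
  seed <- config$seed %||% 1
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1, 4)

  coding <- code_pollen_dataset(samples, catalog)
  missing_sp <- setdiff(tree$tip.label, coding$species)
  matrices <- list()
  for (p in partitions) {
    st <- if (p == "PS") {
      stats::setNames(coding$specificity, coding$species)
    } else {
      stats::setNames(coding$accessibility, coding$species)
    }
    matrices[[p]] <- build_character_matrix(st, p,
                                            tip_labels = tree$tip.label)
  }

  asr <- list()
  asr_parts <- asr_cfg$partitions %||% intersect(c("PA2", "PS"), partitions)
  for (p in asr_parts) {
    res <- asr_marginal_posteriors(tree, matrices[[p]],
                                   n_iter = asr_cfg$n_iter %||% 2000,
                                   seed = stage_seeds[1])
    entry <- list(posteriors = res)
    if (isTRUE(asr_cfg$run_bf)) {
      nodes <- asr_cfg$bf_nodes %||% (ape::Ntip(tree) + 1L)
      entry$bf <- lapply(nodes, function(nd)
        node_bayes_factor(tree, matrices[[p]], nd,
                          n_rungs = asr_cfg$n_rungs %||% 10,
                          n_iter = asr_cfg$bf_iter %||% 200,
                          seed = stage_seeds[2] + nd))
    }
    asr[[p]] <- entry
  }

  ml_tables <- list()
  for (p in partitions) {
    fits <- lapply(ml_models, function(m)
      fit_ml(tree, matrices[[p]], m, sampling = rho,
             n_starts = config$n_starts %||% 5,
             seed = stage_seeds[3]))
    ml_tables[[p]] <- compare_aic(fits)
  }

  mcmc_summaries <- list()
  for (p in partitions) {
    for (m in c("five_param_equal_mu", "full_bisse")) {
      tr <- run_mcmc(tree, matrices[[p]], model = m, sampling = rho,
                     n_iter = mcmc_cfg$n_iter %||% 10000,
                     burn_in_frac = mcmc_cfg$burn_in_frac %||% 0.2,
                     seed = stage_seeds[4] + match(p, partitions))
      mcmc_summaries[[paste(p, m, sep = ".")]] <-
        summarize_diversification(tr)
    }
  }

  report <- structure(list(tree = tree,
                           coding = coding,
                           data_deficient = missing_sp,
                           matrices = matrices, asr = asr,
                           ml_tables = ml_tables,
                           mcmc_summaries = mcmc_summaries,
                           config = config, seed = seed),
                      class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$coding, file.path(out_dir, "coding.csv"),
                   row.names = FALSE)
  for (p in names(report$matrices)) {
    write_character_matrix(report$matrices[[p]],
                           file.path(out_dir, paste0("matrix_", p, ".csv")))
  }
  for (p in names(report$ml_tables)) {
    utils::write.csv(report$ml_tables[[p]],
                     file.path(out_dir, paste0("ml_", p, ".csv")),
                     row.names = FALSE)
  }
  for (p in names(report$asr)) {
    post <- report$asr[[p]]$posteriors$node_posterior
    utils::write.csv(as.data.frame(post),
                     file.path(out_dir, paste0("asr_", p, ".csv")))
    # tree annotated with P(state 1) as node labels
    tr <- report$tree
    if (!is.null(tr)) {
      tr$node.label <- sprintf("%.3f", post[, "P1"])
      write_tree(tr, file.path(out_dir, paste0("asr_", p, ".nwk")))
    }
  }
  mc <- do.call(rbind, lapply(names(report$mcmc_summaries), function(nm) {
    s <- report$mcmc_summaries[[nm]]
    data.frame(analysis = nm, pp_greater = s$pp_greater,
               diff_median = s$diff_median, ratio_median = s$ratio_median)
  }))
  utils::write.csv(mc, file.path(out_dir, "mcmc_summaries.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("empirical pipeline report:",
      nrow(x$coding), "species coded,",
      length(x$ml_tables), "partitions x", nrow(x$ml_tables[[1]]),
      "ML models,", length(x$mcmc_summaries), "MCMC runs\n")
  for (nm in names(x$mcmc_summaries)) {
    cat(sprintf("  %-28s PP(d1>d0) = %.3f\n", nm,
                x$mcmc_summaries[[nm]]$pp_greater))
  }
  invisible(x)
}
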