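# Univariate slice sampling (stepping-out and shrinkage, Neal 2003) on a
# bounded domain.  logf is the log target as a function of the scalar
# coordinate; logf0 its value at x0.  Returns the new point, its log
# density, and the number of target evaluations used.
slice_sample_one <- function(x0, logf, logf0, w, lower = 0, upper = Inf,
                             max_steps = 50L) {
  neval <- 0L
  f <- function(x) {
    neval <<- neval + 1L
    logf(x)
  }
  y <- logf0 + log(stats::runif(1))
  L <- x0 - stats::runif(1) * w
  R <- L + w
  j <- floor(stats::runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && L > lower && f(L) > y) {
    L <- L - w
    j <- j - 1
  }
  while (k > 0 && R < upper && f(R) > y) {
    R <- R + w
    k <- k - 1
  }
  L <- max(L, lower)
  R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    lf1 <- f(x1)
    if (lf1 >= y) return(list(x = x1, logf = lf1, neval = neval))
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-300) return(list(x = x0, logf = logf0, neval = neval))
  }
}

# Coordinate-wise slice sampler over a positive parameter vector.
# logpost(par) returns the log target.  widths are per-coordinate and, when
# adapt = TRUE, re-tuned from the sample spread every 100 iterations of the
# adaptation phase.  Deterministic under set.seed().
mcmc_slice <- function(logpost, init, n_iter, widths = NULL,
                       adapt_iter = 0L, lower = 0, upper = Inf) {
  d <- length(init)
  if (is.null(widths)) widths <- pmax(abs(init), 0.1)
  out <- matrix(NA_real_, n_iter, d)
  lp <- numeric(n_iter)
  x <- init
  cur <- logpost(x)
  if (!is.finite(cur)) stop("non-finite log posterior at initial point",
                            call. = FALSE)
  nevals <- 0L
  for (it in seq_len(n_iter)) {
    for (k in seq_len(d)) {
      res <- slice_sample_one(
        x[k],
        function(v) {
          xx <- x
          xx[k] <- v
          logpost(xx)
        },
        cur, widths[k], lower = lower, upper = upper)
      x[k] <- res$x
      cur <- res$logf
      nevals <- nevals + res$neval
    }
    out[it, ] <- x
    lp[it] <- cur
    if (it <= adapt_iter && it %% 100L == 0L) {
      win <- out[max(1L, it - 99L):it, , drop = FALSE]
      sds <- apply(win, 2, stats::sd)
      ok <- is.finite(sds) & sds > 0
      widths[ok] <- 2 * sds[ok]
    }
  }
  list(samples = out, logpost = lp, widths = widths, n_evals = nevals)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
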