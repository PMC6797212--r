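# shooting_optimizer (1/2): rank-1 + rank-mu CMA-ES with box constraints.

#' Covariance Matrix Adaptation Evolution Strategy
#'
#' Minimizes `fn` over a box with the standard (Hansen) CMA-ES: cumulative
#' step-size adaptation and a combined rank-1 + rank-mu covariance update,
#' with recombination over the `mu` best of `lambda` candidates per
#' generation.  Per-parameter initial standard deviations seed a diagonal
#' initial covariance, so heterogeneous design vectors (gains, thresholds,
#' joint angles, velocities) are searched on their own scales.  Box
#' constraints are handled by resampling (with a capped retry count, then
#' clipping).  Best-ever bookkeeping is elitist, and a fixed seed makes the
#' full history bit-reproducible.
#'
#' @param par initial mean (numeric vector, inside the box).
#' @param fn objective function of one vector argument, returning a finite
#'   scalar (non-finite values are treated as very bad candidates).
#' @param lower,upper box bounds (recycled to `length(par)`).
#' @param sigma per-parameter initial standard deviations (recycled).
#' @param lambda population size per generation.
#' @param mu number of parents used in the update.
#' @param max_gen maximum number of generations.
#' @param seed RNG seed; the global RNG state is saved and restored.
#' @param stop_fitness stop early when the best value drops below this.
#' @param fn_list optional vectorized evaluator taking a list of candidate
#'   vectors and returning a numeric vector; results must be reduced by
#'   candidate index so evaluation order cannot change the outcome.
#' @return list with `best_par`, `best_value`, `history` (one row per
#'   generation: best/median of the generation and best-ever),
#'   `generations`, `seed`.
#' @examples
#' res <- cma_es(rep(3, 4), function(x) sum(x^2), lower = -5, upper = 5,
#'               sigma = 1, lambda = 8, mu = 4, max_gen = 60, seed = 1)
#' res$best_value
#' @export
cma_es <- function(par, fn, lower = -Inf, upper = Inf, sigma = 0.3,
                   lambda = 16, mu = 8, max_gen = 200, seed = NULL,
                   stop_fitness = -Inf, fn_list = NULL) {
  n <- length(par)
  stopifnot(n >= 1, mu <= lambda, max_gen >= 1)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  sigma0 <- rep_len(sigma, n)
  stopifnot(all(lower < upper), all(sigma0 > 0),
            all(par >= lower & par <= upper))

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }

  # strategy constants (Hansen's defaults, weights log-decreasing)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  # search in scaled coordinates: x = xmean + sig * D0 * y, D0 = diag(sigma0)
  xmean <- par
  sig <- 1.0
  C <- diag(n)
  pc <- ps <- numeric(n)
  eigen_up <- TRUE
  B <- diag(n); Dv <- rep(1, n)

  best_par <- par
  best_value <- Inf
  hist <- matrix(NA_real_, nrow = max_gen, ncol = 3,
                 dimnames = list(NULL, c("best", "median", "best_ever")))

  for (gen in seq_len(max_gen)) {
    if (eigen_up) {
      eg <- eigen(C, symmetric = TRUE)
      B <- eg$vectors
      Dv <- sqrt(pmax(eg$values, 1e-20))
      eigen_up <- FALSE
    }
    Z <- matrix(NA_real_, n, lambda)
    X <- matrix(NA_real_, n, lambda)
    for (k in seq_len(lambda)) {
      ok <- FALSE
      for (try in 1:50) {                      # bounds by resampling
        z <- rnorm(n)
        y <- B %*% (Dv * z)
        x <- xmean + sig * sigma0 * as.numeric(y)
        if (all(x >= lower & x <= upper)) { ok <- TRUE; break }
      }
      if (!ok) {                               # clip and back-derive z
        x <- pmin(pmax(x, lower), upper)
        y <- (x - xmean) / (sig * sigma0)
        z <- as.numeric(crossprod(B, y) / Dv)
      }
      Z[, k] <- z
      X[, k] <- x
    }
    vals <- if (is.null(fn_list)) {
      vapply(seq_len(lambda), function(k) fn(X[, k]), numeric(1))
    } else {
      fn_list(lapply(seq_len(lambda), function(k) X[, k]))
    }
    if (all(!is.finite(vals))) {
      stop("optimization error: objective returned no finite value in an ",
           "entire generation (generation ", gen, ")")
    }
    vals[!is.finite(vals)] <- max(vals[is.finite(vals)]) + 1e6
    ord <- order(vals)
    if (vals[ord[1]] < best_value) {
      best_value <- vals[ord[1]]
      best_par <- X[, ord[1]]
    }
    hist[gen, ] <- c(vals[ord[1]], median(vals), best_value)

    sel <- ord[seq_len(mu)]
    zmean <- as.numeric(Z[, sel, drop = FALSE] %*% w)
    ymean <- as.numeric(B %*% (Dv * zmean))
    xmean <- xmean + sig * sigma0 * ymean

    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * as.numeric(B %*% zmean)
    hsig <- as.numeric(sqrt(sum(ps^2)) /
                       sqrt(1 - (1 - cs)^(2 * gen)) / chiN < 1.4 + 2 / (n + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ymean
    Ymu <- B %*% (Dv * Z[, sel, drop = FALSE])      # n x mu, scaled steps
    rank_mu <- matrix(0, n, n)
    for (k in seq_len(mu)) rank_mu <- rank_mu + w[k] * tcrossprod(Ymu[, k])
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * rank_mu
    C <- (C + t(C)) / 2
    sig <- sig * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    if (!is.finite(sig) || sig > 1e6) sig <- 1e6
    eigen_up <- TRUE

    if (best_value <= stop_fitness) {
      hist <- hist[seq_len(gen), , drop = FALSE]
      break
    }
  }
  gens <- sum(!is.na(hist[, 1]))
  list(best_par = best_par, best_value = best_value,
       history = as.data.frame(hist[seq_len(gens), , drop = FALSE]),
       generations = gens, seed = seed)
}

#' Parallel-set restart protocol
#'
#' Runs a set of `n_parallel` optimizations from the same initial guess
#' (differing only by RNG seed), takes the best solution of the set, and
#' uses it to seed the next set.  Stops when the best of a set improves on
#' the best of the previous set by less than the improvement threshold
#' (default 5%).
#'
#' @param fn objective function (scalar).
#' @param x0 initial guess.
#' @param lower,upper,sigma as in [cma_es()].
#' @param protocol list with `lambda`, `mu`, `max_gen`, `n_parallel`,
#'   `improvement_threshold` (see [gait_protocol()]).
#' @param seed base seed; run `r` of set `s` uses `seed + 1000*s + r`.
#' @param max_sets safety cap on the number of sets.
#' @return list with `best_par`, `best_value`, `sets` (data.frame: set,
#'   best value, improvement), and the per-run results of the last set.
#' @export
restart_protocol <- function(fn, x0, lower, upper, sigma, protocol,
                             seed = 1, max_sets = 20) {
  stopifnot(protocol$n_parallel >= 1,
            protocol$improvement_threshold > 0,
            protocol$improvement_threshold < 1)
  best_prev <- Inf
  x_seed <- x0
  sets <- data.frame()
  best_par <- x0; best_value <- Inf
  last_runs <- NULL
  for (s in seq_len(max_sets)) {
    runs <- lapply(seq_len(protocol$n_parallel), function(r) {
      cma_es(x_seed, fn, lower = lower, upper = upper, sigma = sigma,
             lambda = protocol$lambda, mu = protocol$mu,
             max_gen = protocol$max_gen, seed = seed + 1000 * s + r)
    })
    vals <- vapply(runs, `[[`, numeric(1), "best_value")
    k <- which.min(vals)
    improvement <- if (is.finite(best_prev)) (best_prev - vals[k]) / abs(best_prev) else NA_real_
    sets <- rbind(sets, data.frame(set = s, best = vals[k],
                                   improvement = improvement))
    if (vals[k] < best_value) {
      best_value <- vals[k]
      best_par <- runs[[k]]$best_par
    }
    last_runs <- runs
    if (is.finite(best_prev) &&
        (best_prev - vals[k]) / abs(best_prev) < protocol$improvement_threshold) {
      break
    }
    best_prev <- vals[k]
    x_seed <- runs[[k]]$best_par
  }
  list(best_par = best_par, best_value = best_value, sets = sets,
       runs = last_runs)
}
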