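# Black-box hyperparameter optimization. The study delegated tuning to a
# surrogate-assisted direct-search algorithm; here the optimizer is a
# contract (bounded proposals, deterministic given seed, best point + full
# trace returned) with a reference implementation: an RBF-surrogate-assisted
# pattern search with Latin hypercube initialization. Faithful reproduction
# of any specific optimizer's internals is a non-goal.

#' Define a hyperparameter box
#'
#' @param name parameter names.
#' @param lower,upper bounds (lower < upper elementwise).
#' @param init initial values within the bounds (default midpoint).
#' @param scale "linear" or "log" per parameter (informational; log-scaled
#'   quantities such as lambda should be passed as their log10).
#' @return Object of class `hyper_box`.
#' @export
hyper_box <- function(name, lower, upper, init = NULL,
                      scale = rep("linear", length(name))) {
  stopifnot(length(lower) == length(name), length(upper) == length(name))
  if (any(lower >= upper)) stop_invalid("need lower < upper for all parameters")
  if (is.null(init)) init <- (lower + upper) / 2
  if (any(init < lower | init > upper))
    stop_invalid("init must lie within the bounds")
  structure(list(name = name, lower = lower, upper = upper, init = init,
                 scale = scale), class = "hyper_box")
}

#' Derivative-free maximization over a box
#'
#' Surrogate-assisted direct search: after a Latin-hypercube initial design
#' the incumbent is refined by coordinate poll steps (expanding on success,
#' shrinking on failure) interleaved with proposals that maximize a
#' Gaussian-RBF surrogate fitted to all evaluated points. All proposals stay
#' within the box, the run is deterministic given `seed`, and the full
#' evaluation trace is returned.
#'
#' @param objective function of a parameter vector returning a finite scalar
#'   to maximize.
#' @param box a [hyper_box()].
#' @param n_iter total number of objective evaluations (default 200).
#' @param seed integer seed.
#' @return List with `best_par`, `best_value`, and `trace` (data.frame of
#'   evaluated points, values and the incumbent value).
#' @export
optimize_blackbox <- function(objective, box, n_iter = 200L, seed = 1L) {
  stopifnot(inherits(box, "hyper_box"))
  d <- length(box$lower)
  span <- box$upper - box$lower
  to_unit <- function(x) (x - box$lower) / span
  from_unit <- function(u) box$lower + pmin(1, pmax(0, u)) * span
  set.seed(derive_seed(seed, "bbo"))

  eval_pt <- function(u) {
    par <- from_unit(u)
    val <- tryCatch(objective(par), error = function(e)
      stop("objective failed at (", paste(signif(par, 4), collapse = ", "),
           "): ", conditionMessage(e)))
    if (!is.finite(val)) val <- -Inf
    list(par = par, u = u, val = val)
  }

  n_init <- min(n_iter, max(4L, 2L * d + 2L))
  U <- matrix(0, n_init, d)
  U[1L, ] <- to_unit(box$init)
  if (n_init > 1L) {
    # stratified Latin hypercube over the remaining initial evaluations
    lhs <- matrix(0, n_init - 1L, d)
    for (j in seq_len(d))
      lhs[, j] <- (sample.int(n_init - 1L) - stats::runif(n_init - 1L)) /
        (n_init - 1L)
    U[-1L, ] <- lhs
  }
  evals <- vector("list", n_iter)
  for (i in seq_len(n_init)) evals[[i]] <- eval_pt(U[i, ])
  k <- n_init
  best <- which.max(vapply(evals[1:k], `[[`, numeric(1), "val"))
  step <- 0.25

  while (k < n_iter) {
    inc <- evals[[best]]$u
    vals <- vapply(evals[1:k], `[[`, numeric(1), "val")
    pts <- matrix(unlist(lapply(evals[1:k], `[[`, "u")), ncol = d,
                  byrow = TRUE)
    use_surrogate <- (k %% 3L == 0L) && k >= d + 2L
    if (use_surrogate) {
      cand <- rbind(
        matrix(stats::runif(32L * d), 32L, d),
        rep_incumbent_jitter(inc, step, 32L, d))
      sv <- rbf_predict(pts, vals, cand)
      u_new <- cand[which.max(sv), ]
      k <- k + 1L; evals[[k]] <- eval_pt(u_new)
      if (evals[[k]]$val > vals[best]) best <- k
    } else {
      improved <- FALSE
      dims <- sample.int(d)
      for (j in dims) {
        for (sgn in sample(c(-1, 1))) {
          if (k >= n_iter) break
          u_new <- inc
          u_new[j] <- min(1, max(0, inc[j] + sgn * step))
          if (all(abs(u_new - inc) < 1e-12)) next
          k <- k + 1L; evals[[k]] <- eval_pt(u_new)
          if (evals[[k]]$val > evals[[best]]$val) {
            best <- k; improved <- TRUE; break
          }
        }
        if (improved || k >= n_iter) break
      }
      step <- if (improved) min(0.5, step * 2) else max(0.01, step / 2)
    }
  }
  evals <- evals[seq_len(k)]
  vals <- vapply(evals, `[[`, numeric(1), "val")
  pars <- matrix(unlist(lapply(evals, `[[`, "par")), ncol = d, byrow = TRUE)
  colnames(pars) <- box$name
  trace <- data.frame(pars, value = vals, incumbent = cummax(vals))
  list(best_par = evals[[which.max(vals)]]$par,
       best_value = max(vals), trace = trace)
}

rep_incumbent_jitter <- function(inc, step, m, d) {
  matrix(pmin(1, pmax(0, rep(inc, each = m) +
                        stats::rnorm(m * d, sd = step))), m, d)
}

# Gaussian RBF interpolation with ridge jitter; bandwidth = median distance
rbf_predict <- function(X, y, Xnew) {
  D <- as.matrix(stats::dist(X))
  h <- stats::median(D[D > 0])
  if (!is.finite(h) || h == 0) h <- 1
  K <- exp(-(D / h)^2)
  alpha <- tryCatch(solve(K + diag(1e-6, nrow(K)), y - mean(y)),
                    error = function(e) rep(0, length(y)))
  D2 <- outer(rowSums(Xnew^2), rowSums(X^2), "+") - 2 * Xnew %*% t(X)
  D2[D2 < 0] <- 0
  exp(-D2 / h^2) %*% alpha + mean(y)
}

#' Autocorrelation time of a series
#'
#' The shortest lag at which the normalized absolute autocorrelation drops
#' below `threshold` (default 0.05).
#'
#' @param x numeric series (length >= 10, non-constant).
#' @param threshold drop-below fraction of the zero-lag autocorrelation.
#' @return Integer lag in samples (>= 1).
#' @export
autocorrelation_time <- function(x, threshold = 0.05) {
  if (length(x) < 10L) stop_invalid("need at least 10 samples")
  if (stats::sd(x) == 0) stop("undefined ACT: constant series")
  n <- length(x)
  # unbiased-normalization autocorrelation via FFT (the usual biased
  # estimator decays as (n - tau)/n even for a perfectly periodic series,
  # which would fake a finite ACT)
  xc <- x - mean(x)
  np <- stats::nextn(2L * n, 2)
  ac <- Re(stats::fft(Mod(stats::fft(c(xc, numeric(np - n))))^2,
                      inverse = TRUE))[1L + seq_len(n - 1L)] / np
  ac <- (ac / (n - seq_len(n - 1L))) / (sum(xc^2) / n)
  hit <- which(abs(ac[seq_len(n - 2L)]) < threshold)
  if (!length(hit))
    stop("no lag with |acf| < ", threshold, " within the series length")
  hit[1L]
}

#' Allocate lag windows across modulation-frequency groups by ACT
#'
#' The slowest temporal-modulation group receives `window_slow`, the
#' fastest `window_fast`, and intermediate groups windows interpolated
#' linearly in proportion to their mean autocorrelation times between the
#' two anchors.
#'
#' @param window_slow,window_fast anchor lag windows c(tMin, tMax) seconds.
#' @param group_acts per-group mean ACT values, ordered from slowest
#'   (largest ACT) to fastest modulation group.
#' @return List of per-group lag windows.
#' @export
allocate_gabor_lags <- function(window_slow, window_fast, group_acts) {
  if (length(group_acts) < 2L) stop_invalid("need at least 2 groups")
  a_slow <- group_acts[1L]; a_fast <- group_acts[length(group_acts)]
  lapply(group_acts, function(a) {
    frac <- if (a_slow == a_fast) 0.5 else (a - a_fast) / (a_slow - a_fast)
    window_fast + frac * (window_slow - window_fast)
  })
}
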