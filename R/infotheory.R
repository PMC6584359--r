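# Gaussian-copula information theory and partial information decomposition.
#
# Continuous variables are rank-transformed to standard-normal marginals
# (empirical CDF followed by the inverse normal CDF), after which mutual
# information is computed from fitted Gaussian models with an analytic
# small-sample bias correction. The PID follows the common-change-in-
# surprisal (I_ccs) construction: redundancy is the expectation of pointwise
# co-information restricted to samples where (I) both sources carry
# pointwise MI about the target with the same sign and (II) the pointwise
# co-information shares that sign; unique information and synergy follow
# from the lattice, so the lattice identities hold by construction and
# negative unique information is possible. All quantities are in bits.

#' Copula-normalize continuous samples
#'
#' Per channel: ranks (average over ties) are scaled by 1/(n+1) and passed
#' through the inverse standard normal CDF, yielding standard-normal
#' marginals while preserving rank order.
#'
#' @param x numeric vector or time x channel matrix (n >= 10).
#' @return Matrix of the same shape with standard-normal marginals.
#' @export
copula_normalize <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 10L) stop_invalid("need at least 10 samples")
  out <- x
  for (j in seq_len(ncol(x))) {
    if (length(unique(x[, j])) == 1L)
      stop("cannot copula-normalize an all-constant channel (", j, ")")
    tie_frac <- 1 - length(unique(x[, j])) / n
    if (tie_frac > 0.10)
      warning(sprintf("channel %d has %.0f%% ties; copula normalization %s",
                      j, 100 * tie_frac, "may be degraded"))
    out[, j] <- stats::qnorm(rank(x[, j], ties.method = "average") / (n + 1))
  }
  out
}

# bias-corrected log-determinant of a Gaussian fit: E[logdet(Chat)] exceeds
# logdet(C) by sum_i psi((n-i)/2) + d log(2/(n-1)); subtracting the excess
# makes entropy differences approximately unbiased.
logdet_corrected <- function(C, n, bias = TRUE) {
  d <- nrow(C)
  ch <- tryCatch(chol(C), error = function(e)
    stop("singular covariance: collinear channels (d = ", d, ")"))
  ld <- 2 * sum(log(diag(ch)))
  if (bias)
    ld <- ld - (sum(digamma((n - seq_len(d)) / 2)) + d * log(2 / (n - 1)))
  ld
}

mi_from_cov <- function(C, dx, dy, n, bias = TRUE) {
  ix <- seq_len(dx); iy <- dx + seq_len(dy)
  # rank-degenerate cross-dependence (e.g. y a monotone transform of x)
  # yields a singular joint covariance although both marginal blocks are
  # fine; report the (regularized) estimator ceiling instead of crashing
  ld_joint <- tryCatch(logdet_corrected(C, n, bias), error = function(e)
    logdet_corrected(regularize_cov(C, 1e-12), n, bias))
  0.5 * (logdet_corrected(C[ix, ix, drop = FALSE], n, bias) +
           logdet_corrected(C[iy, iy, drop = FALSE], n, bias) -
           ld_joint) / log(2)
}

#' Gaussian-copula mutual information
#'
#' Continuous/continuous: both arguments are copula-normalized and the MI of
#' the fitted joint Gaussian is returned with a small-sample bias
#' correction. Continuous/discrete (`y` a factor or integer labels): a
#' class-conditional Gaussian model on copula-normalized `x`, MI as the
#' difference between the overall and the class-conditional entropies.
#'
#' @param x continuous vector or matrix.
#' @param y continuous vector/matrix, or discrete labels (factor, character
#'   or integer with at most 20 distinct values).
#' @param bias_correct apply the analytic bias correction (default TRUE).
#' @return MI in bits.
#' @export
mi_gaussian_copula <- function(x, y, bias_correct = TRUE) {
  x <- as.matrix(x)
  if (is.factor(y) || is.character(y) ||
      (is.numeric(y) && !is.matrix(y) && length(unique(y)) <= 20L &&
       all(y == round(y)))) {
    return(mi_model_gd(copula_normalize(x), as.factor(y), bias_correct))
  }
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop_invalid("sample count mismatch")
  cx <- copula_normalize(x); cy <- copula_normalize(y)
  C <- stats::cov(cbind(cx, cy))
  mi_from_cov(C, ncol(cx), ncol(cy), nrow(cx), bias_correct)
}

# MI between Gaussian-modelled x and discrete y: H(x) - sum_c p_c H(x|c)
mi_model_gd <- function(cx, y, bias = TRUE) {
  n <- nrow(cx); d <- ncol(cx)
  lev <- levels(y)
  if (length(lev) < 2L) stop_invalid("need >= 2 classes")
  tab <- table(y)
  if (any(tab < d + 2L))
    stop_invalid("every class needs at least dim(x)+2 samples")
  h_all <- logdet_corrected(stats::cov(cx), n, bias)
  h_cond <- 0
  for (l in lev) {
    sel <- y == l
    h_cond <- h_cond + (tab[[l]] / n) *
      logdet_corrected(stats::cov(cx[sel, , drop = FALSE]), tab[[l]], bias)
  }
  0.5 * (h_all - h_cond) / log(2)
}

#' Discrete MI after equipopulated binning
#'
#' `x` is discretized into `n_bins` equipopulated bins (quantile edges, ties
#' broken by stable rank) and the plugin discrete MI with the class labels
#' is returned, optionally with the Miller-Madow bias correction.
#'
#' @param x continuous samples.
#' @param classes discrete labels.
#' @param n_bins number of bins (default 4).
#' @param miller_madow subtract the analytic plugin bias (default FALSE).
#' @return MI in bits.
#' @export
binned_mi <- function(x, classes, n_bins = 4L, miller_madow = FALSE) {
  n <- length(x)
  classes <- as.factor(classes)
  if (length(classes) != n) stop_invalid("length mismatch")
  if (n_bins < 1L) stop_invalid("n_bins must be >= 1")
  if (n_bins == 1L) return(0)
  if (length(unique(x)) < n_bins)
    stop("fewer distinct values than bins")
  bins <- ceiling(rank(x, ties.method = "first") * n_bins / n)
  tab <- table(bins, classes)
  p <- tab / n
  px <- rowSums(p); pc <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log2(p[nz] / outer(px, pc)[nz]))
  if (miller_madow)
    mi <- mi - (sum(nz) - length(px) - length(pc) + 1) / (2 * n * log(2))
  mi
}

# ------------------------------------------------------------------ PID

new_pid_result <- function(red, mi_x, mi_y, mi_joint, n, n_mc) {
  structure(list(redundancy = red,
                 unique_x = mi_x - red,
                 unique_y = mi_y - red,
                 synergy = mi_joint - mi_x - mi_y + red,
                 mi_x = mi_x, mi_y = mi_y, mi_joint = mi_joint,
                 n = n, n_mc = n_mc), class = "pid_result")
}

#' @export
print.pid_result <- function(x, ...) {
  cat(sprintf(paste0("<pid_result> (bits)  red %.4f  unq_x %.4f  unq_y %.4f",
                     "  syn %.4f\n  MI: x %.4f  y %.4f  joint %.4f  (n=%d)\n"),
              x$redundancy, x$unique_x, x$unique_y, x$synergy,
              x$mi_x, x$mi_y, x$mi_joint, x$n))
  invisible(x)
}

# Gaussian log density (base e), mean mu, cholesky chC of covariance
mvn_logpdf <- function(X, mu, C) {
  X <- as.matrix(X)
  ch <- chol(C)
  z <- forwardsolve(t(ch), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * nrow(ch) * log(2 * pi)
}

mvn_sample <- function(n, mu, C) {
  ch <- chol(C)
  sweep(matrix(stats::rnorm(n * nrow(ch)), n) %*% ch, 2L, mu, `+`)
}

regularize_cov <- function(C, eps = 1e-8) {
  C + diag(eps * mean(diag(C)), nrow(C))
}

#' Partial information decomposition by common change in surprisal (I_ccs)
#'
#' Two sources `x` and `y` (continuous, possibly multichannel) about a
#' target `t` that is either continuous or discrete class labels. All
#' continuous variables are copula-normalized. For a continuous target a
#' joint Gaussian is fitted and `n_mc` Monte-Carlo samples are drawn from
#' it; for a discrete target a class-conditional Gaussian mixture (per-class
#' means and covariances, empirical class weights) is fitted and sampled.
#' Redundancy is the Monte-Carlo expectation of pointwise co-information
#' over samples satisfying the two sign conditions; unique information and
#' synergy follow from the lattice. Deterministic given `seed`.
#'
#' @param x,y source samples (vector or time x channel matrix).
#' @param t continuous target samples, or discrete labels (factor /
#'   character / small-integer vector).
#' @param n_mc Monte-Carlo sample count (default 1e5).
#' @param seed integer seed for the Monte-Carlo draw.
#' @param bias_correct bias-correct the marginal/joint MI terms
#'   (continuous target only; default TRUE).
#' @return A `pid_result` with redundancy, unique_x, unique_y, synergy,
#'   mi_x, mi_y and mi_joint (bits).
#' @export
pid_ccs <- function(x, y, t, n_mc = 1e5, seed = 1L, bias_correct = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop_invalid("sample count mismatch")
  discrete <- is.factor(t) || is.character(t) ||
    (is.numeric(t) && !is.matrix(t) && length(unique(t)) <= 20L &&
     all(t == round(t)))
  cx <- copula_normalize(x); cy <- copula_normalize(y)
  if (discrete) {
    pid_ccs_discrete(cx, cy, as.factor(t), n_mc, seed)
  } else {
    t <- as.matrix(t)
    if (nrow(t) != nrow(x)) stop_invalid("sample count mismatch")
    pid_ccs_gaussian(cx, cy, copula_normalize(t), n_mc, seed, bias_correct)
  }
}

pid_ccs_gaussian <- function(cx, cy, ct, n_mc, seed, bias_correct) {
  n <- nrow(cx)
  dx <- ncol(cx); dy <- ncol(cy); dt <- ncol(ct)
  Z <- cbind(cx, cy, ct)
  C <- regularize_cov(stats::cov(Z))
  ix <- seq_len(dx); iy <- dx + seq_len(dy); it <- dx + dy + seq_len(dt)
  # marginal and joint MI terms from the same fitted model
  mi_x <- mi_from_cov(C[c(ix, it), c(ix, it), drop = FALSE], dx, dt, n,
                      bias_correct)
  mi_y <- mi_from_cov(C[c(iy, it), c(iy, it), drop = FALSE], dy, dt, n,
                      bias_correct)
  mi_j <- mi_from_cov(C, dx + dy, dt, n, bias_correct)
  mu <- colMeans(Z)
  set.seed(derive_seed(seed, "pid_mc"))
  V <- mvn_sample(n_mc, mu, C)
  lp <- function(cols) mvn_logpdf(V[, cols, drop = FALSE], mu[cols],
                                  C[cols, cols, drop = FALSE])
  l_x <- lp(ix); l_y <- lp(iy); l_t <- lp(it); l_xy <- lp(c(ix, iy))
  l_xt <- lp(c(ix, it)); l_yt <- lp(c(iy, it)); l_xyt <- lp(seq_len(ncol(Z)))
  pmi_x <- (l_xt - l_x - l_t) / log(2)
  pmi_y <- (l_yt - l_y - l_t) / log(2)
  pmi_xy <- (l_xyt - l_xy - l_t) / log(2)
  coi <- pmi_x + pmi_y - pmi_xy
  keep <- (sign(pmi_x) == sign(pmi_y)) & (sign(coi) == sign(pmi_x))
  red <- mean(coi * keep)
  new_pid_result(red, mi_x, mi_y, mi_j, n, n_mc)
}

pid_ccs_discrete <- function(cx, cy, t, n_mc, seed) {
  n <- nrow(cx)
  dx <- ncol(cx); dy <- ncol(cy)
  lev <- levels(droplevels(t)); t <- droplevels(t)
  if (length(lev) < 2L) stop_invalid("need >= 2 target classes")
  ix <- seq_len(dx); iy <- dx + seq_len(dy)
  Z <- cbind(cx, cy)
  pc <- as.numeric(table(t)[lev]) / n
  # one shared ridge for all classes: a per-class epsilon would give
  # degenerate directions class-dependent variances and fabricate class
  # information out of the regularizer
  eps <- 1e-8 * mean(diag(stats::cov(Z)))
  mus <- list(); covs <- list()
  for (l in lev) {
    sel <- t == l
    if (sum(sel) < dx + dy + 2L)
      stop_invalid("class ", l, " has too few samples")
    mus[[l]] <- colMeans(Z[sel, , drop = FALSE])
    covs[[l]] <- stats::cov(Z[sel, , drop = FALSE]) +
      diag(eps, ncol(Z))
  }
  set.seed(derive_seed(seed, "pid_mc_d"))
  ncls <- stats::rmultinom(1L, n_mc, pc)[, 1L]
  V <- do.call(rbind, lapply(seq_along(lev), function(i)
    mvn_sample(ncls[i], mus[[i]], covs[[i]])))
  cls <- rep(seq_along(lev), ncls)
  # log densities under each class-conditional model, for mixtures
  logp_cond <- function(cols) {
    sapply(seq_along(lev), function(i)
      mvn_logpdf(V[, cols, drop = FALSE], mus[[i]][cols],
                 covs[[i]][cols, cols, drop = FALSE]))
  }
  mix <- function(L) {
    m <- apply(L, 1L, max)
    m + log(rowSums(exp(L - m) %*% diag(pc, length(pc))))
  }
  pointwise <- function(cols) {
    L <- logp_cond(cols)
    own <- L[cbind(seq_len(nrow(L)), cls)]
    (own - mix(L)) / log(2)          # log2 p(v|c) - log2 p(v)
  }
  pmi_x <- pointwise(ix)
  pmi_y <- pointwise(iy)
  pmi_xy <- pointwise(c(ix, iy))
  coi <- pmi_x + pmi_y - pmi_xy
  keep <- (sign(pmi_x) == sign(pmi_y)) & (sign(coi) == sign(pmi_x))
  red <- mean(coi * keep)
  new_pid_result(red, mean(pmi_x), mean(pmi_y), mean(pmi_xy), n, n_mc)
}

#' Co-information of two sources about a target
#'
#' MI(x;t) + MI(y;t) - MI(\[x,y\];t): positive values indicate net
#' redundancy, negative values net synergy. Equals redundancy minus synergy
#' of the I_ccs decomposition fitted to the same data.
#'
#' @inheritParams mi_gaussian_copula
#' @param t target samples.
#' @param y second source.
#' @return Co-information in bits.
#' @export
coinformation <- function(x, y, t, bias_correct = TRUE) {
  mi_gaussian_copula(x, t, bias_correct) +
    mi_gaussian_copula(y, t, bias_correct) -
    mi_gaussian_copula(cbind(as.matrix(x), as.matrix(y)), t, bias_correct)
}

#' Permutation noise threshold with circular shifts and maximum statistics
#'
#' For each permutation the `permutable` series is circularly shifted by a
#' uniform draw of at least `min_shift` samples (and at most n - min_shift),
#' the statistic is recomputed (it may be vector-valued over channels or
#' conditions) and its maximum recorded; the threshold is the stated
#' percentile of the permutation maxima.
#'
#' @param fixed samples held fixed (vector or matrix).
#' @param permutable series to be circularly shifted (vector or matrix,
#'   shifted along time).
#' @param stat function(fixed, permuted) returning a numeric scalar or
#'   vector.
#' @param n_perm number of permutations (default 1000).
#' @param min_shift minimum shift in samples (default 200).
#' @param percentile percentile of the maxima (default 95).
#' @param seed integer seed.
#' @return Scalar threshold.
#' @export
permutation_threshold <- function(fixed, permutable, stat, n_perm = 1000L,
                                  min_shift = 200L, percentile = 95,
                                  seed = 1L) {
  n <- if (is.matrix(permutable)) nrow(permutable) else length(permutable)
  if (n <= 2L * min_shift)
    stop_invalid("series too short: need length > 2*min_shift = ",
                 2L * min_shift)
  set.seed(derive_seed(seed, "perm"))
  shifts <- sample(min_shift:(n - min_shift), n_perm, replace = TRUE)
  maxima <- vapply(shifts, function(k)
    max(stat(fixed, circshift_rows(permutable, k))), numeric(1))
  unname(stats::quantile(maxima, percentile / 100))
}

#' Normalize a PID by a reference MI
#'
#' Divides all seven components by `reference_mi` (typically the marginal
#' MI of a benchmark model's prediction about the observed response).
#' Because unique information can be negative, normalized redundancy ratios
#' can exceed 1.
#'
#' @param pid a `pid_result`.
#' @param reference_mi reference MI in bits (> 0).
#' @return A `pid_result` with all components divided by `reference_mi`.
#' @export
normalize_pid <- function(pid, reference_mi) {
  stopifnot(inherits(pid, "pid_result"))
  if (!is.finite(reference_mi) || reference_mi <= 0)
    stop("reference_mi must be > 0")
  for (f in c("redundancy", "unique_x", "unique_y", "synergy",
              "mi_x", "mi_y", "mi_joint"))
    pid[[f]] <- pid[[f]] / reference_mi
  pid
}
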