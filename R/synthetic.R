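# Synthetic-data generators. Every downstream stage of the pipeline is
# exercised on data produced here, with known ground truth: smoothed-noise
# feature time series, renewal-process event sequences with class labels,
# responses generated by convolving features with known kernels plus Gaussian
# noise, leakage-mixed grids emulating limited spatial resolution of source
# reconstructions, and designed source/target triplets with known
# redundant / unique / synergistic structure.

#' Simulate a slowly varying feature time series
#'
#' Gaussian noise smoothed with a Gaussian kernel of the stated width and
#' z-scored per channel; a stand-in for spectrogram-like stimulus features.
#'
#' @param duration_s duration in seconds.
#' @param rate sampling rate in Hz.
#' @param n_channels number of channels.
#' @param smoothness Gaussian smoothing kernel sd in seconds (0 = white).
#' @param seed integer seed; the generator is bit-reproducible given it.
#' @return A [feature_space()] of shape `duration_s*rate` x `n_channels`.
#' @export
simulate_features <- function(duration_s, rate, n_channels = 1L,
                              smoothness = 0.05, seed = 1L) {
  assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  assert_scalar_num(rate, "rate", positive = TRUE)
  if (smoothness < 0) stop_invalid("smoothness must be >= 0")
  n <- round(duration_s * rate)
  if (n < 10) stop_invalid("need at least 10 samples")
  set.seed(derive_seed(seed, "features"))
  m <- matrix(stats::rnorm(n * n_channels), n, n_channels)
  sd_samp <- smoothness * rate
  if (sd_samp > 1e-8) {
    half <- max(1L, ceiling(4 * sd_samp))
    k <- stats::dnorm(-half:half, sd = sd_samp)
    k <- k / sum(k)
    # FFT circular convolution; circular wrap is immaterial for surrogates
    nk <- length(k)
    kpad <- numeric(n)
    kpad[1:nk] <- k
    kpad <- circshift_rows(kpad, -(half))
    K <- stats::fft(kpad)
    for (j in seq_len(n_channels))
      m[, j] <- Re(stats::fft(stats::fft(m[, j]) * K, inverse = TRUE)) / n
  }
  feature_space(zscore_cols(m, warn = FALSE), rate, "synthetic")
}

#' Simulate event onsets with class labels
#'
#' Renewal process with exponential inter-event intervals truncated below at
#' a refractory period, emulating phoneme onsets (roughly 10 events/s in
#' running speech). Each event is assigned one of four manner-of-articulation
#' classes by `class_probs`.
#'
#' @param duration_s duration in seconds.
#' @param rate target event rate (events/s).
#' @param refractory_s minimum inter-onset interval in seconds.
#' @param class_probs probability vector over the 4 classes (sums to 1).
#' @param seed integer seed.
#' @return An [event_table()] with columns onset_s, phoneme, class.
#' @export
simulate_events <- function(duration_s, rate = 10, refractory_s = 0.03,
                            class_probs = rep(0.25, 4), seed = 1L) {
  assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  assert_scalar_num(rate, "rate", positive = TRUE)
  if (refractory_s < 0) stop_invalid("refractory_s must be >= 0")
  if (rate * refractory_s >= 1)
    stop_invalid("infeasible: rate * refractory_s must be < 1")
  if (abs(sum(class_probs) - 1) > 1e-12)
    stop_invalid("class_probs must sum to 1")
  set.seed(derive_seed(seed, "events"))
  # exponential part rate chosen so the mean interval is 1/rate overall
  exp_rate <- 1 / (1 / rate - refractory_s)
  n_guess <- ceiling(duration_s * rate * 1.5) + 20L
  gaps <- refractory_s + stats::rexp(n_guess, exp_rate)
  onsets <- cumsum(gaps)
  while (onsets[length(onsets)] < duration_s) {
    gaps <- refractory_s + stats::rexp(n_guess, exp_rate)
    onsets <- c(onsets, onsets[length(onsets)] + cumsum(gaps))
  }
  onsets <- onsets[onsets < duration_s]
  cls <- sample.int(4L, length(onsets), replace = TRUE, prob = class_probs)
  classes <- c("vowel", "nasal", "plosive", "fricative")
  event_table(onset_s = onsets,
              phoneme = paste0("syn", cls),
              class = classes[cls])
}

#' Generate a smooth ground-truth TRF tensor
#'
#' Gamma-shaped impulse responses with random per-channel gains: a smooth,
#' channel-varying kernel supported on the stated lag window, the kind of
#' temporal response function the estimators are expected to recover.
#'
#' @param lag_window c(tMin, tMax) in seconds, tMin < tMax.
#' @param rate sampling rate in Hz.
#' @param n_channels number of feature channels.
#' @param shape,scale gamma kernel parameters (seconds enter via `scale`).
#' @param gain_sd sd of the random per-channel gains (0 gives a zero tensor).
#' @param seed integer seed.
#' @return A channel x lag matrix with attributes `lags` (in samples) and
#'   `rate`.
#' @export
make_ground_truth_trf <- function(lag_window = c(0, 0.4), rate = 40,
                                  n_channels = 31L, shape = 2, scale = 0.05,
                                  gain_sd = 1, seed = 1L) {
  if (length(lag_window) != 2L || !(lag_window[1] < lag_window[2]))
    stop_invalid("lag_window must satisfy tMin < tMax")
  lags <- seq.int(round(lag_window[1] * rate), round(lag_window[2] * rate))
  set.seed(derive_seed(seed, "trf"))
  tt <- pmax(lags / rate - lag_window[1], 0)
  base <- stats::dgamma(tt, shape = shape, scale = scale)
  base <- base / max(base)
  gains <- stats::rnorm(n_channels, sd = gain_sd)
  w <- outer(gains, base)
  dimnames(w) <- list(NULL, paste0("lag", lags))
  attr(w, "lags") <- lags
  attr(w, "rate") <- rate
  w
}

#' Simulate responses from the linear forward model
#'
#' Clean response r(t) = sum over channels and lags of w(ch, tau) s(ch, t-tau)
#' with the same zero-padded lag convention as [build_lagged_design()]. Each
#' repeat adds independent Gaussian noise scaled so that
#' var(clean)/var(noise) equals `snr`; repeats share the clean component
#' exactly, so the expected repeat-to-repeat correlation is snr/(snr+1).
#'
#' @param features a [feature_space()].
#' @param trf_true channel x lag matrix from [make_ground_truth_trf()].
#' @param snr linear signal-to-noise variance ratio (> 0; `Inf` = noiseless).
#' @param n_repeats number of repeated presentations.
#' @param seed integer seed.
#' @return List with `clean` (vector) and `repeats` (time x n_repeats
#'   matrix), plus `snr`.
#' @export
simulate_response <- function(features, trf_true, snr = 10, n_repeats = 2L,
                              seed = 1L) {
  stopifnot(inherits(features, "feature_space"))
  if (!is.infinite(snr) && snr <= 0) stop_invalid("snr must be > 0")
  if (nrow(trf_true) != n_channels(features))
    stop_invalid("feature channels (", n_channels(features),
                 ") do not match trf channels (", nrow(trf_true), ")")
  lags <- attr(trf_true, "lags")
  if (is.null(lags)) lags <- seq_len(ncol(trf_true)) - 1L
  n <- n_samples(features)
  clean <- numeric(n)
  X <- features$data
  for (k in seq_along(lags))
    clean <- clean + shift_pad(X, lags[k]) %*% trf_true[, k]
  clean <- drop(clean)
  set.seed(derive_seed(seed, "response"))
  vc <- stats::var(clean)
  noise_sd <- if (is.infinite(snr) || vc == 0) {
    if (vc == 0) 1 else 0
  } else sqrt(vc / snr)
  if (vc == 0 && !is.infinite(snr)) noise_sd <- 1  # zero trf: pure noise
  reps <- matrix(clean, n, n_repeats) +
    matrix(stats::rnorm(n * n_repeats, sd = noise_sd), n, n_repeats)
  list(clean = clean, repeats = reps, snr = snr)
}

#' Mix latent sources onto a grid with leakage
#'
#' Each grid point is a fixed weighted sum of the latent source time series
#' plus independent Gaussian noise, emulating the leakage structure of
#' linear inverse solutions where neighboring grid points are highly
#' correlated.
#'
#' @param latent_sources time x source matrix.
#' @param leakage grid-point x source mixing matrix.
#' @param noise_sd sd of independent additive noise per grid point.
#' @param seed integer seed.
#' @return time x grid-point matrix.
#' @export
simulate_source_grid <- function(latent_sources, leakage, noise_sd = 0.1,
                                 seed = 1L) {
  latent_sources <- as.matrix(latent_sources)
  leakage <- as.matrix(leakage)
  if (ncol(leakage) != ncol(latent_sources))
    stop_invalid("leakage columns (", ncol(leakage),
                 ") must match number of latent sources (",
                 ncol(latent_sources), ")")
  if (any(!is.finite(leakage))) stop_invalid("leakage must be finite")
  set.seed(derive_seed(seed, "grid"))
  g <- latent_sources %*% t(leakage)
  if (noise_sd > 0)
    g <- g + matrix(stats::rnorm(length(g), sd = noise_sd), nrow(g), ncol(g))
  g
}

#' Designed source/target triplets with known PID structure
#'
#' Fixtures for the partial information decomposition: `redundant` makes the
#' two sources identical, `unique_x` makes only x informative, `synergistic`
#' makes the target depend on the sum of two independent sources so that
#' neither alone is informative.
#'
#' @param n number of samples.
#' @param structure one of "redundant", "unique_x", "synergistic".
#' @param strength correlation-like strength in (0, 1).
#' @param seed integer seed.
#' @return List with numeric vectors `x`, `y`, `t`.
#' @export
simulate_pid_triplet <- function(n, structure = c("redundant", "unique_x",
                                                  "synergistic"),
                                 strength = 0.7, seed = 1L) {
  structure <- match.arg(structure)
  if (strength <= 0 || strength >= 1)
    stop_invalid("strength must be in (0, 1)")
  set.seed(derive_seed(seed, paste0("pid_", structure)))
  noise_sd <- sqrt(1 - strength^2)
  x <- stats::rnorm(n)
  if (structure == "redundant") {
    y <- x
    t <- strength * x + stats::rnorm(n, sd = noise_sd)
  } else if (structure == "unique_x") {
    y <- stats::rnorm(n)
    t <- strength * x + stats::rnorm(n, sd = noise_sd)
  } else {
    y <- stats::rnorm(n)
    t <- strength * (x + y) / sqrt(2) + stats::rnorm(n, sd = noise_sd)
  }
  list(x = x, y = y, t = t)
}

# shift rows down by k (k > 0: past samples predict the present), zero-pad
shift_pad <- function(X, k) {
  n <- nrow(X)
  out <- matrix(0, n, ncol(X))
  if (k >= 0) {
    if (k < n) out[(k + 1L):n, ] <- X[1L:(n - k), ]
  } else {
    if (-k < n) out[1L:(n + k), ] <- X[(1L - k):n, ]
  }
  out
}
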