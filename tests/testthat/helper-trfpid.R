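# shared fixtures and small oracles used across test files

# cosine similarity between two channel x lag tensors on the union lag grid
union_cosine <- function(w, v) {
  lw <- attr(w, "lags"); lv <- attr(v, "lags")
  u <- sort(union(lw, lv))
  A <- matrix(0, nrow(w), length(u)); A[, match(lw, u)] <- w
  B <- matrix(0, nrow(v), length(u)); B[, match(lv, u)] <- v
  sum(A * B) / sqrt(sum(A^2) * sum(B^2))
}

# closed-form MI (bits) of a bivariate Gaussian with correlation rho
gaussian_mi_oracle <- function(rho) -0.5 * log2(1 - rho^2)

# brute-force ridge solve oracle: generic dense solver on the normal
# equations, independent of the package's cholesky path
ridge_oracle <- function(S, r, pen_diag) {
  solve(crossprod(S) + diag(pen_diag, ncol(S)), crossprod(S, r))
}

# analytic plugin-MI bias for an R x C contingency table (bits)
plugin_mi_bias <- function(n, n_bins, n_classes)
  (n_bins - 1) * (n_classes - 1) / (2 * n * log(2))

# event-driven forward-model world for the phoneme-locked analyses:
# class-dependent impulse gains drive an envelope-like feature which is
# convolved with a smooth kernel; observed = clean response + noise
phoneme_world <- function(duration = 600, rate = 40, snr = 4, seed = 1,
                          gains = c(vowel = 1, nasal = 2, plosive = 3,
                                    fricative = 4)) {
  ev <- simulate_events(duration, 10, 0.03, rep(0.25, 4),
                        seed = derive_seed(seed, "pw_ev"))
  n <- duration * rate
  idx <- ceiling(ev$onset_s * rate - 0.5) + 1L
  feat <- matrix(0, n, 1)
  feat[idx, 1] <- gains[ev$class]
  kern <- make_ground_truth_trf(c(0, 0.35), rate, 1, gain_sd = 0,
                                seed = 1)
  kern[1, ] <- abs(stats::dgamma(attr(kern, "lags") / rate,
                                 shape = 2, scale = 0.05))
  fs <- feature_space(feat, rate, "EnvImp")
  clean <- simulate_response(fs, kern, snr = Inf, seed = 1)$clean
  set.seed(derive_seed(seed, "pw_noise"))
  observed <- clean + rnorm(n, sd = sqrt(stats::var(clean) / snr))
  list(events = ev, clean = clean, observed = observed, rate = rate)
}

# a small synthetic world reused by several encoding tests
small_world <- function(duration = 150, n_ch = 6, snr = 10, seed = 42) {
  fs <- simulate_features(duration, 40, n_ch, 0.05, seed = seed)
  trf <- make_ground_truth_trf(c(0, 0.4), 40, n_ch, seed = seed + 1)
  resp <- simulate_response(fs, trf, snr = snr, seed = seed + 2)
  list(fs = fs, trf = trf, resp = resp)
}
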