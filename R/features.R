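# Acoustic feature spaces: log-mel spectrogram (Sg), amplitude envelope
# (Env), half-wave rectified spectral derivative (Deriv), 2D Gabor
# modulation filterbank (Gabor), and the Hilbert-envelope spectrogram with
# 16 Butterworth bands (Sg16 / Sg16c) used for EEG-style modelling.

# ---------------------------------------------------------------- STFT / mel

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# power spectrogram frames: n_fft/2+1 bins x n_frames
stft_power <- function(x, win_len, hop, n_fft) {
  n <- length(x)
  starts <- seq.int(1L, max(1L, n - win_len + 1L), by = hop)
  w <- hann_window(win_len)
  out <- matrix(0, n_fft %/% 2L + 1L, length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + win_len - 1L)] * w
    X <- stats::fft(c(seg, numeric(n_fft - win_len)))
    out[, i] <- Mod(X[seq_len(nrow(out))])^2
  }
  out
}

mel_filterbank <- function(n_bands, fmin, fmax, n_fft, sr) {
  # centers mel-spaced with first/last exactly at fmin/fmax; triangle edges
  # at the neighboring centers (extrapolated one step beyond at the ends)
  mc <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_bands)
  step <- mc[2] - mc[1]
  edges <- mel_to_hz(c(mc[1] - step, mc, mc[n_bands] + step))
  freqs <- (seq_len(n_fft %/% 2L + 1L) - 1L) * sr / n_fft
  fb <- matrix(0, n_bands, length(freqs))
  for (b in seq_len(n_bands)) {
    lo <- edges[b]; ce <- edges[b + 1L]; hi <- edges[b + 2L]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[b, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Log-mel spectrogram (Sg)
#'
#' Short-time power spectra (25 ms Hann window, 10 ms hop, i.e. a native
#' 100 Hz frame rate) passed through a 31-band mel filterbank whose center
#' frequencies run from `fmin` to `fmax`, followed by logarithmic
#' compression with a floor of 1e-10 of the peak energy.
#'
#' @param audio mono waveform (numeric vector), or a list with elements
#'   `samples` and `sr` as returned by [read_wav()].
#' @param sr sampling rate in Hz (ignored if `audio` carries its own).
#' @param n_bands number of mel bands (default 31).
#' @param fmin,fmax first and last band center frequency in Hz.
#' @param win_s,hop_s frame length and hop in seconds.
#' @return A [feature_space()] named "Sg" at the frame rate `1/hop_s`.
#' @export
log_mel_spectrogram <- function(audio, sr = NULL, n_bands = 31L,
                                fmin = 124.1, fmax = 7284.1,
                                win_s = 0.025, hop_s = 0.010) {
  if (is.list(audio)) { sr <- audio$sr; audio <- audio$samples }
  assert_scalar_num(sr, "sr", positive = TRUE)
  if (sr < 2 * fmax) stop_invalid("sr must be at least 2*fmax = ", 2 * fmax)
  if (any(!is.finite(audio))) stop_invalid("audio must be finite")
  win_len <- round(win_s * sr)
  hop <- round(hop_s * sr)
  n_fft <- 2^ceiling(log2(win_len))
  pw <- stft_power(audio, win_len, hop, n_fft)
  fb <- mel_filterbank(n_bands, fmin, fmax, n_fft, sr)
  e <- fb %*% pw
  floor_val <- max(e) * 1e-10
  if (floor_val == 0) floor_val <- 1e-20  # all-zero audio: constant floor
  m <- t(log(pmax(e, floor_val)))
  feature_space(m, 1 / hop_s, "Sg",
                channel_names = sprintf("mel%02d", seq_len(n_bands)))
}

#' Amplitude envelope (Env)
#'
#' The channel-sum of a spectrogram-type feature space.
#'
#' @param sg a spectrogram [feature_space()].
#' @return A one-channel [feature_space()] named "Env".
#' @export
envelope <- function(sg) {
  stopifnot(inherits(sg, "feature_space"))
  feature_space(matrix(rowSums(sg$data), ncol = 1L), sg$rate, "Env")
}

#' Half-wave rectified spectral derivative (Deriv)
#'
#' Per-channel first difference with negative values set to zero; one zero
#' sample is prepended so Deriv aligns sample-for-sample with its input.
#'
#' @param sg a spectrogram [feature_space()] with at least 2 samples.
#' @return A [feature_space()] named "Deriv" with the same shape as `sg`.
#' @export
halfwave_derivative <- function(sg) {
  stopifnot(inherits(sg, "feature_space"))
  if (n_samples(sg) < 2L) stop_invalid("need at least 2 time samples")
  d <- pmax(rbind(0, diff(sg$data)), 0)
  feature_space(d, sg$rate, "Deriv")
}

# ------------------------------------------------------------- Gabor bank

# Multiplicative spacing of modulation center frequencies: adjacent filters
# are separated in proportion to their bandwidth, giving the descending
# series omega, omega/space, ... with space = (nu + 4 d) / (nu - 4 d).
gabor_mod_freqs <- function(omega_max, size_max, nu, d) {
  space <- (nu + 4 * d) / (nu - 4 * d)
  omega_min <- pi * nu / size_max
  om <- omega_max
  while (om[length(om)] / space >= omega_min)
    om <- c(om, om[length(om)] / space)
  c(om, 0)
}

# Hann-enveloped complex exponential, DC-free and L2-normalized. omega = 0
# gives the plain (normalized) envelope with support capped at size_max.
gabor_kernel_1d <- function(omega, nu, size_max) {
  size <- if (omega > 0) min(size_max, 2 * pi * nu / abs(omega)) else size_max
  half <- floor((round(size) - 1) / 2)
  kidx <- -half:half
  env <- 0.5 - 0.5 * cos(2 * pi * (kidx + half + 1) / (2 * half + 3))
  env * exp(1i * omega * kidx)
}

gabor_bank_spec <- function(n_channels = 31L,
                            omega_max = c(pi / 2, pi / 2),
                            nu = c(3.5, 3.5), distance = c(0.3, 0.2),
                            size_factor = c(3, 40)) {
  size_max <- c(size_factor[1] * n_channels, size_factor[2])
  om_k <- gabor_mod_freqs(omega_max[1], size_max[1], nu[1], distance[1])
  om_n <- gabor_mod_freqs(omega_max[2], size_max[2], nu[2], distance[2])
  combos <- list()
  for (ok in om_k) for (on in om_n) {
    combos[[length(combos) + 1L]] <- c(ok, on)
    if (ok > 0 && on > 0)                      # two spectral orientations
      combos[[length(combos) + 1L]] <- c(-ok, on)
  }
  list(combos = combos, nu = nu, size_max = size_max,
       om_k = om_k, om_n = om_n)
}

# Redundancy-reduction channel selection: filter outputs are subsampled
# along frequency in proportion to the spectral filter extent, symmetric
# about the center channel; purely temporal filters (omega_k = 0) keep the
# center channel only. The proportionality (one tenth of the uncapped
# extent) reproduces the reference bank's 455 output dimensions at 31 mel
# channels.
gabor_channel_sel <- function(omega_k, nu_k, n_channels) {
  center <- floor(n_channels / 2) + 1L
  if (omega_k == 0) return(center)
  delta <- max(1L, as.integer(round(0.2 * pi * nu_k / abs(omega_k))))
  down <- rev(seq.int(center, 1L, by = -delta))
  up <- seq.int(center, n_channels, by = delta)
  unique(c(down, up))
}

#' 2D Gabor modulation filterbank (Gabor)
#'
#' Filters a 31-channel log-mel spectrogram with 2D Gabor kernels (real
#' part) covering all retained combinations of spectral modulation
#' frequencies Omega in \{0, 2.9, 6, 12.2, 25\} (scaled units) and temporal
#' modulation frequencies omega in \{0, 6.2, 9.9, 15.7, 25\} Hz at the
#' native 100 Hz frame rate, including both spectral orientations where
#' defined. Each filter's output is subsampled across channels in
#' proportion to its spectral extent, yielding 455 output channels with the
#' default parameters.
#'
#' @param sg the 31-channel log-mel [feature_space()] from
#'   [log_mel_spectrogram()].
#' @param spectral_mods,temporal_mods optional explicit modulation frequency
#'   sets (radians per channel / per frame); defaults follow the reference
#'   construction.
#' @return A [feature_space()] named "Gabor".
#' @export
gabor_filterbank <- function(sg, spectral_mods = NULL, temporal_mods = NULL) {
  stopifnot(inherits(sg, "feature_space"))
  K <- n_channels(sg)
  spec <- gabor_bank_spec(K)
  if (!is.null(spectral_mods)) {
    if (any(spectral_mods < 0) || max(spectral_mods) > pi)
      stop_invalid("unknown spectral modulation values")
    spec <- modify_bank_mods(spec, sort(spectral_mods, decreasing = TRUE),
                             spec$om_n)
  }
  if (!is.null(temporal_mods)) {
    if (any(temporal_mods < 0) || max(temporal_mods) > pi)
      stop_invalid("unknown temporal modulation values")
    spec <- modify_bank_mods(spec, spec$om_k,
                             sort(temporal_mods, decreasing = TRUE))
  }
  S <- t(sg$data)                               # channel x time
  out <- list(); nms <- character(0)
  for (cmb in spec$combos) {
    ok <- cmb[1]; on <- cmb[2]
    ck <- gabor_kernel_1d(ok, spec$nu[1], spec$size_max[1])
    cn <- gabor_kernel_1d(on, spec$nu[2], spec$size_max[2])
    kern <- Re(outer(ck, cn))
    if (ok != 0 || on != 0) {                   # remove DC response
      env <- outer(Mod(ck) , Mod(cn))
      kern <- kern - env * sum(kern) / sum(env)
    }
    kern <- kern / sqrt(sum(kern^2))
    resp <- xcorr2_same(S, kern)
    sel <- gabor_channel_sel(ok, spec$nu[1], K)
    out[[length(out) + 1L]] <- t(resp[sel, , drop = FALSE])
    nms <- c(nms, sprintf("gb_k%+.3f_n%.3f_c%d", ok, on, sel))
  }
  feature_space(do.call(cbind, out), sg$rate, "Gabor", channel_names = nms)
}

modify_bank_mods <- function(spec, om_k, om_n) {
  om_k <- unique(c(om_k[om_k > 0], 0)); om_n <- unique(c(om_n[om_n > 0], 0))
  combos <- list()
  for (ok in om_k) for (on in om_n) {
    combos[[length(combos) + 1L]] <- c(ok, on)
    if (ok > 0 && on > 0) combos[[length(combos) + 1L]] <- c(-ok, on)
  }
  spec$combos <- combos; spec$om_k <- om_k; spec$om_n <- om_n
  spec
}

# 2D cross-correlation, 'same' output, zero padding (FFT based)
xcorr2_same <- function(S, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  nr <- stats::nextn(nrow(S) + kr - 1L, c(2, 3, 5))
  nc <- stats::nextn(ncol(S) + kc - 1L, c(2, 3, 5))
  P <- matrix(0, nr, nc); P[seq_len(nrow(S)), seq_len(ncol(S))] <- S
  Q <- matrix(0, nr, nc)
  # correlation = convolution with the flipped kernel
  Q[seq_len(kr), seq_len(kc)] <- kern[kr:1, kc:1]
  R <- Re(stats::fft(stats::fft(P) * stats::fft(Q), inverse = TRUE)) / (nr * nc)
  r0 <- (kr + 1L) %/% 2L; c0 <- (kc + 1L) %/% 2L
  R[r0 + seq_len(nrow(S)) - 1L, c0 + seq_len(ncol(S)) - 1L, drop = FALSE]
}

#' Number of filters in the default Gabor bank
#'
#' @param n_channels number of spectrogram channels (default 31).
#' @return Integer count of output channels (455 for the default bank).
#' @export
gabor_bank_size <- function(n_channels = 31L) {
  spec <- gabor_bank_spec(n_channels)
  sum(vapply(spec$combos, function(cmb)
    length(gabor_channel_sel(cmb[1], spec$nu[1], n_channels)), integer(1)))
}

# --------------------------------------------------- Butterworth / Hilbert

# order-n analog Butterworth bandpass (2n poles) discretized bilinearly
butter_bandpass <- function(n, lo, hi, fs) {
  if (hi >= fs / 2 || lo <= 0 || lo >= hi)
    stop_invalid("invalid band edges for fs = ", fs)
  w1 <- 2 * fs * tan(pi * lo / fs)
  w2 <- 2 * fs * tan(pi * hi / fs)
  w0sq <- w1 * w2; B <- w2 - w1
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  s_poles <- c()
  for (p in proto) {
    disc <- sqrt((p * B)^2 - 4 * w0sq)
    s_poles <- c(s_poles, (p * B + disc) / 2, (p * B - disc) / 2)
  }
  fs2 <- 2 * fs
  zp <- (fs2 + s_poles) / (fs2 - s_poles)
  a <- Re(poly_from_roots(zp))
  b <- Re(poly_from_roots(c(rep(1, n), rep(-1, n)))) *
    Re(B^n * fs2^n / prod(fs2 - s_poles))
  list(b = b, a = a / a[1], b_scaled = b / a[1])
}

poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# IIR filtering via C-level primitives: FIR part with stats::filter
# (convolution, zero initial conditions), recursive part with
# method = "recursive".
iir_filter <- function(b, a, x) {
  nb <- length(b)
  xf <- as.numeric(stats::filter(x, b, method = "convolution", sides = 1))
  for (i in seq_len(min(nb - 1L, length(x))))
    xf[i] <- sum(b[seq_len(i)] * x[i:1])
  as.numeric(stats::filter(xf, -a[-1L], method = "recursive"))
}

# zero-phase forward-reverse filtering with odd-reflection edge padding
filtfilt_fr <- function(b, a, x) {
  npad <- 3L * (max(length(a), length(b)) - 1L)
  stopifnot(length(x) > npad + 1L)
  pre <- 2 * x[1] - x[(npad + 1L):2L]
  post <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - npad)]
  xp <- c(pre, x, post)
  y <- iir_filter(b, a, xp)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(npad + 1L):(npad + length(x))]
}

hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Hilbert-envelope spectrogram with 16 Butterworth bands (Sg16 / Sg16c)
#'
#' A bank of fourth-order zero-phase (forward-reverse) Butterworth bandpass
#' filters with mel-spaced center frequencies from 250 to 8001 Hz; band
#' edges lie at half the distance to the neighboring centers. The analytic
#' signal magnitude of each band forms a channel; with `compress = TRUE`
#' values are raised to the power 0.3 (name "Sg16c").
#'
#' @param audio mono waveform, or a list with `samples` and `sr`.
#' @param sr sampling rate in Hz; must exceed twice the top band edge.
#' @param compress apply the power-0.3 compressive nonlinearity.
#' @return A [feature_space()] with 16 channels at the audio rate.
#' @export
hilbert_spectrogram16 <- function(audio, sr = NULL, compress = FALSE) {
  if (is.list(audio)) { sr <- audio$sr; audio <- audio$samples }
  assert_scalar_num(sr, "sr", positive = TRUE)
  centers <- c(250, 402, 577, 780, 1015, 1288, 1605, 1971, 2396, 2888,
               3459, 4121, 4888, 5777, 6807, 8001)
  gaps <- diff(centers)
  lo <- centers - c(gaps[1], gaps) / 2
  hi <- centers + c(gaps, gaps[length(gaps)]) / 2
  if (sr <= 2 * max(hi))
    stop_invalid("sr must exceed twice the top band edge (", 2 * max(hi), ")")
  m <- matrix(0, length(audio), 16L)
  for (i in seq_len(16L)) {
    flt <- butter_bandpass(2L, lo[i], hi[i], sr)
    m[, i] <- hilbert_envelope(filtfilt_fr(flt$b_scaled, flt$a, audio))
  }
  if (compress) m <- m^0.3
  feature_space(m, sr, if (compress) "Sg16c" else "Sg16",
                channel_names = sprintf("bp%d", centers))
}
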