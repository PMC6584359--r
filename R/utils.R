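#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. These are deliberately dependency
# free: the package only imports stats/utils/jsonlite.

#' Derive a reproducible substream seed
#'
#' All generators take one user-facing seed; independent stages derive their
#' own substream from it so that any stage can be regenerated in isolation.
#'
#' @param seed integer master seed.
#' @param tag character tag naming the substream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  # 64-bit-safe modular mix done in doubles (exact below 2^53)
  x <- (abs(seed) %% 2147483647) * 48271 + h * 69621 + 11
  as.integer(x %% 2147483647)
}

stop_invalid <- function(...) {
  stop(structure(class = c("trfpid_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a finite numeric scalar")
  if (positive && x <= 0)
    stop_invalid(name, " must be > 0")
  invisible(x)
}

#' z-score columns of a matrix
#'
#' Constant columns are left at zero with a warning, matching the behaviour
#' required for degenerate feature channels.
#'
#' @param m numeric matrix.
#' @param warn warn on constant columns.
#' @return Matrix with column mean 0 and sd 1 (constant columns all-zero).
#' @keywords internal
zscore_cols <- function(m, warn = TRUE) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  m <- sweep(m, 2L, mu)
  s <- sqrt(colSums(m^2) / max(1L, nrow(m) - 1L))
  zero <- s < .Machine$double.eps^0.5
  if (any(zero) && warn)
    warning(sum(zero), " constant channel(s) left at 0 during z-scoring")
  s[zero] <- 1
  sweep(m, 2L, s, "/")
}

#' FFT-based resampling of a multichannel series
#'
#' Fourier-domain resampling (truncate or zero-pad the spectrum), the same
#' scheme as scipy.signal.resample; inherently anti-aliased for downsampling.
#'
#' @param m time x channel matrix.
#' @param n_out target number of samples.
#' @return Resampled matrix with `n_out` rows.
#' @keywords internal
fft_resample <- function(m, n_out) {
  m <- as.matrix(m)
  n_in <- nrow(m)
  if (n_out == n_in) return(m)
  out <- matrix(0, n_out, ncol(m))
  for (j in seq_len(ncol(m))) {
    X <- stats::fft(m[, j])
    Y <- complex(real = numeric(n_out), imaginary = numeric(n_out))
    nk <- min(n_in, n_out)
    half <- floor((nk + 1) / 2)
    Y[seq_len(half)] <- X[seq_len(half)]
    if (nk > 1) {
      nneg <- nk - half
      Y[n_out - seq_len(nneg) + 1L] <- X[n_in - seq_len(nneg) + 1L]
    }
    # keep a real Nyquist bin when truncating an even-length spectrum
    if (nk %% 2 == 0 && n_out < n_in)
      Y[half + 1L] <- Re(X[half + 1L])
    out[, j] <- Re(stats::fft(Y, inverse = TRUE)) / n_in
  }
  out
}

#' Pearson correlation with defined errors
#'
#' @param pred,obs equal-length numeric vectors, length >= 3, non-constant.
#' @return Sample Pearson correlation in `[-1, 1]`.
#' @export
pearson_score <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop_invalid("pred and obs must have equal length")
  if (length(pred) < 3L)
    stop_invalid("need at least 3 samples")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stop("undefined score: constant input series")
  stats::cor(pred, obs)
}

# circular shift of rows of a vector/matrix by k samples (k >= 0 moves down)
circshift_rows <- function(x, k) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  idx <- c((n - k + 1L):n, 1L:(n - k))
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
}
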