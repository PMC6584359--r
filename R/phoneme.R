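# Phoneme-locked analyses: event epoching, phoneme-related field averaging
# per manner-of-articulation class, MI time courses over the four classes
# after equipopulated binning, and PID of observed versus predicted epochs.

#' Epoch a continuous signal around event onsets
#'
#' Per event, samples from round(onset*rate) + round(window[1]*rate) through
#' round(onset*rate) + round(window[2]*rate) inclusive (onset-to-sample
#' rounding: nearest, ties toward the earlier sample). Events whose window
#' exceeds the recording are dropped with a message; overlapping epochs are
#' permitted and no baseline correction is applied.
#'
#' @param signal numeric vector.
#' @param events an [event_table()]; rows without a manner class are kept
#'   (their class is NA).
#' @param window c(start, end) in seconds relative to onset
#'   (default c(-0.1, 0.6)).
#' @param rate sampling rate of `signal` in Hz.
#' @return Object of class `epoch_set`: `epochs` (event x time matrix),
#'   `classes`, `window`, `rate`, `times` (seconds relative to onset).
#' @export
epoch_events <- function(signal, events, window = c(-0.1, 0.6), rate) {
  assert_scalar_num(rate, "rate", positive = TRUE)
  rel <- round(window[1] * rate):round(window[2] * rate)
  onset_idx <- ceiling(events$onset_s * rate - 0.5) + 1L
  lo <- onset_idx + rel[1L]; hi <- onset_idx + rel[length(rel)]
  keep <- lo >= 1L & hi <= length(signal)
  if (!any(keep)) stop("zero events survive epoching")
  if (any(!keep))
    message(sum(!keep), " event(s) dropped (window exceeds recording)")
  idx0 <- onset_idx[keep]
  ep <- matrix(0, sum(keep), length(rel))
  for (i in seq_along(idx0))
    ep[i, ] <- signal[idx0[i] + rel]
  structure(list(epochs = ep, classes = events$class[keep],
                 window = window, rate = rate, times = rel / rate),
            class = "epoch_set")
}

#' Per-class mean time courses (phoneme-related fields)
#'
#' @param epochs an [epoch_events()] result whose events carry classes.
#' @return class x time matrix of mean time courses.
#' @export
class_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  cls <- epochs$classes[!is.na(epochs$classes)]
  lev <- unique(cls)
  if (!length(lev)) stop("no events with a defined class")
  out <- matrix(0, length(lev), ncol(epochs$epochs),
                dimnames = list(lev, NULL))
  for (l in lev) {
    sel <- !is.na(epochs$classes) & epochs$classes == l
    if (!any(sel)) stop("empty class: ", l)
    out[l, ] <- colMeans(epochs$epochs[sel, , drop = FALSE])
  }
  out
}

#' MI about the manner classes at every epoch time point
#'
#' At each time sample, epoch values are discretized into `n_bins`
#' equipopulated bins and the plugin MI with the classes is computed.
#' Summing the returned time course gives the scalar objective used for
#' decoding-oriented source selection.
#'
#' @param epochs an [epoch_events()] result.
#' @param n_bins equipopulated bins (default 4).
#' @param miller_madow apply the Miller-Madow correction (default FALSE).
#' @return Numeric MI time course in bits (length = epoch samples).
#' @export
mi_timecourse <- function(epochs, n_bins = 4L, miller_madow = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  ok <- !is.na(epochs$classes)
  cls <- as.factor(epochs$classes[ok])
  if (any(table(cls) < 20L)) stop_invalid("need >= 20 events per class")
  apply(epochs$epochs[ok, , drop = FALSE], 2L, binned_mi, classes = cls,
        n_bins = n_bins, miller_madow = miller_madow)
}

#' PID of observed and predicted epochs about the manner classes
#'
#' At every epoch time point, a PID with the observed and the predicted
#' epoch values as sources and the manner classes as the discrete target.
#'
#' @param observed,predicted [epoch_events()] results over the same events
#'   and window.
#' @param n_mc Monte-Carlo samples per time point (default 2e4).
#' @param seed integer seed.
#' @return data.frame with one row per time point: time, redundancy,
#'   unique_observed, unique_predicted, synergy, mi_observed, mi_predicted.
#' @export
pid_timecourse <- function(observed, predicted, n_mc = 2e4, seed = 1L) {
  stopifnot(inherits(observed, "epoch_set"), inherits(predicted, "epoch_set"))
  if (!identical(dim(observed$epochs), dim(predicted$epochs)) ||
      !identical(observed$classes, predicted$classes))
    stop_invalid("observed and predicted epochs must match")
  ok <- !is.na(observed$classes)
  cls <- as.factor(observed$classes[ok])
  nt <- ncol(observed$epochs)
  out <- vector("list", nt)
  for (j in seq_len(nt)) {
    pid <- pid_ccs(observed$epochs[ok, j], predicted$epochs[ok, j], cls,
                   n_mc = n_mc, seed = derive_seed(seed, paste0("t", j)))
    out[[j]] <- data.frame(time = observed$times[j],
                           redundancy = pid$redundancy,
                           unique_observed = pid$unique_x,
                           unique_predicted = pid$unique_y,
                           synergy = pid$synergy,
                           mi_observed = pid$mi_x,
                           mi_predicted = pid$mi_y)
  }
  do.call(rbind, out)
}
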