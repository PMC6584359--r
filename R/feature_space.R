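# FeatureSpace: the package's central container for stimulus representations.
# A time x channel matrix at a stated sampling rate, with an ordered subspace
# partition so that joint spaces (e.g. "Sg & Deriv") remember which columns
# belong to which component.

#' Construct a FeatureSpace
#'
#' @param data time x channel numeric matrix.
#' @param rate sampling rate in Hz.
#' @param name identifier (e.g. "Sg", "Env", "Sg & Deriv").
#' @param subspaces named list mapping subspace name to integer channel
#'   indices; defaults to a single subspace covering all channels.
#' @param channel_names optional channel labels.
#' @return An object of class `feature_space`.
#' @export
feature_space <- function(data, rate, name = "features",
                          subspaces = NULL, channel_names = NULL) {
  data <- as.matrix(data)
  assert_scalar_num(rate, "rate", positive = TRUE)
  if (anyNA(data) || any(!is.finite(data)))
    stop_invalid("feature data must be finite and free of NA")
  if (is.null(subspaces))
    subspaces <- stats::setNames(list(seq_len(ncol(data))), name)
  idx <- unlist(subspaces, use.names = FALSE)
  if (length(idx) != ncol(data) || anyDuplicated(idx) ||
      !setequal(idx, seq_len(ncol(data))))
    stop_invalid("subspace ranges must partition the channel axis")
  if (!is.null(channel_names)) {
    stopifnot(length(channel_names) == ncol(data))
    colnames(data) <- channel_names
  }
  structure(list(data = data, rate = rate, name = name, subspaces = subspaces),
            class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space '%s'> %d samples x %d channels @ %g Hz\n",
              x$name, nrow(x$data), ncol(x$data), x$rate))
  cat("subspaces:",
      paste(sprintf("%s[%d]", names(x$subspaces),
                    lengths(x$subspaces)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_space <- function(x) dim(x$data)

n_samples <- function(fs) nrow(fs$data)
n_channels <- function(fs) ncol(fs$data)

#' Concatenate feature spaces column-wise into a joint space
#'
#' Joint spaces keep per-component bookkeeping so that downstream models can
#' assign each subspace its own lag window and regularization.
#'
#' @param spaces list of `feature_space` objects with equal rates and lengths.
#' @param name optional name; defaults to components joined by " & ".
#' @return A `feature_space` whose subspace partition records each component.
#' @export
concat_subspaces <- function(spaces, name = NULL) {
  stopifnot(is.list(spaces), length(spaces) >= 1L)
  if (length(spaces) == 1L) return(spaces[[1L]])
  rates <- vapply(spaces, function(s) s$rate, numeric(1))
  lens <- vapply(spaces, n_samples, numeric(1))
  if (length(unique(rates)) != 1L)
    stop_invalid("rate mismatch across spaces: ", paste(rates, collapse = ", "))
  if (length(unique(lens)) != 1L)
    stop_invalid("length mismatch across spaces: ", paste(lens, collapse = ", "))
  dat <- do.call(cbind, lapply(spaces, function(s) s$data))
  offs <- cumsum(c(0L, vapply(spaces, n_channels, integer(1))))
  subs <- list()
  for (i in seq_along(spaces)) {
    ss <- spaces[[i]]$subspaces
    # a multi-subspace component keeps its own partition, shifted
    for (nm in names(ss))
      subs[[nm]] <- ss[[nm]] + offs[i]
  }
  if (anyDuplicated(names(subs)))
    names(subs) <- make.unique(names(subs))
  if (is.null(name))
    name <- paste(vapply(spaces, function(s) s$name, character(1)),
                  collapse = " & ")
  feature_space(dat, rates[1L], name, subs)
}

#' Resample to a target rate and z-score all channels
#'
#' Acoustic feature spaces are computed at their native frame rate and then
#' brought to the modelling rate (default 40 Hz) by anti-aliased Fourier
#' resampling; every channel is z-scored over the full duration. Binary event
#' spaces are constructed directly at the target rate and only z-scored.
#'
#' @param fs a `feature_space`.
#' @param target_rate target sampling rate in Hz (default 40).
#' @return A `feature_space` at `target_rate` with unit-variance channels
#'   (constant channels are left at zero with a warning).
#' @export
preprocess <- function(fs, target_rate = 40) {
  stopifnot(inherits(fs, "feature_space"))
  assert_scalar_num(target_rate, "target_rate", positive = TRUE)
  if (fs$rate < target_rate)
    stop_invalid("cannot upsample: feature rate ", fs$rate,
                 " below target ", target_rate)
  dat <- fs$data
  if (fs$rate > target_rate) {
    n_out <- round(nrow(dat) * target_rate / fs$rate)
    dat <- fft_resample(dat, n_out)
  }
  dat <- zscore_cols(dat)
  feature_space(dat, target_rate, fs$name, fs$subspaces)
}
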