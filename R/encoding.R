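# Lagged ridge regression (multivariate temporal response functions).
#
# The forward model in discrete time is
#   r_hat(t) = sum_v sum_{tau = tMin..tMax} w(v, tau) s(v, t - tau)
# with tau > 0 meaning past stimulus samples predict the present response
# and tau < 0 meaning future samples. The closed-form ridge solution is
#   w = (S'S + Lambda)^-1 S'r
# where S is the lagged design and Lambda a block-diagonal penalty: when the
# feature space carries several subspaces, each subspace's columns receive
# their own lag window and regularization value.

#' Build the lagged design matrix
#'
#' Columns are organized in groups of columns per time lag, with neighboring
#' feature dimensions in neighboring columns within each lag group; each
#' subspace contributes its own block of lag groups. Out-of-range samples
#' are zero-padded.
#'
#' @param features a [feature_space()].
#' @param windows per-subspace lag windows: either a single c(tMin, tMax) in
#'   seconds applied to all subspaces, or a named list with one window per
#'   subspace.
#' @return List of class `lagged_design` with the design matrix `S`, the
#'   per-column subspace id and lag, and the per-subspace windows.
#' @export
build_lagged_design <- function(features, windows) {
  stopifnot(inherits(features, "feature_space"))
  wl <- normalize_windows(features, windows)
  n <- n_samples(features); rate <- features$rate
  blocks <- list(); col_sub <- integer(0); col_lag <- integer(0)
  for (s in names(features$subspaces)) {
    w <- wl[[s]]
    lags <- seq.int(round(w[1] * rate), round(w[2] * rate))
    if (max(abs(lags)) >= n)
      stop_invalid("lag window exceeds signal duration for subspace ", s)
    X <- features$data[, features$subspaces[[s]], drop = FALSE]
    for (tau in lags) {
      blocks[[length(blocks) + 1L]] <- shift_pad(X, tau)
      col_sub <- c(col_sub, rep(match(s, names(features$subspaces)), ncol(X)))
      col_lag <- c(col_lag, rep(tau, ncol(X)))
    }
  }
  structure(list(S = do.call(cbind, blocks), col_subspace = col_sub,
                 col_lag = col_lag, windows = wl, rate = rate,
                 subspace_names = names(features$subspaces)),
            class = "lagged_design")
}

normalize_windows <- function(features, windows) {
  if (is.numeric(windows) && length(windows) == 2L)
    windows <- stats::setNames(
      rep(list(windows), length(features$subspaces)),
      names(features$subspaces))
  missing <- setdiff(names(features$subspaces), names(windows))
  if (length(missing))
    stop_invalid("no lag window for subspace(s): ",
                 paste(missing, collapse = ", "))
  for (w in windows) if (w[1] > w[2]) stop_invalid("window needs tMin <= tMax")
  windows[names(features$subspaces)]
}

#' Fit a ridge TRF with a block-diagonal penalty
#'
#' Solves the penalized normal equations (S'S + Lambda) w = S'r, where each
#' subspace's diagonal block of Lambda carries its own regularization value.
#' No intercept is fitted; features and responses are expected to be
#' z-scored upstream.
#'
#' @param design a [build_lagged_design()] result.
#' @param response numeric vector (or time x channel matrix) matching the
#'   design rows.
#' @param lambdas per-subspace penalty values (scalar recycled; all >= 0).
#' @return An object of class `trf_model` with the weight vector/matrix `w`,
#'   per-column metadata, lambdas and windows.
#' @export
fit_ridge <- function(design, response, lambdas) {
  stopifnot(inherits(design, "lagged_design"))
  response <- as.matrix(response)
  if (nrow(response) != nrow(design$S))
    stop_invalid("design rows do not match response length")
  ns <- length(design$subspace_names)
  lambdas <- rep_len(lambdas, ns)
  if (any(lambdas < 0) || any(!is.finite(lambdas)))
    stop_invalid("lambdas must be finite and >= 0")
  C <- crossprod(design$S)
  b <- crossprod(design$S, response)
  w <- ridge_solve(C, b, lambdas[design$col_subspace])
  new_trf_model(w, design, lambdas)
}

# solve (C + diag(pen)) w = b, with a rank-deficiency error at pen = 0
ridge_solve <- function(C, b, pen) {
  if (any(pen == 0)) {
    ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < 1e-10 * max(diag(C)))
      stop("S'S is rank deficient and lambda = 0 for at least one subspace; ",
           "increase lambda")
  }
  diag(C) <- diag(C) + pen
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch))
    ch <- chol(C + diag(1e-10 * mean(diag(C)), nrow(C)))
  backsolve(ch, forwardsolve(t(ch), b))
}

new_trf_model <- function(w, design, lambdas) {
  structure(list(w = w, col_subspace = design$col_subspace,
                 col_lag = design$col_lag, windows = design$windows,
                 lambdas = lambdas, rate = design$rate,
                 subspace_names = design$subspace_names),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("<trf_model> %d coefficients @ %g Hz\n", NROW(x$w), x$rate))
  for (i in seq_along(x$subspace_names))
    cat(sprintf("  %s: window [%g, %g] s, lambda %.3g\n",
                x$subspace_names[i], x$windows[[i]][1], x$windows[[i]][2],
                x$lambdas[i]))
  invisible(x)
}

#' Weight tensor of one subspace as a channel x lag matrix
#'
#' @param model a `trf_model`.
#' @param subspace subspace name or index (default first).
#' @return channel x lag matrix with a `lags` attribute (samples).
#' @export
trf_weights <- function(model, subspace = 1L) {
  if (is.character(subspace)) subspace <- match(subspace, model$subspace_names)
  sel <- model$col_subspace == subspace
  lags <- model$col_lag[sel]
  w <- matrix(model$w[sel, 1L], ncol = length(unique(lags)))
  colnames(w) <- paste0("lag", unique(lags))
  attr(w, "lags") <- unique(lags)
  w
}

#' Predict the response from a fitted TRF
#'
#' @param object a `trf_model`.
#' @param features a [feature_space()] with the same subspaces/channels the
#'   model was trained on.
#' @param ... unused.
#' @return Predicted response vector (or matrix for multichannel fits).
#' @export
predict.trf_model <- function(object, features, ...) {
  stopifnot(inherits(features, "feature_space"))
  if (!identical(names(features$subspaces), object$subspace_names))
    stop_invalid("feature subspaces do not match the fitted model")
  design <- build_lagged_design(features, object$windows)
  if (ncol(design$S) != NROW(object$w))
    stop_invalid("feature channels do not match the fitted model")
  pred <- design$S %*% object$w
  if (ncol(pred) == 1L) drop(pred) else pred
}

#' Nested cross-validation scheme
#'
#' All ordered (test, tune) pairs of distinct portions; the remaining
#' portions form the training set. With `n_portions` portions this yields
#' `n_portions * (n_portions - 1)` assignments (30 for the default 6), and
#' every portion appears as test in `n_portions - 1` of them.
#'
#' @param n_portions number of equal-duration contiguous portions (>= 3).
#' @return Object of class `cv_scheme`: list of assignments with elements
#'   `test`, `tune`, `train`.
#' @export
make_cv_scheme <- function(n_portions = 6L) {
  if (n_portions < 3L) stop_invalid("need at least 3 portions")
  assignments <- list()
  for (te in seq_len(n_portions)) for (tu in seq_len(n_portions)) {
    if (tu == te) next
    assignments[[length(assignments) + 1L]] <-
      list(test = te, tune = tu, train = setdiff(seq_len(n_portions),
                                                 c(te, tu)))
  }
  structure(list(assignments = assignments, n_portions = n_portions),
            class = "cv_scheme")
}

portion_index <- function(n, n_portions) {
  sizes <- rep(floor(n / n_portions), n_portions)
  sizes[seq_len(n %% n_portions)] <- sizes[seq_len(n %% n_portions)] + 1L
  rep(seq_len(n_portions), sizes)
}

#' Nested cross-validation with black-box hyperparameter optimization
#'
#' Splits features and response into contiguous equal-duration portions.
#' For each outer fold (test portion) the inner loop runs once per tuning
#' portion: a derivative-free optimizer proposes per-subspace
#' (tMin, tMax, log10 lambda) combinations, each evaluated by training on
#' the four training portions and correlating the tuning-set prediction with
#' the observed tuning response, for `n_iter` objective evaluations. The
#' inner folds' chosen hyperparameters are then averaged (lag bounds in
#' seconds, rounded toward wider windows; lambda on the log10 scale),
#' weights are retrained on each of the five train assignments with the
#' averaged hyperparameters and averaged, and the averaged model predicts
#' the held-out test portion.
#'
#' Responses are z-scored within each portion before fitting.
#'
#' @param features a [feature_space()].
#' @param response numeric response vector.
#' @param scheme a [make_cv_scheme()] scheme.
#' @param bounds hyperparameter box from [default_trf_bounds()] (per-subspace
#'   tMin/tMax/log10 lambda bounds).
#' @param n_iter objective evaluations per inner fold (default 200).
#' @param seed integer seed for the optimizer.
#' @return Object of class `trf_cv`: per-outer-fold test predictions,
#'   Pearson scores, averaged hyperparameters, fitted weights, and the full
#'   optimizer traces.
#' @export
nested_cv <- function(features, response, scheme = make_cv_scheme(6L),
                      bounds = default_trf_bounds(features), n_iter = 200L,
                      seed = 1L) {
  stopifnot(inherits(features, "feature_space"), inherits(scheme, "cv_scheme"))
  n <- n_samples(features); rate <- features$rate
  if (length(response) != n) stop_invalid("response length mismatch")
  np <- scheme$n_portions
  pid <- portion_index(n, np)
  ns <- length(features$subspaces)

  # cache, per portion, the lagged design over the widest window in the box
  # (any sub-window's design is a column subset) and its cross-products
  wide <- widest_windows(bounds, ns)
  cache <- vector("list", np)
  for (p in seq_len(np)) {
    fsp <- feature_space(features$data[pid == p, , drop = FALSE], rate,
                         features$name, features$subspaces)
    d <- build_lagged_design(fsp, wide)
    r <- as.numeric(scale(response[pid == p]))
    cache[[p]] <- list(S = d$S, C = crossprod(d$S), b = crossprod(d$S, r),
                       r = r, col_subspace = d$col_subspace,
                       col_lag = d$col_lag)
  }
  col_sub <- cache[[1L]]$col_subspace
  col_lag <- cache[[1L]]$col_lag

  train_fit <- function(train, params) {
    sel <- param_col_sel(params, col_sub, col_lag, rate, ns)
    C <- Reduce(`+`, lapply(cache[train], function(z)
      z$C[sel$idx, sel$idx, drop = FALSE]))
    b <- Reduce(`+`, lapply(cache[train], function(z) z$b[sel$idx]))
    w <- ridge_solve(C, matrix(b, ncol = 1L), sel$pen)
    list(w = w, idx = sel$idx)
  }
  predict_portion <- function(fit, p)
    drop(cache[[p]]$S[, fit$idx, drop = FALSE] %*% fit$w)

  out_folds <- vector("list", np)
  traces <- list()
  for (a in seq_along(scheme$assignments)) {
    asg <- scheme$assignments[[a]]
    obj <- function(par) {
      fit <- train_fit(asg$train, par)
      pred <- predict_portion(fit, asg$tune)
      if (stats::sd(pred) == 0) return(-1)
      stats::cor(pred, cache[[asg$tune]]$r)
    }
    res <- optimize_blackbox(obj, bounds, n_iter = n_iter,
                             seed = derive_seed(seed, paste0("cv", a)))
    traces[[a]] <- res
    ofold <- asg$test
    out_folds[[ofold]]$best_params <- rbind(out_folds[[ofold]]$best_params,
                                            res$best_par)
  }

  results <- vector("list", np)
  for (te in seq_len(np)) {
    pars <- out_folds[[te]]$best_params
    avg <- average_hyperparams(pars, rate, ns)
    train_asgs <- Filter(function(z) z$test == te, scheme$assignments)
    fits <- lapply(train_asgs, function(z) train_fit(z$train, avg))
    wbar <- Reduce(`+`, lapply(fits, `[[`, "w")) / length(fits)
    fit <- list(w = wbar, idx = fits[[1L]]$idx)
    pred <- predict_portion(fit, te)
    results[[te]] <- list(
      test_portion = te, prediction = pred,
      observed = cache[[te]]$r,
      score = pearson_score(pred, cache[[te]]$r),
      hyperparams = avg, w = wbar,
      col_subspace = col_sub[fit$idx], col_lag = col_lag[fit$idx])
  }
  structure(list(folds = results, scheme = scheme, bounds = bounds,
                 traces = traces, rate = rate,
                 subspace_names = names(features$subspaces)),
            class = "trf_cv")
}

#' @export
print.trf_cv <- function(x, ...) {
  sc <- vapply(x$folds, `[[`, numeric(1), "score")
  cat(sprintf("<trf_cv> %d outer folds, mean test r = %.3f (range %.3f..%.3f)\n",
              length(x$folds), mean(sc), min(sc), max(sc)))
  invisible(x)
}

#' Per-fold test scores of a cross-validated TRF
#' @param cv a `trf_cv` object.
#' @return Numeric vector of per-outer-fold Pearson scores.
#' @export
cv_scores <- function(cv) vapply(cv$folds, `[[`, numeric(1), "score")

#' Consolidated weight tensor across outer folds
#'
#' Per-fold weight vectors are embedded on the union lag grid of a subspace
#' and averaged, yielding one channel x lag tensor for inspection or
#' comparison against a ground-truth kernel.
#'
#' @param cv a `trf_cv` object.
#' @param subspace subspace index or name.
#' @return channel x lag matrix with `lags` attribute.
#' @export
consolidate_trf <- function(cv, subspace = 1L) {
  if (is.character(subspace))
    subspace <- match(subspace, cv$subspace_names)
  all_lags <- sort(unique(unlist(lapply(cv$folds, function(f)
    f$col_lag[f$col_subspace == subspace]))))
  acc <- NULL
  for (f in cv$folds) {
    sel <- f$col_subspace == subspace
    lags <- f$col_lag[sel]
    nch <- sum(sel) / length(unique(lags))
    wm <- matrix(0, nch, length(all_lags))
    wf <- matrix(f$w[sel], nch)
    wm[, match(unique(lags), all_lags)] <- wf
    acc <- if (is.null(acc)) wm else acc + wm
  }
  acc <- acc / length(cv$folds)
  attr(acc, "lags") <- all_lags
  acc
}

# hyperparameter vector layout: per subspace (tMin_s, tMax_s, log10 lambda)
param_col_sel <- function(par, col_sub, col_lag, rate, ns) {
  idx <- logical(length(col_sub)); pen <- numeric(length(col_sub))
  for (s in seq_len(ns)) {
    p <- par[(s - 1L) * 3L + 1:3]
    lo <- round(p[1] * rate); hi <- round(p[2] * rate)
    if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
    keep <- col_sub == s & col_lag >= lo & col_lag <= hi
    idx <- idx | keep
    pen[keep] <- 10^p[3]
  }
  list(idx = which(idx), pen = pen[idx])
}

average_hyperparams <- function(pars, rate, ns) {
  avg <- numeric(ncol(pars))
  for (s in seq_len(ns)) {
    j <- (s - 1L) * 3L
    # round averaged lag bounds toward the wider window
    avg[j + 1L] <- floor(mean(pars[, j + 1L]) * rate) / rate
    avg[j + 2L] <- ceiling(mean(pars[, j + 2L]) * rate) / rate
    avg[j + 3L] <- mean(pars[, j + 3L])
  }
  avg
}

widest_windows <- function(bounds, ns) {
  wl <- list()
  for (s in seq_len(ns)) {
    j <- (s - 1L) * 3L
    wl[[s]] <- c(bounds$lower[j + 1L], bounds$upper[j + 2L])
  }
  stats::setNames(wl, bounds$subspace_names)
}

#' Default hyperparameter box for TRF tuning
#'
#' Per subspace: tMin in \[-0.3, 0\] s, tMax in \[0.05, 1\] s, log10 lambda
#' in \[-3, 8\]. These are repository defaults (the constraint ranges used
#' with real MEG data are study-specific) and are fully user-configurable.
#'
#' @param features the feature space to be modelled (defines subspaces).
#' @param tmin_range,tmax_range,log10_lambda_range per-parameter bounds.
#' @return A `hyper_box` (see [hyper_box()]) with 3 parameters per subspace.
#' @export
default_trf_bounds <- function(features, tmin_range = c(-0.3, 0),
                               tmax_range = c(0.05, 1),
                               log10_lambda_range = c(-3, 8)) {
  ns <- length(features$subspaces)
  nm <- names(features$subspaces)
  box <- hyper_box(
    name = as.vector(rbind(paste0(nm, ".tmin"), paste0(nm, ".tmax"),
                           paste0(nm, ".log10_lambda"))),
    lower = rep(c(tmin_range[1], tmax_range[1], log10_lambda_range[1]), ns),
    upper = rep(c(tmin_range[2], tmax_range[2], log10_lambda_range[2]), ns),
    init = rep(c(mean(tmin_range), mean(tmax_range),
                 mean(log10_lambda_range)), ns))
  box$subspace_names <- nm
  box
}

#' Block-rotation cross-validation with an exhaustive lambda grid
#'
#' EEG-style fitting: the recording is split into blocks; each block serves
#' as the test set once, one further block is the validation set and the
#' rest train. A single shared lambda is selected from `lambda_grid` by
#' validation performance (averaged over response channels), with a fixed
#' lag window. A warning is emitted if an extreme grid value is selected.
#'
#' @param features a [feature_space()].
#' @param response time x channel response matrix (or vector).
#' @param blocks number of blocks (default 20).
#' @param lag_window fixed c(tMin, tMax) in seconds (default c(-0.1, 0.4)).
#' @param lambda_grid candidate penalties (default `0.1^(-25..60)`, 86
#'   values).
#' @return Object of class `trf_cv_grid` with per-rotation test scores,
#'   selected lambdas and predictions.
#' @export
grid_search_cv <- function(features, response, blocks = 20L,
                           lag_window = c(-0.1, 0.4),
                           lambda_grid = 0.1^(-25:60)) {
  stopifnot(inherits(features, "feature_space"))
  if (length(lambda_grid) == 0L) stop_invalid("lambda grid is empty")
  if (blocks < 3L) stop_invalid("need at least 3 blocks")
  response <- as.matrix(response)
  n <- n_samples(features)
  if (nrow(response) != n) stop_invalid("response length mismatch")
  pid <- portion_index(n, blocks)
  cache <- vector("list", blocks)
  for (p in seq_len(blocks)) {
    fsp <- feature_space(features$data[pid == p, , drop = FALSE],
                         features$rate, features$name, features$subspaces)
    d <- build_lagged_design(fsp, lag_window)
    r <- zscore_cols(response[pid == p, , drop = FALSE], warn = FALSE)
    cache[[p]] <- list(S = d$S, C = crossprod(d$S), b = crossprod(d$S, r),
                       r = r)
  }
  rots <- vector("list", blocks)
  for (te in seq_len(blocks)) {
    va <- te %% blocks + 1L
    tr <- setdiff(seq_len(blocks), c(te, va))
    C <- Reduce(`+`, lapply(cache[tr], `[[`, "C"))
    b <- Reduce(`+`, lapply(cache[tr], `[[`, "b"))
    eg <- eigen(C, symmetric = TRUE)
    Ub <- crossprod(eg$vectors, b)
    val_scores <- vapply(lambda_grid, function(lam) {
      w <- eg$vectors %*% (Ub / (eg$values + lam))
      pred <- cache[[va]]$S %*% w
      mean(vapply(seq_len(ncol(pred)), function(j)
        if (stats::sd(pred[, j]) == 0) -1 else
          stats::cor(pred[, j], cache[[va]]$r[, j]), numeric(1)))
    }, numeric(1))
    k <- which.max(val_scores)
    if (k == 1L || k == length(lambda_grid))
      warning("extreme lambda grid value selected (index ", k, ")")
    w <- eg$vectors %*% (Ub / (eg$values + lambda_grid[k]))
    pred <- cache[[te]]$S %*% w
    test_r <- mean(vapply(seq_len(ncol(pred)), function(j)
      stats::cor(pred[, j], cache[[te]]$r[, j]), numeric(1)))
    rots[[te]] <- list(test_block = te, lambda = lambda_grid[k],
                       score = test_r, prediction = pred)
  }
  structure(list(rotations = rots, lambda_grid = lambda_grid,
                 lag_window = lag_window), class = "trf_cv_grid")
}
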