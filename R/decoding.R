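#' Add Gaussian observation noise to recorded rates
#'
#' Post-hoc i.i.d. zero-mean Gaussian noise on the excitatory rate matrix;
#' the underlying dynamics are untouched (noise models a noisy observation
#' channel, not intrinsic variability).
#'
#' @param rates n_e x T rate matrix (or a `session_recording`, whose `r_E` is
#'   used).
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return Noisy rate matrix of the same dimension.
#' @export
add_observation_noise <- function(rates, sigma, seed = 1L) {
  if (inherits(rates, "session_recording")) rates <- rates$r_E
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(rates)
  rates + with_seed(seed, matrix(stats::rnorm(length(rates), 0, sigma),
                                 nrow(rates), ncol(rates)))
}

# Default noise grid: log-spaced 1e-6..10, 15 values.
default_sigma_grid <- function() 10^seq(-6, 1, length.out = 15)

# Window-mean features for every trial at a given window start (in steps,
# 0-based within the trial). `cums` is the 0-padded row cumsum of the rate
# matrix (n_e x (T+1)).
window_features <- function(cums, L, n_trials, start, wlen) {
  n_e <- nrow(cums)
  feats <- matrix(0, n_trials, n_e)
  for (k in seq_len(n_trials)) {
    i0 <- (k - 1) * L + start
    feats[k, ] <- (cums[, i0 + wlen + 1] - cums[, i0 + 1]) / wlen
  }
  feats
}

# Stratified k-fold assignment of trials by label.
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# L2-regularized logistic classifier accuracy on one train/test split.
# Features are standardized inside the fit so the penalty is scale-free;
# with no informative feature the fit collapses to the intercept and the
# classifier falls back to the majority class.
fit_predict_accuracy <- function(x_tr, y_tr, x_te, y_te, lambda) {
  if (length(unique(y_tr)) < 2)
    stop("a class is absent from the training fold", call. = FALSE)
  sds <- apply(x_tr, 2, stats::sd)
  if (all(sds == 0)) {  # degenerate: no variation at all -> majority rule
    maj <- names(which.max(table(y_tr)))
    return(mean(maj == y_te))
  }
  # separable clean data drives the unpenalized directions to the iteration
  # cap; the returned solution still classifies correctly
  fit <- suppressWarnings(
    glmnet::glmnet(x_tr, factor(y_tr, levels = c("X", "Y")),
                   family = "binomial", alpha = 0,
                   lambda = lambda, standardize = TRUE))
  pred <- stats::predict(fit, newx = x_te, type = "class")
  mean(pred == y_te)
}

#' Sliding-window linear decoding of stimulus identity under noise
#'
#' For each window start and noise level, Gaussian observation noise is added
#' to the excitatory rates (independently redrawn for every fold), features
#' are the window-mean rates of each excitatory unit per trial, and an
#' L2-regularized logistic classifier is scored by stratified k-fold
#' cross-validation over trials. A whole-trial entry (window spanning the
#' trial) is included as `window_ms = NA`.
#'
#' @param recording `session_recording` (or a rate matrix n_e x T).
#' @param sequence the session's `stimulus_sequence`.
#' @param window window length in seconds (default 0.2).
#' @param stride window stride in seconds (default `dt`; coarser strides cut
#'   cost proportionally).
#' @param sigma_grid noise standard deviations (default log-spaced 1e-6..10
#'   plus 0).
#' @param folds number of stratified CV folds (default 5).
#' @param lambda ridge penalty for the logistic fit (default `1/n_train`,
#'   i.e. unit-strength regularization on the summed loss).
#' @param seed base seed for folds and noise.
#' @param whole_trial include the pooled whole-trial window (default TRUE).
#' @return An object of class `decoding_result`: data.frame `accuracy`
#'   (window_ms, sigma, accuracy = mean over folds), `baseline`
#'   (majority-class rate), plus the grid metadata.
#' @export
sliding_window_decode <- function(recording, sequence, window = 0.2,
                                  stride = NULL,
                                  sigma_grid = c(0, default_sigma_grid()),
                                  folds = 5, lambda = NULL, seed = 1L,
                                  whole_trial = TRUE) {
  rates <- if (inherits(recording, "session_recording")) recording$r_E else recording
  dt <- if (inherits(recording, "session_recording")) recording$dt else sequence$protocol$dt
  L <- if (inherits(recording, "session_recording")) recording$steps_per_trial
       else round(sequence$protocol$isi / dt)
  labels <- sequence$labels
  n_trials <- length(labels)
  if (is.null(stride)) stride <- dt
  wlen <- round(window / dt)
  starts <- seq(0L, L - wlen, by = max(1L, round(stride / dt)))
  fold <- stratified_folds(labels, folds, seed)
  base_rate <- max(mean(labels == "X"), mean(labels == "Y"))
  rows <- list()
  for (si in seq_along(sigma_grid)) {
    sg <- sigma_grid[si]
    acc_win <- matrix(0, length(starts), folds)
    acc_all <- numeric(folds)
    for (f in seq_len(folds)) {
      noisy <- add_observation_noise(rates, sg,
                                     seed = seed + 1000L * si + f)
      cums <- cbind(0, t(apply(noisy, 1, cumsum)))
      if (nrow(noisy) == 1) cums <- matrix(c(0, cumsum(noisy[1, ])), nrow = 1)
      te <- fold == f
      n_tr <- sum(!te)
      lam <- if (is.null(lambda)) 1 / n_tr else lambda
      for (wi in seq_along(starts)) {
        feats <- window_features(cums, L, n_trials, starts[wi], wlen)
        acc_win[wi, f] <- fit_predict_accuracy(feats[!te, , drop = FALSE],
                                               labels[!te],
                                               feats[te, , drop = FALSE],
                                               labels[te], lam)
      }
      if (whole_trial) {
        feats <- window_features(cums, L, n_trials, 0L, L)
        acc_all[f] <- fit_predict_accuracy(feats[!te, , drop = FALSE],
                                           labels[!te],
                                           feats[te, , drop = FALSE],
                                           labels[te], lam)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      window_ms = starts * dt * 1000, sigma = sg,
      accuracy = rowMeans(acc_win))
    if (whole_trial)
      rows[[length(rows) + 1L]] <- data.frame(
        window_ms = NA_real_, sigma = sg, accuracy = mean(acc_all))
  }
  structure(list(accuracy = do.call(rbind, rows), baseline = base_rate,
                 sigma_grid = sigma_grid, window = window, folds = folds),
            class = "decoding_result")
}

#' Contrast two decoding surfaces
#'
#' Cell-wise accuracy difference of two matched decoding grids; when lists of
#' per-instance results are supplied, adds paired-across-instances t
#' statistics per cell.
#'
#' @param result_a,result_b `decoding_result`s, or lists of them (one per
#'   instance, matching order).
#' @return data.frame (window_ms, sigma, diff) plus `t` and `p` columns for
#'   the instance-list form.
#' @export
condition_contrast <- function(result_a, result_b) {
  pair_key <- function(df) paste(df$window_ms, df$sigma)
  if (inherits(result_a, "decoding_result")) {
    a <- result_a$accuracy; b <- result_b$accuracy
    if (!identical(pair_key(a), pair_key(b)))
      stop("decoding grids do not match", call. = FALSE)
    return(data.frame(window_ms = a$window_ms, sigma = a$sigma,
                      diff = a$accuracy - b$accuracy))
  }
  stopifnot(length(result_a) == length(result_b), length(result_a) >= 2)
  diffs <- mapply(function(ra, rb) {
    a <- ra$accuracy; b <- rb$accuracy
    if (!identical(pair_key(a), pair_key(b)))
      stop("decoding grids do not match", call. = FALSE)
    a$accuracy - b$accuracy
  }, result_a, result_b)
  tmpl <- result_a[[1]]$accuracy
  mn <- rowMeans(diffs)
  sdv <- apply(diffs, 1, stats::sd)
  n <- ncol(diffs)
  tstat <- ifelse(sdv > 0, mn / (sdv / sqrt(n)), ifelse(mn == 0, 0, Inf))
  p <- ifelse(is.finite(tstat), 2 * stats::pt(-abs(tstat), df = n - 1), 0)
  data.frame(window_ms = tmpl$window_ms, sigma = tmpl$sigma,
             diff = mn, t = tstat, p = p)
}
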