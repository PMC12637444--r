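#' Initialize a recursive-least-squares (RLS) state
#'
#' FORCE training maintains a running inverse-correlation matrix
#' `P = (R^T R + alpha I)^{-1}` over the regressor stream, with
#' `P(0) = I / alpha` and `W_out(0) = 0`.
#'
#' @param n number of regressors (frontal excitatory units).
#' @param alpha positive ridge regularizer (default 1).
#' @param k number of readout channels (default 2).
#' @return An object of class `rls_state` with `W_out` (k x n), `P` (n x n),
#'   `alpha`.
#' @export
rls_state <- function(n, alpha = 1, k = 2) {
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  structure(list(W_out = matrix(0, k, n), P = diag(n) / alpha, alpha = alpha),
            class = "rls_state")
}

#' One RLS / FORCE update
#'
#' With regressor `r` and target `target`: the error `e = W_out r - target` is
#' computed with the pre-update weights, `P` is updated first
#' (`P <- P - (P r r^T P)/(1 + r^T P r)`, then symmetrized), and the weight
#' step uses the updated matrix: `W_out <- W_out - e (P_new r)^T`. Run over a
#' stream of pairs this reproduces the ridge regression solution of the same
#' stream exactly.
#'
#' @param state an [rls_state()].
#' @param r regressor vector (length n).
#' @param target target vector (length k).
#' @return Updated `rls_state` with an `error` field (pre-update error).
#' @export
rls_update <- function(state, r, target) {
  stopifnot(inherits(state, "rls_state"))
  e <- unname(drop(state$W_out %*% r) - target)
  Pr <- drop(state$P %*% r)
  denom <- 1 + sum(r * Pr)
  P <- state$P - tcrossprod(Pr) / denom
  P <- (P + t(P)) / 2
  if (!all(is.finite(P))) stop("non-finite P in RLS update", call. = FALSE)
  k_gain <- drop(P %*% r)
  state$W_out <- state$W_out - outer(e, k_gain)
  state$P <- P
  state$error <- e
  state
}

#' Specify the depressing feedback pathway of the active model
#'
#' Readout units project back onto frontal excitatory units only, with
#' weights U\[0, gain_fb); the feedback synapses carry their own STD resource
#' `x_y` with recovery time constant `tau_xy`.
#'
#' @param gain_fb positive feedback gain (default 0.1, mirroring the
#'   feedforward reference strength).
#' @param tau_xy feedback STD time constant in seconds (default 20).
#' @return An object of class `feedback_spec`.
#' @export
feedback_spec <- function(gain_fb = 0.1, tau_xy = 20) {
  if (gain_fb < 0) stop("`gain_fb` must be >= 0", call. = FALSE)
  structure(list(gain_fb = gain_fb, tau_xy = tau_xy), class = "feedback_spec")
}

#' Sample feedback weights
#'
#' @param spec a [feedback_spec()].
#' @param n_e number of frontal excitatory units.
#' @param seed integer seed.
#' @param k number of readout channels.
#' @return The `spec` with `W_fb` (n_e x k) filled in.
#' @export
init_feedback <- function(spec, n_e = 80, seed = 1L, k = 2) {
  stopifnot(inherits(spec, "feedback_spec"))
  spec$W_fb <- with_seed(seed, matrix(stats::runif(n_e * k, 0, spec$gain_fb),
                                      n_e, k))
  spec$seed <- as.integer(seed)
  spec
}

#' Create an active-oddball model instance
#'
#' A [hierarchical_instance()] augmented with a linear readout
#' `y = g_out W_out r_2E` from the frontal excitatory units and a depressing
#' feedback path `W_fb (x_y * y)` onto frontal excitatory units.
#'
#' @param config a [model_config()].
#' @param ff a [feedforward_spec()].
#' @param fb a [feedback_spec()].
#' @param g_out readout gain (default 1, plain linear readout).
#' @param fb_seed seed for the feedback weights.
#' @param ... passed to [hierarchical_instance()].
#' @return An object of class `active_instance`.
#' @export
active_instance <- function(config = model_config(), ff = feedforward_spec(),
                            fb = feedback_spec(), g_out = 1,
                            fb_seed = config$seed + 300007L, ...) {
  hier <- hierarchical_instance(config, ff, ...)
  if (is.null(fb$W_fb)) fb <- init_feedback(fb, n_e = config$n_e, seed = fb_seed)
  structure(c(unclass(hier), list(fb = fb, g_out = g_out)),
            class = c("active_instance", "hierarchical_instance"))
}

# Teacher signal: one-hot target held for each full trial window
# (onset to next onset), 2 x T, channel order (X, Y).
teacher_signal <- function(sequence, input) {
  L <- input$steps_per_trial
  n <- length(sequence$labels)
  yt <- matrix(0, 2, n * L, dimnames = list(c("X", "Y"), NULL))
  for (k in seq_len(n)) {
    ch <- if (sequence$labels[k] == "X") 1L else 2L
    yt[ch, (k - 1L) * L + seq_len(L)] <- 1
  }
  yt
}

#' Train the readout with FORCE learning
#'
#' Simulates `n_sessions` freshly drawn oddball sessions with teacher-forced
#' feedback (the one-hot target, not the produced readout, drives the
#' depressing feedback path) and updates `W_out` by RLS every `stride`
#' timesteps. The sensory region is feedback-free, so it is simulated first
#' and its feedforward drive handed to the compiled training loop.
#'
#' @param instance an [active_instance()].
#' @param protocol a [stimulus_protocol()]; each training session uses seed
#'   `protocol$seed + session - 1`.
#' @param alpha RLS regularizer (default 1).
#' @param n_sessions number of training sessions (default 5).
#' @param stride RLS update stride in timesteps (default 1).
#' @return list with `W_out`, final `P`, and `training_log` (data.frame of
#'   session mean absolute errors).
#' @export
train_force <- function(instance, protocol, alpha = 1, n_sessions = 5,
                        stride = 1) {
  stopifnot(inherits(instance, "active_instance"))
  cfg <- instance$config
  st <- rls_state(cfg$n_e, alpha = alpha)
  W_out <- st$W_out; P <- st$P
  log <- data.frame(session = integer(0), mean_abs_error = numeric(0))
  w2 <- instance$frontal$weights
  for (s in seq_len(n_sessions)) {
    proto_s <- protocol
    proto_s$seed <- protocol$seed + s - 1L
    seqn <- generate_sequence(proto_s)
    input <- render_input(seqn, proto_s)
    rec1 <- simulate_sensory(instance$sensory, input)
    ff_drive <- instance$ff$W_12 %*% rec1$r_E
    yt <- teacher_signal(seqn, input)
    res <- cpp_force_train(w2$W_EE, w2$W_EI, w2$W_IE, w2$W_II,
                           ff_drive, instance$fb$W_fb, yt,
                           W_out, P, instance$g_out,
                           cfg$dt, cfg$tau, instance$fb$tau_xy,
                           as.integer(stride))
    W_out <- res$W_out; P <- res$P
    log <- rbind(log, data.frame(session = s,
                                 mean_abs_error = mean(res$error_log)))
  }
  list(W_out = W_out, P = P, training_log = log)
}

#' Simulate the active model in closed loop
#'
#' The frozen readout `y = g_out W_out r_2E` is computed each step and fed
#' back through the depressing feedback synapses. The STD update of the
#' feedback resource uses the rectified readout `max(0, y)` so transient
#' negative readout values cannot push the resource above 1; the feedback
#' drive itself uses the raw readout. With `W_out = 0` (or `W_fb = 0`) the
#' simulation reduces exactly to the passive hierarchy.
#'
#' @param instance an [active_instance()].
#' @param input an [render_input()] input time series.
#' @param W_out trained readout weights (2 x n_e).
#' @param std_enabled logical, STD on sensory input synapses.
#' @return list with `recording` (a `hierarchical_recording`) and `readout`
#'   (class `readout_trace`: `y` 2 x T, `x_y` 2 x T).
#' @export
simulate_active <- function(instance, input, W_out, std_enabled = TRUE) {
  stopifnot(inherits(instance, "active_instance"))
  cfg <- instance$config
  rec1 <- simulate_sensory(instance$sensory, input, std_enabled = std_enabled)
  w2 <- instance$frontal$weights
  ff_drive <- instance$ff$W_12 %*% rec1$r_E
  res <- cpp_simulate_active(w2$W_EE, w2$W_EI, w2$W_IE, w2$W_II,
                             ff_drive, instance$fb$W_fb, W_out,
                             instance$g_out, cfg$dt, cfg$tau,
                             instance$fb$tau_xy)
  rec2 <- structure(list(r_E = res$r_E, r_I = res$r_I, x_trace = NULL,
                         dt = cfg$dt,
                         steps_per_trial = input$steps_per_trial),
                    class = "session_recording")
  readout <- structure(list(y = res$y, x_y = res$x_y, dt = cfg$dt,
                            steps_per_trial = input$steps_per_trial),
                       class = "readout_trace")
  list(recording = structure(list(sensory = rec1, frontal = rec2),
                             class = "hierarchical_recording"),
       readout = readout)
}

#' Per-timestep confusion matrix of the readout
#'
#' Within each trial window (onset to next onset) the predicted label at each
#' timestep is the argmax over the two readout units; entries are the
#' fraction of in-trial timesteps per true label (rows sum to 1). Row/column
#' order is (standard, deviant).
#'
#' @param readout a `readout_trace` from [simulate_active()].
#' @param sequence the test-session `stimulus_sequence`.
#' @return 2 x 2 row-normalized matrix with dimnames
#'   `(true standard/deviant) x (predicted standard/deviant)`.
#' @export
confusion_matrix <- function(readout, sequence) {
  stopifnot(inherits(readout, "readout_trace"),
            inherits(sequence, "stimulus_sequence"))
  L <- readout$steps_per_trial
  n <- length(sequence$labels)
  if (ncol(readout$y) < n * L) stop("readout shorter than the trial set", call. = FALSE)
  if (n == 0) stop("empty trial set", call. = FALSE)
  pred <- ifelse(readout$y[1, ] >= readout$y[2, ], "X", "Y")
  lv <- c(sequence$standard, sequence$deviant)
  counts <- matrix(0, 2, 2, dimnames = list(true = lv, predicted = lv))
  for (k in seq_len(n)) {
    idx <- (k - 1L) * L + seq_len(L)
    tab <- table(factor(pred[idx], levels = lv))
    counts[sequence$labels[k], ] <- counts[sequence$labels[k], ] + tab
  }
  sweep(counts, 1, pmax(rowSums(counts), 1), "/")
}
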