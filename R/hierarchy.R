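#' Specify the sensory-to-frontal feedforward projection
#'
#' Between-region connections are excitatory-to-excitatory only. Connections
#' exist with probability `density`; existing weights are drawn U\[0, gain).
#'
#' @param gain positive feedforward gain `g` (default 0.1, the reference
#'   connection strength G).
#' @param density connection probability in \[0, 1\] (default 1, full density).
#' @return An object of class `feedforward_spec`.
#' @export
feedforward_spec <- function(gain = 0.1, density = 1.0) {
  if (gain < 0) stop("`gain` must be >= 0", call. = FALSE)
  if (density < 0 || density > 1)
    stop("`density` must lie in [0, 1]", call. = FALSE)
  structure(list(gain = gain, density = density), class = "feedforward_spec")
}

#' Sample feedforward weights
#'
#' Draws the Bernoulli(`density`) mask and the U\[0, gain) weights of the
#' sensory-E to frontal-E projection `W_12`.
#'
#' @param spec a [feedforward_spec()].
#' @param n_e number of excitatory units per region.
#' @param seed integer seed.
#' @return The `spec` with `mask` and `W_12` (n_e x n_e) filled in.
#' @export
init_feedforward <- function(spec, n_e = 80, seed = 1L) {
  stopifnot(inherits(spec, "feedforward_spec"))
  out <- with_seed(seed, {
    mask <- matrix(stats::runif(n_e * n_e) < spec$density, n_e, n_e)
    w <- matrix(stats::runif(n_e * n_e, 0, spec$gain), n_e, n_e) * mask
    list(mask = mask * 1, W_12 = w)
  })
  spec$mask <- out$mask
  spec$W_12 <- out$W_12
  spec$seed <- as.integer(seed)
  spec
}

#' Create a two-region (sensory + frontal) model instance
#'
#' The frontal region is an independent E/I network built by the same
#' procedure as the sensory one (distinct seed stream) and receives no direct
#' stimulus input; its excitatory units are driven by `W_12 %*% r_1E`.
#' Frontal inhibitory units receive no feedforward drive.
#'
#' @param config a [model_config()]; `config$seed` seeds the sensory weights,
#'   the frontal weights use an offset stream.
#' @param ff a [feedforward_spec()]; sampled here if its weights are absent.
#' @param frontal_seed seed for the frontal recurrent weights.
#' @param ff_seed seed for the feedforward weights.
#' @return An object of class `hierarchical_instance` with elements
#'   `sensory` and `frontal` ([network_instance()]s) and `ff`.
#' @export
hierarchical_instance <- function(config = model_config(),
                                  ff = feedforward_spec(),
                                  frontal_seed = config$seed + 100003L,
                                  ff_seed = config$seed + 200003L) {
  sensory <- network_instance(config)
  frontal_cfg <- config
  frontal_cfg$seed <- as.integer(frontal_seed)
  frontal <- network_instance(frontal_cfg)
  if (is.null(ff$W_12)) ff <- init_feedforward(ff, n_e = config$n_e, seed = ff_seed)
  structure(list(sensory = sensory, frontal = frontal, ff = ff,
                 config = config),
            class = "hierarchical_instance")
}

#' @export
print.hierarchical_instance <- function(x, ...) {
  cat(sprintf("Two-region model: %d+%d units per region, feedforward gain %g, density %g\n",
              x$config$n_e, x$config$n_i, x$ff$gain, x$ff$density))
  invisible(x)
}

#' Simulate the passive two-region model
#'
#' The sensory region is integrated exactly as in [simulate_sensory()] (the
#' feedforward projection is one-way, so sensory dynamics are unaffected by
#' the frontal region); the frontal region is then integrated with external
#' drive `W_12 %*% r_1E` on its excitatory units.
#'
#' @param instance a [hierarchical_instance()].
#' @param input an [render_input()] input time series.
#' @param std_enabled logical, STD on the sensory input synapses.
#' @param sensory_recording optional precomputed sensory
#'   `session_recording` (to reuse across feedforward settings).
#' @return An object of class `hierarchical_recording` with fields `sensory`
#'   and `frontal`, each a `session_recording`.
#' @export
simulate_hierarchy <- function(instance, input, std_enabled = TRUE,
                               sensory_recording = NULL) {
  stopifnot(inherits(instance, "hierarchical_instance"),
            inherits(input, "input_timeseries"))
  cfg <- instance$config
  rec1 <- if (is.null(sensory_recording)) {
    simulate_sensory(instance$sensory, input, std_enabled = std_enabled)
  } else {
    sensory_recording
  }
  rec2 <- simulate_frontal(instance, rec1)
  structure(list(sensory = rec1, frontal = rec2),
            class = "hierarchical_recording")
}

# Integrate the frontal region given a sensory recording.
simulate_frontal <- function(instance, sensory_recording) {
  cfg <- instance$config
  w2 <- instance$frontal$weights
  ff_drive <- instance$ff$W_12 %*% sensory_recording$r_E
  res <- cpp_simulate_region(w2$W_EE, w2$W_EI, w2$W_IE, w2$W_II,
                             ff_drive,
                             matrix(0, cfg$n_i, ncol(ff_drive)),
                             cfg$dt, cfg$tau)
  structure(list(r_E = res$r_E, r_I = res$r_I, x_trace = NULL,
                 dt = cfg$dt,
                 steps_per_trial = sensory_recording$steps_per_trial),
            class = "session_recording")
}
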