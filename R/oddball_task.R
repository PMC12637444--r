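#' Define an oddball stimulus protocol
#'
#' An oddball session presents one of two stimuli, X and Y, at regular
#' interstimulus intervals (ISI). Labels are drawn i.i.d. with probabilities
#' `p_x` and `p_y = 1 - p_x`; the lower-probability stimulus is the *deviant*,
#' the higher-probability one the *standard*.
#'
#' @param n_trials number of trials in the session (total across both
#'   stimuli; default 100, i.e. a 200 s session at the default 2 s ISI).
#' @param p_x probability of stimulus X on each trial (default 0.8).
#' @param isi interstimulus (onset-to-onset) interval in seconds (default 2).
#' @param stim_duration stimulus duration in seconds (default 0.2).
#' @param dt sampling step in seconds (default 0.01).
#' @param seed integer seed for the label sequence.
#' @return An object of class `stimulus_protocol`.
#' @examples
#' proto <- stimulus_protocol(n_trials = 10, p_x = 0.8, seed = 1)
#' proto
#' @export
stimulus_protocol <- function(n_trials = 100, p_x = 0.8, isi = 2,
                              stim_duration = 0.2, dt = 0.01, seed = 1L) {
  if (!is.numeric(p_x) || length(p_x) != 1L || p_x < 0 || p_x > 1)
    stop("`p_x` must be a probability in [0, 1]", call. = FALSE)
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  if (stim_duration > isi)
    stop("`stim_duration` must not exceed `isi`", call. = FALSE)
  if (dt <= 0 || dt > stim_duration)
    stop("`dt` must be positive and no larger than `stim_duration`", call. = FALSE)
  structure(
    list(n_trials = as.integer(n_trials), p_x = p_x, p_y = 1 - p_x,
         isi = isi, stim_duration = stim_duration, dt = dt,
         seed = as.integer(seed)),
    class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "Oddball protocol: %d trials, p_X = %.2f / p_Y = %.2f, ISI %.2g s, stimulus %.3g s, dt %.3g s, seed %d\n",
    x$n_trials, x$p_x, x$p_y, x$isi, x$stim_duration, x$dt, x$seed))
  invisible(x)
}

#' Draw an oddball label sequence
#'
#' Labels are drawn i.i.d. from \{X, Y\} with the protocol probabilities.
#' Onsets are regular: trial k (0-based) starts at `k * isi` seconds. The
#' lower-probability label is tagged as the deviant; at `p_x = 0.5` the tie is
#' broken by assigning Y as deviant and the sequence is flagged as tied.
#'
#' @param protocol a [stimulus_protocol()].
#' @return An object of class `stimulus_sequence` with fields `labels`
#'   (character vector of "X"/"Y"), `onset_times` (seconds), `standard`,
#'   `deviant`, and `tie` (logical).
#' @examples
#' seq <- generate_sequence(stimulus_protocol(n_trials = 20, seed = 7))
#' table(seq$labels)
#' @export
generate_sequence <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  labels <- with_seed(protocol$seed, {
    sample(c("X", "Y"), protocol$n_trials, replace = TRUE,
           prob = c(protocol$p_x, protocol$p_y))
  })
  tie <- protocol$p_x == 0.5
  deviant <- if (protocol$p_x >= 0.5) "Y" else "X"
  structure(
    list(labels = labels,
         onset_times = (seq_len(protocol$n_trials) - 1) * protocol$isi,
         standard = setdiff(c("X", "Y"), deviant),
         deviant = deviant, tie = tie,
         protocol = protocol),
    class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("Oddball sequence: %d trials (%d X, %d Y), deviant = %s%s\n",
              length(x$labels), sum(x$labels == "X"), sum(x$labels == "Y"),
              x$deviant, if (x$tie) " (tie at p = 0.5)" else ""))
  invisible(x)
}

#' Render a label sequence as a binary one-hot input drive
#'
#' Produces the 2 x T input matrix `u` driving the sensory network: channel 1
#' is stimulus X, channel 2 stimulus Y. The channel of trial k is 1 on the
#' half-open interval `[k*isi, k*isi + stim_duration)` and 0 elsewhere, so
#' each trial contributes exactly `round(stim_duration/dt)` active steps.
#'
#' @param sequence a [generate_sequence()] result.
#' @param protocol the protocol; defaults to the one stored in `sequence`.
#' @return An object of class `input_timeseries`: list with `u` (2 x T binary
#'   matrix, rownames "X"/"Y"), `dt`, `n_steps`, and the per-trial step count
#'   `steps_per_trial`.
#' @examples
#' proto <- stimulus_protocol(n_trials = 3, seed = 1)
#' inp <- render_input(generate_sequence(proto))
#' dim(inp$u)
#' @export
render_input <- function(sequence, protocol = sequence$protocol) {
  stopifnot(inherits(sequence, "stimulus_sequence"),
            inherits(protocol, "stimulus_protocol"))
  if (protocol$stim_duration > protocol$isi)
    stop("`stim_duration` must not exceed `isi`", call. = FALSE)
  steps_trial <- round(protocol$isi / protocol$dt)
  steps_on <- round(protocol$stim_duration / protocol$dt)
  if (abs(steps_trial * protocol$dt - protocol$isi) > 1e-9 ||
      abs(steps_on * protocol$dt - protocol$stim_duration) > 1e-9)
    stop("`dt` must divide `isi` and `stim_duration`", call. = FALSE)
  n <- length(sequence$labels)
  T_steps <- n * steps_trial
  u <- matrix(0, nrow = 2, ncol = T_steps, dimnames = list(c("X", "Y"), NULL))
  for (k in seq_len(n)) {
    ch <- if (sequence$labels[k] == "X") 1L else 2L
    idx <- (k - 1L) * steps_trial + seq_len(steps_on)
    u[ch, idx] <- 1
  }
  structure(list(u = u, dt = protocol$dt, n_steps = T_steps,
                 steps_per_trial = steps_trial, steps_on = steps_on),
            class = "input_timeseries")
}

#' Export a stimulus sequence as a trial table
#'
#' @param sequence a `stimulus_sequence`.
#' @param path optional path; when given, the table is written as CSV.
#' @return A data.frame with columns `trial`, `onset_s`, `label`, `role`
#'   (standard/deviant), invisibly when written to file.
#' @export
sequence_table <- function(sequence, path = NULL) {
  stopifnot(inherits(sequence, "stimulus_sequence"))
  df <- data.frame(trial = seq_along(sequence$labels),
                   onset_s = sequence$onset_times,
                   label = sequence$labels,
                   role = ifelse(sequence$labels == sequence$deviant,
                                 "deviant", "standard"))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so package randomness never perturbs the
# user's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
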