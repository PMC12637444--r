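#' Trial-aligned average responses and the deviant-standard difference trace
#'
#' The population response is the mean rate over excitatory units (inhibitory
#' units are excluded from all summaries). It is cut into onset-aligned trial
#' windows of length `round(isi/dt)` and averaged over trials of each label.
#'
#' @param recording a `session_recording` (sensory) or
#'   `hierarchical_recording` (pick `region`).
#' @param sequence the session's `stimulus_sequence`.
#' @param region "sensory" or "frontal" (ignored for plain recordings).
#' @param discard_first number of initial trials dropped before averaging
#'   (default 0).
#' @return An object of class `erp_summary`: `trace_X`, `trace_Y`,
#'   `mean_trace_standard`, `mean_trace_deviant`, `diff_trace`
#'   (deviant - standard), `diff_trace_yx` (Y - X, fixed labels),
#'   `time_ms` (window-relative sample times), `peak_latency_ms`,
#'   `peak_amplitude`, and `mean_amplitude` (time-mean of `diff_trace` over
#'   the 0-500 ms analysis window).
#' @export
trial_average <- function(recording, sequence, region = c("sensory", "frontal"),
                          discard_first = 0) {
  region <- match.arg(region)
  if (inherits(recording, "hierarchical_recording"))
    recording <- recording[[region]]
  stopifnot(inherits(recording, "session_recording"),
            inherits(sequence, "stimulus_sequence"))
  L <- recording$steps_per_trial
  n <- length(sequence$labels)
  pop <- colMeans(recording$r_E)
  if (length(pop) < n * L) stop("recording does not cover all trials", call. = FALSE)
  trials <- matrix(pop[seq_len(n * L)], nrow = L)  # L x n_trials
  keep <- seq_len(n) > discard_first
  lab <- sequence$labels[keep]
  if (!all(c("X", "Y") %in% lab))
    stop("a stimulus label is absent from the (kept) sequence", call. = FALSE)
  trace_X <- rowMeans(trials[, keep & sequence$labels == "X", drop = FALSE])
  trace_Y <- rowMeans(trials[, keep & sequence$labels == "Y", drop = FALSE])
  std <- if (sequence$standard == "X") trace_X else trace_Y
  dev <- if (sequence$deviant == "X") trace_X else trace_Y
  diff_trace <- dev - std
  time_ms <- (seq_len(L) - 1) * recording$dt * 1000
  win500 <- time_ms < 500
  structure(list(
    trace_X = trace_X, trace_Y = trace_Y,
    mean_trace_standard = std, mean_trace_deviant = dev,
    diff_trace = diff_trace, diff_trace_yx = trace_Y - trace_X,
    time_ms = time_ms, dt = recording$dt,
    peak_latency_ms = peak_latency(diff_trace, recording$dt),
    peak_amplitude = max(diff_trace[time_ms < 1000]),
    mean_amplitude = mean(diff_trace[win500])),
    class = "erp_summary")
}

#' Latency of the peak of a difference trace
#'
#' Argmax over the post-onset samples, reported in milliseconds (sample k,
#' 1-based, maps to `(k-1)*dt*1000` ms). Ties break toward the earliest
#' sample; a constant (flat) trace has no defined peak and returns `NA` with
#' attribute `undefined = TRUE`.
#'
#' @param diff_trace numeric trace, onset-aligned.
#' @param dt sample step in seconds.
#' @return Peak latency in ms (multiple of `dt*1000`), or flagged `NA`.
#' @export
peak_latency <- function(diff_trace, dt) {
  if (length(diff_trace) == 0) stop("empty trace", call. = FALSE)
  if (diff(range(diff_trace)) == 0)
    return(structure(NA_real_, undefined = TRUE))
  (which.max(diff_trace) - 1) * dt * 1000
}

#' Frontal-to-sensory amplification ratio
#'
#' Ratio of peak deviant-standard difference amplitudes (peaks over the
#' 0-1000 ms post-onset window), frontal over sensory. With
#' `metric = "mean"` the 0-500 ms time-mean amplitudes are used instead.
#'
#' @param sensory,frontal `erp_summary` objects.
#' @param metric "peak" (default) or "mean".
#' @return Scalar ratio; flagged `NA` when the sensory amplitude is not
#'   positive.
#' @export
amplification_ratio <- function(sensory, frontal, metric = c("peak", "mean")) {
  metric <- match.arg(metric)
  num <- if (metric == "peak") frontal$peak_amplitude else frontal$mean_amplitude
  den <- if (metric == "peak") sensory$peak_amplitude else sensory$mean_amplitude
  if (!is.finite(den) || den <= 0)
    return(structure(NA_real_, undefined = TRUE))
  num / den
}

#' Pearson correlation of a sweep metric against a covariate
#'
#' Pools rows of a long-format sweep table (instances x conditions, or
#' trial-level) and reports the Pearson correlation with a two-sided p-value.
#'
#' @param table data.frame with the metric and covariate columns.
#' @param metric,covariate column names.
#' @return list with `r`, `p`, `n`.
#' @export
sweep_correlation <- function(table, metric, covariate) {
  x <- table[[covariate]]; y <- table[[metric]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 3)
    stop("need >= 3 distinct covariate values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in metric or covariate", call. = FALSE)
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Paired t-test across model instances
#'
#' Two-sided paired t-test of instance-level values (Welch test when
#' `paired = FALSE`). A degenerate zero-variance difference with a non-zero
#' mean is reported as an infinite-t flag rather than an error.
#'
#' @param values_a,values_b numeric vectors (one value per instance).
#' @param paired logical (default TRUE).
#' @return list with `t`, `p`, `df`, `n`.
#' @export
instance_ttest <- function(values_a, values_b, paired = TRUE) {
  if (length(values_a) < 2) stop("need at least 2 instances", call. = FALSE)
  if (paired && length(values_a) != length(values_b))
    stop("paired test needs equal lengths", call. = FALSE)
  if (paired) {
    d <- values_a - values_b
    if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
      if (mean(d) == 0) return(list(t = 0, p = 1, df = length(d) - 1, n = length(d)))
      return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1,
                  n = length(d), degenerate = TRUE))
    }
  }
  tt <- stats::t.test(values_a, values_b, paired = paired)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n = length(values_a))
}

# Per-trial evoked responses: time-mean population E rate over the first
# `window_s` seconds of each trial. Returns a data.frame
# (trial, label, response).
evoked_by_trial <- function(recording, sequence, region = "sensory",
                            window_s = 0.5) {
  if (inherits(recording, "hierarchical_recording"))
    recording <- recording[[region]]
  L <- recording$steps_per_trial
  n <- length(sequence$labels)
  pop <- colMeans(recording$r_E)
  trials <- matrix(pop[seq_len(n * L)], nrow = L)
  w <- seq_len(min(L, round(window_s / recording$dt)))
  data.frame(trial = seq_len(n), label = sequence$labels,
             response = colMeans(trials[w, , drop = FALSE]))
}
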