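#' @useDynLib erpnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom utils head write.csv read.csv
NULL

# Deterministic seed streams: every random draw is traceable to
# (base_seed, instance, stream, condition). Offsets keep seeds < 2^31 for
# any base seed below ~2e9.
seed_for <- function(base, instance, stream = c("weights", "frontal", "ff",
                                                "fb", "sequence", "noise",
                                                "test_sequence"),
                     condition = 0L) {
  stream <- match.arg(stream)
  off <- c(weights = 11L, frontal = 211L, ff = 411L, fb = 611L,
           sequence = 811L, noise = 1011L, test_sequence = 1211L)[[stream]]
  as.integer((base + off + 37L * (instance - 1L) + 9973L * condition) %% .Machine$integer.max)
}

# Build the per-instance model object of a given variant.
build_instance <- function(variant = c("sensory", "hierarchy", "active"),
                           base_seed, instance, gain = 0.1, density = 1,
                           gain_fb = 0.1) {
  variant <- match.arg(variant)
  cfg <- model_config(seed = seed_for(base_seed, instance, "weights"))
  if (variant == "sensory") return(network_instance(cfg))
  ff <- feedforward_spec(gain = gain, density = density)
  if (variant == "hierarchy")
    return(hierarchical_instance(cfg, ff,
                                 frontal_seed = seed_for(base_seed, instance, "frontal"),
                                 ff_seed = seed_for(base_seed, instance, "ff")))
  active_instance(cfg, ff, fb = feedback_spec(gain_fb = gain_fb),
                  frontal_seed = seed_for(base_seed, instance, "frontal"),
                  ff_seed = seed_for(base_seed, instance, "ff"),
                  fb_seed = seed_for(base_seed, instance, "fb"))
}

#' Simulate the default oddball condition across instances
#'
#' Runs `n_instances` seeded models under one protocol and returns
#' instance-level ERP summaries: peak latencies and amplitudes per region,
#' frontal/sensory amplification ratio, and mean evoked responses to
#' standard and deviant stimuli (0-500 ms window).
#'
#' @param model "sensory" or "hierarchy".
#' @param n_instances number of seeded instances (default 30).
#' @param n_trials trials per session (default 100).
#' @param p_x,isi protocol parameters.
#' @param base_seed base seed.
#' @param std_enabled STD on input synapses (FALSE = ablation control).
#' @return data.frame with one row per instance.
#' @export
run_default_condition <- function(model = c("sensory", "hierarchy"),
                                  n_instances = 30, n_trials = 100,
                                  p_x = 0.8, isi = 2, base_seed = 1L,
                                  std_enabled = TRUE) {
  model <- match.arg(model)
  rows <- lapply(seq_len(n_instances), function(i) {
    inst <- build_instance(if (model == "sensory") "sensory" else "hierarchy",
                           base_seed, i)
    proto <- stimulus_protocol(n_trials = n_trials, p_x = p_x, isi = isi,
                               seed = seed_for(base_seed, i, "sequence"))
    seqn <- generate_sequence(proto)
    input <- render_input(seqn, proto)
    rec <- if (model == "sensory") {
      simulate_sensory(inst, input, std_enabled = std_enabled)
    } else {
      simulate_hierarchy(inst, input, std_enabled = std_enabled)
    }
    sens <- trial_average(rec, seqn, region = "sensory")
    ev <- evoked_by_trial(rec, seqn, region = "sensory")
    out <- data.frame(
      instance = i,
      lat_sensory_ms = sens$peak_latency_ms,
      amp_sensory = sens$peak_amplitude,
      mean_amp_sensory = sens$mean_amplitude,
      evoked_standard = mean(ev$response[ev$label == seqn$standard]),
      evoked_deviant = mean(ev$response[ev$label == seqn$deviant]))
    if (model == "hierarchy") {
      fro <- trial_average(rec, seqn, region = "frontal")
      out$lat_frontal_ms <- fro$peak_latency_ms
      out$amp_frontal <- fro$peak_amplitude
      out$mean_amp_frontal <- fro$mean_amplitude
      out$ratio <- amplification_ratio(sens, fro)
    }
    out
  })
  do.call(rbind, rows)
}

#' Probability sweep across instances
#'
#' Each instance keeps its weights fixed while the stimulus probability runs
#' over `p_grid` (fresh label sequence per condition). Returns condition-level
#' amplitudes, trial-level evoked responses and, optionally, the
#' condition-concatenated PCA geometry per region.
#'
#' @param model "sensory" or "hierarchy".
#' @param n_instances,n_trials,base_seed as in [run_default_condition()].
#' @param p_grid probabilities of stimulus X (default 0.1-0.9 step 0.1).
#' @param isi interstimulus interval (default 2 s).
#' @param geometry also compute PCA + ellipse tables (default FALSE).
#' @param geometry_last number of final trials for the ellipse fits.
#' @return list of data.frames: `amplitudes` (instance, p_x, region, amp_yx =
#'   Y-X 0-500 ms mean difference, amp_devstd, peak_latency_ms), `trials`
#'   (instance, p_x, region, label, response), and with `geometry = TRUE`
#'   `ellipses` (instance, region, condition, stimulus, a, b, theta_rad,
#'   jittered) and `pca` (instance, region, pc1_fraction, pc2_fraction,
#'   pc3_fraction).
#' @export
sweep_probability <- function(model = c("sensory", "hierarchy"),
                              n_instances = 30, n_trials = 100,
                              base_seed = 1L,
                              p_grid = seq(0.1, 0.9, by = 0.1), isi = 2,
                              geometry = FALSE, geometry_last = 50) {
  model <- match.arg(model)
  sweep_conditions(model, n_instances, n_trials, base_seed,
                   values = p_grid, axis = "p_x", isi = isi, p_x = NA,
                   geometry = geometry, geometry_last = geometry_last)
}

#' Interstimulus-interval sweep across instances
#'
#' As [sweep_probability()], but the ISI runs over `isi_grid` at fixed
#' `p_x`.
#'
#' @inheritParams sweep_probability
#' @param isi_grid ISI values in seconds (default 1.0-5.0 step 0.5).
#' @param p_x fixed stimulus-X probability (default 0.8).
#' @return Same shape as [sweep_probability()], with sweep column `isi`.
#' @export
sweep_isi <- function(model = c("sensory", "hierarchy"), n_instances = 30,
                      n_trials = 100, base_seed = 1L,
                      isi_grid = seq(1, 5, by = 0.5), p_x = 0.8,
                      geometry = FALSE, geometry_last = 50) {
  model <- match.arg(model)
  sweep_conditions(model, n_instances, n_trials, base_seed,
                   values = isi_grid, axis = "isi", isi = NA, p_x = p_x,
                   geometry = geometry, geometry_last = geometry_last)
}

# Shared engine for the probability and ISI sweeps.
sweep_conditions <- function(model, n_instances, n_trials, base_seed,
                             values, axis, isi, p_x, geometry,
                             geometry_last) {
  regions <- if (model == "sensory") "sensory" else c("sensory", "frontal")
  amp_rows <- list(); trial_rows <- list(); ell_rows <- list(); pca_rows <- list()
  for (i in seq_len(n_instances)) {
    inst <- build_instance(if (model == "sensory") "sensory" else "hierarchy",
                           base_seed, i)
    recs <- list(); seqs <- list()
    for (ci in seq_along(values)) {
      v <- values[ci]
      proto <- stimulus_protocol(
        n_trials = n_trials,
        p_x = if (axis == "p_x") v else p_x,
        isi = if (axis == "isi") v else isi,
        seed = seed_for(base_seed, i, "sequence", condition = ci))
      seqn <- generate_sequence(proto)
      input <- render_input(seqn, proto)
      rec <- if (model == "sensory") {
        simulate_sensory(inst, input)
      } else {
        simulate_hierarchy(inst, input)
      }
      for (reg in regions) {
        summ <- trial_average(rec, seqn, region = reg)
        amp_yx <- mean(summ$diff_trace_yx[summ$time_ms < 500])
        amp_rows[[length(amp_rows) + 1L]] <- data.frame(
          instance = i, value = v, region = reg, amp_yx = amp_yx,
          amp_devstd = summ$mean_amplitude,
          peak_latency_ms = summ$peak_latency_ms,
          peak_amplitude = summ$peak_amplitude)
        ev <- evoked_by_trial(rec, seqn, region = reg)
        trial_rows[[length(trial_rows) + 1L]] <- data.frame(
          instance = i, value = v, region = reg, label = ev$label,
          response = ev$response)
      }
      if (geometry) {
        recs[[ci]] <- rec
        seqs[[ci]] <- seqn
      }
    }
    if (geometry) {
      for (reg in regions) {
        pca <- pca_concat(recs, region = reg, k = 3)
        pca_rows[[length(pca_rows) + 1L]] <- data.frame(
          instance = i, region = reg,
          pc1_fraction = pca$variance_fractions[1],
          pc2_fraction = pca$variance_fractions[2],
          pc3_fraction = pca$variance_fractions[3])
        plane <- if (reg == "frontal") c(1, 3) else c(1, 2)
        ell <- geometry_sweep(pca, seqs, values, pc_plane = plane,
                              n_last = geometry_last,
                              seed = seed_for(base_seed, i, "noise"))
        if (!is.null(ell) && nrow(ell)) {
          ell$instance <- i; ell$region <- reg
          ell_rows[[length(ell_rows) + 1L]] <- ell
        }
      }
    }
  }
  amplitudes <- do.call(rbind, amp_rows)
  names(amplitudes)[names(amplitudes) == "value"] <- axis
  trials <- do.call(rbind, trial_rows)
  names(trials)[names(trials) == "value"] <- axis
  out <- list(amplitudes = amplitudes, trials = trials)
  if (geometry) {
    out$ellipses <- do.call(rbind, ell_rows)
    out$pca <- do.call(rbind, pca_rows)
  }
  out
}

#' Feedforward gain x density sweep
#'
#' Per instance the sensory session is simulated once and the frontal region
#' re-integrated for every (gain, density) cell (feedforward weights resampled
#' per cell from a cell-specific stream). Reports the frontal/sensory peak
#' amplification ratio per cell and instance.
#'
#' @param g_grid feedforward gains (default c(0.025, 0.05, 0.075, 0.1)).
#' @param density_grid connection densities (default c(0.25, 0.5, 0.75, 1)).
#' @inheritParams run_default_condition
#' @return data.frame (g, density, instance, ratio).
#' @export
sweep_gain_density <- function(g_grid = c(0.025, 0.05, 0.075, 0.1),
                               density_grid = c(0.25, 0.5, 0.75, 1),
                               n_instances = 30, n_trials = 100,
                               p_x = 0.8, isi = 2, base_seed = 1L) {
  grid <- expand.grid(g = g_grid, density = density_grid)
  rows <- list()
  for (i in seq_len(n_instances)) {
    hier <- build_instance("hierarchy", base_seed, i)
    proto <- stimulus_protocol(n_trials = n_trials, p_x = p_x, isi = isi,
                               seed = seed_for(base_seed, i, "sequence"))
    seqn <- generate_sequence(proto)
    input <- render_input(seqn, proto)
    rec1 <- simulate_sensory(hier$sensory, input)
    sens <- trial_average(rec1, seqn)
    for (ci in seq_len(nrow(grid))) {
      ff <- init_feedforward(feedforward_spec(gain = grid$g[ci],
                                              density = grid$density[ci]),
                             n_e = hier$config$n_e,
                             seed = seed_for(base_seed, i, "ff", condition = ci))
      hier$ff <- ff
      rec2 <- simulate_frontal(hier, rec1)
      fro <- trial_average(rec2, seqn)
      rows[[length(rows) + 1L]] <- data.frame(
        g = grid$g[ci], density = grid$density[ci], instance = i,
        ratio = amplification_ratio(sens, fro))
    }
  }
  do.call(rbind, rows)
}

#' Active vs passive comparison across instances
#'
#' For each instance: train the readout with FORCE on fresh sessions, then
#' simulate one held-out test session in closed loop (active) and passively
#' (same stimuli, no readout), and summarize the confusion matrix, the
#' frontal and sensory deviant-standard amplitudes in both conditions, and
#' the active frontal peak latency.
#'
#' @inheritParams run_default_condition
#' @param n_train_sessions FORCE training sessions per instance (default 5).
#' @param alpha RLS regularizer.
#' @param keep_recordings also return the per-instance test recordings
#'   (active + passive hierarchical recordings and sequences), for decoding.
#' @return data.frame with one row per instance (plus `recordings` attribute
#'   when requested).
#' @export
run_active_comparison <- function(n_instances = 30, n_trials = 100,
                                  p_x = 0.8, isi = 2, base_seed = 1L,
                                  n_train_sessions = 5, alpha = 1,
                                  keep_recordings = FALSE) {
  rows <- list(); keep <- list()
  for (i in seq_len(n_instances)) {
    inst <- build_instance("active", base_seed, i)
    train_proto <- stimulus_protocol(n_trials = n_trials, p_x = p_x, isi = isi,
                                     seed = seed_for(base_seed, i, "sequence"))
    trained <- train_force(inst, train_proto, alpha = alpha,
                           n_sessions = n_train_sessions)
    test_proto <- stimulus_protocol(n_trials = n_trials, p_x = p_x, isi = isi,
                                    seed = seed_for(base_seed, i, "test_sequence"))
    seqn <- generate_sequence(test_proto)
    input <- render_input(seqn, test_proto)
    act <- simulate_active(inst, input, trained$W_out)
    # the passive condition is an independent experimental session (its own
    # stimulus draw), as when the two conditions are run separately
    pas_proto <- stimulus_protocol(n_trials = n_trials, p_x = p_x, isi = isi,
                                   seed = seed_for(base_seed, i, "test_sequence",
                                                   condition = 1L))
    pas_seq <- generate_sequence(pas_proto)
    pas <- simulate_hierarchy(inst, render_input(pas_seq, pas_proto))
    cm <- confusion_matrix(act$readout, seqn)
    act_fro <- trial_average(act$recording, seqn, region = "frontal")
    pas_fro <- trial_average(pas, pas_seq, region = "frontal")
    act_sen <- trial_average(act$recording, seqn, region = "sensory")
    pas_sen <- trial_average(pas, pas_seq, region = "sensory")
    rows[[length(rows) + 1L]] <- data.frame(
      instance = i,
      cm_standard = cm[1, 1], cm_deviant = cm[2, 2],
      frontal_active = act_fro$mean_amplitude,
      frontal_passive = pas_fro$mean_amplitude,
      sensory_active = act_sen$mean_amplitude,
      sensory_passive = pas_sen$mean_amplitude,
      lat_frontal_active_ms = act_fro$peak_latency_ms,
      lat_frontal_passive_ms = pas_fro$peak_latency_ms,
      train_error = trained$training_log$mean_abs_error[n_train_sessions])
    if (keep_recordings)
      keep[[i]] <- list(active = act$recording, passive = pas,
                        sequence = seqn, passive_sequence = pas_seq,
                        readout = act$readout)
  }
  out <- do.call(rbind, rows)
  if (keep_recordings) attr(out, "recordings") <- keep
  out
}
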