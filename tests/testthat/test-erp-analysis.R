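mk_recording <- function(pop_trace, n_e = 4, dt = 0.01, L) {
  # embed a population-mean trace into a flat rate matrix
  structure(list(r_E = matrix(rep(pop_trace, each = n_e), n_e),
                 r_I = NULL, dt = dt, steps_per_trial = L),
            class = "session_recording")
}

test_that("trial averaging recovers constructed responses exactly", {
  proto <- stimulus_protocol(n_trials = 6, p_x = 0.5, isi = 1, seed = 1)
  seqn <- generate_sequence(proto)
  seqn$labels <- rep(c("X", "Y"), 3)   # fixed alternation
  L <- 100
  base <- sin(seq(0, pi, length.out = L))
  bump <- base + c(rep(0, 19), 2, rep(0, 80))      # delta at 190 ms
  # interleave: X trials get base, Y trials get bump
  pop <- numeric(0)
  for (k in 1:6) pop <- c(pop, if (seqn$labels[k] == "X") base else bump)
  rec <- mk_recording(pop, L = L)
  summ <- trial_average(rec, seqn)
  # identical response every trial: mean trace equals the single-trial trace
  expect_equal(summ$trace_X, base)
  expect_equal(summ$trace_Y, bump)
  # constructed deviant bump at 190 ms is found
  expect_equal(summ$peak_latency_ms, 190)
  expect_equal(summ$diff_trace, bump - base)
  # label symmetry: relabeling the same recording negates the Y - X
  # difference
  seqn2 <- seqn
  seqn2$labels <- ifelse(seqn$labels == "X", "Y", "X")
  summ2 <- trial_average(rec, seqn2)
  expect_equal(summ2$diff_trace_yx, -summ$diff_trace_yx)
  # missing label
  seqn3 <- seqn; seqn3$labels <- rep("X", 6)
  expect_error(trial_average(rec, seqn3), "absent")
})

test_that("peak latency follows the tie and flag rules", {
  expect_equal(peak_latency(c(rep(0, 19), 1, rep(0, 10)), 0.01), 190)
  flat <- peak_latency(rep(0.3, 50), 0.01)
  expect_true(is.na(flat) && isTRUE(attr(flat, "undefined")))
  two <- rep(0, 50); two[c(16, 31)] <- 1   # equal maxima at 150 and 300 ms
  expect_equal(peak_latency(two, 0.01), 150)
  expect_error(peak_latency(numeric(0), 0.01), "empty")
})

test_that("amplification ratio is a pure peak ratio with a guard", {
  s <- list(peak_amplitude = 2, mean_amplitude = 1)
  expect_equal(amplification_ratio(s, s), 1)
  f <- list(peak_amplitude = 6, mean_amplitude = 3)
  expect_equal(amplification_ratio(s, f), 3)
  bad <- amplification_ratio(list(peak_amplitude = 0, mean_amplitude = 0), f)
  expect_true(is.na(bad) && isTRUE(attr(bad, "undefined")))
})

test_that("sweep correlations and instance t-tests behave on edge cases", {
  df <- data.frame(x = rep(1:5, each = 4))
  df$y <- df$x
  expect_equal(sweep_correlation(df, "y", "x")$r, 1)
  set.seed(1)
  df$z <- -df$x + rnorm(20, 0, 1e-8)
  expect_equal(sweep_correlation(df, "z", "x")$r, -1, tolerance = 1e-6)
  expect_error(sweep_correlation(data.frame(x = c(1, 1, 2), y = 1:3), "y", "x"),
               "distinct")
  expect_error(sweep_correlation(data.frame(x = 1:4, y = rep(2, 4)), "y", "x"),
               "variance")

  a <- c(1.2, 0.9, 1.4, 1.1)
  expect_equal(instance_ttest(a, a)$t, 0)
  deg <- instance_ttest(a + 1, a)
  expect_true(is.infinite(deg$t) && deg$t > 0)
  w <- instance_ttest(a + 1, a, paired = FALSE)
  expect_gt(w$t, 0)
  expect_error(instance_ttest(1, 2), "2 instances")
})

test_that("difference amplitude declines with probability and ISI (sign law)", {
  amp <- prob_sweep_geom()$amplitudes
  as <- amp[amp$region == "sensory", ]
  as$p_y <- 1 - as$p_x
  sp <- stats::cor.test(as$amp_yx, as$p_y, method = "spearman", exact = FALSE)
  expect_lt(sp$estimate, 0)
  ai <- isi_sweep_cached()$amplitudes
  sp2 <- stats::cor.test(ai$amp_yx, ai$isi, method = "spearman", exact = FALSE)
  expect_lt(sp2$estimate, 0)
})

test_that("no-STD difference traces are centered on zero", {
  tab <- nostd_summary()
  d <- tab$evoked_deviant - tab$evoked_standard
  sem <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 2 * sem + 1e-12)
})
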