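test_that("RLS updates have the stated zero-error and scaling behavior", {
  st <- rls_state(4, alpha = 1)
  r <- c(1, 0.5, -0.2, 0.1)
  # zero error: weights untouched, P still contracts
  st$W_out <- matrix(0, 2, 4)
  up <- rls_update(st, r, target = c(0, 0))
  expect_equal(up$W_out, st$W_out)
  expect_false(isTRUE(all.equal(up$P, st$P)))
  # P stays symmetric positive-definite
  expect_equal(up$P, t(up$P))
  expect_true(all(eigen(up$P, symmetric = TRUE, only.values = TRUE)$values > 0))
  # huge alpha: P ~ 0, weights barely move
  stbig <- rls_state(4, alpha = 1e8)
  upbig <- rls_update(stbig, r, target = c(1, 0))
  expect_lt(max(abs(upbig$W_out)), 1e-6)
})

test_that("RLS converges on a single repeated pair", {
  st <- rls_state(3, alpha = 1)
  r <- c(0.3, 0.8, 0.1)
  tgt <- c(1, 0)
  for (i in 1:500) st <- rls_update(st, r, tgt)
  # RLS after N identical pairs fits N||r||^2 / (N||r||^2 + alpha) of the
  # target (the ridge shrinkage factor)
  shrink <- 500 * sum(r^2) / (500 * sum(r^2) + 1)
  expect_equal(drop(st$W_out %*% r), tgt * shrink, tolerance = 1e-9)
  for (i in 1:9500) st <- rls_update(st, r, tgt)
  expect_equal(drop(st$W_out %*% r), tgt, tolerance = 2e-4)
})

test_that("RLS equals the direct ridge solution of the same stream", {
  set.seed(42)
  n <- 6; Tn <- 40; alpha <- 0.7
  R <- matrix(rnorm(Tn * n), Tn, n)
  Y <- matrix(rnorm(Tn * 2), Tn, 2)
  st <- rls_state(n, alpha = alpha)
  for (t in seq_len(Tn)) st <- rls_update(st, R[t, ], Y[t, ])
  ridge <- solve(crossprod(R) + alpha * diag(n), crossprod(R, Y))
  expect_equal(t(st$W_out), ridge, tolerance = 1e-8)
  # P is the regularized inverse correlation of the stream
  expect_equal(st$P, solve(crossprod(R) + alpha * diag(n)), tolerance = 1e-8)
})

test_that("compiled FORCE trainer matches an R-level reference pass", {
  cfg <- tiny_config(seed = 6)
  inst <- active_instance(cfg, feedforward_spec(gain = 0.1),
                          feedback_spec(gain_fb = 0.1))
  proto <- short_protocol(n_trials = 4, isi = 1, seed = 5)
  seqn <- generate_sequence(proto)
  inp <- render_input(seqn, proto)
  rec1 <- simulate_sensory(inst$sensory, inp)
  ff <- inst$ff$W_12 %*% rec1$r_E
  yt <- erpnet:::teacher_signal(seqn, inp)
  w2 <- inst$frontal$weights
  got <- erpnet:::cpp_force_train(w2$W_EE, w2$W_EI, w2$W_IE, w2$W_II, ff,
                                  inst$fb$W_fb, yt,
                                  matrix(0, 2, cfg$n_e), diag(cfg$n_e),
                                  1, cfg$dt, cfg$tau, 20, 1L)
  # R reference: same integration via rate_step/std_step + rls_update
  st <- rls_state(cfg$n_e, alpha = 1)
  r_e <- rep(0, cfg$n_e); r_i <- rep(0, cfg$n_i); xy <- c(1, 1)
  for (t in seq_len(inp$n_steps)) {
    ytt <- yt[, t]
    de <- drop(w2$W_EE %*% r_e - w2$W_IE %*% r_i + ff[, t] +
                 inst$fb$W_fb %*% (xy * ytt))
    di <- drop(w2$W_EI %*% r_e - w2$W_II %*% r_i)
    stp <- rate_step(r_e, r_i, de, di, cfg)
    r_e <- stp$r_e; r_i <- stp$r_i
    st <- rls_update(st, r_e, ytt)
    xy <- xy + cfg$dt * ((1 - xy) / 20 - xy * pmax(ytt, 0))
  }
  expect_equal(got$W_out, st$W_out, tolerance = 1e-8)
  expect_equal(got$P, st$P, tolerance = 1e-8)
})

test_that("training edge cases: zero sessions and frozen zero readout", {
  cfg <- tiny_config(seed = 2)
  inst <- active_instance(cfg)
  proto <- short_protocol(n_trials = 3, isi = 1, seed = 1)
  tr <- train_force(inst, proto, n_sessions = 0)
  expect_true(all(tr$W_out == 0))
  # W_out = 0: readout trace is identically zero
  inp <- render_input(generate_sequence(proto))
  act <- simulate_active(inst, inp, tr$W_out)
  expect_true(all(act$readout$y == 0))
})

test_that("active simulation reduces to the passive hierarchy in the limits", {
  cfg <- tiny_config(seed = 9)
  proto <- short_protocol(n_trials = 5, isi = 1, seed = 7)
  inp <- render_input(generate_sequence(proto))
  inst <- active_instance(cfg)
  passive <- simulate_hierarchy(inst, inp)
  # W_out = 0 closes no loop
  act0 <- simulate_active(inst, inp, matrix(0, 2, cfg$n_e))
  expect_identical(act0$recording$frontal$r_E, passive$frontal$r_E)
  # W_fb = 0 with a nonzero readout: frontal dynamics also bit-identical
  inst_nofb <- inst
  inst_nofb$fb$W_fb[] <- 0
  w_out <- matrix(rnorm(2 * cfg$n_e), 2, cfg$n_e)
  act1 <- simulate_active(inst_nofb, inp, w_out)
  expect_identical(act1$recording$frontal$r_E, passive$frontal$r_E)
})

test_that("feedback resource depletes more on the frequently used channel", {
  inst <- erpnet:::build_instance("active", 7L, 1L)
  proto <- stimulus_protocol(n_trials = 100,
                             seed = erpnet:::seed_for(7L, 1L, "sequence"))
  trained <- train_force(inst, proto)
  seqn <- generate_sequence(proto)
  act <- simulate_active(inst, render_input(seqn, proto), trained$W_out)
  xy <- act$readout$x_y
  # X (standard) channel readout is exercised most: lower steady resource
  second_half <- seq(ncol(xy) / 2, ncol(xy))
  expect_lt(mean(xy[1, second_half]), mean(xy[2, second_half]))
})

test_that("confusion matrices handle perfect, constant and trained readouts", {
  proto <- short_protocol(n_trials = 20, p_x = 0.8, isi = 1, seed = 3)
  seqn <- generate_sequence(proto)
  inp <- render_input(seqn, proto)
  L <- inp$steps_per_trial
  mk_readout <- function(y) structure(list(y = y, dt = proto$dt,
                                           steps_per_trial = L),
                                      class = "readout_trace")
  # perfect readout: identity matrix
  perfect <- mk_readout(erpnet:::teacher_signal(seqn, inp))
  cm <- confusion_matrix(perfect, seqn)
  expect_equal(unname(cm), diag(2))
  # constant (1, 0) predictor: both rows (1, 0)
  const <- mk_readout(matrix(c(1, 0), 2, 20 * L))
  cmc <- confusion_matrix(const, seqn)
  expect_equal(unname(cmc), matrix(c(1, 1, 0, 0), 2, 2))
  expect_error(confusion_matrix(mk_readout(matrix(0, 2, 10)), seqn), "shorter")
})
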