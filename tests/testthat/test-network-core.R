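test_that("weight initialization satisfies radius and balance constraints", {
  for (seed in c(1L, 17L)) {
    w <- init_weights(model_config(seed = seed))
    # all unsigned blocks non-negative by construction
    expect_true(all(w$W_EE >= 0) && all(w$W_EI >= 0) &&
                  all(w$W_IE >= 0) && all(w$W_II >= 0))
    expect_true(all(w$W_in_E >= 0) && all(w$W_in_E < 1))
    # E/I balance ratios exactly 1
    expect_equal(sum(w$W_EI) / sum(w$W_II), 1, tolerance = 1e-9)
    expect_equal(sum(w$W_EE) / sum(w$W_IE), 1, tolerance = 1e-9)
    # spectral radius at the normalization step is 1: rebuild the
    # pre-balance composite from the inhibitory blocks (untouched by the
    # default gauge) and the unbalanced excitatory blocks
    cfg <- model_config(seed = seed)
    raw <- erpnet:::with_seed(seed, {
      ne <- cfg$n_e; ni <- cfg$n_i
      list(W_in_E = matrix(runif(ne * 2), ne, 2),
           W_in_I = matrix(runif(ni * 2), ni, 2),
           W_EE = matrix(runif(ne * ne), ne, ne),
           W_EI = matrix(runif(ni * ne), ni, ne),
           W_IE = matrix(runif(ne * ni), ne, ni),
           W_II = matrix(runif(ni * ni), ni, ni))
    })
    pre <- rbind(cbind(-raw$W_II, raw$W_EI), cbind(-raw$W_IE, raw$W_EE)) * w$scale
    # growth-rate oracle for the radius: ||M^k v||^(1/k) -> rho
    v <- rep(1, nrow(pre)); m <- pre
    for (k in 1:200) v <- m %*% v / sqrt(sum((m %*% v)^2))
    growth <- log(sqrt(sum((m %*% v)^2)))
    expect_lt(abs(exp(growth) - 1), 1e-2)
    # and to eigensolver precision
    expect_lt(abs(max(Mod(eigen(pre, only.values = TRUE)$values)) - 1), 1e-6)
  }
})

test_that("scaling factor matches the closed-form 3x3 spectral radius", {
  # hand-set 2E + 1I blocks: radius of the signed composite from the
  # characteristic polynomial (polyroot), independent of eigen()
  b <- list(W_in_E = matrix(0.5, 2, 2), W_in_I = matrix(0.5, 1, 2),
            W_EE = matrix(c(0.2, 0.4, 0.1, 0.3), 2, 2),
            W_EI = matrix(c(0.6, 0.2), 1, 2),
            W_IE = matrix(c(0.5, 0.1), 2, 1),
            W_II = matrix(0.7, 1, 1))
  comp <- rbind(cbind(-b$W_II, b$W_EI), cbind(-b$W_IE, b$W_EE))
  # char poly of 3x3: -l^3 + tr l^2 - m2 l + det
  tr <- sum(diag(comp))
  m2 <- sum(diag(comp)[1] * diag(comp)[2] - comp[1, 2] * comp[2, 1],
            diag(comp)[1] * diag(comp)[3] - comp[1, 3] * comp[3, 1],
            diag(comp)[2] * diag(comp)[3] - comp[2, 3] * comp[3, 2])
  rho_poly <- max(Mod(polyroot(c(det(comp), -m2, tr, -1))))
  w <- erpnet:::scale_weights(b)
  expect_equal(w$scale, 1 / rho_poly, tolerance = 1e-9)
})

test_that("STD update has the predicted fixed points and relaxation", {
  cfg <- model_config(seed = 1)
  # x = 1, u = 0 is a fixed point
  expect_equal(std_step(c(1, 1), c(0, 0), cfg), c(1, 1))
  # held drive: converge to 1/(1 + tau_x) = 1/21 (exact Euler fixed point)
  x <- c(1, 1)
  for (i in 1:20000) x <- std_step(x, c(1, 1), cfg)
  expect_equal(x, c(1 / 21, 1 / 21), tolerance = 1e-10)
  # relaxation toward 1 follows the linear ODE solution
  x <- c(0.5, 0.5)
  n <- round(cfg$tau_x * log(2) / cfg$dt)
  for (i in seq_len(n)) x <- std_step(x, c(0, 0), cfg)
  expected <- 1 - 0.5 * (1 - cfg$dt / cfg$tau_x)^n
  expect_equal(x[1], expected, tolerance = 1e-12)
  expect_equal(x[1], 0.75, tolerance = 5e-3)  # ~half the gap closed at t = tau_x ln 2
})

test_that("rate update is quiescent, convergent and rectified", {
  cfg <- model_config(seed = 1)
  # zero weights, zero input
  st <- rate_step(rep(0, 3), rep(0, 2), rep(0, 3), rep(0, 2), cfg)
  expect_true(all(st$r_e == 0) && all(st$r_i == 0))
  # scalar, constant positive drive d: r -> d
  r <- 0
  for (i in 1:5000) r <- rate_step(r, 0, 0.37, 0, cfg)$r_e
  expect_equal(r, 0.37, tolerance = 1e-10)
  # negative drive: clamped to zero, geometric decay by (1 - dt/tau)
  st <- rate_step(1, 0, -5, 0, cfg)
  expect_equal(st$r_e, 1 - cfg$dt / cfg$tau)
})

test_that("compiled sensory integrator matches the R reference stepper", {
  cfg <- tiny_config(seed = 5)
  inst <- network_instance(cfg)
  proto <- short_protocol(n_trials = 4, seed = 2)
  inp <- render_input(generate_sequence(proto))
  for (std_on in c(TRUE, FALSE)) {
    rec <- simulate_sensory(inst, inp, std_enabled = std_on)
    ref <- r_reference_sensory(inst, inp, std_enabled = std_on)
    expect_equal(rec$r_E, ref$r_E, tolerance = 1e-12)
    expect_equal(rec$r_I, ref$r_I, tolerance = 1e-12)
    if (std_on) expect_equal(rec$x_trace, ref$x_trace, tolerance = 1e-12)
  }
})

test_that("session invariants hold: non-negative rates, bounded resources", {
  inst <- network_instance(model_config(seed = 3))
  proto <- short_protocol(n_trials = 20, isi = 2, seed = 8)
  rec <- simulate_sensory(inst, render_input(generate_sequence(proto)))
  expect_true(all(rec$r_E >= 0) && all(rec$r_I >= 0))
  expect_true(all(rec$x_trace >= 0) && all(rec$x_trace <= 1))
  # all-zero input keeps the network quiescent
  p0 <- stimulus_protocol(n_trials = 5, p_x = 1, seed = 1)
  inp0 <- render_input(generate_sequence(p0), p0)
  inp0$u[] <- 0
  rec0 <- simulate_sensory(inst, inp0)
  expect_true(all(rec0$r_E == 0))
  # STD disabled pins x at 1
  recn <- simulate_sensory(inst, render_input(generate_sequence(proto)),
                           std_enabled = FALSE)
  expect_true(all(recn$x_trace == 1))
})

test_that("periodic-drive STD steady state matches the affine recursion", {
  cfg <- model_config(seed = 1)
  proto <- stimulus_protocol(n_trials = 400, p_x = 1, isi = 2,
                             stim_duration = 0.2, seed = 1)
  inp <- render_input(generate_sequence(proto), proto)
  xt <- erpnet:::cpp_std_trace(inp$u, cfg$dt, cfg$tau_x)
  fp <- erpnet:::std_periodic_fixed_point(cfg, isi = 2, stim_duration = 0.2)
  L <- inp$steps_per_trial
  # pre-stimulus x of the last trials sits at the closed-form fixed point
  pre <- xt[1, (396:399) * L + 1]
  expect_equal(pre, rep(fp, 4), tolerance = 1e-9)
})

test_that("steady-state resource decreases with presentation rate", {
  cfg <- model_config(seed = 1)
  # ISI sweep: shorter intervals (higher rate) deplete the channel more
  fps <- sapply(c(1, 2, 3, 4, 5), function(isi)
    erpnet:::std_periodic_fixed_point(cfg, isi = isi, stim_duration = 0.2))
  expect_true(all(diff(fps) > 0))
  # probability sweep: simulated mean pre-stimulus x of channel X rises as
  # p_x falls
  pre_x <- sapply(c(0.9, 0.5, 0.1), function(p) {
    proto <- stimulus_protocol(n_trials = 200, p_x = p, isi = 2, seed = 21)
    inp <- render_input(generate_sequence(proto), proto)
    xt <- erpnet:::cpp_std_trace(inp$u, cfg$dt, cfg$tau_x)
    L <- inp$steps_per_trial
    mean(xt[1, (150:199) * L + 1])
  })
  expect_true(all(diff(pre_x) > 0))
})
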