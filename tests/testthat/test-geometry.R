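test_that("conic fits recover canonical ellipses", {
  th <- seq(0, 2 * pi, length.out = 40)
  circ <- cbind(cos(th), sin(th))
  expect_equal(unname(fit_conic(circ)), c(1, 0, 1, 0, 0), tolerance = 1e-9)
  ell <- cbind(2 * cos(th), sin(th))    # x^2/4 + y^2 = 1
  expect_equal(unname(fit_conic(ell)), c(0.25, 0, 1, 0, 0), tolerance = 1e-9)
  # noisy samples of a known rotated ellipse: conic close to the generator's
  pts <- ellipse_points(1, -2, pi / 6, 3, 1, n = 400, noise_sd = 0.01, seed = 2)
  expect_equal(unname(fit_conic(pts)),
               unname(ellipse_conic(1, -2, pi / 6, 3, 1)), tolerance = 0.05)
  # degenerate: collinear points
  line <- cbind(1:10, 2 * (1:10))
  expect_error(fit_conic(line), "degenerate")
  expect_error(fit_conic(circ[1:4, ]), ">= 5")
})

test_that("conic-to-ellipse conversion matches closed forms", {
  circ <- conic_to_ellipse(c(A = 1, B = 0, C = 1, D = 0, E = 0))
  expect_equal(unname(circ$center), c(0, 0))
  expect_equal(circ$a, 1); expect_equal(circ$b, 1)
  expect_equal(circ$theta, 0)  # circle: orientation reported as 0
  ax <- conic_to_ellipse(c(A = 0.25, B = 0, C = 1, D = 0, E = 0))
  expect_equal(ax$a, 2, tolerance = 1e-12)
  expect_equal(ax$b, 1, tolerance = 1e-12)
  expect_equal(ax$theta, 0)
  # full round trip on one reference ellipse
  fit <- conic_to_ellipse(ellipse_conic(1, -2, pi / 6, 3, 1))
  expect_equal(unname(fit$center), c(1, -2), tolerance = 1e-6)
  expect_equal(fit$theta, pi / 6, tolerance = 1e-6)
  expect_equal(fit$a, 3, tolerance = 1e-6)
  expect_equal(fit$b, 1, tolerance = 1e-6)
  # hyperbola rejected by the discriminant
  expect_error(conic_to_ellipse(c(A = 1, B = 0, C = -1, D = 0, E = 0)),
               "discriminant")
})

test_that("round trip recovers 1000 random ellipses to 1e-6", {
  set.seed(99)
  n_ok <- 0
  for (i in 1:1000) {
    x0 <- runif(1, -5, 5); y0 <- runif(1, -5, 5)
    th <- runif(1, -pi / 2 + 0.01, pi / 2 - 0.01)
    b <- runif(1, 0.2, 2); a <- b * runif(1, 1.05, 4)
    conic <- tryCatch(ellipse_conic(x0, y0, th, a, b), error = function(e) NULL)
    if (is.null(conic)) next  # origin on the ellipse: representation excluded
    fit <- conic_to_ellipse(conic)
    expect_equal(unname(fit$center), c(x0, y0), tolerance = 1e-6)
    expect_equal(fit$a, a, tolerance = 1e-6)
    expect_equal(fit$b, b, tolerance = 1e-6)
    expect_equal(fit$theta, th, tolerance = 1e-6)
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 990)
})

test_that("ellipse fits are rotation-equivariant", {
  pts <- ellipse_points(0.5, 0.3, 0.4, 2, 0.8, n = 80, seed = 4)
  base <- conic_to_ellipse(fit_conic(pts))
  for (phi in c(0.3, 1.1, -0.7)) {
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    rot <- conic_to_ellipse(fit_conic(t(R %*% t(pts))))
    expect_equal(rot$a, base$a, tolerance = 1e-6)
    expect_equal(rot$b, base$b, tolerance = 1e-6)
    dth <- (rot$theta - base$theta - phi) %% pi
    expect_lt(min(dth, pi - dth), 1e-6)
  }
})

test_that("hull fitting agrees with direct fits and falls back on jitter", {
  pts <- ellipse_points(0, 0, 0.2, 3, 2, n = 500, seed = 5)
  hf <- hull_and_fit(pts, use_hull = TRUE)
  df <- conic_to_ellipse(fit_conic(pts))
  expect_equal(hf$a, df$a, tolerance = 1e-3)
  expect_equal(hf$b, df$b, tolerance = 1e-3)
  expect_false(hf$jittered)
  # a triangle cannot support a 5-parameter conic: jitter path engages
  tri <- matrix(c(0, 0, 1, 0, 0.4, 1), 3, 2, byrow = TRUE)
  trifit <- hull_and_fit(tri, seed = 3)
  expect_true(trifit$jittered)
  # no extent at all: error after the retry
  same <- matrix(1, 6, 2)
  expect_error(hull_and_fit(same), "extent|degenerate")
})

test_that("PCA on concatenated recordings is sound and permutation-invariant", {
  mk <- function(m) structure(list(r_E = m, dt = 0.01, steps_per_trial = 10),
                              class = "session_recording")
  # rank-1 activity: all variance on the first component
  set.seed(8)
  u <- rnorm(12); tt <- rnorm(300)
  r1 <- pca_concat(list(mk(outer(u, tt[1:150])), mk(outer(u, tt[151:300]))))
  expect_equal(r1$variance_fractions[1], 1, tolerance = 1e-12)
  expect_equal(sum(r1$variance_fractions), 1, tolerance = 1e-8)
  # orthonormal basis
  expect_equal(crossprod(r1$components), diag(3), tolerance = 1e-8)
  # general activity: unit permutation leaves the spectrum unchanged
  m <- matrix(rnorm(12 * 200), 12)
  pa <- pca_concat(list(mk(m)))
  pb <- pca_concat(list(mk(m[sample(12), ])))
  expect_equal(pa$variance_fractions, pb$variance_fractions, tolerance = 1e-8)
  expect_error(pca_concat(list(mk(m), mk(m[1:6, ]))), "unit count")
})

test_that("geometry sweep tracks a constructed radius law", {
  # synthetic trajectories whose radius declines linearly in p: a vs p
  # strongly negative
  ps <- seq(0.1, 0.9, by = 0.2)
  L <- 100
  mk_cond <- function(p, seed) {
    set.seed(seed)
    n_tr <- 60
    labels <- rep(c("X", "Y"), length.out = n_tr)
    ang <- seq(0, 2 * pi, length.out = L)
    cols <- lapply(seq_len(n_tr), function(k) {
      rad <- (2 - 1.5 * p) * (1 + 0.01 * rnorm(1))
      rbind(rad * cos(ang), 0.5 * rad * sin(ang)) + rnorm(2 * L, 0, 0.005)
    })
    proj <- do.call(cbind, cols)
    seqn <- structure(list(labels = labels, standard = "X", deviant = "Y",
                           protocol = list(dt = 0.01)),
                      class = "stimulus_sequence")
    list(proj = proj, seqn = seqn)
  }
  conds <- lapply(seq_along(ps), function(i) mk_cond(ps[i], i))
  pca <- list(projections = lapply(conds, function(cn) cn$proj))
  tab <- geometry_sweep(pca, lapply(conds, function(cn) cn$seqn), ps,
                        pc_plane = c(1, 2), n_last = 50, window_s = 1)
  ex <- tab[tab$stimulus == "X", ]
  expect_lt(sweep_correlation(ex, "a", "condition")$r, -0.95)
})
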