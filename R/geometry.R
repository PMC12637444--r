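#' PCA over condition-concatenated population activity
#'
#' Concatenates the excitatory-unit rate matrices of one network instance
#' across sweep conditions along time, mean-centers each unit over the
#' concatenated axis (no variance scaling: units share a scale), and
#' eigendecomposes the covariance. Projections are returned per condition.
#'
#' @param recordings list of `session_recording`s (or
#'   `hierarchical_recording`s, with `region` selecting the node), one per
#'   condition, sharing unit identity and `dt`.
#' @param region "sensory" or "frontal".
#' @param k number of components to project onto (default 3).
#' @return An object of class `pca_result`: `components` (n_e x k orthonormal
#'   basis), `variance_fractions` (all n_e, non-increasing, summing to 1),
#'   `projections` (list per condition of k x T matrices), `center`.
#' @export
pca_concat <- function(recordings, region = c("sensory", "frontal"), k = 3) {
  region <- match.arg(region)
  mats <- lapply(recordings, function(r) {
    if (inherits(r, "hierarchical_recording")) r <- r[[region]]
    r$r_E
  })
  n_units <- vapply(mats, nrow, integer(1))
  if (length(unique(n_units)) != 1)
    stop("recordings disagree on unit count", call. = FALSE)
  X <- do.call(cbind, mats)                       # n_e x sum(T)
  ctr <- rowMeans(X)
  Xc <- X - ctr
  cv <- tcrossprod(Xc) / (ncol(Xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  vf <- ev / sum(ev)
  comp <- eg$vectors[, seq_len(k), drop = FALSE]
  lens <- vapply(mats, ncol, integer(1))
  ends <- cumsum(lens); starts <- c(1, head(ends, -1) + 1)
  projections <- lapply(seq_along(mats), function(i) {
    crossprod(comp, Xc[, starts[i]:ends[i], drop = FALSE])  # k x T_i
  })
  names(projections) <- names(recordings)
  structure(list(components = comp, variance_fractions = vf,
                 projections = projections, center = ctr, k = k),
            class = "pca_result")
}

#' Least-squares conic fit
#'
#' Fits `A x^2 + B x y + C y^2 + D x + E y = 1` to a set of 2-D points by
#' linear least squares.
#'
#' @param points numeric matrix/data.frame with two columns.
#' @param min_norm use the SVD minimum-norm solution for rank-deficient
#'   designs instead of erroring (used by the jitter fallback, where fewer
#'   than five support points can occur).
#' @return Named numeric vector `c(A, B, C, D, E)`.
#' @export
fit_conic <- function(points, min_norm = FALSE) {
  points <- as.matrix(points)
  if (nrow(points) < 3 || (!min_norm && nrow(points) < 5))
    stop("need >= 5 points for a conic fit", call. = FALSE)
  x <- points[, 1]; y <- points[, 2]
  M <- cbind(x^2, x * y, y^2, x, y)
  qr_m <- qr(M)
  if (qr_m$rank < 5) {
    if (!min_norm)
      stop("degenerate conic fit: rank-deficient design", call. = FALSE)
    sv <- svd(M)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], rep(1, nrow(M)))) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qr_m, rep(1, nrow(M)))
  }
  if (!all(is.finite(beta)))
    stop("degenerate conic fit: non-finite coefficients", call. = FALSE)
  stats::setNames(beta, c("A", "B", "C", "D", "E"))
}

#' Convert a conic to ellipse parameters
#'
#' Requires an elliptic discriminant `B^2 - 4AC < 0`. The center solves the
#' gradient system (equivalently `x0 = (2CD - BE)/Delta`,
#' `y0 = (2AE - BD)/Delta` with `Delta = B^2 - 4AC`); orientation and
#' semi-axes come from the eigendecomposition of the quadratic-form matrix
#' `[[A, B/2], [B/2, C]]`: with `G` the conic value at the center minus 1,
#' the semi-axis along eigenvector `v_i` is `sqrt(-G / lambda_i)`. The larger
#' root is the semi-major axis `a`; `theta` is the major-axis angle mapped to
#' `(-pi/2, pi/2]` (0 by convention for a circle).
#'
#' @param conic named vector `(A, B, C, D, E)` from [fit_conic()].
#' @return An object of class `ellipse_fit`: `conic`, `center`, `theta`,
#'   `a`, `b`, `jittered` (FALSE here).
#' @export
conic_to_ellipse <- function(conic) {
  A <- conic[["A"]]; B <- conic[["B"]]; C <- conic[["C"]]
  D <- conic[["D"]]; E <- conic[["E"]]
  disc <- B^2 - 4 * A * C
  if (!is.finite(disc) || disc >= 0)
    stop(sprintf("conic is not an ellipse (discriminant %.3g >= 0)", disc),
         call. = FALSE)
  x0 <- (2 * C * D - B * E) / disc
  y0 <- (2 * A * E - B * D) / disc
  # conic value at the center (implicit F = -1)
  G <- A * x0^2 + B * x0 * y0 + C * y0^2 + D * x0 + E * y0 - 1
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eg <- eigen(Q, symmetric = TRUE)
  ax <- sqrt(-G / eg$values)
  if (!all(is.finite(ax)) || any(ax <= 0))
    stop("degenerate ellipse: non-positive axis", call. = FALSE)
  major <- which.max(ax)
  a <- ax[major]; b <- ax[-major]
  theta <- if (abs(diff(ax)) < 1e-12 * max(ax)) {
    0  # circle: orientation undefined, report 0
  } else {
    v <- eg$vectors[, major]
    th <- atan2(v[2], v[1])
    if (th <= -pi / 2) th <- th + pi
    if (th > pi / 2) th <- th - pi
    th
  }
  structure(list(conic = conic, center = c(x0 = x0, y0 = y0), theta = theta,
                 a = a, b = b, jittered = FALSE),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("Ellipse: center (%.4g, %.4g), theta %.4g rad, a %.4g, b %.4g%s\n",
              x$center[1], x$center[2], x$theta, x$a, x$b,
              if (x$jittered) " [jittered]" else ""))
  invisible(x)
}

#' Fit an ellipse to a point cloud, optionally via its convex hull
#'
#' With `use_hull = TRUE` the conic is fitted to the convex-hull vertices of
#' the cloud; otherwise to all points. When the direct fit is degenerate
#' (rank deficiency, non-elliptic conic, or non-positive axes - e.g. a
#' triangular hull), zero-mean isotropic Gaussian jitter with standard
#' deviation `0.01 * mean(range(x), range(y))` is added to the fitted points
#' and the fit retried once, flagging the result as jittered. A second
#' failure is an error.
#'
#' @param points 2-column matrix of points.
#' @param use_hull fit to the convex-hull vertices (default TRUE).
#' @param seed seed for the jitter fallback.
#' @return An `ellipse_fit` (field `jittered` records the fallback).
#' @export
hull_and_fit <- function(points, use_hull = TRUE, seed = 1L) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("need >= 3 points", call. = FALSE)
  pick <- function(p) if (use_hull) p[grDevices::chull(p), , drop = FALSE] else p
  fit1 <- try(conic_to_ellipse(fit_conic(pick(points))), silent = TRUE)
  if (!inherits(fit1, "try-error")) return(fit1)
  # degenerate cloud (e.g. a triangular hull of near-coincident points):
  # jitter the coordinates, recompute the hull, retry once
  sd_j <- 0.01 * mean(c(diff(range(points[, 1])), diff(range(points[, 2]))))
  if (!is.finite(sd_j) || sd_j <= 0)
    stop("degenerate geometry: point cloud has no extent", call. = FALSE)
  jit <- with_seed(seed, points + matrix(stats::rnorm(length(points), 0, sd_j),
                                         nrow(points), ncol(points)))
  fit2 <- try(conic_to_ellipse(fit_conic(pick(jit), min_norm = TRUE)),
              silent = TRUE)
  if (inherits(fit2, "try-error"))
    stop("degenerate geometry: ellipse fit failed after jitter", call. = FALSE)
  fit2$jittered <- TRUE
  fit2
}

#' Ellipse parameters across a sweep, per condition and stimulus
#'
#' For each condition and stimulus, selects the projected samples of the
#' last `n_last` trials of that stimulus in the configured PC plane - the
#' first `window_s` seconds after onset per trial (`window_s = NULL` keeps
#' whole trials, the active-task convention) - and fits an ellipse to the
#' convex hull of the selection (`use_hull = FALSE` fits all samples
#' directly instead; direct fits of partially filled trajectory clouds are
#' prone to non-elliptic conics, which is why the hull is the default).
#'
#' @param pca a [pca_concat()] result whose projections are per condition.
#' @param sequences list of `stimulus_sequence`s matching the conditions.
#' @param condition_values numeric vector (the sweep axis values).
#' @param pc_plane integer pair of component indices (default c(1, 2)).
#' @param n_last number of final trials used (default 50).
#' @param window_s post-onset selection window in seconds (default 1);
#'   `NULL` selects whole trials.
#' @param use_hull fit the convex hull of the selection (default TRUE).
#' @param seed jitter-fallback seed.
#' @return data.frame (condition, stimulus, x0, y0, theta_rad, a, b,
#'   jittered); fit failures are dropped with a warning.
#' @export
geometry_sweep <- function(pca, sequences, condition_values,
                           pc_plane = c(1, 2), n_last = 50, window_s = 1,
                           use_hull = TRUE, seed = 1L) {
  stopifnot(length(pca$projections) == length(condition_values),
            length(sequences) == length(condition_values))
  rows <- list()
  for (i in seq_along(condition_values)) {
    proj <- pca$projections[[i]]
    seqn <- sequences[[i]]
    L <- ncol(proj) / length(seqn$labels)
    stopifnot(L == round(L))
    wlen <- if (is.null(window_s)) L
      else min(L, round(window_s / seqn$protocol$dt))
    first_kept <- max(1L, length(seqn$labels) - n_last + 1L)
    for (stim in c("X", "Y")) {
      trials <- which(seqn$labels == stim & seq_along(seqn$labels) >= first_kept)
      if (length(trials) == 0) next
      idx <- unlist(lapply(trials, function(k) (k - 1) * L + seq_len(wlen)))
      pts <- t(proj[pc_plane, idx, drop = FALSE])
      fit <- try(hull_and_fit(pts, use_hull = use_hull,
                              seed = seed + i), silent = TRUE)
      if (inherits(fit, "try-error")) {
        warning(sprintf("ellipse fit failed for condition %g stimulus %s",
                        condition_values[i], stim))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = condition_values[i], stimulus = stim,
        x0 = fit$center[[1]], y0 = fit$center[[2]], theta_rad = fit$theta,
        a = fit$a, b = fit$b, jittered = fit$jittered)
    }
  }
  do.call(rbind, rows)
}
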