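# Superposition, RMSD series, stable-window detection, average structures.

test_that("superposition recovers rigid transforms exactly", {
  b <- small_bundle()
  sel <- backbone_select(b$topology)
  s <- superpose(b$coords, b$coords, sel)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$transform$rotation, diag(3), tolerance = 1e-8)
  R <- dimerdyn:::rotation_about(c(1, 2, 3), 77)
  moved <- sweep(b$coords %*% t(R), 2, c(5, -3, 8), `+`)
  s2 <- superpose(moved, b$coords, sel)
  expect_lt(s2$rmsd, 1e-8)
  # symmetry of the fitted RMSD
  s3 <- superpose(b$coords, moved, sel)
  expect_lt(abs(s2$rmsd - s3$rmsd), 1e-8)
})

test_that("fitted RMSD matches a brute-force rotation-grid minimisation", {
  set.seed(31)
  P <- matrix(stats::rnorm(12, sd = 2), 4, 3)
  Q <- matrix(stats::rnorm(12, sd = 2), 4, 3)
  fit <- superpose(P, Q)
  # oracle: exhaustive search over an Euler-angle grid, centroids matched
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  grid <- seq(0, 350, by = 10)
  best <- Inf
  for (a1 in grid) for (a2 in seq(0, 170, by = 10)) for (a3 in grid) {
    R <- dimerdyn:::rotation_about(c(0, 0, 1), a1) %*%
      dimerdyn:::rotation_about(c(0, 1, 0), a2) %*%
      dimerdyn:::rotation_about(c(0, 0, 1), a3)
    best <- min(best, sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2))))
  }
  expect_lte(fit$rmsd, best + 1e-9)   # Kabsch is the true minimum
  expect_lt(best - fit$rmsd, 0.35)    # grid approaches it at 10-degree steps
})

test_that("superposition agrees with the bio3d reference fit", {
  b <- small_bundle()
  set.seed(5)
  R <- dimerdyn:::rotation_about(stats::rnorm(3), 33)
  mob <- sweep((b$coords + matrix(stats::rnorm(length(b$coords), sd = 0.3),
                                  ncol = 3)) %*% t(R), 2, c(1, 2, 3), `+`)
  sel <- backbone_select(b$topology)
  ours <- superpose(mob, b$coords, sel)
  ref_fit <- bio3d::fit.xyz(as.numeric(t(b$coords)), as.numeric(t(mob)),
                            fixed.inds = dimerdyn:::atom_cols(sel),
                            mobile.inds = dimerdyn:::atom_cols(sel))
  ref_rmsd <- sqrt(mean(rowSums(
    (matrix(ref_fit, ncol = 3, byrow = TRUE)[sel, ] - b$coords[sel, ])^2)))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("degenerate selections are rejected", {
  P <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 0, 0), 4, 3, byrow = TRUE)
  expect_error(superpose(P, P + 1), "collinear|degenerate")
  expect_error(superpose(P[1:2, ], P[1:2, ]), "at least 3")
})

test_that("RMSD series is zero for static runs and rigid-motion invariant", {
  b <- small_bundle()
  xyz <- matrix(rep(as.numeric(t(b$coords)), 10), 10, byrow = TRUE)
  tr <- dimerdyn:::new_trajectory(b$topology, xyz, 100)
  expect_equal(rmsd_series(tr), rep(0, 10), tolerance = 1e-8)

  man <- reference_manifest(b, seed = 6, unwound_fraction = NULL)
  sim <- simulate_trajectory(b, man, 20, 100)
  r0 <- rmsd_series(sim$trajectory)
  moved <- sim$trajectory
  R <- dimerdyn:::rotation_about(c(1, 1, 0), 120)
  for (i in seq_len(nrow(moved$xyz))) {
    f <- sweep(matrix(moved$xyz[i, ], ncol = 3, byrow = TRUE) %*% t(R),
               2, c(10, 0, -4), `+`)
    moved$xyz[i, ] <- as.numeric(t(f))
  }
  expect_equal(rmsd_series(moved), r0, tolerance = 1e-7)
})

test_that("drift-phase RMSD ramps monotonically up to noise", {
  b <- small_bundle()
  man <- reference_manifest(b, seed = 12, hbond_occupancies = NULL,
                            contact_occupancy = NULL, unwound_fraction = NULL,
                            mode_variances = c(0.25),
                            drift = list(n_frames = 60, amplitude = 3))
  sim <- simulate_trajectory(b, man, 120, 100)
  r <- rmsd_series(sim$trajectory)
  smooth <- stats::filter(r[1:60], rep(1 / 5, 5), sides = 2)
  d <- diff(smooth[!is.na(smooth)])
  expect_gt(mean(d > -0.05), 0.95)   # nondecreasing within noise tolerance
  expect_gt(r[55], r[5])
})

test_that("stable-window detection honours the plateau and the span rule", {
  # constant series over 100 ns: full range qualifies
  r <- rep(1.5, 101)
  w <- find_stable_window(r, frame_interval_ps = 1000)
  expect_equal(w$start_frame, 1)
  expect_equal(w$end_frame, 101)
  expect_gte(w$span_ns, 40)

  # ramp 0-50 ns then flat to 180 ns: the window sits inside the plateau,
  # up to the detector's ~3 ns boundary resolution on a gentle ramp tail
  t_ns <- seq(0, 180, by = 0.5)
  rr <- ifelse(t_ns < 50, 0.06 * t_ns, 3) + 0.05 * sin(t_ns)
  w2 <- find_stable_window(rr, frame_interval_ps = 500)
  expect_gte((w2$start_frame - 1) * 0.5, 47)
  expect_lte(w2$end_frame, length(rr))
  expect_gte(w2$span_ns, 40)

  # too-short input is a hard error, never a silent fallback
  expect_error(find_stable_window(rep(1, 31), frame_interval_ps = 1000),
               "30 ns")
  # pure ramp is unstable
  expect_error(find_stable_window(seq(0, 10, length.out = 101),
                                  frame_interval_ps = 1000), "unstable")
  # determinism
  w3 <- find_stable_window(rr, frame_interval_ps = 500)
  expect_identical(w2, w3)
})

test_that("average structure is exact for static and symmetric inputs", {
  b <- small_bundle()
  xyz0 <- as.numeric(t(b$coords))
  tr <- dimerdyn:::new_trajectory(b$topology, rbind(xyz0, xyz0, xyz0), 100)
  w <- window_frames(1, 3, 100)
  avg <- average_structure(tr, w)
  expect_lt(max(abs(avg - b$coords)), 1e-8)

  # +/- d displacement of one atom along x averages to the midpoint
  d <- numeric(length(xyz0)); d[1] <- 0.4
  tr2 <- dimerdyn:::new_trajectory(b$topology, rbind(xyz0 + d, xyz0 - d), 100)
  avg2 <- average_structure(tr2, window_frames(1, 2, 100))
  # midpoint up to the second-order effect of fitting a non-rigid displacement
  expect_lt(max(abs(avg2 - b$coords)), 0.01)
})

test_that("average of a planted-mode run converges to the generator mean", {
  b <- small_bundle()
  man <- ground_truth(seed = 21, modes = make_planted_modes(b, c(1), seed = 21))
  sim <- simulate_trajectory(b, man, 400, 100)
  avg <- average_structure(sim$trajectory, window_frames(1, 400, 100))
  fit <- superpose(avg, b$coords, backbone_select(b$topology))
  # 3 standard errors of the per-atom mean under variance 1 over 400 frames
  expect_lt(fit$rmsd, 3 * sqrt(1 / 400))
})
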