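# PCA schemes: spectra, projections, r-squared, distance features.

test_that("a static trajectory has an all-zero spectrum", {
  b <- small_bundle()
  xyz <- matrix(rep(as.numeric(t(b$coords)), 5), 5, byrow = TRUE)
  tr <- dimerdyn:::new_trajectory(b$topology, xyz, 100)
  ms <- pca_cartesian(tr, window_frames(1, 5, 100))
  expect_lt(max(ms$eigenvalues), 1e-12)
})

test_that("planted modes are recovered: eigenvalues, subspace, trace, orthonormality", {
  b <- small_bundle()
  modes <- make_planted_modes(b, variances = c(4, 1), seed = 17)
  man <- ground_truth(seed = 17, modes = modes)
  sim <- simulate_trajectory(b, man, 1200, 100)
  w <- window_frames(1, 1200, 100)
  ms <- pca_cartesian(sim$trajectory, w, target_frames = 1200)
  se1 <- 4 * sqrt(2 / 1200)
  expect_lt(abs(ms$eigenvalues[1] - 4), 3 * se1)
  expect_lt(abs(ms$eigenvalues[2] - 1), 3 * sqrt(2 / 1200))
  sel_idx <- dimerdyn:::atom_cols(ms$selection)
  for (k in 1:2) {
    planted <- modes[[k]]$vector[sel_idx]
    expect_gt(abs(sum(ms$eigenvectors[, k] * planted)), 0.99)
  }
  # trace conservation and orthonormal eigenvectors
  expect_lt(abs(sum(ms$eigenvalues) - ms$trace) / ms$trace, 1e-6)
  G <- crossprod(ms$eigenvectors[, 1:10])
  expect_lt(max(abs(G - diag(10))), 1e-8)
  # cumulative explained fraction closes at 1
  expect_equal(ms$cumulative_fraction[length(ms$cumulative_fraction)], 1,
               tolerance = 1e-9)
})

test_that("projection identities hold", {
  b <- small_bundle()
  modes <- make_planted_modes(b, variances = c(2), seed = 5)
  man <- ground_truth(seed = 5, modes = modes)
  sim <- simulate_trajectory(b, man, 300, 100)
  w <- window_frames(1, 300, 100)
  ms <- pca_cartesian(sim$trajectory, w, target_frames = 300)
  # variance of the PC1 projection equals the first eigenvalue (same frames)
  expect_equal(stats::var(ms$projections[, 1]), ms$eigenvalues[1],
               tolerance = 1e-6 * ms$eigenvalues[1])
  # projecting the mean structure gives zero
  mu_traj <- dimerdyn:::new_trajectory(
    b$topology,
    matrix(rep(as.numeric(t(b$coords)), 2), 2, byrow = TRUE), 100)
  # frames constructed as mean + c * v1 project back to c exactly
  cvals <- c(-1.5, 0, 2)
  sel <- ms$selection
  v_full <- numeric(3 * b$topology$n_atoms)
  v_full[dimerdyn:::atom_cols(sel)] <- ms$eigenvectors[, 1]
  mean_full <- as.numeric(t(b$coords))
  mean_full[dimerdyn:::atom_cols(sel)] <- as.numeric(t(ms$mean_structure))
  xyz <- t(vapply(cvals, function(cc) mean_full + cc * v_full,
                  numeric(length(mean_full))))
  ctr <- dimerdyn:::new_trajectory(b$topology, xyz, 100)
  pr <- project(ctr, ms, 1)
  expect_equal(pr, cvals, tolerance = 1e-6)
})

test_that("r-squared is symmetric, sign-invariant and near zero under the null", {
  set.seed(33)
  a <- stats::rnorm(2500)
  b <- stats::rnorm(2500)
  expect_equal(pc_correlation(a, a)$r_squared, 1)
  expect_equal(pc_correlation(a, -a)$r_squared, 1)
  expect_identical(pc_correlation(a, b)$r_squared, pc_correlation(b, a)$r_squared)
  # two independent series at n = 2500: r^2 below 0.01
  expect_lt(pc_correlation(a, b)$r_squared, 0.01)
  # zero-variance series flagged, not NaN
  z <- pc_correlation(rep(1, 100), a[1:100])
  expect_false(z$defined)
  expect_true(is.na(z$r_squared))
  # unequal lengths are resampled by interpolation (smooth series)
  sm <- sin(seq(0, 6 * pi, length.out = 2500))
  expect_equal(pc_correlation(sm, sm[seq(1, 2500, by = 5)])$r_squared, 1,
               tolerance = 1e-3)
})

test_that("distance features are constant for rigid runs and track construction", {
  b <- small_bundle()
  xyz <- matrix(rep(as.numeric(t(b$coords)), 6), 6, byrow = TRUE)
  tr <- dimerdyn:::new_trajectory(b$topology, xyz, 100)
  f <- helix_distance_features(tr, b$helices, stride = 1)
  featcols <- setdiff(names(f), c("frame", "system"))
  expect_true(all(vapply(f[featcols], stats::sd, numeric(1)) < 1e-12))
  expect_true(all(as.matrix(f[featcols]) > 0))
  # stride larger than the trajectory gives a single sampled frame
  f1 <- helix_distance_features(tr, b$helices, stride = 50)
  expect_equal(nrow(f1), 1)

  # translating helix A1 by +2 A along an inter-centroid axis in half the
  # frames makes that feature bimodal with modes 2 A apart
  res <- b$topology$residues
  a1_atoms <- which(b$topology$atoms$res_dimer >= b$helices$A1[1] &
                      b$topology$atoms$res_dimer <= b$helices$A1[2])
  ca_a1 <- intersect(atom_select(b$topology, "CA"), a1_atoms)
  ca_a2 <- atom_select(b$topology, "CA",
                       residues = b$helices$A2[1]:b$helices$A2[2])
  axis <- colMeans(b$coords[ca_a2, ]) - colMeans(b$coords[ca_a1, ])
  axis <- axis / sqrt(sum(axis^2))
  xyz2 <- xyz
  for (i in 4:6) {
    fshift <- matrix(xyz2[i, ], ncol = 3, byrow = TRUE)
    fshift[a1_atoms, ] <- sweep(fshift[a1_atoms, ], 2, 2 * axis, `-`)
    xyz2[i, ] <- as.numeric(t(fshift))
  }
  tr2 <- dimerdyn:::new_trajectory(b$topology, xyz2, 100)
  f2 <- helix_distance_features(tr2, b$helices, stride = 1)
  d12 <- f2[["A1-A2"]]
  expect_equal(abs(mean(d12[4:6]) - mean(d12[1:3])), 2, tolerance = 1e-6)
})

test_that("feature PCA: exact 2D subspaces, dispersion ratios, null behaviour", {
  mkfeat <- function(M, system) {
    df <- as.data.frame(M)
    names(df) <- c("A1-A2", "A1-B1", "A1-B2", "A2-B1", "A2-B2", "B1-B2")
    df$frame <- seq_len(nrow(M))
    df$system <- system
    class(df) <- c("distance_features", "data.frame")
    df
  }
  set.seed(71)
  # features confined to a 2D affine subspace: two components explain 100%
  basis <- qr.Q(qr(matrix(stats::rnorm(12), 6, 2)))
  scores <- matrix(stats::rnorm(400), 200, 2) %*% diag(c(3, 1))
  M <- sweep(scores %*% t(basis), 2, c(10, 12, 14, 12, 10, 9), `+`)
  p <- pca_features(mkfeat(M, "flat"))
  expect_equal(sum(p$explained_fraction), 1, tolerance = 1e-9)

  # tight vs 5x-noise systems: dispersion ratio ~ 25, centroids separated
  base <- c(10, 12, 14, 12, 10, 9)
  n <- 800
  tight <- sweep(matrix(stats::rnorm(6 * n, sd = 0.2), n, 6), 2, base, `+`)
  wide <- sweep(matrix(stats::rnorm(6 * n, sd = 1.0), n, 6), 2, base + 3, `+`)
  p2 <- pca_features(list(mkfeat(tight, "tight"), mkfeat(wide, "wide")))
  ratio <- p2$dispersion[["wide"]] / p2$dispersion[["tight"]]
  expect_gt(ratio, 15)
  expect_lt(ratio, 40)
  expect_gt(p2$centroid_distance["tight", "wide"],
            3 * sqrt(p2$dispersion[["tight"]]))

  # single system, 6 iid equal-variance features: 2 components explain ~ 2/6
  # (slightly above, by the expected top-eigenvalue inflation at p = 6)
  iid <- matrix(stats::rnorm(6 * 2000), 2000, 6)
  p3 <- pca_features(mkfeat(iid, "iid"))
  expect_lt(abs(sum(p3$explained_fraction) - 2 / 6), 0.05)
})

test_that("mode animations round-trip through PDB with the right amplitude", {
  b <- small_bundle()
  man <- ground_truth(seed = 2, modes = make_planted_modes(b, c(1), seed = 2))
  sim <- simulate_trajectory(b, man, 50, 100)
  ms <- pca_cartesian(sim$trajectory, window_frames(1, 50, 100), target_frames = 50)
  fp <- withr::local_tempfile(fileext = ".pdb")
  fa <- withr::local_tempfile(fileext = ".csv")
  out <- export_mode_animation(ms, b$topology, 1, amplitude = 3, n_steps = 7,
                               pdb_path = fp, arrows_path = fa)
  expect_equal(nrow(out$xyz), 7)
  # extremes differ by 2 * amplitude * |v| per coordinate
  expect_equal(as.numeric(out$xyz[7, ] - out$xyz[1, ]),
               2 * 3 * ms$eigenvectors[, 1], tolerance = 1e-9)
  back <- bio3d::read.pdb(fp, multi = TRUE, verbose = FALSE)
  disp <- back$xyz[7, ] - back$xyz[1, ]
  expect_equal(as.numeric(disp), 6 * ms$eigenvectors[, 1], tolerance = 1e-2)
  # amplitude 0: every model equals the mean
  out0 <- export_mode_animation(ms, b$topology, 1, amplitude = 0, n_steps = 3)
  expect_lt(max(abs(sweep(out0$xyz, 2, as.numeric(t(ms$mean_structure))))), 1e-12)
})
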