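# Essential dynamics: PCA of coordinate fluctuations. Frames are superposed
# onto an iteratively refined mean over the analysis selection (removing
# rigid-body motion), the 3N covariance matrix is diagonalised, and the
# eigenvectors are the concerted-motion directions with eigenvalues their
# variances (Angstrom^2). Three schemes are supported: global C-alpha (PCA-1),
# central-helix C-alpha (PCA-2), and inter-helix distance features (PCA-3).

#' Cartesian-coordinate PCA over a stable window
#'
#' @param traj a `trajectory`.
#' @param window a `stable_window`.
#' @param selection atom indices (default: all C-alpha; pass the central-helix
#'   C-alphas for the helix-restricted analysis).
#' @param target_frames frames are subsampled uniformly down to this count
#'   (default 2500); all frames are used when the window is shorter.
#' @return object of class `mode_set`: eigenvalues (descending, clipped at 0),
#'   orthonormal eigenvectors (columns), mean structure over the selection,
#'   explained fractions (per-mode and cumulative), per-frame projections, and
#'   the selection/topology needed to project new frames.
#' @export
pca_cartesian <- function(traj, window, selection = NULL, target_frames = 2500) {
  top <- traj$topology
  if (is.null(selection)) selection <- atom_select(top, "CA")
  idx <- window_indices(window, traj)
  if (length(idx) < 2) stop("need at least 2 frames for PCA")
  if (length(idx) > target_frames)
    idx <- unique(round(seq(idx[1], idx[length(idx)], length.out = target_frames)))
  nsel <- length(selection)
  frames <- lapply(idx, function(i) traj_frame(traj, i)[selection, , drop = FALSE])
  ref <- frames[[1]]
  for (pass in 1:2) {
    acc <- matrix(0, nsel, 3)
    for (f in frames) acc <- acc + apply_transform(f, kabsch(f, ref))
    ref <- acc / length(frames)
  }
  X <- t(vapply(frames, function(f) as.numeric(t(apply_transform(f, kabsch(f, ref)))),
                numeric(3 * nsel)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(Xc) - 1)
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  V <- eg$vectors
  # deterministic sign: largest-magnitude component positive
  for (k in seq_len(ncol(V))) {
    m <- which.max(abs(V[, k]))
    if (V[m, k] < 0) V[, k] <- -V[, k]
  }
  proj <- Xc %*% V
  structure(list(eigenvalues = lam, eigenvectors = V,
                 mean_structure = matrix(mu, nsel, 3, byrow = TRUE),
                 explained_fraction = lam / sum(lam),
                 cumulative_fraction = cumsum(lam) / sum(lam),
                 projections = proj, frames = idx,
                 selection = selection, trace = sum(diag(C))),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat("mode set:", length(x$eigenvalues), "modes over", length(x$selection),
      "atoms\n  top eigenvalues (A^2):",
      paste(sprintf("%.3f", x$eigenvalues[seq_len(k)]), collapse = ", "), "\n")
  cat(sprintf("  PC1 explains %.1f%%; PC1-3 %.1f%%\n",
              100 * x$explained_fraction[1], 100 * x$cumulative_fraction[3]))
  invisible(x)
}

#' Project trajectory frames onto one mode
#'
#' Each frame is superposed onto the mode set's mean structure over its
#' selection; the projection is the inner product of the displacement from the
#' mean with eigenvector `k`.
#'
#' @param traj a `trajectory` (its topology must contain the mode selection).
#' @param mode_set a [pca_cartesian()] result.
#' @param k mode index.
#' @param window optional `stable_window` restricting the frames.
#' @return numeric vector of per-frame projections (Angstrom).
#' @export
project <- function(traj, mode_set, k, window = NULL) {
  if (k < 1 || k > length(mode_set$eigenvalues)) stop("invalid mode index")
  sel <- mode_set$selection
  if (max(sel) > traj$topology$n_atoms)
    stop("selection mismatch: trajectory lacks the mode set's atoms")
  idx <- if (is.null(window)) seq_len(n_frames(traj)) else window_indices(window, traj)
  v <- mode_set$eigenvectors[, k]
  mu <- as.numeric(t(mode_set$mean_structure))
  vapply(idx, function(i) {
    f <- traj_frame(traj, i)[sel, , drop = FALSE]
    ft <- apply_transform(f, kabsch(f, mode_set$mean_structure))
    sum((as.numeric(t(ft)) - mu) * v)
  }, numeric(1))
}

#' Squared Pearson correlation of two projection series
#'
#' Series of different lengths are resampled to a common length by linear
#' interpolation. The result is sign-invariant (eigenvector signs are
#' arbitrary) and symmetric in its arguments.
#'
#' @param series_a,series_b numeric vectors.
#' @return list(r_squared, defined); `defined` is FALSE (with r_squared NA)
#'   when either series has zero variance.
#' @export
pc_correlation <- function(series_a, series_b) {
  n <- max(length(series_a), length(series_b))
  resample <- function(x) {
    if (length(x) == n) return(x)
    stats::approx(seq(0, 1, length.out = length(x)), x,
                  xout = seq(0, 1, length.out = n))$y
  }
  a <- resample(series_a); b <- resample(series_b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r_squared = NA_real_, defined = FALSE))
  list(r_squared = stats::cor(a, b)^2, defined = TRUE)
}

#' Inter-helix centroid distance features (PCA-3 input)
#'
#' For every sampled frame, the six pairwise distances between the C-alpha
#' centroids of the four central helices (A1-A2, A1-B1, A1-B2, A2-B1, A2-B2,
#' B1-B2).
#'
#' @param traj a `trajectory`.
#' @param helix_set a [helix_set()].
#' @param stride sample every `stride`-th frame (default 50).
#' @param window optional `stable_window`.
#' @param system label attached to the rows (for combined multi-system PCA).
#' @return data.frame of class `distance_features` with the six distance
#'   columns, `frame` and `system`.
#' @export
helix_distance_features <- function(traj, helix_set, stride = 50,
                                    window = NULL, system = "system") {
  top <- traj$topology
  idx <- if (is.null(window)) seq_len(n_frames(traj)) else window_indices(window, traj)
  idx <- idx[seq(1, length(idx), by = max(1, stride))]
  sel <- lapply(helix_set, function(r) atom_select(top, "CA", residues = r[1]:r[2]))
  if (any(lengths(sel) == 0)) stop("empty helix selection")
  pairs <- utils::combn(names(helix_set), 2)
  out <- t(vapply(idx, function(i) {
    f <- traj_frame(traj, i)
    cent <- vapply(sel, function(s) colMeans(f[s, , drop = FALSE]), numeric(3))
    apply(pairs, 2, function(p) vnorm(cent[, p[1]] - cent[, p[2]]))
  }, numeric(ncol(pairs))))
  out <- as.data.frame(out)
  names(out) <- apply(pairs, 2, paste, collapse = "-")
  out$frame <- idx
  out$system <- system
  class(out) <- c("distance_features", "data.frame")
  out
}

#' PCA of inter-helix distance features across systems
#'
#' Frames from all systems are concatenated and jointly mean-centred (no
#' rescaling: the features share units), then decomposed with [stats::prcomp].
#' Reports loadings, explained variance, per-system projection clouds, each
#' system's dispersion (trace of its projection covariance) and the centroid
#' separation matrix.
#'
#' @param feature_sets list of [helix_distance_features()] outputs (or a
#'   single one).
#' @param n_components components retained (default 2).
#' @return list: loadings, explained_fraction (per retained component),
#'   projections (data.frame with `system`), dispersion (named vector),
#'   centroid_distance (matrix).
#' @export
pca_features <- function(feature_sets, n_components = 2) {
  if (inherits(feature_sets, "data.frame")) feature_sets <- list(feature_sets)
  all <- do.call(rbind, lapply(feature_sets, as.data.frame))
  featcols <- setdiff(names(all), c("frame", "system"))
  M <- as.matrix(all[, featcols])
  if (nrow(M) < 2) stop("need at least 2 frames across systems")
  pr <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pr$rotation))
  tot <- sum(pr$sdev^2)
  proj <- as.data.frame(pr$x[, seq_len(k), drop = FALSE])
  proj$system <- all$system
  disp <- vapply(split(proj[seq_len(k)], proj$system),
                 function(d) sum(apply(d, 2, stats::var)), numeric(1))
  cent <- vapply(split(proj[seq_len(k)], proj$system), colMeans,
                 numeric(k))
  cd <- as.matrix(stats::dist(t(cent)))
  list(loadings = pr$rotation[, seq_len(k), drop = FALSE],
       explained_fraction = if (tot > 0) pr$sdev[seq_len(k)]^2 / tot
                            else rep(NA_real_, k),
       projections = proj, dispersion = disp, centroid_distance = cd)
}

#' Export a mode as a multi-model PDB animation plus an arrow table
#'
#' Writes `n_steps` models interpolating mean - amplitude * v_k ... mean +
#' amplitude * v_k over the mode selection, and a CSV of per-atom displacement
#' vectors (the arrow table used for concerted-motion figures).
#'
#' @param mode_set a [pca_cartesian()] result.
#' @param topology the topology the selection refers to.
#' @param k mode index.
#' @param amplitude displacement amplitude, Angstrom.
#' @param n_steps number of models (default 11).
#' @param pdb_path,arrows_path output files (either may be NULL to skip).
#' @return invisible list(xyz, arrows).
#' @export
export_mode_animation <- function(mode_set, topology, k, amplitude,
                                  n_steps = 11, pdb_path = NULL,
                                  arrows_path = NULL) {
  if (k < 1 || k > length(mode_set$eigenvalues)) stop("invalid mode index")
  sel <- mode_set$selection
  v <- mode_set$eigenvectors[, k]
  mu <- as.numeric(t(mode_set$mean_structure))
  steps <- seq(-1, 1, length.out = n_steps)
  xyz <- t(vapply(steps, function(s) mu + s * amplitude * v, numeric(length(mu))))
  a <- topology$atoms[sel, , drop = FALSE]
  arrows <- data.frame(serial = a$serial, name = a$name, res_dimer = a$res_dimer,
                       dx = v[seq(1, length(v), 3)] * amplitude,
                       dy = v[seq(2, length(v), 3)] * amplitude,
                       dz = v[seq(3, length(v), 3)] * amplitude)
  if (!is.null(pdb_path)) {
    bio3d::write.pdb(file = pdb_path, xyz = xyz, resno = a$res_dimer,
                     chain = a$chain, resid = a$resname, elety = a$name)
  }
  if (!is.null(arrows_path))
    utils::write.csv(arrows, arrows_path, row.names = FALSE, quote = FALSE)
  invisible(list(xyz = xyz, arrows = arrows))
}
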