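# Conformational-stability gating: every downstream statistic (occupancies,
# secondary-structure content, average structures, PCA) is computed over a
# stable window of the trajectory - a contiguous stretch, at least 40 ns by
# default, over which the backbone RMSD has plateaued.

#' Kabsch superposition of one coordinate set onto another
#'
#' Least-squares fit (proper rotation + translation) of `mobile` onto
#' `reference` over `selection`; the transform is applied to all atoms.
#'
#' @param mobile,reference n_atoms x 3 coordinate matrices.
#' @param selection atom indices used for the fit (default: all atoms).
#' @return list with `coords` (transformed mobile), `transform`
#'   (list(rotation, translation)) and `rmsd` (Angstrom, over the selection).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (!length(selection)) stop("empty selection")
  fit <- kabsch(mobile[selection, , drop = FALSE],
                reference[selection, , drop = FALSE])
  list(coords = apply_transform(mobile, fit),
       transform = fit[c("rotation", "translation")],
       rmsd = fit$rmsd)
}

#' Per-frame backbone RMSD relative to a reference frame
#'
#' Each frame is independently superposed onto the reference over `selection`
#' before the RMSD is taken, so global rigid motion never contributes.
#'
#' @param traj a `trajectory`.
#' @param reference reference coordinates (n_atoms x 3) or a frame index
#'   (default: frame 1).
#' @param selection atom indices (default: backbone N, CA, C, O).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = 1, selection = NULL) {
  if (is.null(selection)) selection <- backbone_select(traj$topology)
  ref <- if (is.matrix(reference)) reference else traj_frame(traj, reference)
  refsel <- ref[selection, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(i) {
    kabsch(traj_frame(traj, i)[selection, , drop = FALSE], refsel)$rmsd
  }, numeric(1))
}

#' Detect the stable window of an RMSD series
#'
#' Scans contiguous windows and keeps those that satisfy three conditions:
#' least-squares slope magnitude at most `slope_tol`, standard deviation at
#' most `sd_tol`, and - to stop a long window from quietly absorbing the tail
#' of a drift ramp, which the whole-window statistics barely notice - the
#' window's leading `head_ns` also passes the slope test on its own. Among
#' qualifying windows the longest wins, ties broken towards the latest start.
#' Never falls back silently: an unstable trajectory is an error. Boundary
#' resolution is limited: a ramp portion whose deviation from the plateau is
#' statistically indistinguishable at these tolerances (typically the last
#' 2-3 ns of a gentle approach) may be included.
#'
#' @param rmsd numeric RMSD series (Angstrom).
#' @param frame_interval_ps frame spacing, ps.
#' @param min_span_ns minimum window span in ns (default 40).
#' @param slope_tol maximum |slope| in Angstrom/ns (default 0.01).
#' @param sd_tol maximum standard deviation in Angstrom (default 0.5).
#' @param head_ns leading stretch that must independently pass the slope test
#'   (default 10 ns; set to 0 to disable).
#' @param max_grid windows are anchored on a start/end grid of at most this
#'   many points (prefix-sum evaluation keeps this exact per candidate).
#' @return object of class `stable_window`: list(start_frame, end_frame,
#'   span_ns) with inclusive frame indices.
#' @export
find_stable_window <- function(rmsd, frame_interval_ps, min_span_ns = 40,
                               slope_tol = 0.01, sd_tol = 0.5, head_ns = 10,
                               max_grid = 256) {
  n <- length(rmsd)
  total_ns <- (n - 1) * frame_interval_ps / 1000
  if (total_ns < min_span_ns)
    stop("trajectory spans ", round(total_ns, 2), " ns < minimum window of ",
         min_span_ns, " ns")
  t_ns <- (seq_len(n) - 1) * frame_interval_ps / 1000
  cs_y <- cumsum(rmsd); cs_y2 <- cumsum(rmsd^2)
  cs_t <- cumsum(t_ns); cs_t2 <- cumsum(t_ns^2); cs_ty <- cumsum(t_ns * rmsd)
  grid <- unique(round(seq(1, n, length.out = min(n, max_grid))))
  stats_win <- function(i, j) {
    m <- j - i + 1
    sy <- cs_y[j] - if (i > 1) cs_y[i - 1] else 0
    sy2 <- cs_y2[j] - if (i > 1) cs_y2[i - 1] else 0
    st <- cs_t[j] - if (i > 1) cs_t[i - 1] else 0
    st2 <- cs_t2[j] - if (i > 1) cs_t2[i - 1] else 0
    sty <- cs_ty[j] - if (i > 1) cs_ty[i - 1] else 0
    denom <- st2 - st^2 / m
    slope <- if (denom > 0) (sty - st * sy / m) / denom else 0
    v <- max(0, sy2 / m - (sy / m)^2)
    c(slope = slope, sd = sqrt(v))
  }
  best <- NULL
  for (i in grid) {
    for (j in rev(grid[grid > i])) {
      span <- t_ns[j] - t_ns[i]
      if (span < min_span_ns) break
      s <- stats_win(i, j)
      head_ok <- TRUE
      if (head_ns > 0 && t_ns[j] - t_ns[i] > head_ns) {
        jh <- which(t_ns >= t_ns[i] + head_ns)[1]
        if (jh > i + 1)
          head_ok <- abs(stats_win(i, jh)["slope"]) <= slope_tol
      }
      if (head_ok && abs(s["slope"]) <= slope_tol && s["sd"] <= sd_tol) {
        cand <- c(i, j, span)
        if (is.null(best) || span > best[3] + 1e-12 ||
            (abs(span - best[3]) <= 1e-12 && i > best[1]))
          best <- cand
      }
    }
  }
  if (is.null(best))
    stop("unstable trajectory: no window of >= ", min_span_ns,
         " ns satisfies slope <= ", slope_tol, " A/ns and sd <= ", sd_tol, " A")
  structure(list(start_frame = as.integer(best[1]),
                 end_frame = as.integer(best[2]),
                 span_ns = best[3]),
            class = "stable_window")
}

#' @export
print.stable_window <- function(x, ...) {
  cat(sprintf("stable window: frames %d-%d (%.2f ns)\n",
              x$start_frame, x$end_frame, x$span_ns))
  invisible(x)
}

#' Stable window covering given frames (for fixtures and full-range analyses).
#' @param start_frame,end_frame inclusive frame indices.
#' @param frame_interval_ps frame spacing, ps.
#' @export
window_frames <- function(start_frame, end_frame, frame_interval_ps) {
  stopifnot(start_frame <= end_frame)
  structure(list(start_frame = as.integer(start_frame),
                 end_frame = as.integer(end_frame),
                 span_ns = (end_frame - start_frame) * frame_interval_ps / 1000),
            class = "stable_window")
}

window_indices <- function(window, traj = NULL) {
  idx <- window$start_frame:window$end_frame
  if (!is.null(traj) && window$end_frame > n_frames(traj))
    stop("window exceeds trajectory length")
  idx
}

#' Average structure over a stable window
#'
#' Two-pass iterative mean: all window frames are superposed (over `selection`)
#' onto the running mean, the mean is recomputed, and the procedure repeats
#' once more, which is sufficient for plateaued trajectories.
#'
#' @param traj a `trajectory`.
#' @param window a `stable_window`.
#' @param selection atom indices for the fit (default: backbone).
#' @return n_atoms x 3 matrix of mean coordinates.
#' @export
average_structure <- function(traj, window, selection = NULL) {
  if (is.null(selection)) selection <- backbone_select(traj$topology)
  idx <- window_indices(window, traj)
  ref <- traj_frame(traj, idx[1])
  for (pass in 1:2) {
    acc <- matrix(0, traj$topology$n_atoms, 3)
    for (i in idx) {
      acc <- acc + superpose(traj_frame(traj, i), ref, selection)$coords
    }
    ref <- acc / length(idx)
  }
  ref
}
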