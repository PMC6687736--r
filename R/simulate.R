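# Stochastic trajectory generator. Frames are the ideal bundle plus Gaussian
# amplitudes along planted orthonormal modes; planted hydrogen bonds and
# hydrophobic contacts toggle between formed and broken geometries by
# independent Bernoulli draws; planted segments unwind (helical -> extended
# backbone) in a stated fraction of frames; an optional drift phase prepends a
# monotone RMSD ramp. No force-field physics: the noise model is purely
# Gaussian/Bernoulli so every analysis has exact, machine-readable ground truth.

#' Ground-truth manifest for a synthetic trajectory
#'
#' @param seed integer RNG seed; all draws in [simulate_trajectory()] descend
#'   from it, so identical seed + manifest gives bit-identical frames.
#' @param modes list of `list(vector, variance)`: orthonormal 3N displacement
#'   vectors (Angstrom) with their variances (Angstrom^2). See
#'   [make_planted_modes()].
#' @param hbonds data.frame with columns `donor`, `hydrogen`, `acceptor` (atom
#'   indices) and `occupancy` in `[0, 1]`. In formed frames the acceptor is
#'   placed at donor-acceptor 2.9 Angstrom with a 165-degree D-H-A angle; in
#'   broken frames at 4.5 Angstrom.
#' @param contacts data.frame with columns `atom1`, `atom2`, `occupancy`:
#'   hydrophobic atom pairs placed at 4.5 Angstrom when formed, 8 when broken.
#' @param unwound list of `list(range = c(lo, hi), fraction)`: dimer-numbered
#'   residue ranges whose backbone is replaced by extended geometry in the
#'   stated fraction of frames.
#' @param drift NULL or `list(n_frames, amplitude)`: initial frames carry a
#'   linearly decaying non-rigid displacement of per-atom RMS `amplitude`
#'   Angstrom, so the RMSD series ramps up before the plateau.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(seed, modes = list(), hbonds = NULL, contacts = NULL,
                         unwound = list(), drift = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (length(modes) > 1) {
    V <- do.call(cbind, lapply(modes, `[[`, "vector"))
    G <- crossprod(V)
    if (max(abs(G - diag(ncol(V)))) > 1e-8)
      stop("planted mode vectors must be mutually orthonormal to 1e-8")
  } else if (length(modes) == 1) {
    if (abs(sum(modes[[1]]$vector^2) - 1) > 1e-8)
      stop("planted mode vector must have unit norm")
  }
  occ <- c(if (!is.null(hbonds)) hbonds$occupancy,
           if (!is.null(contacts)) contacts$occupancy,
           vapply(unwound, `[[`, numeric(1), "fraction"))
  if (length(occ) && (any(occ < 0) || any(occ > 1)))
    stop("validation error: occupancy fractions must lie in [0, 1]")
  structure(list(seed = as.integer(seed), modes = modes, hbonds = hbonds,
                 contacts = contacts, unwound = unwound, drift = drift),
            class = "ground_truth")
}

#' Rigid-body basis (3 translations + 3 rotations) of a selection, as columns.
#' @noRd
rigid_basis <- function(coords, sel) {
  n <- length(sel)
  x <- sweep(coords[sel, , drop = FALSE], 2, colMeans(coords[sel, , drop = FALSE]))
  B <- matrix(0, 3 * n, 6)
  for (k in 1:3) B[seq(k, 3 * n, by = 3), k] <- 1
  axes <- diag(3)
  for (k in 1:3) {
    disp <- t(apply(x, 1, function(p) vcross(axes[, k], p)))
    B[, 3 + k] <- as.numeric(t(disp))
  }
  qr.Q(qr(B))[, 1:6, drop = FALSE]
}

#' Generate planted orthonormal displacement modes
#'
#' Random directions supported on the coordinates of `selection`, made
#' orthogonal to the selection's six rigid-body motions (so least-squares
#' superposition cannot absorb them) and to each other.
#'
#' @param bundle a [build_ideal_bundle()] result.
#' @param variances mode variances in Angstrom^2 (one mode per entry); the
#'   default (4, 1) matches the generator's reference study conditions.
#' @param selection atom indices carrying the motion (default: all C-alpha).
#' @param seed RNG seed.
#' @return list of `list(vector, variance)` suitable for [ground_truth()].
#' @export
make_planted_modes <- function(bundle, variances = c(4, 1), selection = NULL,
                               seed = 1) {
  top <- bundle$topology
  if (is.null(selection)) selection <- atom_select(top, "CA")
  set.seed(seed)
  n <- length(selection)
  R <- rigid_basis(bundle$coords, selection)
  out <- list()
  basis <- R
  for (v in variances) {
    w <- stats::rnorm(3 * n)
    w <- w - basis %*% crossprod(basis, w)
    w <- w / vnorm(w)
    basis <- cbind(basis, w)
    full <- numeric(3 * top$n_atoms)
    idx <- as.numeric(t(outer(selection, 1:3, function(a, k) 3 * (a - 1) + k)))
    full[idx] <- w
    out[[length(out) + 1]] <- list(vector = full, variance = v)
  }
  out
}

#' Simulate a synthetic dimer trajectory from a ground-truth manifest
#'
#' @param bundle a [build_ideal_bundle()] result (the mean structure).
#' @param manifest a [ground_truth()].
#' @param n_frames total frames (>= 10), including any drift phase.
#' @param frame_interval_ps frame spacing in picoseconds (default 2; small
#'   fixtures typically use a coarser interval and the ns conversion always
#'   comes from this metadata).
#' @return list with `trajectory` (a `trajectory`) and `manifest`: the input
#'   manifest with `$draws` added - the exact per-frame Bernoulli draw log for
#'   every planted bond, contact and unwound segment.
#' @export
simulate_trajectory <- function(bundle, manifest, n_frames,
                                frame_interval_ps = 2) {
  stopifnot(inherits(manifest, "ground_truth"))
  if (n_frames < 10) stop("n_frames must be >= 10")
  top <- bundle$topology
  nat <- top$n_atoms
  set.seed(manifest$seed)

  mean_flat <- as.numeric(t(bundle$coords))
  X <- matrix(mean_flat, n_frames, 3 * nat, byrow = TRUE)

  if (length(manifest$modes)) {
    V <- do.call(rbind, lapply(manifest$modes, `[[`, "vector"))
    sd <- sqrt(vapply(manifest$modes, `[[`, numeric(1), "variance"))
    A <- sweep(matrix(stats::rnorm(n_frames * length(sd)), n_frames), 2, sd, `*`)
    X <- X + A %*% V
  }

  if (!is.null(manifest$drift)) {
    nd <- manifest$drift$n_frames
    amp <- manifest$drift$amplitude
    if (nd >= n_frames) stop("drift phase must be shorter than the trajectory")
    Rb <- rigid_basis(bundle$coords, seq_len(nat))
    delta <- stats::rnorm(3 * nat)
    delta <- delta - Rb %*% crossprod(Rb, delta)
    if (length(manifest$modes)) {
      Vt <- t(do.call(cbind, lapply(manifest$modes, `[[`, "vector")))
      delta <- delta - crossprod(Vt, Vt %*% delta)
    }
    delta <- as.numeric(delta / vnorm(delta)) * amp * sqrt(nat)
    fac <- pmax(0, 1 - (seq_len(n_frames) - 1) / nd)
    X <- X + outer(fac, delta)
  }

  draws <- list(hbonds = NULL, contacts = NULL, unwound = NULL)
  cols3 <- function(a) 3 * (a - 1) + 1:3

  hb <- manifest$hbonds
  if (!is.null(hb) && nrow(hb)) {
    draws$hbonds <- matrix(0L, n_frames, nrow(hb))
    for (j in seq_len(nrow(hb))) {
      formed <- stats::rbinom(n_frames, 1, hb$occupancy[j])
      draws$hbonds[, j] <- formed
      d <- hb$donor[j]; h <- hb$hydrogen[j]; a <- hb$acceptor[j]
      movers <- c(a, top$donors$hydrogen[top$donors$donor == a])
      # placement radius r from H along (cos t * u + sin t * w), t = 165 deg,
      # chosen so the donor-acceptor distance hits the target exactly
      for (f in seq_len(n_frames)) {
        D <- X[f, cols3(d)]; H <- X[f, cols3(h)]
        u <- vunit(D - H)
        w <- orthogonal_to(u)
        dha <- 165 * pi / 180
        target <- if (formed[f]) 2.9 else 4.5
        lh <- vnorm(D - H)
        # |DA|^2 = lh^2 + r^2 - 2 lh r cos(165)
        cc <- cos(dha)
        r <- (2 * lh * cc + sqrt(4 * lh^2 * cc^2 - 4 * (lh^2 - target^2))) / 2
        newA <- H + r * (cos(dha) * u + sin(dha) * w)
        shift <- newA - X[f, cols3(a)]
        for (m in movers) X[f, cols3(m)] <- X[f, cols3(m)] + shift
      }
    }
  }

  ct <- manifest$contacts
  if (!is.null(ct) && nrow(ct)) {
    draws$contacts <- matrix(0L, n_frames, nrow(ct))
    for (j in seq_len(nrow(ct))) {
      formed <- stats::rbinom(n_frames, 1, ct$occupancy[j])
      draws$contacts[, j] <- formed
      a1 <- ct$atom1[j]; a2 <- ct$atom2[j]
      for (f in seq_len(n_frames)) {
        P <- X[f, cols3(a1)]; Q <- X[f, cols3(a2)]
        target <- if (formed[f]) 4.5 else 8.0
        X[f, cols3(a2)] <- P + target * vunit(Q - P)
      }
    }
  }

  uw <- manifest$unwound
  if (length(uw)) {
    draws$unwound <- matrix(0L, n_frames, length(uw))
    for (j in seq_along(uw)) {
      seg <- uw[[j]]$range
      frac <- uw[[j]]$fraction
      repl <- extended_replacement(bundle, seg)
      drawn <- stats::rbinom(n_frames, 1, frac)
      draws$unwound[, j] <- drawn
      idx <- as.numeric(t(outer(repl$rows, 1:3, function(a, k) 3 * (a - 1) + k)))
      flat <- as.numeric(t(repl$coords))
      for (f in which(drawn == 1L)) X[f, idx] <- flat
    }
  }

  manifest$draws <- draws
  list(trajectory = new_trajectory(top, X, frame_interval_ps),
       manifest = manifest)
}

#' Extended-backbone replacement coordinates for a residue range.
#'
#' The segment is rebuilt with phi = psi = 180 starting from its first
#' N position and heading along the segment's original end-to-end direction;
#' side-chain atoms ride along with their residue's C-alpha displacement.
#' @noRd
extended_replacement <- function(bundle, seg) {
  top <- bundle$topology
  a <- top$atoms
  res <- seg[1]:seg[2]
  rows <- which(a$res_dimer %in% res)
  resnames <- a$resname[rows][match(res, a$res_dimer[rows])]
  nb <- length(res)
  ext <- build_chain(resnames, rep(180, nb), rep(180, nb))
  ca_rows_new <- which(ext$atoms$name == "CA")
  ca_rows_old <- vapply(res, function(r) which(a$res_dimer == r & a$name == "CA")[1],
                        integer(1))
  # centre the extended chain on the original segment midpoint (keeping the
  # perturbation local) but tilt it radially outwards from the bundle axis so
  # the splayed ends clear the intact turns of the same helix
  centre <- colMeans(bundle$coords[ca_rows_old, , drop = FALSE])
  axis_dir <- vunit(bundle$coords[ca_rows_old[nb], ] - bundle$coords[ca_rows_old[1], ])
  radial <- centre - colMeans(bundle$coords)
  radial <- radial - sum(radial * axis_dir) * axis_dir
  dir <- if (vnorm(radial) > 1e-6) {
    vunit(cos(25 * pi / 180) * axis_dir + sin(25 * pi / 180) * vunit(radial))
  } else axis_dir
  newc <- orient_helix(ext$coords, ca_rows_new, centre + 1.5 * vunit(radial), dir)
  # map rebuilt atoms onto the topology's atom rows (same names per residue)
  out <- matrix(NA_real_, length(rows), 3)
  for (k in seq_along(res)) {
    orow <- rows[a$res_dimer[rows] == res[k]]
    nrow_ <- which(ext$atoms$res_local == k)
    m <- match(a$name[orow], ext$atoms$name[nrow_])
    got <- !is.na(m)
    out[match(orow[got], rows), ] <- newc[nrow_[m[got]], , drop = FALSE]
    if (any(!got)) {
      shift <- newc[nrow_[ext$atoms$name[nrow_] == "CA"][1], ] -
        bundle$coords[ca_rows_old[k], ]
      out[match(orow[!got], rows), ] <-
        sweep(bundle$coords[orow[!got], , drop = FALSE], 2, shift, `+`)
    }
  }
  list(rows = rows, coords = out)
}

#' Default planted-feature manifest for a bundle
#'
#' Convenience constructor reproducing the generator's reference study
#' conditions: two concerted C-alpha modes of variance 4 and 1 Angstrom^2, two
#' interface hydrogen bonds at occupancies 0.719 and 0.574 (serine hydroxyl
#' donor on chain A to serine hydroxyl acceptor on chain B), one interface
#' hydrophobic contact at occupancy 0.30, and 20 percent unwinding of the
#' middle of helix A1.
#'
#' @param bundle a [build_ideal_bundle()] result.
#' @param seed RNG seed for the manifest and simulation.
#' @param hbond_occupancies,contact_occupancy,unwound_fraction override the
#'   reference occupancies.
#' @param mode_variances variances for [make_planted_modes()].
#' @param drift optional drift spec passed through to [ground_truth()].
#' @return a `ground_truth`.
#' @export
reference_manifest <- function(bundle, seed = 1,
                               hbond_occupancies = c(0.719, 0.574),
                               contact_occupancy = 0.30,
                               unwound_fraction = 0.20,
                               mode_variances = c(4, 1),
                               drift = NULL) {
  top <- bundle$topology
  a <- top$atoms
  uw <- list()
  uw_res <- integer(0)
  if (!is.null(unwound_fraction)) {
    a1 <- bundle$helices$A1
    pad <- max(3, ceiling((a1[2] - a1[1] + 1) / 3))
    lo <- a1[1] + pad; hi <- a1[2] - pad
    if (hi < lo) { lo <- a1[1] + 3; hi <- a1[2] - 3 }
    uw <- list(list(range = c(lo, hi), fraction = unwound_fraction))
    uw_res <- lo:hi
  }
  # serine OG donors sorted by distance to the opposite chain's centroid,
  # keeping clear of the unwound segment so the planted geometries survive
  centB <- colMeans(bundle$coords[a$chain == "B", , drop = FALSE])
  ogA <- which(a$name == "OG" & a$chain == "A" & !(a$res_dimer %in% uw_res))
  ogB <- which(a$name == "OG" & a$chain == "B")
  ogA <- ogA[order(sqrt(colSums((t(bundle$coords[ogA, , drop = FALSE]) - centB)^2)))]
  hb <- NULL
  if (length(hbond_occupancies)) {
    nb <- length(hbond_occupancies)
    if (length(ogA) < nb || length(ogB) < nb)
      stop("bundle sequence lacks enough serine donors/acceptors for the manifest")
    don <- ogA[seq_len(nb)]
    acc <- integer(0)
    avail <- ogB
    for (d in don) {  # nearest still-unused acceptor, so bonds never share atoms
      pick <- avail[which.min(sqrt(colSums((t(bundle$coords[avail, , drop = FALSE]) -
                                              bundle$coords[d, ])^2)))]
      acc <- c(acc, pick)
      avail <- setdiff(avail, pick)
    }
    hyd <- vapply(don, function(d) top$donors$hydrogen[top$donors$donor == d][1],
                  integer(1))
    hb <- data.frame(donor = don, hydrogen = hyd, acceptor = acc,
                     occupancy = hbond_occupancies)
  }
  ctc <- NULL
  if (!is.null(contact_occupancy)) {
    cbA <- which(a$name == "CB" & a$resname == "ALA" & a$chain == "A" &
                   !(a$res_dimer %in% uw_res))
    cbB <- which(a$name == "CB" & a$resname == "ALA" & a$chain == "B")
    dmat <- outer(cbA, cbB, Vectorize(function(i, j)
      vnorm(bundle$coords[i, ] - bundle$coords[j, ])))
    pick <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
    ctc <- data.frame(atom1 = cbA[pick[1]], atom2 = cbB[pick[2]],
                      occupancy = contact_occupancy)
  }
  ground_truth(seed = seed,
               modes = make_planted_modes(bundle, mode_variances, seed = seed),
               hbonds = hb, contacts = ctc, unwound = uw, drift = drift)
}
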