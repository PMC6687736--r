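# Kabsch-Sander secondary-structure assignment. A backbone hydrogen bond is
# scored with the electrostatic model
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  [kcal/mol]
# and accepted when E < -0.5 kcal/mol. Helical (H) residues sit in runs of
# consecutive i -> i+4 turns; strand (E) residues sit on bridge ladders; all
# else is coil (C). Only H matters for the helical-content summaries; E is
# retained for completeness.

DSSP_CUTOFF <- -0.5
DSSP_Q <- 0.084 * 332

#' Per-residue secondary-structure labels for one frame
#'
#' @param coords n_atoms x 3 coordinate matrix.
#' @param topology the matching `topology`; backbone N, C, O (and amide H)
#'   are required. Chains shorter than 5 residues come back all-coil.
#' @return character vector over {"H", "E", "C"}, one label per residue, in
#'   `topology$residues` order.
#' @export
assign_frame <- function(coords, topology) {
  res <- topology$residues
  nres <- nrow(res)
  labels <- rep("C", nres)
  a <- topology$atoms
  row_of <- function(name) {
    vapply(res$res_dimer, function(r) {
      w <- which(a$res_dimer == r & a$name == name)
      if (length(w)) w[1] else NA_integer_
    }, integer(1))
  }
  iN <- row_of("N"); iC <- row_of("C"); iO <- row_of("O"); iH <- row_of("H")
  bonded <- hbond_energy_matrix(coords, iN, iC, iO, iH)
  # i -> i+4 turns: CO of residue i bonded to NH of residue i+4 (same chain)
  turn <- rep(FALSE, nres)
  ok <- seq_len(nres - 4)
  same <- res$chain[ok] == res$chain[ok + 4]
  turn[ok[same]] <- bonded[cbind(ok[same], ok[same] + 4)]
  # minimal helix: turns at i-1 and i give H for residues i..i+3
  for (i in which(turn)) {
    if (i > 1 && turn[i - 1]) labels[i:(i + 3)] <- "H"
  }
  # bridges (strand ladders): nonadjacent residues with the Kabsch-Sander
  # parallel or antiparallel bridge bond patterns
  for (i in seq_len(nres)) {
    for (j in seq_len(nres)) {
      if (abs(i - j) < 3 && res$chain[i] == res$chain[j]) next
      if (j <= i) next
      par <- (i > 1 && i < nres && bonded_at(bonded, i - 1, j) &&
                bonded_at(bonded, j, i + 1)) ||
        (j > 1 && j < nres && bonded_at(bonded, j - 1, i) &&
           bonded_at(bonded, i, j + 1))
      anti <- (bonded_at(bonded, i, j) && bonded_at(bonded, j, i)) ||
        (i > 1 && j < nres && i + 1 <= nres && j - 1 >= 1 &&
           bonded_at(bonded, i - 1, j + 1) && bonded_at(bonded, j - 1, i + 1))
      if ((par || anti) && labels[i] != "H" && labels[j] != "H") {
        labels[i] <- "E"; labels[j] <- "E"
      }
    }
  }
  # chains shorter than 5 residues are always coil
  for (ch in unique(res$chain)) {
    rs <- which(res$chain == ch)
    if (length(rs) < 5) labels[rs] <- "C"
  }
  labels
}

bonded_at <- function(bonded, i, j) {
  if (i < 1 || j < 1 || i > nrow(bonded) || j > ncol(bonded)) return(FALSE)
  bonded[i, j]
}

#' Kabsch-Sander bond matrix: bonded[i, j] iff the CO of residue i hydrogen
#' bonds the NH of residue j (E < -0.5 kcal/mol).
#' @noRd
hbond_energy_matrix <- function(coords, iN, iC, iO, iH) {
  nres <- length(iN)
  far <- 1e6  # missing atoms sit "at infinity": their 1/r terms vanish
  grab <- function(rows) {
    P <- matrix(far, nres, 3)
    ok <- !is.na(rows)
    P[ok, ] <- coords[rows[ok], , drop = FALSE]
    P
  }
  dm <- function(Pi, Pj) {
    d2 <- outer(rowSums(Pi^2), rep(1, nres)) +
      outer(rep(1, nres), rowSums(Pj^2)) - 2 * tcrossprod(Pi, Pj)
    sqrt(pmax(d2, 1e-12))
  }
  N <- grab(iN); C <- grab(iC); O <- grab(iO); H <- grab(iH)
  # energy of CO(i) ... H-N(j)
  E <- DSSP_Q * (1 / dm(O, N) + 1 / dm(C, H) - 1 / dm(O, H) - 1 / dm(C, N))
  diag(E) <- 0
  if (nres > 1) E[cbind(seq_len(nres - 1), seq_len(nres - 1) + 1)] <- 0
  E[, is.na(iH)] <- 0  # prolines / missing amide H never donate
  E[is.na(iO) | is.na(iC), ] <- 0
  E[, is.na(iN)] <- 0
  E < DSSP_CUTOFF
}

#' Secondary-structure profile of a trajectory window
#'
#' @param traj a `trajectory`.
#' @param window a `stable_window`.
#' @param stride assign every `stride`-th frame of the window (default 1).
#' @return object of class `ss_profile`: list(labels) where `labels` is an
#'   n_assigned_frames x n_residues character matrix, plus the residue table
#'   and the frame indices used.
#' @export
ss_profile <- function(traj, window, stride = 1) {
  idx <- window_indices(window, traj)
  idx <- idx[seq(1, length(idx), by = stride)]
  lab <- t(vapply(idx, function(i) assign_frame(traj_frame(traj, i), traj$topology),
                  character(nrow(traj$topology$residues))))
  structure(list(labels = lab, residues = traj$topology$residues,
                 frames = idx),
            class = "ss_profile")
}

#' Helical secondary-structure content (SSC) per helix segment
#'
#' SSC of a segment is 100 x (number of H labels over the window) /
#' (segment length x assigned frames); the accumulated average pools the
#' residue-frames of all four segments (residue-frame-weighted mean).
#'
#' @param profile an [ss_profile()].
#' @param helix_set a [helix_set()].
#' @return list with `per_helix` (named percent vector) and `accumulated`
#'   (percent).
#' @export
ssc <- function(profile, helix_set) {
  res <- profile$residues
  nH_tot <- 0; nRF_tot <- 0
  per <- stats::setNames(numeric(length(helix_set)), names(helix_set))
  for (nm in names(helix_set)) {
    r <- helix_set[[nm]]
    cols <- which(res$res_dimer >= r[1] & res$res_dimer <= r[2])
    if (!length(cols)) stop("empty helix segment ", nm)
    block <- profile$labels[, cols, drop = FALSE]
    nH <- sum(block == "H")
    per[nm] <- 100 * nH / length(block)
    nH_tot <- nH_tot + nH
    nRF_tot <- nRF_tot + length(block)
  }
  list(per_helix = per, accumulated = 100 * nH_tot / nRF_tot)
}
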