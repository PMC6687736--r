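# Reading and writing structures (PDB) and trajectories (multi-model PDB and
# DCD). PDB parsing/writing goes through bio3d; the DCD writer is a minimal
# CHARMM-format implementation (no installed R package writes DCD).

#' Read a two-chain structure from a PDB file
#'
#' Parses ATOM records, maps chains to the A/B dimer convention, assigns dimer
#' residue numbering (chain-B residue i -> i + 913) and builds the chemistry
#' tables. Files whose chain-B residues are already dimer-numbered (first B
#' residue > 913) are recognised and mapped back to local indices.
#'
#' @param path PDB file.
#' @param chain_map optional named character vector mapping file chain ids to
#'   "A"/"B" (required when the file does not use chains A and B, or has more
#'   than two chains to be subset).
#' @param add_hydrogens place idealised polar hydrogens when the file has no
#'   hydrogen atoms (default TRUE; see [place_polar_hydrogens()]).
#' @return list with elements `topology` and `coords` (n_atoms x 3, Angstrom).
#' @export
read_structure <- function(path, chain_map = NULL, add_hydrogens = TRUE) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  chains <- unique(at$chain)
  if (is.null(chain_map)) {
    if (length(chains) != 2 || !all(sort(chains) == c("A", "B")))
      stop("configuration error: expected exactly chains A and B, found {",
           paste(chains, collapse = ","), "}; supply chain_map")
    chain_map <- c(A = "A", B = "B")
  } else {
    if (!all(names(chain_map) %in% chains))
      stop("chain_map names not present in file")
    at <- at[at$chain %in% names(chain_map), , drop = FALSE]
    at$chain <- unname(chain_map[at$chain])
  }
  res_local <- at$resno
  for (ch in c("A", "B")) {
    sel <- at$chain == ch
    if (!any(sel)) stop("chain ", ch, " missing from file")
    if (ch == "B" && min(at$resno[sel]) > DIMER_OFFSET)
      res_local[sel] <- at$resno[sel] - DIMER_OFFSET
  }
  atoms <- data.frame(name = at$elety, resname = at$resid,
                      chain = at$chain, res_local = res_local)
  coords <- cbind(at$x, at$y, at$z)
  out <- list(topology = make_topology(atoms, coords), coords = coords)
  if (add_hydrogens && !any(out$topology$atoms$element == "H"))
    out <- place_polar_hydrogens(out)
  out
}

#' Write a structure (or trajectory frames) as a PDB file
#'
#' Residues are written in dimer numbering (chain B starting above 913, the
#' convention the chain-B helix labels use). A multi-row `xyz` produces a
#' multi-model PDB.
#'
#' @param topology a `topology`.
#' @param xyz either an n_atoms x 3 coordinate matrix or an
#'   n_frames x (3 n_atoms) matrix of stacked frames.
#' @param path output file.
#' @export
write_structure <- function(topology, xyz, path) {
  a <- topology$atoms
  if (is.matrix(xyz) && ncol(xyz) == 3 && nrow(xyz) == topology$n_atoms)
    xyz <- matrix(t(xyz), nrow = 1)
  stopifnot(ncol(xyz) == 3 * topology$n_atoms)
  bio3d::write.pdb(file = path, xyz = xyz, resno = a$res_dimer,
                   chain = a$chain, resid = a$resname, elety = a$name,
                   eleno = a$serial)
  invisible(path)
}

#' Read a trajectory from a multi-model PDB or a DCD file
#'
#' @param path trajectory file; format chosen by extension (`.dcd` vs PDB).
#' @param topology the matching `topology`; the per-frame atom count must agree.
#' @param frame_interval_ps time between stored frames in picoseconds
#'   (default 2, the usual MD save interval for this analysis).
#' @return object of class `trajectory`: list(topology, xyz, frame_interval_ps)
#'   where `xyz` is n_frames x (3 n_atoms) (x1,y1,z1,x2,... per row).
#' @export
read_trajectory <- function(path, topology, frame_interval_ps = 2) {
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    xyz <- matrix(as.numeric(xyz), nrow = nrow(xyz))
  } else {
    # pre-check per-model atom counts so a mismatch names the frame
    lines <- readLines(path)
    starts <- grep("^MODEL", lines)
    if (length(starts)) {
      ends <- grep("^ENDMDL", lines)
      counts <- mapply(function(s, e) sum(grepl("^ATOM|^HETATM", lines[s:e])),
                       starts, ends)
      bad <- which(counts != topology$n_atoms)
      if (length(bad))
        stop("atom-count mismatch in frame ", bad[1], ": ", counts[bad[1]],
             " atoms, topology has ", topology$n_atoms)
    }
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    xyz <- matrix(as.numeric(xyz), nrow = nrow(xyz))
  }
  if (ncol(xyz) != 3 * topology$n_atoms)
    stop("atom-count mismatch in frame 1: trajectory has ", ncol(xyz) / 3,
         " atoms, topology has ", topology$n_atoms)
  new_trajectory(topology, xyz, frame_interval_ps)
}

new_trajectory <- function(topology, xyz, frame_interval_ps) {
  stopifnot(nrow(xyz) >= 1, frame_interval_ps > 0)
  structure(list(topology = topology, xyz = xyz,
                 frame_interval_ps = frame_interval_ps),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", nrow(x$xyz), "frames x", x$topology$n_atoms, "atoms,",
      x$frame_interval_ps, "ps/frame",
      sprintf("(%.3f ns)\n", nrow(x$xyz) * x$frame_interval_ps / 1000))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame of a trajectory as an n_atoms x 3 matrix.
#' @param traj a `trajectory`.
#' @param i frame index.
#' @export
traj_frame <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Write a trajectory to multi-model PDB or DCD (by extension)
#'
#' @param traj a `trajectory`.
#' @param path output path; `.dcd` selects the binary CHARMM DCD format,
#'   anything else a multi-model PDB.
#' @export
write_trajectory <- function(traj, path) {
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    write_dcd(traj$xyz, path)
  } else {
    write_structure(traj$topology, traj$xyz, path)
  }
  invisible(path)
}

#' Minimal CHARMM-format DCD writer (single precision, no unit cell).
#' @noRd
write_dcd <- function(xyz, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(write_payload, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    write_payload()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  icntrl <- integer(20)
  icntrl[1] <- nf          # frames
  icntrl[2] <- 1L          # first step
  icntrl[3] <- 1L          # save interval
  icntrl[4] <- nf          # total steps
  icntrl[20] <- 24L        # CHARMM version flag
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4)
  }, 84)
  title <- formatC("written by dimerdyn", width = -80)
  rec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(na), con, size = 4), 4)
  xi <- seq(1, 3 * na, by = 3)
  for (f in seq_len(nf)) {
    fr <- xyz[f, ]
    for (k in 0:2) {
      rec(function() writeBin(fr[xi + k], con, size = 4), 4 * na)
    }
  }
  invisible(path)
}
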