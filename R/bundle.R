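# Construction of an ideal C2-symmetric four-helix-bundle dimer. Each monomer
# is a helix-loop-helix; the dimer is generated by a two-fold rotation about
# the bundle axis, so subunit B is an exact C2 image of subunit A. Backbones
# are built from internal coordinates (phi = -57, psi = -47 in the helices),
# which yields the classic alpha-helical rise of ~1.5 Angstrom and ~100 degrees
# of twist per residue without imposing them directly.

# Idealised backbone internal coordinates (Engh-Huber-style values).
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
BOND_C_O  <- 1.231
BOND_N_H  <- 1.010
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7
ANGLE_CA_C_O <- 120.5

# Side-chain templates: internal coordinates relative to the backbone.
# Only residues the builder knows how to place; read_structure() accepts all 20.
BUILDER_RESIDUES <- c("GLY", "ALA", "SER", "LEU")

#' Build one chain from per-residue (phi, psi) torsions.
#' Returns list(atoms, coords). Residues get N, H, CA, C, O plus side chain.
#' @noRd
build_chain <- function(resnames, phi, psi) {
  n <- length(resnames)
  stopifnot(length(phi) == n, length(psi) == n)
  if (!all(resnames %in% BUILDER_RESIDUES))
    stop("builder supports residues ", paste(BUILDER_RESIDUES, collapse = ", "))
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BOND_N_CA, 0, 0)
  th <- (180 - ANGLE_N_CA_C) * pi / 180
  C[1, ] <- CA[1, ] + BOND_CA_C * c(cos(th), sin(th), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         BOND_C_N, ANGLE_CA_C_N, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          BOND_N_CA, ANGLE_C_N_CA, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         BOND_CA_C, ANGLE_N_CA_C, phi[i])
  }
  atoms <- list(); coords <- list()
  add <- function(name, resname, res, pos) {
    atoms[[length(atoms) + 1]] <<- data.frame(name = name, resname = resname,
                                              res_local = res)
    coords[[length(coords) + 1]] <<- as.numeric(pos)
  }
  for (i in seq_len(n)) {
    rn <- resnames[i]
    add("N", rn, i, N[i, ])
    # amide hydrogen: bisector of C(prev)->N and CA->N
    hdir <- if (i > 1) vunit(vunit(N[i, ] - C[i - 1, ]) + vunit(N[i, ] - CA[i, ]))
            else vunit(N[i, ] - (CA[i, ] + C[i, ]) / 2)
    add("H", rn, i, N[i, ] + BOND_N_H * hdir)
    add("CA", rn, i, CA[i, ])
    add("C", rn, i, C[i, ])
    o_tor <- if (i < n) psi[i] + 180 else psi[i] + 180
    add("O", rn, i, place_atom(N[i, ], CA[i, ], C[i, ], BOND_C_O, ANGLE_CA_C_O, o_tor))
    if (rn != "GLY") {
      CB <- place_atom(C[i, ], N[i, ], CA[i, ], 1.53, 110.5, -122.5)
      add("CB", rn, i, CB)
      if (rn == "SER") {
        OG <- place_atom(N[i, ], CA[i, ], CB, 1.417, 110.8, -60)
        add("OG", rn, i, OG)
        add("HG", rn, i, OG + 0.96 * vunit(OG - CB))
      } else if (rn == "LEU") {
        CG <- place_atom(N[i, ], CA[i, ], CB, 1.53, 116.3, -60)
        add("CG", rn, i, CG)
        add("CD1", rn, i, place_atom(CA[i, ], CB, CG, 1.52, 110.7, 180))
        add("CD2", rn, i, place_atom(CA[i, ], CB, CG, 1.52, 110.7, 60))
      }
    }
  }
  list(atoms = do.call(rbind, atoms), coords = do.call(rbind, coords))
}

#' Principal axis of a helix through its C-alpha cloud.
#' @noRd
helix_axis <- function(ca) {
  ctr <- colMeans(ca)
  s <- svd(sweep(ca, 2, ctr))
  ax <- s$v[, 1]
  # orient along increasing residue index
  if (sum((ca[nrow(ca), ] - ca[1, ]) * ax) < 0) ax <- -ax
  list(center = ctr, axis = ax)
}

#' Rigidly move a coordinate block so its helix axis matches a target line.
#' @noRd
orient_helix <- function(coords, ca_rows, target_point, target_axis) {
  ax <- helix_axis(coords[ca_rows, , drop = FALSE])
  v <- vcross(ax$axis, target_axis)
  s <- vnorm(v)
  c_ <- sum(ax$axis * target_axis)
  R <- if (s < 1e-12) {
    if (c_ > 0) diag(3) else rotation_about(orthogonal_to(ax$axis), 180)
  } else {
    rotation_about(v, atan2(s, c_) * 180 / pi)
  }
  moved <- sweep(coords, 2, ax$center) %*% t(R)
  sweep(moved, 2, target_point, `+`)
}

orthogonal_to <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  vunit(vcross(u, ref))
}

#' Build an ideal C2-symmetric four-helix-bundle dimer
#'
#' Each monomer is two antiparallel ideal alpha-helices joined by a short
#' extended loop; the dimer is the monomer plus its image under a 180-degree
#' (C2) rotation about the bundle axis. Helix axes sit on the corners of a
#' square of side `inter_helix_spacing`, so each chain-A helix faces a chain-B
#' helix across the dimer interface.
#'
#' @param n_res_per_helix residues per helix (>= 8).
#' @param sequence_spec 3-letter residue codes recycled along each helix
#'   (supported: GLY, ALA, SER, LEU). The default alternates leucine (packing
#'   the interface with hydrophobic side chains) with alanine and serine
#'   (hydroxyl donors/acceptors across the interface).
#' @param inter_helix_spacing distance between adjacent helix axes, Angstrom.
#' @param loop_length residues in the connecting loop (glycine, extended).
#' @return list of class `bundle`: `topology`, `coords`, `helices` (a
#'   [helix_set()] with the two helix ranges of each chain), `axis_spacing`.
#' @export
build_ideal_bundle <- function(n_res_per_helix = 12,
                               sequence_spec = c("LEU", "ALA", "SER", "LEU",
                                                 "ALA", "ALA", "SER"),
                               inter_helix_spacing = 11.5,
                               loop_length = 4) {
  if (n_res_per_helix < 8) stop("n_res_per_helix must be >= 8")
  n <- n_res_per_helix
  seq1 <- rep(sequence_spec, length.out = n)
  if (!any(seq1 %in% c("SER")) || !any(seq1 %in% c("LEU", "ALA")))
    stop("sequence_spec must place at least one donor/acceptor (SER) and one hydrophobic residue")
  helical <- function(n) list(phi = rep(-57, n), psi = rep(-47, n))
  tor <- helical(n)
  h1 <- build_chain(seq1, tor$phi, tor$psi)
  h2 <- build_chain(seq1, tor$phi, tor$psi)
  loop <- build_chain(rep("GLY", loop_length),
                      rep(180, loop_length), rep(180, loop_length))

  ca1 <- which(h1$atoms$name == "CA")
  # backbone helix radius, for the overlap check
  ax1 <- helix_axis(h1$coords[ca1, , drop = FALSE])
  rel <- sweep(h1$coords[ca1, , drop = FALSE], 2, ax1$center)
  radial <- sqrt(rowSums((rel - outer(as.numeric(rel %*% ax1$axis), ax1$axis))^2))
  r_helix <- max(radial)
  if (inter_helix_spacing < 2 * r_helix)
    stop("overlap error: inter_helix_spacing ", inter_helix_spacing,
         " < sum of helix backbone radii ", round(2 * r_helix, 2))

  s <- inter_helix_spacing / 2
  # chain A: helix 1 runs +z at (-s, -s); helix 2 runs -z at (-s, +s)
  c1 <- orient_helix(h1$coords, ca1, c(-s, -s, 0), c(0, 0, 1))
  c2 <- orient_helix(h2$coords, which(h2$atoms$name == "CA"),
                     c(-s, s, 0), c(0, 0, -1))
  # loop bridges the +z ends of the two helices
  top1 <- c1[ca1[n], ]
  top2 <- c2[which(h2$atoms$name == "CA")[1], ]
  gap_dir <- vunit(top2 - top1)
  loop_ca <- which(loop$atoms$name == "CA")
  lc <- orient_helix(loop$coords, loop_ca, (top1 + top2) / 2 + c(0, 0, 3), gap_dir)

  atomsA <- rbind(h1$atoms, loop$atoms, h2$atoms)
  atomsA$res_local <- c(h1$atoms$res_local,
                        loop$atoms$res_local + n,
                        h2$atoms$res_local + n + loop_length)
  coordsA <- rbind(c1, lc, c2)
  atomsA$chain <- "A"
  # C2 rotation about z generates chain B
  C2 <- diag(c(-1, -1, 1))
  atomsB <- atomsA
  atomsB$chain <- "B"
  coordsB <- coordsA %*% t(C2)
  atoms <- rbind(atomsA, atomsB)
  coords <- rbind(coordsA, coordsB)
  rownames(atoms) <- NULL

  top <- make_topology(atoms, coords)
  hs <- helix_set(c(1L, n), c(n + loop_length + 1L, 2L * n + loop_length))
  structure(list(topology = top, coords = coords, helices = hs,
                 axis_spacing = inter_helix_spacing,
                 n_res_per_helix = n, loop_length = loop_length),
            class = "bundle")
}

#' @export
print.bundle <- function(x, ...) {
  cat("four-helix-bundle dimer:", x$n_res_per_helix, "residues/helix,",
      x$topology$n_atoms, "atoms, axis spacing", x$axis_spacing, "A\n")
  invisible(x)
}
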