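# Topology: the atom table of a two-chain structure, the dimer residue
# numbering convention, and the chemistry tables (hydrogen-bond donors and
# acceptors, hydrophobic side-chain atoms) that the interaction detectors use.

# Chain-B residues are renumbered into "dimer numbering": dimer index =
# chain-local index + 913, the subunit length of the anoctamin-5 monomer whose
# dimer models motivated this package. The map (chain, local index) <->
# dimer index is a bijection and is asserted on every parsed structure.
DIMER_OFFSET <- 913L

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT", "H", "HA")

#' Element symbol from a PDB atom name (supported set: C, N, O, S, H).
#' @noRd
element_of <- function(name) {
  first <- substr(gsub("[0-9]", "", name), 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "H"), first, NA_character_)
}

#' Build a topology from an atom table and coordinates
#'
#' The atom table needs columns `name`, `resname`, `chain` ('A' or 'B') and
#' `res_local` (1-based residue index within the chain). Dimer numbering,
#' element symbols, hydrogen attachment and the chemistry tables are derived.
#' Hydrogens are attached to the nearest heavy atom of the same residue within
#' 1.3 Angstrom; every hydrogen must attach to exactly one heavy atom.
#'
#' @param atoms data.frame with columns name, resname, chain, res_local.
#' @param coords n_atoms x 3 numeric matrix (Angstrom), used to attach
#'   hydrogens to their donor heavy atoms.
#' @return object of class `topology`: the completed atom table plus `donors`
#'   (data.frame of heavy-atom / hydrogen row pairs), `acceptors` (atom rows),
#'   and `hydrophobic` (side-chain C/S atom rows), all indexed into `atoms`.
#' @export
make_topology <- function(atoms, coords) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "resname", "chain", "res_local") %in% names(atoms)))
  n <- nrow(atoms)
  stopifnot(is.matrix(coords), nrow(coords) == n, ncol(coords) == 3,
            all(is.finite(coords)))
  if (!all(atoms$chain %in% c("A", "B")))
    stop("configuration error: chains other than A/B present and no chain mapping given")
  atoms$serial <- seq_len(n)
  atoms$element <- element_of(atoms$name)
  if (anyNA(atoms$element))
    stop("unsupported element in atom name(s): ",
         paste(unique(atoms$name[is.na(atoms$element)]), collapse = ", "))
  atoms$res_dimer <- ifelse(atoms$chain == "B",
                            atoms$res_local + DIMER_OFFSET, atoms$res_local)

  # bijection (chain, local) <-> dimer index
  key <- paste(atoms$chain, atoms$res_local)
  map <- tapply(atoms$res_dimer, key, function(x) length(unique(x)))
  stopifnot(all(map == 1))
  resmap <- unique(atoms[, c("chain", "res_local", "res_dimer")])
  if (anyDuplicated(resmap$res_dimer))
    stop("dimer numbering is not a bijection")

  known <- atoms$resname %in% AMINO3
  if (!all(known)) {
    warning("unknown residue name(s) excluded from chemistry tables: ",
            paste(unique(atoms$resname[!known]), collapse = ", "))
  }

  heavy <- which(atoms$element != "H" & known)
  hyd <- which(atoms$element == "H" & known)
  don <- data.frame(donor = integer(0), hydrogen = integer(0))
  if (length(hyd)) {
    attach_to <- vapply(hyd, function(h) {
      same_res <- heavy[atoms$res_dimer[heavy] == atoms$res_dimer[h]]
      if (!length(same_res)) return(NA_integer_)
      d <- sqrt(rowSums((coords[same_res, , drop = FALSE] -
                           matrix(coords[h, ], length(same_res), 3, byrow = TRUE))^2))
      near <- same_res[d <= 1.3]
      if (length(near) != 1) {
        near <- same_res[which.min(d)]
        if (min(d) > 1.3) return(NA_integer_)
      }
      near
    }, integer(1))
    if (anyNA(attach_to))
      stop("hydrogen atom(s) not bonded to exactly one heavy atom")
    is_no <- atoms$element[attach_to] %in% c("N", "O")
    don <- data.frame(donor = attach_to[is_no], hydrogen = hyd[is_no])
  }
  # acceptors: all oxygens, plus side-chain nitrogens that carry no hydrogen
  ox <- heavy[atoms$element[heavy] == "O"]
  sc_n <- heavy[atoms$element[heavy] == "N" &
                  !(atoms$name[heavy] %in% BACKBONE_NAMES) &
                  !(heavy %in% don$donor)]
  acceptors <- sort(c(ox, sc_n))
  hydrophobic <- heavy[atoms$element[heavy] %in% c("C", "S") &
                         !(atoms$name[heavy] %in% BACKBONE_NAMES) &
                         atoms$name[heavy] != "CA"]

  res <- unique(atoms[known, c("chain", "res_local", "res_dimer", "resname")])
  res <- res[order(res$res_dimer), ]
  rownames(res) <- NULL

  structure(list(atoms = atoms, residues = res, n_atoms = n,
                 donors = don, acceptors = acceptors,
                 hydrophobic = sort(hydrophobic)),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", x$n_atoms, "atoms,", nrow(x$residues), "residues",
      sprintf("(chain A: %d, chain B: %d)\n",
              sum(x$residues$chain == "A"), sum(x$residues$chain == "B")))
  cat("  donors:", nrow(x$donors), " acceptors:", length(x$acceptors),
      " hydrophobic atoms:", length(x$hydrophobic), "\n")
  invisible(x)
}

#' Residue ranges of the four central helices
#'
#' Labels the four interface helices A1/A2 (chain A) and B1/B2 (chain B) by
#' inclusive dimer-numbered residue ranges, e.g. `helix_set(c(609, 639),
#' c(692, 715))` with the B ranges defaulting to the symmetric +913 offset.
#'
#' @param a1,a2 length-2 integer vectors (start, end), chain A, dimer numbering.
#' @param b1,b2 as above for chain B; default `a1 + 913`, `a2 + 913`.
#' @return object of class `helix_set`.
#' @export
helix_set <- function(a1, a2, b1 = a1 + DIMER_OFFSET, b2 = a2 + DIMER_OFFSET) {
  ranges <- list(A1 = as.integer(a1), A2 = as.integer(a2),
                 B1 = as.integer(b1), B2 = as.integer(b2))
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2]) stop("bad range for ", nm)
  }
  if (any(ranges$A1[2] > DIMER_OFFSET & ranges$A1[1] <= DIMER_OFFSET) ||
      ranges$A1[2] > DIMER_OFFSET || ranges$A2[2] > DIMER_OFFSET)
    stop("A1/A2 must lie in chain A (dimer index <= 913)")
  if (ranges$B1[1] <= DIMER_OFFSET || ranges$B2[1] <= DIMER_OFFSET)
    stop("B1/B2 must lie in chain B (dimer index > 913)")
  segs <- unlist(lapply(ranges, function(r) r[1]:r[2]))
  if (anyDuplicated(segs)) stop("helix ranges must be disjoint")
  structure(ranges, class = "helix_set")
}

#' Which helix (if any) a dimer-numbered residue belongs to.
#' @noRd
helix_of <- function(res_dimer, hset) {
  out <- rep(NA_character_, length(res_dimer))
  for (nm in names(hset)) {
    r <- hset[[nm]]
    out[res_dimer >= r[1] & res_dimer <= r[2]] <- nm
  }
  out
}

#' Indices of atoms by name within each residue (utility selection).
#'
#' @param topology a `topology`.
#' @param names atom names to keep (default C-alpha).
#' @param residues optional dimer-numbered residues to restrict to.
#' @return integer vector of atom row indices.
#' @export
atom_select <- function(topology, names = "CA", residues = NULL) {
  a <- topology$atoms
  keep <- a$name %in% names
  if (!is.null(residues)) keep <- keep & a$res_dimer %in% residues
  which(keep)
}

#' Backbone (N, CA, C, O) atom indices.
#' @rdname atom_select
#' @export
backbone_select <- function(topology) {
  atom_select(topology, names = c("N", "CA", "C", "O"))
}

#' Place missing polar hydrogens by idealised geometry
#'
#' Adds a backbone amide hydrogen to every non-proline residue lacking one
#' (N-H 1.01 Angstrom along the bisector of the C(prev)-N and CA-N directions;
#' chain-start residues use the in-residue bisector), and a hydroxyl hydrogen
#' to serine/threonine/tyrosine OG/OG1/OH oxygens (O-H 0.96 Angstrom, anti to
#' the preceding side-chain carbon). Needed for the donor-hydrogen-acceptor
#' angle criterion when a structure comes without hydrogens.
#'
#' @param structure list(topology, coords) as returned by [read_structure()].
#' @return structure with hydrogens appended and the topology rebuilt.
#' @export
place_polar_hydrogens <- function(structure) {
  top <- structure$topology
  a <- top$atoms
  xyz <- structure$coords
  add <- list()
  res <- top$residues
  for (i in seq_len(nrow(res))) {
    rd <- res$res_dimer[i]
    rows <- which(a$res_dimer == rd)
    nm <- a$name[rows]
    if (res$resname[i] != "PRO" && !("H" %in% nm) && all(c("N", "CA", "C") %in% nm)) {
      Npos <- xyz[rows[nm == "N"][1], ]
      CApos <- xyz[rows[nm == "CA"][1], ]
      prev <- which(a$res_dimer == rd - 1 & a$name == "C" & a$chain == a$chain[rows[1]])
      dirs <- if (length(prev)) {
        vunit(vunit(Npos - xyz[prev[1], ]) + vunit(Npos - CApos))
      } else {
        Cpos <- xyz[rows[nm == "C"][1], ]
        vunit(Npos - (CApos + Cpos) / 2)
      }
      add[[length(add) + 1]] <- list(
        row = data.frame(name = "H", resname = res$resname[i],
                         chain = res$chain[i], res_local = res$res_local[i]),
        pos = Npos + 1.01 * dirs)
    }
    hydroxyl <- c(SER = "OG", THR = "OG1", TYR = "OH")[res$resname[i]]
    if (!is.na(hydroxyl) && hydroxyl %in% nm &&
        !any(grepl("^H", nm) & nm %in% c("HG", "HG1", "HH"))) {
      Opos <- xyz[rows[nm == hydroxyl][1], ]
      cb <- if (res$resname[i] == "TYR") "CZ" else "CB"
      anchor <- rows[nm == cb]
      if (length(anchor)) {
        add[[length(add) + 1]] <- list(
          row = data.frame(name = c(SER = "HG", THR = "HG1", TYR = "HH")[res$resname[i]],
                           resname = res$resname[i], chain = res$chain[i],
                           res_local = res$res_local[i]),
          pos = Opos + 0.96 * vunit(Opos - xyz[anchor[1], ]))
      }
    }
  }
  if (!length(add)) return(structure)
  new_rows <- do.call(rbind, lapply(add, `[[`, "row"))
  new_pos <- do.call(rbind, lapply(add, `[[`, "pos"))
  atoms2 <- rbind(a[, c("name", "resname", "chain", "res_local")], new_rows)
  xyz2 <- rbind(xyz, new_pos)
  # keep residue order: sort by chain, residue, with original relative order
  ord <- order(atoms2$chain, atoms2$res_local,
               c(seq_len(nrow(a)), rep(seq_len(nrow(a))[1], nrow(new_rows))) * 0 +
                 c(seq_len(nrow(a)), nrow(a) + seq_len(nrow(new_rows))))
  atoms2 <- atoms2[ord, , drop = FALSE]
  xyz2 <- xyz2[ord, , drop = FALSE]
  rownames(atoms2) <- NULL
  list(topology = make_topology(atoms2, xyz2), coords = xyz2)
}
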