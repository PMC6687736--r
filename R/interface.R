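# PISA-style interface estimator: solvent-accessible surface areas by
# Shrake-Rupley quadrature, interfacing atoms/residues from the SASA loss upon
# complexation, solvation free-energy gain from an atomic-solvation-parameter
# model, and a Monte-Carlo P-value comparing the observed gain with random
# connected surface patches of the same residue count.

# Bondi van der Waals radii (Angstrom) for the supported elements.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

# Atomic solvation parameters, kcal/(mol Angstrom^2), Eisenberg-McLachlan
# style: carbon and sulfur favour burial, nitrogen and oxygen oppose it.
# Charged-group corrections are not modelled (no formal charges are tracked);
# the table is overridable through `solvation_params`.
SOLVATION_SIGMA <- c(C = 0.016, S = 0.021, N = -0.006, O = -0.006, H = 0)

#' Deterministic near-uniform unit sphere points (golden-spiral lattice).
#' @noRd
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Quadrature over a deterministic golden-spiral point lattice on each atom's
#' solvent-expanded sphere; a point is accessible when no other expanded
#' sphere covers it. Hydrogens are ignored (heavy-atom SASA, the usual
#' convention for interface work).
#'
#' @param structure list(topology, coords).
#' @param probe_radius solvent probe radius, Angstrom (default 1.4).
#' @param n_sphere_points quadrature points per atom (default 480).
#' @param subset optional atom indices to treat as the whole system (other
#'   atoms do not occlude); used for per-chain SASA.
#' @return numeric vector of per-atom areas (Angstrom^2), zero for hydrogens
#'   and for atoms outside `subset`.
#' @export
sasa <- function(structure, probe_radius = 1.4, n_sphere_points = 480,
                 subset = NULL) {
  top <- structure$topology
  xyz <- structure$coords
  if (is.null(subset)) subset <- seq_len(top$n_atoms)
  el <- top$atoms$element[subset]
  if (any(!el %in% names(VDW_RADII)))
    stop("no van der Waals radius for element ",
         paste(setdiff(el, names(VDW_RADII)), collapse = ","))
  heavy <- subset[el != "H"]
  r <- VDW_RADII[top$atoms$element[heavy]] + probe_radius
  pts <- sphere_points(n_sphere_points)
  n <- length(heavy)
  P <- xyz[heavy, , drop = FALSE]
  out <- numeric(top$n_atoms)
  # neighbour lists from the pairwise distance matrix (desk-scale systems)
  d2 <- outer(rowSums(P^2), rep(1, n)) + outer(rep(1, n), rowSums(P^2)) -
    2 * tcrossprod(P)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    surf <- sweep(pts * r[i], 2, P[i, ], `+`)
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (surf[acc, 1] - P[j, 1])^2 + (surf[acc, 2] - P[j, 2])^2 +
        (surf[acc, 3] - P[j, 3])^2
      acc[acc] <- dj >= r[j]^2
    }
    out[heavy[i]] <- 4 * pi * r[i]^2 * sum(acc) / n_sphere_points
  }
  out
}

#' PISA-style analysis of the A-B dimer interface
#'
#' Computes per-chain solvent-accessible surfaces in isolation and in the
#' complex; an atom is interfacing iff its SASA decreases upon complexation.
#' The interface area is (SASA_A + SASA_B - SASA_AB) / 2 and the solvation
#' free-energy gain is `delta_G = -sum sigma(element) * deltaSASA(atom)` over
#' interfacing atoms, negative when burying apolar surface is favourable.
#'
#' @param structure list(topology, coords) - typically the stable-window
#'   average structure.
#' @param solvation_params named sigma vector, kcal/(mol Angstrom^2)
#'   (default: the built-in carbon/sulfur-positive set).
#' @param probe_radius,n_sphere_points passed to [sasa()].
#' @return object of class `interface_report`: per-chain N(at), N(res),
#'   surface; interface_area; delta_G; per-atom SASA bookkeeping for the
#'   P-value machinery. `delta_G_p_value` is NA until [delta_g_pvalue()].
#' @export
interface_analysis <- function(structure, solvation_params = SOLVATION_SIGMA,
                               probe_radius = 1.4, n_sphere_points = 480) {
  top <- structure$topology
  chainA <- which(top$atoms$chain == "A")
  chainB <- which(top$atoms$chain == "B")
  s_ab <- sasa(structure, probe_radius, n_sphere_points)
  s_a <- sasa(structure, probe_radius, n_sphere_points, subset = chainA)
  s_b <- sasa(structure, probe_radius, n_sphere_points, subset = chainB)
  s_mono <- s_a + s_b
  dsasa <- s_mono - s_ab          # buried area per atom, >= 0 up to quadrature
  interfacing <- which(dsasa > 1e-9)
  sigma <- solvation_params[top$atoms$element]
  sigma[is.na(sigma)] <- 0
  dG <- -sum(sigma[interfacing] * dsasa[interfacing])
  per_chain <- lapply(list(A = chainA, B = chainB), function(ch) {
    iface <- intersect(interfacing, ch)
    list(n_at = length(iface),
         n_res = length(unique(top$atoms$res_dimer[iface])),
         surface = sum(s_mono[ch]))
  })
  area <- (sum(s_a) + sum(s_b) - sum(s_ab)) / 2
  in_contact <- area > 1e-6
  structure(list(
    chain_A = per_chain$A, chain_B = per_chain$B,
    interface_area = if (in_contact) area else 0,
    delta_G = if (in_contact) dG else 0,
    delta_G_p_value = NA_real_,
    in_contact = in_contact,
    atoms = list(sasa_monomer = s_mono, dsasa = dsasa,
                 interfacing = interfacing, sigma = sigma,
                 chainA = chainA, chainB = chainB)),
    class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  fmt <- function(ch, nm) sprintf("  chain %s: N(at) %d  N(res) %d  surface %.1f A^2\n",
                                  nm, ch$n_at, ch$n_res, ch$surface)
  cat("interface report:\n", fmt(x$chain_A, "A"), fmt(x$chain_B, "B"), sep = "")
  cat(sprintf("  interface area %.1f A^2  deltaG %.2f kcal/mol  P-value %s\n",
              x$interface_area, x$delta_G,
              ifelse(is.na(x$delta_G_p_value), "(not computed)",
                     sprintf("%.3f", x$delta_G_p_value))))
  invisible(x)
}

#' Surface-residue adjacency graph and per-residue hydrophobicity scores.
#' @noRd
surface_graph <- function(structure, report, chain = "A", neighbor_cut = 6) {
  top <- structure$topology
  at <- report$atoms
  ch_atoms <- if (chain == "A") at$chainA else at$chainB
  res_of <- top$atoms$res_dimer[ch_atoms]
  sasa_res <- tapply(at$sasa_monomer[ch_atoms], res_of, sum)
  surf_res <- as.integer(names(sasa_res)[sasa_res > 1])
  # per-residue sigma-weighted exposed area and total exposed area
  sig_area <- tapply(at$sigma[ch_atoms] * at$sasa_monomer[ch_atoms], res_of, sum)
  heavy <- ch_atoms[top$atoms$element[ch_atoms] != "H" &
                      top$atoms$res_dimer[ch_atoms] %in% surf_res]
  P <- structure$coords[heavy, , drop = FALSE]
  rr <- top$atoms$res_dimer[heavy]
  d2 <- outer(rowSums(P^2), rep(1, nrow(P))) +
    outer(rep(1, nrow(P)), rowSums(P^2)) - 2 * tcrossprod(P)
  close <- d2 <= neighbor_cut^2
  adj <- lapply(surf_res, function(r) {
    hits <- rr[apply(close[rr == r, , drop = FALSE], 2, any)]
    setdiff(unique(hits), r)
  })
  names(adj) <- surf_res
  list(residues = surf_res, adj = adj,
       sig_area = sig_area[as.character(surf_res)],
       area = sasa_res[as.character(surf_res)])
}

#' Grow a random connected patch of `size` surface residues.
#' @noRd
random_patch <- function(graph, size) {
  seed <- sample(graph$residues, 1)
  patch <- seed
  frontier <- graph$adj[[as.character(seed)]]
  while (length(patch) < size) {
    frontier <- setdiff(frontier, patch)
    if (!length(frontier)) break
    nxt <- if (length(frontier) == 1) frontier else sample(frontier, 1)
    patch <- c(patch, nxt)
    frontier <- union(frontier, graph$adj[[as.character(nxt)]])
  }
  patch
}

#' Hypothetical solvation gain of burying a surface patch, normalised to the
#' observed buried area so patches of different exposure are comparable.
#' @noRd
patch_score <- function(graph, patch, buried_area) {
  k <- as.character(patch)
  tot <- sum(graph$area[k])
  if (tot <= 0) return(0)
  -sum(graph$sig_area[k]) / tot * buried_area
}

#' Monte-Carlo P-value of the observed solvation free-energy gain
#'
#' Samples `n_samples` random connected surface patches of chain A with the
#' observed number of interfacing residues (grown by surface-neighbour
#' adjacency from a random seed residue) and scores each with the same
#' sigma-times-area accounting, normalised to the observed buried area. The
#' P-value is the fraction of patches whose hypothetical gain is lower (more
#' favourable) than the observed chain-A gain: values below 0.5 mark
#' interfaces more hydrophobic than a random surface patch of the same size.
#'
#' @param structure the structure given to [interface_analysis()].
#' @param report its `interface_report` (needs a nonzero interface).
#' @param n_samples number of random patches (> 0).
#' @param seed RNG seed (results are reproducible bit-exactly).
#' @return the report with `delta_G_p_value` filled in.
#' @export
delta_g_pvalue <- function(structure, report, n_samples = 200, seed = 1) {
  if (n_samples <= 0) stop("n_samples must be positive")
  if (!report$in_contact) {
    report$delta_G_p_value <- NA_real_
    return(report)
  }
  set.seed(seed)
  at <- report$atoms
  ifaceA <- intersect(at$interfacing, at$chainA)
  size <- length(unique(structure$topology$atoms$res_dimer[ifaceA]))
  graph <- surface_graph(structure, report, "A")
  if (size > length(graph$residues))
    stop("interfacing residue count exceeds the surface residue count")
  buried <- sum(at$dsasa[ifaceA])
  observed <- -sum(at$sigma[ifaceA] * at$dsasa[ifaceA])
  scores <- vapply(seq_len(n_samples), function(i)
    patch_score(graph, random_patch(graph, size), buried), numeric(1))
  report$delta_G_p_value <- mean(scores < observed)
  report
}
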