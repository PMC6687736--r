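# Interaction-occupancy accounting over the stable window. Occupancy is the
# percentage of analysed frames in which an interaction satisfies its geometric
# criteria. Detection is exact: a conservative triangle-inequality prescreen
# (mean distance minus both atoms' maximum displacements) only discards pairs
# that can never qualify, then the surviving pairs are evaluated in every frame.

#' Hydrogen-bond geometric criteria
#' @param max_donor_acceptor_distance Angstrom (default 3.2).
#' @param min_dha_angle donor-hydrogen-acceptor angle, degrees (default 120).
#' @export
hbond_criteria <- function(max_donor_acceptor_distance = 3.2,
                           min_dha_angle = 120) {
  stopifnot(max_donor_acceptor_distance > 0,
            min_dha_angle > 0, min_dha_angle <= 180)
  list(max_da = max_donor_acceptor_distance, min_angle = min_dha_angle)
}

#' Hydrophobic-contact criteria
#' @param distance_range inclusive [min, max] for the minimum distance between
#'   the two residues' hydrophobic atom sets, Angstrom (default 3.5-5.5).
#' @export
hydrophobic_criteria <- function(distance_range = c(3.5, 5.5)) {
  stopifnot(length(distance_range) == 2, distance_range[1] > 0,
            distance_range[1] < distance_range[2])
  list(min = distance_range[1], max = distance_range[2])
}

atom_cols <- function(a) as.numeric(t(outer(a, 1:3, function(i, k) 3 * (i - 1) + k)))

#' Per-atom mean position and maximum displacement over a frame block.
#' @noRd
frame_spread <- function(X, nat) {
  mu <- colMeans(X)
  dev2 <- 0
  for (k in 1:3) {
    cols <- seq(k, 3 * nat, by = 3)
    dev2 <- dev2 + (X[, cols, drop = FALSE] -
                      matrix(mu[cols], nrow(X), nat, byrow = TRUE))^2
  }
  list(mean = matrix(mu, nat, 3, byrow = TRUE),
       max_disp = sqrt(apply(dev2, 2, max)))
}

pair_dist <- function(X, a, b) {
  d2 <- 0
  for (k in 1:3) d2 <- d2 + (X[, 3 * (a - 1) + k] - X[, 3 * (b - 1) + k])^2
  sqrt(d2)
}

res_label <- function(topology, res_dimer) {
  r <- topology$residues
  paste0(r$resname[match(res_dimer, r$res_dimer)], res_dimer)
}

new_occupancy_table <- function(df) {
  df <- df[order(-df$occupancy, df$res1, df$res2), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("occupancy_table", "data.frame")
  df
}

#' Hydrogen-bond occupancy table
#'
#' A donor-acceptor pair counts in a frame iff the donor-acceptor distance is
#' at most `max_donor_acceptor_distance` and the donor-hydrogen-acceptor angle
#' at least `min_dha_angle`. Atom-level pairs are aggregated to residue pairs
#' by the maximum occupancy over their atom pairs; pairs within one residue are
#' skipped. Rows with zero occupancy are dropped.
#'
#' @param traj a `trajectory` whose topology has donors/acceptors (hydrogens
#'   placed if the structure lacked them).
#' @param window a `stable_window`.
#' @param criteria a [hbond_criteria()].
#' @param residues optional dimer-numbered residues both partners must lie in.
#' @return `occupancy_table` data.frame: res1, res2 (dimer numbers,
#'   res1 < res2), name1, name2, kind = "HB", occupancy (percent), label.
#' @export
hbond_occupancy <- function(traj, window, criteria = hbond_criteria(),
                            residues = NULL) {
  top <- traj$topology
  idx <- window_indices(window, traj)
  if (!length(idx)) stop("empty window")
  X <- traj$xyz[idx, , drop = FALSE]
  don <- top$donors
  acc <- top$acceptors
  if (!is.null(residues)) {
    don <- don[top$atoms$res_dimer[don$donor] %in% residues, , drop = FALSE]
    acc <- acc[top$atoms$res_dimer[acc] %in% residues]
  }
  if (!nrow(don) || !length(acc)) return(new_occupancy_table(
    data.frame(res1 = integer(0), res2 = integer(0), name1 = character(0),
               name2 = character(0), kind = character(0),
               occupancy = numeric(0), label = character(0))))
  sp <- frame_spread(X, top$n_atoms)
  pairs <- expand.grid(dh = seq_len(nrow(don)), a = seq_along(acc))
  dres <- top$atoms$res_dimer[don$donor[pairs$dh]]
  ares <- top$atoms$res_dimer[acc[pairs$a]]
  keep <- dres != ares
  # conservative lower bound on the frame-wise donor-acceptor distance
  dmu <- sp$mean[don$donor[pairs$dh], , drop = FALSE] -
    sp$mean[acc[pairs$a], , drop = FALSE]
  lb <- sqrt(rowSums(dmu^2)) - sp$max_disp[don$donor[pairs$dh]] -
    sp$max_disp[acc[pairs$a]]
  keep <- keep & lb <= criteria$max_da
  pairs <- pairs[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(p) {
    d <- don$donor[pairs$dh[p]]; h <- don$hydrogen[pairs$dh[p]]
    a <- acc[pairs$a[p]]
    da <- pair_dist(X, d, a)
    hit <- da <= criteria$max_da
    if (!any(hit)) return(NULL)
    # D-H-A angle at the hydrogen, only where the distance already passes
    v1 <- sapply(1:3, function(k) X[hit, 3 * (d - 1) + k] - X[hit, 3 * (h - 1) + k])
    v2 <- sapply(1:3, function(k) X[hit, 3 * (a - 1) + k] - X[hit, 3 * (h - 1) + k])
    v1 <- matrix(v1, ncol = 3); v2 <- matrix(v2, ncol = 3)
    cosang <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
    nqual <- sum(ang >= criteria$min_angle)
    if (nqual == 0) return(NULL)
    data.frame(res1 = top$atoms$res_dimer[d], res2 = top$atoms$res_dimer[a],
               occupancy = 100 * nqual / length(idx))
  })
  rows <- do.call(rbind, rows)
  finish_occupancy(rows, top, "HB")
}

finish_occupancy <- function(rows, topology, kind) {
  empty <- data.frame(res1 = integer(0), res2 = integer(0),
                      name1 = character(0), name2 = character(0),
                      kind = character(0), occupancy = numeric(0),
                      label = character(0))
  if (is.null(rows) || !nrow(rows)) return(new_occupancy_table(empty))
  lo <- pmin(rows$res1, rows$res2); hi <- pmax(rows$res1, rows$res2)
  key <- paste(lo, hi)
  occ <- tapply(rows$occupancy, key, max)
  parts <- do.call(rbind, strsplit(names(occ), " "))
  out <- data.frame(res1 = as.integer(parts[, 1]), res2 = as.integer(parts[, 2]),
                    occupancy = as.numeric(occ))
  out$name1 <- res_label(topology, out$res1)
  out$name2 <- res_label(topology, out$res2)
  out$kind <- kind
  out$label <- vapply(out$occupancy, strength_label, character(1))
  new_occupancy_table(out[, c("res1", "res2", "name1", "name2", "kind",
                              "occupancy", "label")])
}

#' Hydrophobic-contact occupancy table
#'
#' A residue pair counts in a frame iff the minimum distance over their
#' hydrophobic atom sets (side-chain carbons and sulfurs) lies within
#' `distance_range`. Pairs within one residue and sequence-adjacent pairs
#' (|delta index| <= 1 within a chain) are excluded.
#'
#' @inheritParams hbond_occupancy
#' @param criteria a [hydrophobic_criteria()].
#' @return `occupancy_table` with kind = "HI".
#' @export
hydrophobic_occupancy <- function(traj, window,
                                  criteria = hydrophobic_criteria(),
                                  residues = NULL) {
  top <- traj$topology
  idx <- window_indices(window, traj)
  if (!length(idx)) stop("empty window")
  X <- traj$xyz[idx, , drop = FALSE]
  hy <- top$hydrophobic
  if (!is.null(residues)) hy <- hy[top$atoms$res_dimer[hy] %in% residues]
  if (length(hy) < 2) return(finish_occupancy(NULL, top, "HI"))
  sp <- frame_spread(X, top$n_atoms)
  cmb <- expand.grid(i = seq_along(hy), j = seq_along(hy))
  cmb <- cmb[cmb$i < cmb$j, , drop = FALSE]
  a1 <- hy[cmb$i]; a2 <- hy[cmb$j]
  r1 <- top$atoms$res_dimer[a1]; r2 <- top$atoms$res_dimer[a2]
  same_chain <- top$atoms$chain[a1] == top$atoms$chain[a2]
  keep <- !(same_chain & abs(r1 - r2) <= 1)
  lb <- sqrt(rowSums((sp$mean[a1, , drop = FALSE] -
                        sp$mean[a2, , drop = FALSE])^2)) -
    sp$max_disp[a1] - sp$max_disp[a2]
  keep <- keep & lb <= criteria$max
  a1 <- a1[keep]; a2 <- a2[keep]; r1 <- r1[keep]; r2 <- r2[keep]
  if (!length(a1)) return(finish_occupancy(NULL, top, "HI"))
  lo <- pmin(r1, r2); hi <- pmax(r1, r2)
  key <- paste(lo, hi)
  rows <- lapply(split(seq_along(a1), key), function(g) {
    dmin <- rep(Inf, length(idx))
    for (p in g) dmin <- pmin(dmin, pair_dist(X, a1[p], a2[p]))
    nqual <- sum(dmin >= criteria$min & dmin <= criteria$max)
    if (nqual == 0) return(NULL)
    data.frame(res1 = r1[g[1]], res2 = r2[g[1]],
               occupancy = 100 * nqual / length(idx))
  })
  finish_occupancy(do.call(rbind, rows), top, "HI")
}

#' Qualitative persistence label for an occupancy percentage
#'
#' strong >= 50, medium in [20, 50), periodic in (0, 20), absent at 0
#' (thresholds configurable).
#'
#' @param occupancy_percent value in [0, 100].
#' @param strong,medium lower thresholds (percent).
#' @return one of "strong", "medium", "periodic", "absent".
#' @export
strength_label <- function(occupancy_percent, strong = 50, medium = 20) {
  if (!is.finite(occupancy_percent) || occupancy_percent < 0 ||
      occupancy_percent > 100)
    stop("occupancy must lie in [0, 100]")
  if (occupancy_percent >= strong) "strong"
  else if (occupancy_percent >= medium) "medium"
  else if (occupancy_percent > 0) "periodic"
  else "absent"
}

#' Central-helix contact census
#'
#' Counts the interactions (unique residue pairs from the hydrogen-bond and
#' hydrophobic tables) with occupancy at or above the threshold whose partners
#' lie in two different helices of the helix set. Reports the count for each of
#' the six helix pairs, the total, the intersubunit subtotal (one partner in
#' A1/A2, the other in B1/B2), and whether helix A1's intersubunit contacts
#' reach both B1 and B2 or only one of them - the interface balance criterion.
#'
#' @param hb_table,hi_table `occupancy_table`s computed over the same window.
#' @param helix_set a [helix_set()].
#' @param occupancy_threshold_percent minimum occupancy (default 10).
#' @param topology optional; when given, helix ranges are checked against it.
#' @return object of class `contact_census`.
#' @export
contact_census <- function(hb_table, hi_table, helix_set,
                           occupancy_threshold_percent = 10,
                           topology = NULL) {
  if (!is.null(topology)) {
    all_res <- topology$residues$res_dimer
    for (nm in names(helix_set)) {
      r <- helix_set[[nm]]
      if (!all(r[1]:r[2] %in% all_res))
        stop("helix ", nm, " lies outside the topology")
    }
  }
  tab <- rbind(as.data.frame(hb_table), as.data.frame(hi_table))
  input_empty <- nrow(tab) == 0
  pair_names <- c("A1-A2", "A1-B1", "A1-B2", "A2-B1", "A2-B2", "B1-B2")
  counts <- stats::setNames(integer(6), pair_names)
  a1_partners <- character(0)
  if (nrow(tab)) {
    tab <- tab[tab$occupancy >= occupancy_threshold_percent, , drop = FALSE]
    tab$h1 <- helix_of(tab$res1, helix_set)
    tab$h2 <- helix_of(tab$res2, helix_set)
    tab <- tab[!is.na(tab$h1) & !is.na(tab$h2) & tab$h1 != tab$h2, , drop = FALSE]
    tab <- tab[!duplicated(paste(tab$res1, tab$res2)), , drop = FALSE]
    if (nrow(tab)) {
      pr <- apply(cbind(tab$h1, tab$h2), 1, function(x) paste(sort(x), collapse = "-"))
      tt <- table(pr)
      counts[names(tt)] <- as.integer(tt)
      inter <- substr(tab$h1, 1, 1) != substr(tab$h2, 1, 1)
      a1 <- tab[inter & (tab$h1 == "A1" | tab$h2 == "A1"), , drop = FALSE]
      a1_partners <- unique(ifelse(a1$h1 == "A1", a1$h2, a1$h1))
    }
  }
  intersub <- sum(counts[c("A1-B1", "A1-B2", "A2-B1", "A2-B2")])
  balance <- if (input_empty) "undefined"
  else if (all(c("B1", "B2") %in% a1_partners)) "both"
  else if (identical(a1_partners, "B1")) "B1_only"
  else if (identical(a1_partners, "B2")) "B2_only"
  else if (!length(a1_partners)) "none"
  else "both"
  structure(list(pair_counts = counts, total = sum(counts),
                 intersubunit = intersub, a1_balance = balance,
                 threshold = occupancy_threshold_percent),
            class = "contact_census")
}

#' @export
print.contact_census <- function(x, ...) {
  cat("contact census (occupancy >=", x$threshold, "%):\n")
  print(x$pair_counts)
  cat("total:", x$total, " intersubunit:", x$intersubunit,
      " A1 balance:", x$a1_balance, "\n")
  invisible(x)
}
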