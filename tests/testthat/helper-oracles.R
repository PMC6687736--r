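# Independent oracles and shared fixtures. The recount implementations below
# deliberately share no code path with the package's detectors: no prescreen,
# direct per-frame geometry, separate aggregation.

small_bundle <- function(n = 8, ...) build_ideal_bundle(n, ...)

vlen <- function(v) sqrt(sum(v^2))

# naive hydrogen-bond occupancy recount: evaluates every donor-H/acceptor pair
# in every frame from first principles
naive_hbond_recount <- function(traj, window, max_da = 3.2, min_angle = 120) {
  top <- traj$topology
  idx <- window$start_frame:window$end_frame
  X <- traj$xyz[idx, , drop = FALSE]
  don <- top$donors
  acc <- top$acceptors
  res <- top$atoms$res_dimer
  cols <- function(a) 3 * (a - 1) + 1:3
  out <- list()
  for (p in seq_len(nrow(don))) {
    d <- don$donor[p]; h <- don$hydrogen[p]
    D <- X[, cols(d), drop = FALSE]; H <- X[, cols(h), drop = FALSE]
    for (a in acc) {
      if (res[a] == res[d]) next
      A <- X[, cols(a), drop = FALSE]
      da <- sqrt(rowSums((D - A)^2))
      v1 <- D - H; v2 <- A - H
      cosang <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
      count <- sum(da <= max_da & ang >= min_angle)
      if (count > 0)
        out[[length(out) + 1]] <- data.frame(
          res1 = min(res[d], res[a]), res2 = max(res[d], res[a]),
          occupancy = 100 * count / length(idx))
    }
  }
  if (!length(out)) return(data.frame(res1 = integer(0), res2 = integer(0),
                                      occupancy = numeric(0)))
  df <- do.call(rbind, out)
  normalize_recount(stats::aggregate(occupancy ~ res1 + res2, df, max))
}

# naive hydrophobic recount: per frame, the minimum distance over the two
# residues' hydrophobic atom sets must fall inside [lo, hi]
naive_hi_recount <- function(traj, window, lo = 3.5, hi = 5.5) {
  top <- traj$topology
  idx <- window$start_frame:window$end_frame
  X <- traj$xyz[idx, , drop = FALSE]
  res <- top$atoms$res_dimer
  chain <- top$atoms$chain
  cols <- function(a) 3 * (a - 1) + 1:3
  by_res <- split(top$hydrophobic, res[top$hydrophobic])
  rs <- as.integer(names(by_res))
  out <- list()
  for (i in seq_along(rs)) {
    for (j in seq_along(rs)) {
      if (j <= i) next
      r1 <- rs[i]; r2 <- rs[j]
      c1 <- chain[by_res[[i]][1]]; c2 <- chain[by_res[[j]][1]]
      if (c1 == c2 && abs(r1 - r2) <= 1) next
      dmin <- rep(Inf, length(idx))
      for (a in by_res[[i]]) for (b in by_res[[j]])
        dmin <- pmin(dmin, sqrt(rowSums((X[, cols(a), drop = FALSE] -
                                           X[, cols(b), drop = FALSE])^2)))
      count <- sum(dmin >= lo & dmin <= hi)
      if (count > 0)
        out[[length(out) + 1]] <- data.frame(res1 = r1, res2 = r2,
                                             occupancy = 100 * count / length(idx))
    }
  }
  if (!length(out)) return(data.frame(res1 = integer(0), res2 = integer(0),
                                      occupancy = numeric(0)))
  normalize_recount(do.call(rbind, out))
}

# occupancy table reduced to the recount's column layout for exact comparison
normalize_recount <- function(df) {
  df$res1 <- as.integer(df$res1)
  df$res2 <- as.integer(df$res2)
  df <- df[order(df$res1, df$res2), c("res1", "res2", "occupancy")]
  rownames(df) <- NULL
  df
}

table_as_recount <- function(tab) normalize_recount(as.data.frame(tab))

# closed-form exposed area of sphere 1 for two intersecting spheres
# (radii already probe-expanded), from the spherical-cap formula
two_sphere_exposed <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  if (d + r1 <= r2) return(0)
  # height of the buried cap on sphere 1
  h <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  4 * pi * r1^2 - 2 * pi * r1 * h
}

# 99% binomial interval for a count
binom_ci99 <- function(n, p) stats::qbinom(c(0.005, 0.995), n, p)

# one-atom-per-coordinate toy topology builder (single chain pair of glycines
# etc.) for SASA micro-fixtures
atoms_structure <- function(names, resnames, chains, res_local, coords) {
  atoms <- data.frame(name = names, resname = resnames, chain = chains,
                      res_local = res_local)
  top <- suppressWarnings(make_topology(atoms, coords))
  list(topology = top, coords = coords)
}
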