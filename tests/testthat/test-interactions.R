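# Geometric thresholds, occupancy exactness against the naive recount,
# strength labels, and the contact census.

# hand-built one-donor/one-acceptor system: D-H along +x, acceptor placed
# at a chosen distance on the x axis (angle at H is 180 degrees)
toy_hbond_traj <- function(acceptor_x) {
  atoms <- data.frame(
    name = c("N", "H", "CA", "C", "O", "N", "CA", "C", "O"),
    resname = c(rep("GLY", 5), rep("GLY", 4)),
    chain = c(rep("A", 5), rep("B", 4)),
    res_local = c(rep(1L, 5), rep(1L, 4)))
  coords <- matrix(c(
    0, 0, 0,       # N  (donor)
    1, 0, 0,       # H
    -0.8, 1.2, 0,  # CA
    -0.5, 2.6, 0,  # C
    -1.2, 3.6, 0,  # O
    acceptor_x, 0, 30,  # chain B N (far)
    acceptor_x + 1.2, 1, 30,
    acceptor_x + 1.8, 2.3, 30,
    acceptor_x, 0, 0    # chain B O = the acceptor under test
  ), ncol = 3, byrow = TRUE)
  top <- make_topology(atoms, coords)
  dimerdyn:::new_trajectory(top, matrix(as.numeric(t(coords)), 1), 100)
}

test_that("hydrogen-bond thresholds act exactly at 3.2 A and 120 degrees", {
  w <- window_frames(1, 1, 100)
  t1 <- toy_hbond_traj(3.1)   # 3.1 <= 3.2, angle 180 >= 120: counted
  tab1 <- hbond_occupancy(t1, w)
  expect_true(any(tab1$occupancy == 100))
  t2 <- toy_hbond_traj(3.3)   # 3.3 > 3.2: not counted
  tab2 <- hbond_occupancy(t2, w)
  expect_false(any(tab2$res1 == 1 & tab2$res2 == 914 & tab2$occupancy > 0))
})

test_that("planted occupancies are recovered and match the naive recount exactly", {
  b <- small_bundle()
  man <- reference_manifest(b, seed = 19, hbond_occupancies = 0.6,
                            contact_occupancy = 0.3, unwound_fraction = NULL,
                            mode_variances = c(1, 0.5))
  nfr <- 500
  sim <- simulate_trajectory(b, man, nfr, 100)
  w <- window_frames(1, nfr, 100)
  hb <- hbond_occupancy(sim$trajectory, w)
  hi <- hydrophobic_occupancy(sim$trajectory, w)
  expect_identical(table_as_recount(hb), naive_hbond_recount(sim$trajectory, w))
  expect_identical(table_as_recount(hi), naive_hi_recount(sim$trajectory, w))
  # binomial 99% interval around the planted occupancy
  a <- b$topology$atoms
  dres <- a$res_dimer[man$hbonds$donor]; ares <- a$res_dimer[man$hbonds$acceptor]
  occ <- hb$occupancy[hb$res1 == min(dres, ares) & hb$res2 == max(dres, ares)]
  ci <- binom_ci99(nfr, 0.6)
  expect_gte(occ * nfr / 100, ci[1])
  expect_lte(occ * nfr / 100, ci[2])
})

test_that("hydrophobic range excludes the clash regime below 3.5 A", {
  atoms <- data.frame(name = rep(c("N", "CA", "C", "O", "CB"), 2),
                      resname = "ALA",
                      chain = rep(c("A", "B"), each = 5),
                      res_local = 1L)
  base <- matrix(c(0, 0, 0, 1.46, 0, 0, 2, 1.3, 0, 1.6, 2.4, 0, 2.2, -0.8, 1.1),
                 5, 3, byrow = TRUE)
  mk <- function(cb_dist) {
    coords <- rbind(base, sweep(base, 2, c(30, 0, 0), `+`))
    coords[10, ] <- base[5, ] + c(cb_dist, 0, 0)
    top <- make_topology(atoms, coords)
    dimerdyn:::new_trajectory(top, matrix(as.numeric(t(coords)), 1), 100)
  }
  w <- window_frames(1, 1, 100)
  hit <- hydrophobic_occupancy(mk(4.5), w)   # inside [3.5, 5.5]
  expect_true(any(hit$res1 == 1 & hit$res2 == 914 & hit$occupancy == 100))
  clash <- hydrophobic_occupancy(mk(3.4), w) # below the range: not a contact
  expect_false(any(clash$res1 == 1 & clash$res2 == 914))
})

test_that("occupancy is invariant under a global rigid transform of all frames", {
  b <- small_bundle()
  man <- reference_manifest(b, seed = 23, unwound_fraction = NULL)
  sim <- simulate_trajectory(b, man, 60, 100)
  w <- window_frames(1, 60, 100)
  hb0 <- hbond_occupancy(sim$trajectory, w)
  hi0 <- hydrophobic_occupancy(sim$trajectory, w)
  R <- dimerdyn:::rotation_about(c(2, -1, 1), 63)
  moved <- sim$trajectory
  for (i in seq_len(nrow(moved$xyz))) {
    f <- sweep(matrix(moved$xyz[i, ], ncol = 3, byrow = TRUE) %*% t(R),
               2, c(-7, 4, 12), `+`)
    moved$xyz[i, ] <- as.numeric(t(f))
  }
  hb1 <- hbond_occupancy(moved, w)
  hi1 <- hydrophobic_occupancy(moved, w)
  expect_equal(table_as_recount(hb1), table_as_recount(hb0), tolerance = 1e-10)
  expect_equal(table_as_recount(hi1), table_as_recount(hi0), tolerance = 1e-10)
})

test_that("strength labels follow the occupancy bands", {
  expect_identical(strength_label(71.9), "strong")
  expect_identical(strength_label(50), "strong")
  expect_identical(strength_label(20), "medium")
  expect_identical(strength_label(45.2), "medium")
  expect_identical(strength_label(5), "periodic")
  expect_identical(strength_label(0), "absent")
  expect_error(strength_label(101), "\\[0, 100\\]")
})

census_fixture <- function(rows) {
  n <- length(rows$res1)
  df <- data.frame(res1 = rows$res1, res2 = rows$res2,
                   name1 = rep("X", n), name2 = rep("X", n), kind = rows$kind,
                   occupancy = rows$occupancy, label = rep("strong", n))
  dimerdyn:::new_occupancy_table(df)
}

test_that("contact census counts match exhaustive enumeration over rows", {
  hs <- helix_set(c(1, 10), c(21, 30))
  empty <- census_fixture(list(res1 = integer(0), res2 = integer(0),
                               kind = character(0), occupancy = numeric(0)))
  cen0 <- contact_census(empty, empty, hs)
  expect_true(all(cen0$pair_counts == 0))
  expect_identical(cen0$a1_balance, "undefined")

  rows <- list(res1 = c(2, 3, 25, 5, 22, 40, 6),
               res2 = c(915, 940, 927, 6, 926, 916, 938),
               kind = c("HB", "HI", "HI", "HI", "HB", "HB", "HI"),
               occupancy = c(60, 35, 20, 90, 15, 80, 5))
  tab <- census_fixture(rows)
  cen <- contact_census(tab, empty, hs, occupancy_threshold_percent = 10)
  # exhaustive: row1 A1(2)-B1(915) 60; row2 A1(3)-B2(940) 35; row3 B1-B1 skip;
  # row4 A1-A1 skip; row5 B1(922? no: res1=22 not in helix) skip;
  # row6 res1=40 outside helices skip; row7 A1(6)-B2(938) occ 5 < 10 skip
  expect_equal(unname(cen$pair_counts["A1-B1"]), 1)
  expect_equal(unname(cen$pair_counts["A1-B2"]), 1)
  expect_equal(cen$total, 2)
  expect_equal(cen$intersubunit, 2)
  expect_identical(cen$a1_balance, "both")

  # monotone nonincreasing in the threshold
  totals <- vapply(c(0, 10, 30, 50, 70, 100),
                   function(th) contact_census(tab, empty, hs, th)$total,
                   numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("helix ranges outside the topology are rejected", {
  b <- small_bundle()
  hs_bad <- helix_set(c(1, 500), c(600, 650))
  empty <- census_fixture(list(res1 = integer(0), res2 = integer(0),
                               kind = character(0), occupancy = numeric(0)))
  expect_error(contact_census(empty, empty, hs_bad, topology = b$topology),
               "outside the topology")
})
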