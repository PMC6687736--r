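# Structure/trajectory parsing, dimer numbering and round trips.

test_that("dimer numbering maps chain B to local + 913 and is a bijection", {
  atoms <- data.frame(name = rep(c("N", "CA", "C", "O"), 2),
                      resname = "GLY",
                      chain = rep(c("A", "B"), each = 4),
                      res_local = 1L)
  coords <- rbind(matrix(c(0, 0, 0, 1.46, 0, 0, 2, 1.2, 0, 1.7, 2.3, 0),
                         4, 3, byrow = TRUE),
                  matrix(c(10, 0, 0, 11.46, 0, 0, 12, 1.2, 0, 11.7, 2.3, 0),
                         4, 3, byrow = TRUE))
  top <- make_topology(atoms, coords)
  expect_equal(nrow(top$residues), 2)
  expect_equal(top$residues$res_dimer[top$residues$chain == "B"], 914)
  expect_equal(anyDuplicated(top$atoms$res_dimer[top$atoms$name == "CA"]), 0)
})

test_that("a file with an unmapped extra chain is a configuration error", {
  b <- small_bundle()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(b$topology, b$coords, f)
  lines <- readLines(f)
  lines <- sub("^(ATOM.{17})A", "\\1C", lines[1:5]) |> c(lines[-(1:5)])
  writeLines(lines, f)
  expect_error(read_structure(f), "configuration error")
})

test_that("PDB write/read round trip preserves coordinates to format precision", {
  b <- small_bundle()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(b$topology, b$coords, f)
  s2 <- read_structure(f)
  expect_equal(s2$topology$n_atoms, b$topology$n_atoms)
  expect_lt(max(abs(s2$coords - b$coords)), 1e-3)
  # dimer numbering bijection holds on the parsed structure
  r <- s2$topology$residues
  expect_true(all(r$res_dimer[r$chain == "B"] == r$res_local[r$chain == "B"] + 913))
  expect_equal(anyDuplicated(r$res_dimer), 0)
})

test_that("trajectory round trips agree across multi-model PDB and DCD", {
  b <- small_bundle()
  man <- reference_manifest(b, seed = 11, unwound_fraction = NULL)
  sim <- simulate_trajectory(b, man, 15, frame_interval_ps = 100)
  fp <- withr::local_tempfile(fileext = ".pdb")
  fd <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(sim$trajectory, fp)
  write_trajectory(sim$trajectory, fd)
  tp <- read_trajectory(fp, b$topology, 100)
  td <- suppressWarnings(read_trajectory(fd, b$topology, 100))
  expect_equal(nrow(tp$xyz), 15)
  expect_lt(max(abs(tp$xyz - sim$trajectory$xyz)), 1e-3)  # PDB: 3 decimals
  expect_lt(max(abs(td$xyz - sim$trajectory$xyz)), 1e-4)  # DCD: float32
  expect_lt(max(abs(tp$xyz - td$xyz)), 2e-3)
})

test_that("single-model PDB reads as a one-frame trajectory", {
  b <- small_bundle()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(b$topology, b$coords, f)
  tr <- read_trajectory(f, b$topology, 2)
  expect_equal(nrow(tr$xyz), 1)
})

test_that("a frame with the wrong atom count is reported by frame index", {
  b <- small_bundle()
  man <- reference_manifest(b, seed = 2, unwound_fraction = NULL)
  sim <- simulate_trajectory(b, man, 12, 100)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(sim$trajectory, f)
  lines <- readLines(f)
  # drop one ATOM line from the second model
  starts <- grep("^MODEL", lines)
  atom2 <- which(grepl("^ATOM", lines) & seq_along(lines) > starts[2])[1]
  writeLines(lines[-atom2], f)
  expect_error(read_trajectory(f, b$topology, 100), "frame 2")
})

test_that("result tables survive write/read round trips field-exactly", {
  b <- small_bundle()
  man <- reference_manifest(b, seed = 5, unwound_fraction = NULL)
  sim <- simulate_trajectory(b, man, 30, 100)
  w <- window_frames(1, 30, 100)
  hb <- hbond_occupancy(sim$trajectory, w)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_table(hb, f1)
  expect_identical(as.data.frame(read_occupancy_table(f1)), as.data.frame(hb))

  rep <- interface_analysis(list(topology = b$topology, coords = b$coords),
                            n_sphere_points = 120)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_table(rep, f2)
  rep2 <- read_interface_report(f2)
  for (fld in c("interface_area", "delta_G"))  # JSON doubles: 17 sig digits
    expect_equal(rep2[[fld]], rep[[fld]], tolerance = 1e-14)
  expect_identical(rep2$chain_A$n_at, rep$chain_A$n_at)
  expect_equal(rep2$chain_A$surface, rep$chain_A$surface, tolerance = 1e-14)

  ms <- pca_cartesian(sim$trajectory, w, target_frames = 30)
  sm <- mode_summary(ms)
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_table(sm, f3)
  expect_identical(as.data.frame(read_mode_summary(f3)), as.data.frame(sm))
})

test_that("polar hydrogens are placed when a structure lacks them", {
  b <- small_bundle()
  keep <- b$topology$atoms$element != "H"
  atoms <- b$topology$atoms[keep, c("name", "resname", "chain", "res_local")]
  s <- list(topology = make_topology(atoms, b$coords[keep, ]),
            coords = b$coords[keep, ])
  s2 <- place_polar_hydrogens(s)
  expect_gt(sum(s2$topology$atoms$element == "H"), 0)
  expect_gt(nrow(s2$topology$donors), 0)
  # placed amide H sits ~1.01 A from its nitrogen
  d <- s2$topology$donors[1, ]
  expect_equal(vlen(s2$coords[d$donor, ] - s2$coords[d$hydrogen, ]), 1.01,
               tolerance = 0.05)
})
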