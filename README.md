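# dimerdyn

Trajectory analysis of helix-bundle protein dimers, written for the
structural side of a muscular-dystrophy genetics question: recessive
mutations in anoctamin-5 (ANO5, 913 residues) cause the limb-girdle
muscular dystrophy subtype LGMD2L, and one candidate mechanism is
destabilisation of the ANO5 homodimer, whose core is a bundle of four
central alpha-helices (A1/A2 from subunit A, B1/B2 from subunit B, chain-B
residues dimer-numbered `local + 913`). Deciding whether a mutation loosens
that core means asking, of a molecular-dynamics trajectory: which interface
interactions persist, do the helices stay helical, how hydrophobic is the
buried surface, and how large are the concerted motions? This package
implements those analyses for anyone with a two-chain structure and a
trajectory - and, because the original ANO5 trajectories are not deposited,
ships a synthetic dimer generator with exact planted ground truth so every
analysis is testable end-to-end.

## What it computes

* **Stable-window gating** - backbone RMSD series (Kabsch superposition per
  frame) and detection of the analysis window: the longest stretch of at
  least 40 ns with `|slope| <= 0.01` A/ns and `sd <= 0.5` A whose leading
  10 ns also passes the slope test. Iterative-mean average structures.
* **Interaction occupancies** - an interaction's occupancy is
  `100 x (qualifying frames) / (window frames)`. Hydrogen bond: donor-
  acceptor distance `<= 3.2` A and D-H-A angle `>= 120` degrees.
  Hydrophobic contact: minimum side-chain C/S distance between two residues
  in `[3.5, 5.5]` A. Plus the central-helix contact census (counts per
  helix pair at `>= 10%` occupancy, intersubunit subtotal, A1-to-B1/B2
  balance).
* **Secondary structure** - Kabsch-Sander assignment from the backbone
  hydrogen-bond energy
  `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) < -0.5` kcal/mol,
  and helical content (SSC) per helix with the residue-frame-weighted
  accumulated average.
* **Interface energetics** - a PISA-style estimator: Shrake-Rupley SASA,
  interface area `(SASA_A + SASA_B - SASA_AB)/2`, per-chain counts of
  interfacing atoms/residues, solvation free-energy gain
  `deltaG = -sum sigma(element) * deltaSASA`, and a Monte-Carlo P-value
  comparing the observed gain with random connected surface patches of the
  same residue count (P < 0.5 means a hydrophobic, interaction-specific
  interface).
* **Essential dynamics** - PCA of coordinate fluctuations: global C-alpha
  (PCA-1), central-helix C-alpha (PCA-2), and six inter-helix centroid
  distances reduced to two components across systems (PCA-3); projections,
  sign-invariant r-squared between systems, eigen-spectrum tables and
  multi-model PDB mode animations.
* **Variant triage** - the rare-variant filter cascade (MAF < 3% in
  LGMD-panel genes, < 1% elsewhere; at least one damaging verdict among
  Mutation Taster / PolyPhen2 / PROVEAN / SIFT), the dbscSNV splice flag
  (both scores > 0.6), and deterministic prioritisation. A nine-variant
  ANO5 cohort table ships as `inst/extdata/table3_ano5.tsv`.

I/O: PDB (single- and multi-model) and DCD trajectories via bio3d (the DCD
writer is built in); CSV/JSON result tables with bit-exact round trips.

## Worked example

Simulate a wild-type-like synthetic run (two planted interface hydrogen
bonds at 71.9% and 57.4% occupancy, one hydrophobic contact at 30%, 20%
unwinding of mid-A1, concerted modes of 4 and 1 A^2) and analyse it:

```r
library(dimerdyn)

b   <- build_ideal_bundle()                      # C2-symmetric 4-helix dimer
man <- reference_manifest(b, seed = 7)           # planted ground truth
sim <- simulate_trajectory(b, man, n_frames = 600, frame_interval_ps = 100)

r  <- rmsd_series(sim$trajectory)
w  <- find_stable_window(r, 100)
#> stable window: frames 1-600 (59.90 ns)

hb <- hbond_occupancy(sim$trajectory, w)
head(hb[hb$res1 <= 913 & hb$res2 > 913, ], 2)    # intersubunit bonds
#>    res1 res2 name1  name2 kind occupancy  label
#> 33   10  920 SER10 SER920   HB        73 strong
#> 34    3  916  SER3 SER916   HB        57 strong

hi <- hydrophobic_occupancy(sim$trajectory, w)
contact_census(hb, hi, b$helices, 10)
#> contact census (occupancy >= 10 %):
#> A1-A2 A1-B1 A1-B2 A2-B1 A2-B2 B1-B2
#>     4     2     3     4     0     3
#> total: 16  intersubunit: 9  A1 balance: both

s <- ssc(ss_profile(sim$trajectory, w, stride = 2), b$helices)
#> SSC per helix: A1 67.8%, A2 83.3%, B1 83.3%, B2 83.3%; accumulated 79.4%

avg <- average_structure(sim$trajectory, w)
rep <- interface_analysis(list(topology = b$topology, coords = avg))
delta_g_pvalue(list(topology = b$topology, coords = avg), rep, 200, seed = 7)
#> interface report:
#>   chain A: N(at) 21  N(res) 12  surface 2225.3 A^2
#>   chain B: N(at) 14  N(res) 10  surface 2433.7 A^2
#>   interface area 180.0 A^2  deltaG -2.92 kcal/mol  P-value 0.305

pca_cartesian(sim$trajectory, w)
#> mode set: 168 modes over 56 atoms
#>   top eigenvalues (A^2): 8.137, 3.666, 0.891, 0.039, 0.016
#>   PC1 explains 63.8%; PC1-3 99.6%
```

Reading the output: the two planted bonds come back at 73% and 57% (their
draw-level truth - the tests require *exact* agreement with the generator's
Bernoulli log); the census finds A1 contacting both B1 and B2, the balance
signature of an intact interface; A1's helical content is depressed to 68%
by the planted 20% unwinding while the untouched helices sit at 83%; the
interface buries 180 A^2 with a favourable (negative) solvation gain and a
P-value below 0.5, i.e. more hydrophobic than a random surface patch; and
the leading PCA mode (planted variance 4 A^2, inflated here by the
unwinding motion) dominates the spectrum.

`run_pipeline(pipeline_config(seed = 7, out_dir = "run1"))` performs the
whole chain in one call and writes the occupancy tables, census, SSC
summary, interface report, eigen-spectra and feature projections - every
file stamped with the window, criteria and a config hash, byte-identical
on re-runs.

For variant tables:

```r
v   <- read_variants(system.file("extdata", "table3_ano5.tsv", package = "dimerdyn"))
flt <- filter_variants(v, gene_panel = c("ANO5", "DYSF", "CAPN3"))
nrow(flt$retained)                         #> 9  (all cohort variants survive)
v$protein[splice_flag(v$ada_score, v$rf_score)]  #> "p.His841Asp"
rank_variants(flt$retained)$protein[1:3]   #> the three truncating variants
```

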