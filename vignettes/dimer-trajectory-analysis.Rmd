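---
title: "Methods: trajectory analysis of helix-bundle dimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory analysis of helix-bundle dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The problem

Recessive missense mutations in anoctamin-5 (ANO5), a 913-residue putative
intracellular channel/scramblase, cause the limb-girdle muscular dystrophy
subtype LGMD2L. One proposed disease mechanism runs through the ANO5
homodimer: the dimerisation core is a bundle of four central alpha-helices
(two per subunit), and a mutation that loosens that core - fewer persistent
interface contacts, partial helix unwinding, a less hydrophobic buried
surface, larger and more disordered concerted motions - plausibly degrades
function even when the mutated residue is far from the interface.
Molecular-dynamics trajectories of wild-type and mutant dimer models are the
natural instrument for that question, and this package implements the
statistical analyses such a study needs, together with a synthetic trajectory
generator that makes every one of them testable against exact ground truth.

The package deliberately does *not* run molecular dynamics, build homology
models, or call variant-effect predictors. It consumes structures,
trajectories and annotated variant tables, and produces the derived
statistics.

# Conventions

**Dimer numbering.** Residue `i` of chain B carries dimer index `i + 913`
(the monomer length), so the four central helices are labelled A1/A2 in
chain A and B1/B2 at the symmetric offset positions in chain B. The map
(chain, local index) to dimer index is asserted to be a bijection on every
parsed structure. Ranges are inclusive; coordinates are in Angstrom, angles
in degrees.

**Backbone** means N, C-alpha, C, O. Missing polar hydrogens (amide N-H,
serine/threonine/tyrosine hydroxyls) are placed by idealised geometry -
amide H on the bisector of the C(prev)-N and C-alpha-N directions at
1.01 Angstrom - because the hydrogen-bond criterion needs an explicit
donor-hydrogen-acceptor angle.

# Stable-window gating

All averages and occupancies are computed over a *stable window*: a
contiguous stretch of at least 40 ns (`min_span_ns`) over which the backbone
RMSD to the first frame has plateaued. The detector scans candidate windows
(on a grid of up to 256 start/end anchors, evaluated exactly with prefix
sums) and accepts those with

* least-squares slope magnitude at most `slope_tol` (default 0.01 A/ns),
* standard deviation at most `sd_tol` (default 0.5 A), and
* the window's leading 10 ns (`head_ns`) passing the slope test on its own.

The third condition is this package's refinement. With only whole-window
statistics, a long window can absorb ~30 ns of a gentle drift ramp: the ramp
tail shifts the window mean and slope by less than the thresholds. The
head-slope test bounds ramp inclusion to the stretch whose deviation from
the plateau is genuinely indistinguishable at these tolerances - about
2-3 ns for typical ramp rates - which is the detector's stated boundary
resolution. Among qualifying windows the longest wins, ties towards the
latest start. An RMSD series with no qualifying window is a hard error,
never a silent full-range fallback: averaging over an unstable trajectory
would bias every downstream statistic.

Average structures use a two-pass iterative mean (fit all frames to a
reference, average, refit to the average, average again), which converges
for plateaued trajectories.

# Interaction occupancies

Occupancy is the percentage of analysed frames in which an interaction
satisfies its geometric criteria.

* **Hydrogen bond**: donor-acceptor distance at most 3.2 Angstrom *and*
  donor-hydrogen-acceptor angle at least 120 degrees. Atom-level pairs are
  aggregated to residue pairs by the maximum over atom pairs (reports are
  per residue pair; the alternative union-of-frames aggregation is noted but
  not used).
* **Hydrophobic contact**: the *minimum* distance over the two residues'
  hydrophobic atom sets lies in [3.5, 5.5] Angstrom. Hydrophobic atoms are
  the side-chain carbons and sulfurs of *all* residues, not only canonical
  hydrophobic ones - lysine's aliphatic stem makes real contacts and a
  residue-type filter would miss them. Distances below 3.5 Angstrom are the
  clash regime and never count. Intra-residue and sequence-adjacent pairs
  (|delta| <= 1 within a chain) are excluded.

Detection is exact despite a speed prescreen: a pair is skipped only when
the triangle bound (mean-structure distance minus both atoms' maximum
displacements over the window) already exceeds the cutoff, which can never
discard a qualifying pair. The test suite holds the detectors to *exact*
equality with an independent naive per-frame recount.

Persistence labels follow the occupancy bands strong (>= 50%), medium
([20, 50)), periodic ((0, 20)); the contact census counts residue pairs at
or above 10% occupancy (the conventional reporting floor) between distinct
central helices, reports the six helix-pair counts, the intersubunit
subtotal, and whether A1's intersubunit contacts reach both B1 and B2 or
only one of them - the interface balance criterion.

# Secondary structure

Assignment is Kabsch-Sander: the backbone hydrogen bond CO(i)...HN(j) is
scored with the electrostatic model
`E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol and
accepted below -0.5 kcal/mol; helical residues sit in runs of consecutive
i -> i+4 turns, strand residues on bridge ladders, everything else is coil.
Chains shorter than five residues are all-coil. Only the helix class enters
the helical-content summaries (SSC); strand is retained for completeness but
no 3-10/pi subtyping is attempted. SSC of a segment is the fraction of
helical residue-frames; the accumulated average pools the residue-frames of
all four central helices (residue-frame weighting, so unequal segment
lengths are handled correctly).

# Interface energetics

A PISA-style *estimator* (the reference service's internals are not public):

* SASA by Shrake-Rupley quadrature over a deterministic golden-spiral
  lattice (default 480 points/atom; heavy atoms only; Bondi radii C 1.70,
  N 1.55, O 1.52, S 1.80; probe 1.4 Angstrom). The deterministic lattice
  makes "SASA decreases upon complexation" a point-set-comparable test, at
  the cost of rotation invariance of the quadrature itself: per-chain areas
  of an exactly C2-symmetric dimer agree to ~0.1%, not bit-exactly.
* Interface area `(SASA_A + SASA_B - SASA_AB) / 2`; interfacing atoms are
  those whose SASA drops; N(res) counts residues with at least one such
  atom.
* Solvation free-energy gain `deltaG = -sum sigma(element) * deltaSASA`
  with atomic solvation parameters in the Eisenberg-McLachlan style
  (kcal/(mol A^2): C +0.016, S +0.021, N/O -0.006; hydrogens 0). Charged
  groups are not distinguished - formal charges are not tracked - so
  deltaG is comparative, not calorimetric. The table is overridable.
* The deltaG P-value asks whether the observed interface is more
  hydrophobic than chance: random connected surface patches of chain A with
  the observed interfacing-residue count are grown by surface-neighbour
  adjacency (residues within 6 Angstrom, a radius that yields contiguous
  patches of realistic interface shape), scored with the same
  sigma-times-area accounting normalised to the observed buried area, and
  the P-value is the fraction scoring more favourably. Values below 0.5
  mark interaction-specific, hydrophobic interfaces. The raw P-value is
  reported; no significance threshold is imposed. Under a null in which the
  "interface" is itself a random patch the P-value is uniform on [0, 1],
  which the test suite checks with a Kolmogorov-Smirnov test.

# Essential dynamics

Three PCA schemes, all on coordinate fluctuations without mass weighting:

* **PCA-1**: all C-alpha atoms; **PCA-2**: central-helix C-alpha only.
  Frames are uniformly subsampled to 2,500, superposed onto the iterative
  mean *over the analysis selection itself* (removing rigid-body motion
  exactly where the covariance is taken), and the 3N covariance is
  diagonalised. Eigenvalue signs are fixed by making each eigenvector's
  largest-magnitude component positive, so results are deterministic.
  Invariants enforced by tests: trace conservation to 1e-6 relative,
  orthonormal eigenvectors to 1e-8, PC1 projection variance equal to the
  first eigenvalue.
* **PCA-3**: the six pairwise distances between the four central helices'
  C-alpha centroids (4 helices give exactly 6 features, consistent with
  reducing the description to 2 components), sampled every 50th frame,
  concatenated across systems and jointly mean-centred. The features share
  units (Angstrom), so they are *not* z-scored; rescaling would distort the
  relative amplitudes the analysis is meant to compare. Per-system
  projection clouds, dispersions (trace of projection covariance) and
  centroid separations are reported.
* Projection r-squared between systems uses the squared Pearson correlation
  after linear-interpolation resampling to a common length; it is
  sign-invariant because eigenvector signs are arbitrary. Zero-variance
  series return an explicit undefined flag rather than NaN.

Mode animations are written as multi-model PDB interpolations along
mean +/- amplitude * eigenvector, with a per-atom displacement (arrow) CSV.

# The synthetic generator

Real ANO5 dimer trajectories are not publicly deposited, so validation runs
on synthetic ones with exact ground truth. The generator builds a
C2-symmetric four-helix-bundle dimer - each monomer an ideal helix-loop-helix
built from internal coordinates (phi -57, psi -47; the 1.5 Angstrom rise and
~100 degree twist emerge rather than being imposed), helix axes on a square
of side 11.5 Angstrom (clash-free yet in hydrophobic contact), chain B the
exact 180-degree image of chain A. Frames are then

* Gaussian amplitudes along planted orthonormal modes (orthogonalised
  against the selection's rigid-body motions so superposition cannot absorb
  them),
* per-frame Bernoulli toggles of planted hydrogen bonds (formed: D-A
  2.9 Angstrom at a 165-degree D-H-A angle; broken: 4.5 Angstrom) and
  hydrophobic contacts (4.5 vs 8 Angstrom),
* planted unwinding: the segment's backbone is replaced by an extended
  (phi = psi = 180) chain, centred on the segment midpoint and tilted 25
  degrees radially outwards so the splayed ends clear the intact turns,
* an optional drift phase: a linearly decaying non-rigid displacement that
  produces a monotone RMSD ramp before the plateau.

Every Bernoulli draw is logged in the returned manifest, so tests can
demand *exact* agreement between measured occupancies and the draw log, not
just statistical closeness. Identical seed and manifest give bit-identical
frames.

The default study conditions mirror the wild-type reference system this
package was built around: planted interface hydrogen bonds at 71.9% and
57.4% occupancy, a 10% census floor, concerted-mode variances of 4 and
1 Angstrom^2 at 2,500 analysis frames. The unwinding default (20% of frames,
middle third of helix A1) was chosen once as a realistic partial-fraying
level that leaves the accumulated helical content near the high-70s percent
range typical of a stable bundle. Fixture trajectories use a 100 ps frame
interval rather than the production 2 ps so that desk-scale frame counts
still span the 40 ns window rule; every ns conversion reads the interval
from metadata, never from an assumption.

What the generator does *not* emulate: force-field energetics, solvent and
membrane, thermostat correlations (frames are i.i.d., so real trajectories'
autocorrelation is absent), anharmonicity, and side-chain rotamer dynamics.
Passing tests therefore demonstrate that the *analyses* are correct and
well-calibrated on data with known structure - not that any particular
biological conclusion transfers.

# Variant triage

The filter cascade on annotated exome tables: retain a variant iff its
minor allele frequency is absent or below 3% for genes already associated
with limb-girdle muscular dystrophy (1% otherwise) *and* at least one
configured predictor calls it damaging. The default predictor set is
Mutation Taster, PolyPhen2, PROVEAN and SIFT - four, not three, following
the cohort table's footnote rather than the narrower methods wording; the
set is configurable. Absent frequencies (not observed in the population
database) pass the frequency clause. Malformed frequencies skip the record
with an audit note instead of aborting a whole cohort. The dbscSNV splice
flag requires *both* the ada and rf scores strictly above 0.6. Ranking is a
transparent stand-in for phenotype-aware prioritisers: truncating variants
first, then splice-flagged, then missense by damaging-verdict count, ties
by gene and position. ACMG codes pass through as labels; no evidence is
computed.

The packaged cohort fixture (`inst/extdata/table3_ano5.tsv`) holds the nine
distinct ANO5 variants of a five-patient LGMD2L cohort with their published
frequencies and PolyPhen2/SIFT verdicts. The dbscSNV scores for the
His841Asp row are synthetic placeholders (only "both above 0.6" was
reported), marked as such in the file header.

# Problem sizes and numerical choices

Test and acceptance runs use bundles of 8-16 residues per helix (~400-700
atoms), trajectories of 500-2,500 frames, 480-960 SASA points per atom and
200 Monte-Carlo patches; the full suite runs in about a minute and the
acceptance script in seconds on one CPU. Eigendecompositions clip
eigenvalues at zero (they can go negative by rounding only); collinear
superposition selections are rejected rather than silently fit; occupancy
tables drop zero rows and sort by descending occupancy with residue-pair
tie-breaks; all serialised numbers carry 17 significant digits so CSV round
trips are bit-exact (JSON doubles round-trip to the last 1-2 ulps, which the
tests treat as field-exact at 1e-14 relative).

# Known limitations

* The PISA-style deltaG is a surface/solvation estimator; it omits
  electrostatics of charged groups and conformational strain.
* The quadrature point lattice is fixed in the laboratory frame, so SASA is
  rotation-invariant only to ~0.1% at default density (raise
  `n_sphere_points` where that matters).
* Kabsch-Sander here implements the turn and bridge rules but not DSSP's
  full ladder/sheet bookkeeping or 3-10/pi subtypes; for the helix-content
  statistics this package reports, only the H class matters.
* The stable-window detector's boundary resolution on gentle ramps is
  2-3 ns (see above); windows are reported with their frame ranges so any
  gating decision is auditable.
* Synthetic trajectories are i.i.d. across frames; statistical errors on
  real, autocorrelated trajectories will be larger than the binomial
  intervals used here.
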