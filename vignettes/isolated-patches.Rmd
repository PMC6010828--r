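---
title: "Finding genetically and ecologically isolated habitat patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding genetically and ecologically isolated habitat patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopatch)
```

## The problem

Vector-control campaigns fail when a treated area is recolonized from
neighboring habitat. A habitat patch that is both *ecologically* suitable and
*genetically* isolated — little gene flow connecting it to the species' main
range — is therefore a natural target: control applied there is unlikely to be
undone by immigration. `isopatch` implements a pipeline that locates such
patches for a vector species (the motivating system is a riverine tsetse fly
in a ~50,000 km² region) from three inputs:

1. diploid microsatellite genotypes from georeferenced sampling sites,
2. an environmental raster stack at 1 km resolution,
3. presence-only field-survey records (trap locations).

The logic is: first find the environmental variable whose *resistance model*
predicts genetic differentiation beyond plain isolation by distance (IBD);
then convert that variable plus the presence records into a 0–1 connectivity
surface; finally extract discrete above-cutoff patches and keep the ones that
are isolated from the main habitat belt yet lie in suitable habitat.

## Stage by stage

### Genetic differentiation (M1)

Pairwise differentiation between sites is the Weir–Cockerham (1984)
multilocus θ: the a/b/c variance components are computed per locus and
allele, summed across loci, and the ratio taken once
(`fst_matrix()`). Missing genotypes are handled locus-wise, so every locus
contributes the individuals actually typed at it in both sites of a pair.
Negative estimates are reported as computed and clamped to zero only when
linearizing, since a negative θ means "no detectable differentiation".
For regression on distance, θ is linearized as F/(1−F) (`linearize_fst()`),
the transform under which differentiation grows approximately linearly with
distance at migration–drift equilibrium. IBD itself is assessed with a Mantel
test (`mantel_ibd()`): Pearson correlation of unfolded lower triangles,
one-sided significance from joint row/column permutation with the +1
correction so p is never exactly zero.

Per-site diversity (`diversity_stats()`) reports plain mean allele counts
(no rarefaction — with unequal sample sizes AR is biased upward for larger
samples; callers comparing sites should keep that caveat in mind), observed
heterozygosity, unbiased expected heterozygosity `(2n/(2n−1))(1−Σp²)`, and
F_IS = 1 − H_O/H_E.

### Resistance surfaces and circuit models (M2)

Each candidate variable is turned into four hypothesized cost surfaces
(`make_resistance_surface()`): 11 equal-width classes over the variable's
range (the maximum closes the last bin), costed either linearly
(1,10,…,100) or exponentially (1,25,…,500), in both directions (high value
aids or impedes movement). Testing all four reduces the subjectivity of cost
assignment.

Connectivity between sites on a cost surface is computed with circuit
theory: cells are graph nodes, neighboring cells are joined with conductance
`1/((r_i+r_j)/2)` (diagonals scaled by 1/√2 under the 8-neighborhood — the
Circuitscape convention), and the two-point effective resistance comes from
sparse Cholesky solves of the grounded graph Laplacian (`build_graph()`,
`resistance_matrix()`). One factorization per connected component serves all
focal injections; memory stays linear in nodes plus edges. Cumulative
current maps (`current_map()`) sum, over all focal pairs, half the absolute
incident edge current per node, with focal nodes carrying the full unit
current.

Practice differs on whether the site-pair matrices should be effective
resistances or straight-path means over the cost raster; both are
implemented (`mode = "effective"`, the
default, and `mode = "straightpath_surface"`), and the default is the one
that is self-consistent with the uniform-surface control below.

Before any of this, covarying variables are pruned (`covariation_filter()`):
for every variable the mean value along the straight path between each site
pair is computed by supercover traversal (every cell the segment touches,
unweighted), variables with |R| above 0.85 are grouped by single linkage,
and each group keeps its best PC1 representative. The 0.80 threshold is
reported (flagging) but 0.85 governs grouping; the two thresholds are kept
because reporting and pruning serve different purposes.

### Which variable matters (M3)

The association test is a two-step multiple matrix regression with
randomization (`ibd_residual_scan()` built on `mmrr()`): regress unfolded
F_ST on the geographic control, keep the residuals, then regress the
residual matrix on each candidate resistance matrix, with coefficient
significance from jointly permuting rows and columns of the response and
counting |t*| ≥ |t|. Vectors are standardized so betas are comparable across
surfaces. Partial Mantel tests (`partial_mantel()`) are provided as the
confirmatory companion.

The geographic control defaults to the effective resistance on an
all-cost-1 surface (`geographic_control_matrix(mode = "uniform_effective")`),
i.e. a "distance-only" circuit model — the same construction the
environmental matrices use, with the environment switched off. This matters:
on a raster graph, effective resistance grows roughly logarithmically with
distance, so a *linear* regression on raw kilometers leaves systematic
curvature in the residuals, and any spatially smooth but causally irrelevant
surface can soak it up. In null experiments with the synthetic generator,
kilometre controls let decoy variables reach ~10–15% rejection at α = 0.05,
while the matched uniform-resistance control brings them to at or below the
nominal rate (the permutation test conditions on a fitted control and is
conservative for true nulls). Great-circle kilometers remain available via
`geo_mode = "greatcircle"`.

No multiple-testing correction is applied across the 20 surfaces when
flagging significance at α = 0.05 (each surface is a competing hypothesis
for one signal); a Holm-adjusted column is reported alongside. A surface at
exactly p = 0.05 counts as selected (`≤`, not `<`) — the marginal case is
deliberately included.

### Connectivity surface (M4) and suitability (M6)

Both the univariate connectivity surface and the multivariate habitat
suitability model come from one presence-only maximum-entropy engine. The
model is the Gibbs distribution q(x) ∝ exp(w·f(x)) over background cells
maximizing the L1-penalized presence log-likelihood; features are min–max
scaled linear, quadratic, and 10-knot hinge transforms of each variable
(`feature_expand()`), and per-class base constants β (default 1) are scaled
by presence count as β/√m. The optimizer is proximal gradient descent
(FISTA with backtracking); convergence is declared when the KKT box
condition |E_q[f] − mean_presence f| ≤ β_f holds to tolerance (default
1e-6) for every feature — the defining property of the L1-regularized
maximum-entropy solution, and the property the test suite checks directly.

The 0–1 "logistic output" is `c·q·e^H/(1 + c·q·e^H)` with c = τ/(1−τ) and
prevalence τ = 0.5, so an uninformative model scores every cell 0.5. Open
water is a hard barrier for the organism, so masked cells are forced to 0
after the transform. The connectivity surface uses exactly one variable (the
M3 winner); the suitability model uses all retained variables and can be
merged with a prior map by cellwise maximum (`merge_max()`) — the inclusive
choice: over-predicting suitability under-predicts isolation, which is the
conservative direction for control planning.

This engine is a self-contained implementation of the standard penalized
maximum-entropy formulation; it does not attempt bit-compatibility with any
particular desktop MaxEnt release (no product/threshold features, clamping
subtleties, or auto-feature schedules), so percent-contribution tables from
such programs are not reproduction targets.

### Patches (M5) and isolation (M6)

`extract_patches()` thresholds the connectivity surface strictly above 0.5,
labels 8-connected components (union-find, verified against a flood-fill
oracle), and drops components under 4 pixels. `cluster_patches()` merges
patches whose minimum pixel-center gap is ≤ 5 km (single linkage) — 5 km
being the conservative end of the organism's dispersal range — and
`select_isolated()` applies the final rules: the largest patch and its
cluster are the main habitat belt; clusters with any pixel closer than 5 km
to the frame edge are excluded (they may connect to off-frame habitat);
remaining clusters are isolated, and suitable when cluster-mean suitability
exceeds 0.25 (an any-pixel mode is available; the mean is stable to
single-pixel noise).

Two structural facts are worth knowing. Patch count is monotone
non-increasing in the minimum mapping unit, and patches nest as the cutoff
rises (every higher-cutoff patch sits inside a lower-cutoff one, and the
foreground shrinks) — but the *count* is not monotone in the cutoff: one
blob can split into several retained components as the threshold rises, and
it routinely does on real connectivity surfaces. Sensitivity analyses over
cutoffs should therefore inspect the patch maps, not just the counts.

### Validation (band contrast)

`band_contrast()` implements the field check: within a 25–100 km distance
band (inclusive endpoints), pairs that include a predicted-isolated site
should show higher linearized F_ST than pairs entirely within the main
belt. The comparison is a Welch t-test by default (the equal-variance
variant and the one-sided alternative are flags); two-sided p is reported
even though the prediction is directional, which is the conservative
choice. Every reported pair is audited with its distance and group.

## The synthetic study system

`synthetic_dataset()` generates a full study with known ground truth so the
pipeline is testable end to end without any downloads. The defaults *are*
the study conditions of the test suite: a 56×56 grid of 1 km cells, 15
sites, 20 diploid individuals per site, 16 microsatellite loci with up to 10
alleles, deme size N_e = 200, and 400 generations of migration–drift
balance.

**Landscape.** The causal variable is a broad west–east ramp plus a smooth
Gaussian random field (patchiness scale 6 cells); a collinear twin (causal
plus small smooth noise, |R| > 0.9) exercises the covariation filter, and
two decoys are independent fields. The decoys use a finer patchiness scale
(2 cells): a decoy as smooth as the causal field inherits broad spatial
structure that is confounded with distance, which makes it a biased, not a
null, predictor — with fine-grained decoys the scan's null behavior is
measurable.

**Migration.** Demes sit at the sites and exchange genes according to an
exponential dispersal kernel in landscape resistance:
w_ij = exp(−R_ij/R_s), where R_ij is the effective resistance between the
demes on a mild cost transform of the causal layer (cost falls linearly
from 4 to 1 as the variable rises) and R_s is the median nearest-neighbor
resistance divided by 4. The matrix is scaled so the best-connected deme
exports m0 = 0.25 of its genes per generation, and each row's diagonal
absorbs the remainder — so poorly connected demes genuinely receive less.
Two design points deserve justification:

* *Why a kernel rather than migration proportional to conductance?* On a
  two-dimensional raster graph, effective resistance grows only
  logarithmically with distance, so conductance-proportional migration is
  nearly distance-flat and produces no isolation by distance — the defining
  feature of the empirical system. The exponential kernel turns log-growing
  resistance into power-law distance decay, which restores realistic IBD
  while leaving the causal layer as the only environmental driver. (A
  diagnostic with a pure 1/d³ kernel confirmed the drift engine itself
  produces strong IBD when the kernel decays.)
* *Why mild costs (1–4) for the generating surface when the analysis tests
  1–500 ladders?* The empirical regime this emulates has dominant IBD with
  a *marginal* environmental signal. Strong generating costs make the
  environment dominate pairwise resistance, which yields extreme drift
  outliers and paradoxically destroys the distance signal. The tested cost
  ladders are monotone transforms of the same causal field, so the signal
  remains attributable to the right variable.

With these defaults the generator reproduces the intended regime: pairwise
θ spanning ~0–0.15, Mantel IBD significant in ~85–90% of replicates, the
causal variable's surface ranked first in the residual scan in ≈100% of
replicates, and decoy rejection at or below 5%.

**Sites and presences.** Sites follow a jittered regular grid inset from
the frame edge, mimicking spaced trap-cluster protocols. True suitability
is a steep logistic response of the scaled causal variable,
plogis(10·(s − 0.65)): presences concentrate in good habitat, and the
above-cutoff connectivity pockets away from the main belt are rare and well
separated — the fragmented-margin regime in which isolated patches exist at
all. Presence points are drawn without replacement with probability
proportional to suitability, at cell centers. Initial allele frequencies
are one shared ancestral Dirichlet(1) draw per locus; there is no mutation
over the simulated span, and allele labels run 150–168 in steps of 2 like
microsatellite repeat sizes.

**What the generator does not emulate.** Real data add null alleles and
scoring error, temporal population fluctuation, bottlenecks from prior
control campaigns, spatially biased trapping effort, and environmental
layers measured with error and cross-correlated in more complex ways.
Passing the recovery experiments therefore shows the pipeline's inferential
machinery is sound under its own assumptions, not that any particular field
system satisfies them.

## Numerical choices

* Coordinates are degrees, latitude first; rasters store the center of the
  top-left cell and row 1 is northernmost; points snap to the containing
  cell. Degree→km conversion averages the meridian and parallel arcs at the
  grid's mean latitude on a sphere of radius 6371.0088 km; all point-pair
  distances are haversine on the same sphere.
* ESRI ASCII output prints 17 significant digits so write→read round-trips
  are bit-exact; GeoTIFF I/O stores 32-bit floats with a world-file
  georeference.
* Straight-path zonal means use an exact supercover traversal (boundary
  crossings split the segment; each interval midpoint identifies one cell);
  a crossing exactly through a cell corner contributes the diagonal cell —
  a measure-zero tie documented rather than special-cased.
* Laplacian systems use sparse Cholesky (`Matrix::Cholesky`, permuted,
  deterministic ordering) after grounding one focal node per component;
  disconnected focal pairs become `Inf` and are dropped listwise (with a
  reported count) by the matrix regressions.
* Equal-width resistance classes close the last bin on the right, so the
  variable's maximum falls in class 11; interior boundary values go to the
  upper class.
* Permutation p-values all use the +1 correction. Ties in the covariation
  filter's PC1 representative break lexicographically.
* The MaxEnt solver declares convergence on the KKT condition, not on step
  size; the line search doubles the local Lipschitz estimate on failure
  and relaxes it between iterations.

## Problem sizes in the test suite

The shipped tests run the permutation-calibration experiment at 500 null
replicates × 999 permutations for both MMRR and Mantel, the ground-truth
recovery experiment at 50 replicates of the full default-sized synthetic
study (999 scan permutations each), circuit verification on 100 random
graphs of up to 15 nodes against a dense pseudo-inverse oracle plus 100
Rayleigh-monotonicity perturbations, and patch-logic verification against a
recursive flood-fill oracle on random grids up to 50×50. These sizes were
chosen to keep the whole suite in the minutes range on a single core while
leaving the Monte-Carlo error of the calibration checks well inside their
acceptance bands.

## Known limitations

* Allelic richness is not rarefied; cross-site comparisons at unequal n
  overstate richness for larger samples.
* The residual-scan permutation test conditions on the fitted IBD control
  and is conservative for null surfaces; its nominal level is exact only
  for the unconditional null (verified separately in the calibration
  experiment).
* The maximum-entropy engine is deliberately not a clone of any desktop
  MaxEnt build; variable-contribution percentages from such builds are not
  comparable.
* Patch isolation is frame-relative: the edge-exclusion rule removes
  candidates near the boundary rather than modeling off-frame habitat.
* With a single sampled isolate, the band contrast's pairs that share that
  isolate are not independent; the t-test follows the original design and
  should be read as descriptive of the contrast, not as a strict
  independence-based inference.
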