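# isopatch

Identify genetically and ecologically isolated habitat patches of a vector
species from landscape genetic data.

Vector control (tsetse flies being the motivating system) is safest where a
population is unlikely to be recolonized after suppression. `isopatch`
locates such places by combining three data sources — diploid microsatellite
genotypes from georeferenced sampling sites, an environmental raster stack at
1 km resolution, and presence-only field-survey records — in a six-stage
pipeline:

1. **F_ST (M1).** Pairwise multilocus Weir–Cockerham θ between sites, with
   variance components summed over loci before the ratio; linearized as
   F/(1−F) for distance regressions; Mantel test for isolation by distance.
2. **Resistance surfaces and circuit models (M2).** Each environmental
   variable (after a covariation filter based on straight-path zonal means,
   |R| grouping and PC1 representatives) becomes four binned cost surfaces —
   11 classes costed 1–100 linearly or 1–500 exponentially, in both
   directions — and site-pair effective resistances are computed by circuit
   theory on the raster graph (sparse Laplacian solves; cumulative current
   maps available).
3. **Which variable predicts differentiation beyond distance (M3).**
   Two-step MMRR: regress unfolded F_ST on a distance-only control (an
   all-cost-1 circuit model by default), then test each resistance matrix
   against the residuals with row/column permutation of the response;
   partial Mantel tests as confirmation. Surfaces with p ≤ 0.05 advance.
4. **Connectivity surface (M4).** A univariate L1-regularized
   maximum-entropy model (linear + quadratic + hinge features, KKT-verified
   fit, logistic 0–1 output with prevalence τ = 0.5, open water forced to 0)
   built from the selected variable and the presence records.
5. **Patches (M5).** Strict >0.5 threshold, 8-connected components, minimum
   4 pixels, single-linkage clustering of patches closer than 5 km.
6. **Isolated patches within suitable habitat (M6).** A multivariate
   suitability model on all retained variables (optionally merged with a
   prior map by cellwise maximum); the largest patch and its cluster are the
   main habitat belt, clusters within 5 km of the frame edge are excluded,
   and the remainder are isolated when cluster-mean suitability exceeds
   0.25.

A forward-time synthetic-data generator (`synthetic_dataset()`) produces
complete studies with known ground truth — a causal environmental layer, a
collinear twin, decoy layers, resistance-kernel migration among demes,
Wright–Fisher drift, and suitability-weighted presences — so every stage is
testable end to end. A distance-band validation contrast (`band_contrast()`)
implements the field check that pairs involving a predicted-isolated site are
more differentiated than equally distant pairs inside the main belt.

## Worked example

Simulate a study at the default conditions and run the whole pipeline:

```r
library(isopatch)

dat <- synthetic_dataset(sim_config(seed = 8))
res <- run_pipeline(list(
  genotypes = dat$genotypes, sites = dat$sites, presences = dat$presences,
  env = dat$stack, n_perm = 999, seed = 8))
res
#> <pipeline_run> status: ok
#>   Mantel IBD: r = 0.309, p = 0.003
#>   selected variable(s): PSN
#>   [PSN] 3 patches, 1 isolated
```

The genotypes show significant isolation by distance (Mantel r = 0.309,
p = 0.003). The residual scan ranks the causal variable's surfaces first —
here the generator's causal layer is `PSN`, and its resistance models
dominate the table (negative beta for the "increasing" direction and
positive for "decreasing" are the same signal seen from both cost
orientations):

```r
head(res$scan$table[, c("surface", "beta", "t_stat", "p_mmrr", "selected")], 4)
#>                       surface       beta     t_stat p_mmrr selected
#> 1 PSN|increasing|linear_1_100 -0.8095439 -13.995132  0.001     TRUE
#> 2    PSN|increasing|exp_1_500 -0.7251571 -10.687944  0.001     TRUE
#> 3    PSN|decreasing|exp_1_500  0.5573424   6.812628  0.012     TRUE
#> 4 PSN|decreasing|linear_1_100  0.4329760   4.874861  0.062    FALSE
```

The patch stage then finds the main habitat belt plus two discrete patches,
one of which survives the edge and suitability rules as isolated:

```r
res$patches$PSN$table[, c("patch", "pixels", "cluster", "main_belt",
                          "edge_excluded", "isolated")]
#>   patch pixels cluster main_belt edge_excluded isolated
#> 1     1    536       1      TRUE          TRUE    FALSE
#> 2     2    196       2     FALSE         FALSE     TRUE
#> 3     3     33       3     FALSE          TRUE    FALSE
```

So in this simulated landscape the pipeline recovers the causal variable and
flags one 196-km² patch as both suitable and genetically isolated — the kind
of location a control trial would prioritize.

A command-line front-end (`exec/isopatch`) mirrors the stages
(`simulate`, `run`, `fst`, `resist`, `envfilter`, `circuit`, `scan`,
`validate`) for shell-driven runs; `isopatch run --config run.cfg` executes
the whole pipeline from a flat key=value config.

## Documentation

The methods vignette (`vignettes/isolated-patches.Rmd`) describes the models,
their assumptions, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, and the package's
numerical choices. Function-level documentation is in the roxygen comments
in `R/`.
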