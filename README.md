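# osteoshape

Shape-complexity analysis of 3D bone geometry, built for structures — like
the mammalian baculum — whose hooks, bends, grooves and tip projections
defeat landmark-based morphometrics. The package quantifies whole-bone
complexity at multiple spatial scales, summarises the scales by PCA, and
asks which life-history traits predict complexity once shared ancestry is
accounted for.

It is aimed at comparative morphologists working from micro-CT data
(binarised voxel volumes, point clouds, or triangulated surface meshes)
and at methodologists who want a fully testable reference implementation
of the two metrics.

## What it computes

**Alpha-shape complexity profiles** (point clouds). The Delaunay
tetrahedralization is filtered by circumradius; the shape at radius α keeps
the tetrahedra with circumradius ≤ α. Anchored at the *critical alpha*
α_c — the smallest radius giving a single connected region covering every
point — the score at refinement coefficient k is the volume deficiency
relative to the convex hull:

    s(k) = 1 − V(k·α_c) / V_hull,   k ∈ {1, 2, 4, 8, 16, 32} by default.

Convex clouds score ≈ 0 everywhere; bones that stay concave at coarse fits
(bends, hooks, deep grooves) score high even at large k.

**Curvature-energy profiles** (meshes, in the spirit of ariaDNE). On a
unit-surface-area mesh, each vertex's energy is the surface-variation
ratio λ₁/(λ₁+λ₂+λ₃) of the Gaussian-weighted covariance of its
neighbourhood at bandwidth ε ∈ {0.02, …, 0.12}; the bone's score is the
area-weighted sum. Zero for planes, rigid-motion invariant, robust to
triangle count.

**Downstream statistics.** Correlation-matrix PCA per metric; OLS and
PGLS with Pagel's λ (λ = 0, ML, 1) of PC scores on ln intromission
duration, ln sexual size dimorphism, and ln testes mass + ln male mass;
tie-corrected Kruskal–Wallis and pairwise Wilcoxon tests of PC scores
across nine ordinal character states; interobserver percent agreement.

**Synthetic ground truth.** A parametric baculum generator (watertight
tube meshes + solid point clouds + deterministic character scores), Yule
trees, λ-structured trait evolution, and `build_study()`, which plants
known effects of selection proxies on geometry so the entire pipeline can
be validated end to end.

## Worked example

```r
library(osteoshape)

# a synthetic 20-species study with a planted intromission effect
study <- build_study(n_species = 20,
                     effects = list(beta_intromission = 2), seed = 42)

# alpha-shape complexity of one species
pc <- normalize_size(study$clouds[["sp001"]])
complexity_profile(pc, species_id = "sp001")
#>   species coefficient alpha_radius score_volume n_regions
#> 1   sp001           1       0.0924        0.611         1
#> 2   sp001           2       0.1849        0.427         1
#> 4   sp001           8       0.7396        0.324         1
#> 6   sp001          32       2.9583        0.254         1
```

The score stays high as the coefficient grows — this bone keeps coarse
concavity (it carries a bend and a groove), unlike a plain rod whose
profile collapses toward 0.

```r
# all species -> PCA -> regression suite
profiles <- dplyr::bind_rows(lapply(study$species, function(sp)
  complexity_profile(normalize_size(study$clouds[[sp]]), species_id = sp)))
pca <- pca_correlation(complexity_matrix(profiles, "alpha"))
glance(pca)
#>   metric n_species pc1_pct pc2_pct two_pc_total_pct
#> 1  alpha        20    89.1    9.48             98.6

suite <- model_suite(pca, pca, study$life, study$tree)
dplyr::filter(suite, proxy == "intromission", response == "alphaPC1")
#>   lambda_mode  model_p adjusted_r2 f_statistic lambda_hat n_used
#> 1           0 4.32e-05       0.662        32.3      0.000     17
#> 2          ML 9.31e-05       0.627        27.8      0.979     17
#> 3           1 1.15e-04       0.616        26.7      1.000     17
```

PC1 absorbs 89% of the six-coefficient variance; the planted positive
effect of ln intromission duration on complexity is recovered with the
right sign (slope 1.86 ± 0.33) and survives all three λ treatments. With
missing life-history values, 17 of 20 species enter this model — the
complete-case n is reported per row, as in published comparative tables.

`run_pipeline()` orchestrates the same flow from a YAML config over files
on disk (manifest + life-history CSV + Newick tree + character CSV) and
writes `alpha_scores.csv`, `ariadne_scores.csv`, the two PCA score tables,
`variance.csv`, `table2.csv`, `kw_results.csv`, a pairwise-Wilcoxon table,
a log and a run manifest. A thin command-line wrapper lives at
`inst/scripts/osteoshape.R`.

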