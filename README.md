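# fidplan

Fiducial marker placement planning for CyberKnife stereotactic body
radiotherapy (SBRT) of superficial tumors.

CyberKnife tracks tumors by imaging implanted gold fiducial markers with
two kV X-ray sources at ±45°. Marker geometry is constrained: ≥ 3 markers,
pairwise distance ≥ 18 mm, triangle angles ≥ 30°, each marker ≤ 50 mm from
the tumor centroid, and no overlapping markers in either oblique
projection. For superficial tumors (20–50 mm below the skin) `fidplan`
plans compliant marker triples automatically:

1. **Surface modelling** — a tensor-product B-spline surface
   `S(u,v) = Σ_i Σ_j N_{i,p}(u) N_{j,q}(v) P_{i,j}` is least-squares
   fitted (`min Σ_k ‖P_k − S(u_k,v_k)‖²`) to a point cloud around the
   tumor and sampled uniformly in `(u,v)` into candidate implantation
   sites.
2. **Filtering** — candidates are restricted to a Z-band around the tumor
   and to the superficial depth band (20–30 mm from the tumor surface,
   ≤ 50 mm from its centroid).
3. **Set search** — a kd-tree fixed-radius query finds pairs closer than
   18 mm; the admissible-distance graph is their complement, and valid
   triples are its triangles with all interior angles ≥ 30°
   (maximal-clique semantics of the literal published pseudocode are
   available via `strict_paper_cliques`). An exhaustive brute-force
   planner serves as a correctness oracle in the tests.
4. **Projection check** — sets whose markers project within 5 mm of each
   other in either ±45° view are rejected.
5. **Scoring** — plans are scored on a 10-point rubric (proximity count,
   angle, distance, non-overlap).

A seeded ellipsoidal phantom generator supplies tumor + shell clouds so
everything is testable without clinical data.

## Worked example

```r
library(fidplan)

ph <- generate_phantom(phantom_spec(seed = 42L))   # sphere r = 15 mm, shell 20-30 mm
plan <- plan_fiducials(ph$tumor, ph$shell)
plan
#> <fiducial_plan>
#>   fitted cloud: offset-shell; surface residual E = 7324 mm^2
#>   candidates: 144 sampled -> 93 in Z band -> 80 in proximity band
#>   sets: 34032 geometric -> 32324 after DRR overlap filter
#>   best set rubric total: 10 / 10

plan_markers(plan)
#>             x         y          z
#> [1,] 15.99904 -41.12899   7.726035
#> [2,] 28.84482 -28.84595  -1.420007
#> [3,] 14.55520 -32.89314 -20.525734

plan$best_score
#> Fiducial plan rubric score
#>   1. markers within 50 mm of tumor centroid : 3
#>   2. angle between markers meets 30 deg     : 2
#>   3. distance between markers meets 18 mm   : 2
#>   4. non-overlapping markers in the DRRs    : 3
#>   total: 10 / 10
```

The 144 sampled surface sites shrink to 80 admissible candidates; 32 324
triples satisfy every constraint, and the first one scores the full 10
points — the markers sit 35–45 mm from the tumor centre, > 18 mm apart,
with a well-conditioned triangle visible in both views.

`render_report(plan, "plan.json", "json")` writes the config echo,
per-stage counts and per-set metrics; CSV and Markdown formats are also
available.

## Command line

```sh
inst/cli/fidplan phantom --semi-axes 15 --n 500 --seed 42 --out-dir out/
inst/cli/fidplan plan --phantom-seed 42 --out-dir out/        # exit 0; 3 if no set
inst/cli/fidplan score --markers markers.csv --tumor tumor.csv
```

Exit codes: 0 success, 2 input error, 3 no feasible set. A YAML config
file (`--config`) can hold any long option; explicit flags win.

## Scope

Geometry I/O is CSV / ascii-PLY point lists (binary DICOM structure sets
must be converted upstream). Projection is orthographic; DRR image
synthesis, needle-path planning and organ-at-risk avoidance are out of
scope. See `vignettes/fiducial-planning.Rmd` for the model, defaults and
limitations.
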