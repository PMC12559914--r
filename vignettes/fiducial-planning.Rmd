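---
title: "Planning fiducial marker placement for CyberKnife SBRT of superficial tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning fiducial marker placement for CyberKnife SBRT of superficial tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(fidplan)
```

## The clinical problem

CyberKnife tracks a moving tumor during stereotactic body radiotherapy by
imaging implanted gold fiducial markers with two ceiling-mounted kV X-ray
sources angled at ±45°. For tumors that sit 20–50 mm beneath the skin
(chest wall, breast, submandibular gland), markers can be placed in the
superficial tissue around the tumor, but the placement must satisfy strict
geometric constraints or the tracking algorithm discards markers:

* at least three markers, so a rigid 6-D pose can be recovered;
* every pair of markers at least **18 mm** apart;
* every interior angle of the marker triangle at least **30°** (the vendor
  manual allows 15°, but a wider margin is robust to post-implantation
  marker migration; the 15° floor is available as
  `constraint_config(preset = "manual-floor")`);
* each marker within **50 mm** of the tumor centroid, so marker and tumor
  move synchronously;
* no two markers may overlap in either ±45° oblique projection, or they
  cannot be segmented in the radiographs.

Manual placement planning is experience-driven and often needs repeated CT
sessions. `fidplan` automates it: it builds a smooth implantation surface
around the tumor, samples candidate sites on it, and enumerates *all*
marker triples that satisfy every constraint, leaving the physician a
ranked menu of valid options.

## The model and the algorithm

**Candidate surface.** Candidate implantation sites are modelled as a
tensor-product B-spline surface

$$S(u,v) = \sum_{i=0}^{m}\sum_{j=0}^{n} N_{i,p}(u)\, N_{j,q}(v)\, P_{i,j},$$

with basis functions $N_{i,p}$ on clamped knot vectors. Control points are
estimated by minimizing the least-squares error

$$E = \sum_{k=0}^{K-1} \lVert P_k - S(u_k, v_k)\rVert^2$$

over a point cloud $P_k$ surrounding the tumor — either a measured
implantation-shell cloud or the tumor-surface contour itself (in which case
sampled sites are pushed outward to the middle of the depth band). Because
the data are scattered, each point needs parameters $(u_k, v_k)$ before
$E$ can be evaluated; `fidplan` uses a cylindrical parameterization
(azimuth about the cloud's principal axis → $u$, normalized axial
coordinate → $v$). The solve is a dense orthogonal-factorization least
squares; an optional Tikhonov penalty on second differences of the control
grid handles rank-deficient parameterizations. The surface is *not*
periodic in $u$: the seam is accepted, and seam candidates remain valid
marker sites.

**Candidate filtering.** The fitted surface is sampled on a uniform
$(u,v)$ grid. Candidates are then filtered:

1. a Z-axis band around the tumor midpoint (default half-width: half the
   tumor's Z extent plus 10 mm — the threshold is otherwise unspecified
   clinically) keeps sites axially near the tumor;
2. a proximity rule keeps sites within 50 mm of the tumor centroid *and*
   whose distance to the tumor surface (minimum distance to the tumor
   cloud) lies in the 20–30 mm superficial depth band. The 50 mm rule is
   deliberately measured to the centroid and the depth band to the
   surface; both cached distances are reported.

**Set enumeration.** Admissibility is graph-theoretic: vertices are
candidates, and an edge joins two candidates whose distance is ≥ 18 mm
(inclusive — the displayed constraint is "≥ 18 mm", and the same inclusive
reading is used for the 30° rule). Close pairs (< 18 mm) are found with a
kd-tree fixed-radius query and the edge set is their complement, which is
cheaper than testing all pairs when close pairs are rare. Valid triples
are the triangles of this graph whose interior angles all meet the 30°
threshold. Two enumeration modes exist:

* **default** — every 3-clique of the graph (equivalently, every 3-subset
  of every maximal clique). Triangles are listed directly from the graph's
  adjacency structure: on these near-complete graphs maximal-clique
  enumeration (Bron–Kerbosch) can be exponential in the number of disjoint
  close pairs, while triangle listing is polynomial and provably yields
  the same set collection.
* **`strict_paper_cliques`** — only *maximal* cliques of size exactly 3
  (via `igraph::max_cliques`), reproducing the published pseudocode
  literally. This misses triangles embedded in larger cliques, so it is
  always a subset of the default mode; it is kept for fidelity and
  comparison.

A brute-force planner (`brute_force_plan()`) exhaustively enumerates all
triples and applies the constraints directly — angles via the law of
cosines rather than the planner's normalized dot products — and serves as
the correctness oracle: the test suite requires exact agreement with the
graph route on randomized instances up to 200 candidates.

**Projection overlap.** Each surviving set is projected into the two
oblique views. The published recipe rotates marker coordinates about Z by
±45° (taking the tumor centroid as origin) and projects onto the X–Y
plane; but a rotation about Z is an isometry of the X–Y plane, so that
recipe cannot distinguish the two views — overlap decisions become
rotation-independent, which the test suite asserts as a property. The
default mode therefore interprets each imager as a beam along the rotated
Y axis and projects onto the rotated X–Z plane, matching the stereoscopic
±45° geometry; the literal mode is retained behind
`constraint_config(literal_projection = TRUE)`. Overlap is a projected
distance strictly below `overlap_extent` (default 5 mm, a typical gold
fiducial length; no clinical tolerance is published), so "touching"
projections pass. Orthographic projection is used; divergent-beam
geometry is out of scope.

**Scoring.** Accepted plans are scored on a 10-point rubric: markers
within 50 mm of the centroid (1/2/≥3 → 1/2/3 points), all angles meeting
30° (2 points), all distances meeting 18 mm (2 points), non-overlapping
markers in the DRRs (1/2/≥3 → 1/2/3 points). The rubric's printed
inequalities are strict while the planning constraints are inclusive; at
exact boundaries the rubric awards the points (so planner-accepted sets
always total 10), and `strict_rubric = TRUE` switches to the literal
strict reading. Zero qualifying markers is not tabulated by the rubric
and scores 0 with a warning.

## The synthetic phantom

No patient geometry ships with the package, so a seeded generator
(`generate_phantom()`) emulates the superficial-tumor situation: an
ellipsoidal tumor surface cloud plus a shell cloud obtained by offsetting
each surface point outward along the local ellipsoid normal by a uniform
draw from the 20–30 mm depth band. For a convex surface the normal offset
equals the point-to-surface distance, so the generated shell sits exactly
in the band — which makes the proximity filter's behaviour on phantoms
exactly predictable and lets tests verify band semantics against a
numeric point-to-ellipsoid projection oracle. The default spec (sphere of
radius 15 mm, 500 points, no noise) represents a small superficial lesion;
Gaussian coordinate noise is available but defaults to 0 so tests are
exact.

What the phantom does *not* emulate: real contour anisotropy (CT slice
spacing), skin-surface accessibility, tissue heterogeneity, or organs at
risk. Passing on phantoms therefore demonstrates geometric correctness of
the planner, not clinical adequacy of a specific plan.

## A worked run

```{r plan}
ph <- generate_phantom(phantom_spec(seed = 42L))
plan <- plan_fiducials(ph$tumor, ph$shell)
plan
```

```{r markers}
plan_markers(plan)
plan$best_score
```

Reports carry the config echo, per-stage candidate counts and every set's
cached metrics:

```{r report, eval = FALSE}
render_report(plan, "plan.json", "json")
```

## Numerical choices and defaults

* **Degrees** default to cubic ($p=q=3$), the standard smooth-surface
  choice; knot vectors are clamped with uniform interior knots.
* **Control grid** 8×8 and **sampling grid** 12×12 by default: for
  500-point shells this leaves the least-squares system comfortably
  overdetermined, and 144 sampled sites keep triple enumeration (≈ 10^5
  triangles after filtering) interactive on a single core. The acceptance
  analyses in `scripts/acceptance.R` use these defaults.
* **Tie-breaks and determinism**: candidates are ordered in $(u,v)$ grid
  order; set tables are sorted lexicographically by candidate index; all
  randomness lives in seeded generators, so a plan is reproducible from
  its config and seed.
* **Degenerate triangles**: collinear triples yield angles (0, 0, 180) and
  fail the 30° rule naturally; coincident points are a degeneracy error
  in the scalar API and cannot co-occur in a set (their distance is
  below 18 mm).
* **Boundary semantics**: distance and angle thresholds inclusive;
  projected overlap strict. These choices make the planner's acceptances
  and the rubric's full score mutually consistent.
* **Surface seam**: the non-periodic $u$ parameterization duplicates a
  seam meridian approximately; near-coincident seam candidates are never
  co-selected because their mutual distance is far below 18 mm.

## Design decisions that were genuinely open

* The source geometry never states a scattered-data parameterization; the
  cylindrical mapping was chosen because superficial-tumor shells are
  star-shaped about their principal axis, making the mapping injective in
  practice. Pathological (strongly folded) anatomies would need a
  different parameterization.
* Whether the depth rule references the tumor surface or centroid is
  ambiguous in clinical phrasing; `fidplan` measures the 20–30 mm band to
  the surface and the 50 mm rule to the centroid, and caches both
  distances per candidate so either convention can be audited.
* The 18 mm rule is applied in 3-D (not per projection), following the
  displayed constraint.
* Input geometry is read from CSV/ascii-PLY point lists; contour extraction
  from treatment-planning exports is expected to happen upstream, keeping
  the package free of binary-format dependencies.

## Problem sizes used in validation

The shipped validation suite runs entirely on generated data: reference
phantoms with 500-point clouds (the default), randomized
constraint-satisfaction instances up to 200 candidates for
oracle-equivalence checks, and 20-seed phantom batches for threshold
soundness. These sizes were chosen as representative of clinical candidate
counts (a few hundred sampled sites) while keeping the whole suite fast on
one core.

## Limitations

* Orthographic, not divergent-beam, projection; no DRR image synthesis.
* No needle-path or organ-at-risk planning: superficial markers are
  assumed implantable from the skin surface.
* `set_size > 3` is supported (angle rules applied to every 3-subset) but
  redundancy optimization for 4–6 marker protocols is not attempted.
* DICOM structure sets must be converted to point lists upstream.
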