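---
title: "Methods: OCTA morphometry of myopic CNV in octamorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OCTA morphometry of myopic CNV in octamorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octamorph)
```

# Scope and conventions

`octamorph` quantifies the morphology of a myopic choroidal
neovascularization (mCNV) lesion from a 2D en face OCT angiogram and a
manually drawn lesion contour. The package deliberately starts *after*
acquisition: slab segmentation, projection-artifact handling and the
qualitative grading of lesion phenotypes are inputs, not outputs.

**Coordinates.** Pixels are addressed row-major; contour coordinates are
corner-based, so the 0-based pixel `(row r, col c)` covers the unit square
`[c, c+1] × [r, r+1]` and its center sits at `(c + 0.5, r + 0.5)`. A pixel
belongs to a lesion iff its center is inside the polygon under the even-odd
rule. With this convention an axis-aligned square with corners `(10, 10)`
and `(20, 20)` covers exactly 100 pixels — areas behave like true
geometric areas.

**Units.** The physical pixel pitch defaults to `3/304` mm ≈ 9.87 µm, the
pitch of a 3 × 3 mm scan sampled on a 304 × 304 grid; it is a parameter of
every container, and all lengths (mm), areas (mm²) and calibers (µm) scale
from it. Intensities are min–max normalized to `[0, 1]` on load (a constant
image maps to zeros), which pins every filter parameter to a fixed scale.

# The binarization chain

`binarize_lesion()` runs denoise → vesselness → threshold → mask →
small-object removal. All convolutions use reflective boundaries so lesion
borders do not acquire dark-frame artifacts.

| parameter | default | meaning |
|---|---|---|
| `sigma_px` | 0.8 | Gaussian denoising σ (px) |
| `scales_px` | 1–4 | Frangi scales ≈ vessel half-widths (px) |
| `beta` | 0.5 | blobness sensitivity (dimensionless) |
| `c` | adaptive | structureness scale; half the 95th percentile of S per scale |
| `window_px` | 31 | adaptive-threshold window (px; ~0.3 mm) |
| `offset` | 0.15 | threshold offset on the `[0,1]` intensity scale |
| `min_object_px` | 10 | smallest surviving 8-connected component |

The Frangi filter uses γ-normalized Gaussian-derivative Hessians (the `s²`
multiplier), eigenvalues ordered by magnitude, bright-ridge polarity
(`λ₂ < 0`; OCTA flow signal is bright), the per-pixel maximum over scales,
and global max-normalization. Derivative kernels are forced to zero sum and
eigenvalues below `1e-8` in magnitude are treated as structure-free, so a
constant image yields an exactly zero map.

**Why the "combined" threshold mode.** Three modes exist. Thresholding the
vesselness map itself (`"vesselness"`) reproduces one reading of a combined
Frangi + adaptive-threshold strategy, but the multiscale response is
positive over a halo roughly `2 × scale` wide around each tube: on clean
synthetic networks with known tube masks it over-segments (Dice ≈ 0.60
against ground truth at zero offset). The default `"combined"` mode instead
thresholds the *denoised intensity* — which preserves vessel caliber — and
keeps only pixels whose vesselness exceeds 1 % of the map maximum, which
suppresses non-tubular clutter. With the defaults this reaches Dice
0.86–0.88 on clean renders and 0.85–0.87 under default speckle, with exact
junction recovery (next section). The denoising σ of 0.8 px and offset of
0.15 were fixed from this same synthetic-recovery analysis; stronger
smoothing widens the intensity skirt around vessels faster than the
threshold can reject it.

# Skeleton and graph

`skeletonize()` is Zhang–Suen two-subcycle thinning iterated to a fixed
point, followed by a sequential minimization pass that deletes any pixel
whose foreground neighbors remain mutually 8-connected without it. The pass
matters: parallel thinning leaves 2-px staircase remnants whose diagonal
shortcuts read as degree-3 pixels and would inflate junction counts by
roughly a factor of two on curved vessels. After minimization the skeleton
satisfies the natural fixed-point property — no pixel can be removed
without changing connectivity or shortening a branch — and `skeletonize()`
is idempotent.

`build_graph()` classifies skeleton pixels by 8-neighbor count, merges
8-adjacent junction pixels into clusters (a 4-valent crossing counts once;
the raw-pixel count remains available via `junction_count(g, "pixels")`),
and partitions every skeleton adjacency into branch paths. Two artifact
filters follow, both expressed in pixels and config-exposed:

* **Spur pruning** (`prune_px = 3`): endpoint branches not longer than 3 px
  are thinning artifacts at rounded vessel tips. Pruning is
  topology-aware: a spur hanging off a junction with only three
  connections is removed only when a second short endpoint arm marks the
  cluster as a tip-fork; otherwise the spur is an orphaned stub at a
  shallow-angle bifurcation and deleting it would demote a real junction.
* **Junction-bridge contraction** (`merge_junction_px = 8`): thinning can
  split one anatomical bifurcation into two triple points joined by a
  2–5 px bar. Bridges up to 8 px are contracted into a single junction; in
  generated networks real junction pairs are ≥ 15 px apart, so the two
  populations are cleanly separable. Contracted bar length is accounted
  under `internal_length_mm`, so branch lengths plus internal length equal
  the total skeleton length exactly (a tested invariant).

# Biomarker definitions and numerical choices

* **Total length** sums each skeleton adjacency once: 1 px orthogonal,
  √2 px diagonal.
* **Fractal dimension** counts occupied boxes at dyadic sizes
  `s ∈ {2, 4, …, min(h, w)/4}` anchored at the bounding-box origin and fits
  `log N` against `log 1/s`; at least three sizes are required. The
  default single anchor is fully deterministic and hits the analytic
  values for a line (1.00), a filled plane (2.00) and a rasterized
  Sierpinski gasket (1.58). An `offsets` argument averages counts over
  shifted grids; the synthetic ground truth uses `offsets = 4` because the
  single-anchor estimate fluctuates by about ±0.1 on small centerline
  sets, enough to mask treatment-induced changes of similar size.
* **Tortuosity** is the unweighted mean over branches of arc/chord (a
  length-weighted option exists). The branch *path length* keeps the raw
  step-sum definition, but the tortuosity *arc* is measured on a stride-5
  chord resampling of the path: the (1, √2) chain sum overestimates smooth
  arcs by ~5 % on average over directions (a digital semicircle would read
  1.65 instead of π/2 ≈ 1.571), while the resampled arc recovers π/2
  within 0.1 % and leaves straight and axis-aligned branches exact.
  Cycles use the loop diameter (maximum pairwise distance) as their chord;
  branches with zero chord and no extent are excluded.
* **Degenerate lesions.** A lesion with no detected vessels reports zeroed
  extensive metrics (VA, VL, VJ) and *missing* — never zero — for the
  intensive ones that are genuinely undefined there (VD, FD, VT, JD),
  mirroring cohort practice of excluding unidentifiable lesions rather
  than imputing zeros.

# The synthetic lesion generator

`generate_network()` grows seeded stochastic vessel networks in the four
clinical phenotypes: *medusa* (radial from the center), *sea-fan* (radial
from a 60° boundary sector), *tree-in-bud* (compact, no dominant trunk) and
*disorganized loops* (short segments with anastomotic loops). Growth is
depth-limited recursive bifurcation: branches advance in 5-px steps with
Gaussian direction perturbations, children inherit `caliber × 0.75–0.8`
and `length × 0.85–0.9`, and bifurcation half-angles are clamped to
20–55°. Ground truth (arclengths, junction count as nodes of degree ≥ 3,
per-branch arc/chord tortuosity) is computed from the continuous
polylines; areas and FD from the rasterized tube union and centerlines.

The generator is engineered so that ground truth is *resolvable on the
raster*: candidate steps keep a clearance of half the summed calibers plus
3 px from unrelated branches (tested at half-step resolution), branches
must clear three steps, trunk origins are spaced, and loop anastomoses
either join two free endpoints along their own tangents (a cubic Bézier —
no new junction, hence no raster ambiguity) or splice into an interior
vertex at least two steps away from any visible node. A draw that fizzles
into fewer than four segments regrows deterministically, and a loop-type
network that ended up loop-free gets a forced anastomosis pass, since the
loop defines that phenotype.

`apply_anti_vegf()` models treatment as caliber-selective pruning: every
segment thinner than the threshold disappears together with parts
disconnected from the roots, survivors dilate by `trunk_dilation` (default
1.15; remaining trunks carry more flow), and the lesion hull shrinks to the
survivors. Pruning everything is legal and yields the fully regressed
lesion. The transform is deterministic; its `seed` argument exists for
interface symmetry only.

**What passing tests show — and what they do not.** On clean renders the
pipeline recovers the true junction count exactly and total length within
5 % for the interlacing phenotypes (15/15 networks in the acceptance
suite, and ±15 % junctions under default speckle). Across a wider random
seed population exactness is ~100 % for medusa and sea-fan and ~90 % for
tree-in-bud, whose thick shallow-angle bifurcations occasionally thin into
two triple points joined by a bar just beyond the merge radius; the
acceptance script reports the exact-recovery rate it measures on its own
seed-derived panel. Two further honest gaps:
(i) loop-type networks are recovered only approximately (±1 junction on
about a quarter of seeds) because anastomotic attachment points are
inherently marginal at raster scale, so they are excluded from the
exact-recovery panel; (ii) the treated-direction property (areas, FD, VL,
VJ, JD decrease; mean caliber does not decrease) holds on the 20-network
interlacing panel at a 65th-percentile caliber prune, but it is *typical,
not universal* — junction counts are small integers, and on occasional
networks (about 1 in 20) the percent drop in VJ can fall just short of the
drop in VL, flipping the junction-density direction. The same integer
knife-edge, and the clinical tendency of immature loop lesions to regress
wholesale rather than prune selectively, is why the direction panel uses
the interlacing phenotypes that dominate real cohorts.

The generator also does **not** emulate: projection artifacts, perfusion
dropout, motion stripes, the dense capillary interweaving of real lesions
(synthetic vessel densities run 0.1–0.3 versus ~0.55 clinically, because
exact ground truth requires inter-vessel clearance), or realistic branch
microtortuosity (synthetic VT ≈ 1.00–1.05 versus ~1.26 clinically, which
also reflects the digitization bias of chain-length measures in published
pipelines). Conclusions about absolute clinical values therefore rest on
the bundled reference cohort tables, not on the simulator.

# Cohort statistics

`paired_change_test()` offers both the rank-sum convention (default,
mirroring the published analysis of baseline vs post-injection groups) and
the statistically conventional paired signed-rank test; `build_change_report()`
reports both p-values side by side and flags the convention in its
metadata. Small samples use exact enumeration of the null — all 2ⁿ sign
assignments (n ≤ 12 informative pairs) or all `choose(n₁+n₂, n₁)` rank
assignments (pooled n ≤ 12) on tie-averaged ranks, with two-sided
p = 2·min(tail probabilities) capped at 1 — which stays exact under ties,
where the base `wilcox.test` must fall back to an approximation. Larger
samples use the tie-corrected normal approximation; exact and approximate
p agree within 0.02 from n ≈ 10 (tested), and the type-I error at α = 0.05
over 1000 null simulations of 29 eyes is ~0.045.

Relative ratios are computed from group means (post-mean/baseline-mean, as
in the published tables — not the mean of per-eye ratios) and reported to
two decimals with `decrease = 100 − RR`. Two rows of the bundled reference
summary (`VLD`, `VT`) carry published ratios that are not reproducible from
the printed means at two decimals (evidently computed from unrounded
means); they are flagged `rr_consistent = FALSE` and excluded from numeric
reproduction checks. The reference CRT values are in µm (the printed unit
label "mm" is anatomically impossible for values near 317). P-values are
displayed to three decimals with a `<0.001` floor and no multiple-testing
correction, matching the source analysis. Spearman correlations use
tie-averaged ranks with the conventional strength bins on |r|
(≥0.90 very strong, 0.70–0.89 strong, 0.40–0.69 moderate, 0.10–0.39 weak,
otherwise negligible).

# Problem sizes used in the test suite

The suite and the acceptance script run on 304 × 304 images, 9–21 generated
networks per experiment, 1000 null simulations for test calibration, and a
31-eye simulated cohort — sizes chosen so every property is exercised at
the scale of a real 3 × 3 mm scan while the whole suite completes in well
under a minute per file.

# Known limitations

* The binarization defaults are tuned on synthetic renders; real OCTA
  speckle is spatially correlated and device-dependent, so `vessel_params`
  should be treated as a starting point and logged per run (every output
  embeds the parameter hash).
* Junction counting depends on the cluster-merge radius at the scale of
  vessel caliber; both the cluster and raw-pixel conventions are exposed
  because published tools differ silently on 4-valent crossings.
* Per-eye raw data for the reference cohort were never published; only the
  printed summaries are bundled, so cohort-level reproduction is limited
  to quantities derivable from those tables.
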