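# octamorph

Quantitative morphometry of myopic choroidal neovascularization (mCNV) on
en face OCT angiography (OCTA).

Active mCNV appears on OCTA as a bright neovascular network inside a
manually outlined lesion. Anti-VEGF injection prunes the small newly grown
vessels while sparing the larger trunks, and the question for the clinician
is which quantitative descriptor of the network tracks that response most
sensitively. `octamorph` implements the full measurement chain from a raw
angiogram to nine vascular biomarkers, the paired cohort statistics used to
compare baseline against post-injection panels, and a seeded synthetic
lesion generator that provides exact ground truth for validating every
stage.

## The measurement chain

Given a grayscale en face image `I` (min–max normalized to [0, 1]) and a
lesion contour:

1. **Denoise** — convolution with a normalized Gaussian (σ in px,
   reflective boundaries).
2. **Frangi vesselness** — per scale *s*, the γ-normalized Hessian
   eigenvalues |λ₁| ≤ |λ₂| give blobness R_b = λ₁/λ₂ and structureness
   S = √(λ₁² + λ₂²);
   `V = exp(−R_b²/2β²)·(1 − exp(−S²/2c²))` where λ₂ < 0 (bright ridges),
   maximized over scales.
3. **Local adaptive threshold** — pixel > mean over a w×w window + offset;
   the default *combined* mode thresholds the denoised intensity and gates
   it with the vesselness response, then intersects with the lesion mask
   and removes small speckle components.
4. **Skeletonization** — Zhang–Suen thinning run to its fixed point, plus a
   minimization pass that removes staircase-redundant pixels.
5. **Skeleton graph** — pixels classified by 8-neighbor count
   (1 = endpoint, 2 = branch, ≥3 = junction pixel); adjacent junction
   pixels merge into junction clusters, branches are traced between
   terminals, thinning spurs are pruned.

The nine biomarkers are: mCNV area (mm²), vessel area VA (mm²), vessel
density VLD = VA/area, total skeleton length VL (mm; 1 px orthogonal steps,
√2 diagonal), mean caliber VD = VA/VL (µm), box-counting fractal dimension
FD of the skeleton, junction count VJ, junction density JD = VJ/VL (n/mm),
and mean branch tortuosity VT (arc/chord, 1 = straight). Central retinal
thickness (CRT, µm) from structural OCT is carried alongside as the
traditional response marker.

The cohort layer reproduces the published analysis style: relative ratio
RR = 100 × post-mean / baseline-mean per biomarker, two-sided rank tests
(exact enumeration for small samples, including under ties), Mann–Whitney
comparison of stable (≤2 injections) vs unstable (>2) subgroups, and
Spearman correlations of per-eye percent changes against CRT with the
conventional strength labels (0.40–0.69 = "moderate", etc.).

## Worked example

Generate a synthetic medusa-type lesion with known ground truth, render it
with OCTA-like speckle, and quantify it with the default pipeline:

```r
library(octamorph)

tr <- generate_network("medusa", seed = 7)   # exact ground truth
sc <- render_octa(tr, seed = 7)              # speckled en face image + mask
panel <- compute_panel(sc$image, sc$mask, crt_um = 312)
print(panel)
#> <biomarker_panel>
#>  mCNV_area        VA       VLD       FD       VD       VL       VT VJ       JD CRT
#>   1.835332 0.2366473 0.1289398 1.138097 34.03813 6.952419 1.017298 13 1.869853 312
as.data.frame(tr$true_metrics)
#>   mCNV_area        VA      VLD       FD       VD       VL       VT VJ       JD CRT
#> 1  1.835332 0.1808453 0.098536 1.109088 25.99384 6.957237 1.004799 13 1.868558  NA
```

Under default speckle the pipeline recovers the true junction count (13)
exactly and the skeleton length within 0.1% (6.952 vs 6.957 mm); the
binarized vessels are slightly fatter than the true tubes, so VA and VD sit
above truth — the vignette quantifies these recovery errors systematically.

Cohort statistics work directly on the bundled reference tables:

```r
tab <- mcnv_biomarker_summary()
relative_ratio(tab$baseline_mean[tab$biomarker == "VJ"],
               tab$post_mean[tab$biomarker == "VJ"])
#> [1] 49.64        # junction count halves after one injection

summarize_features(mcnv_cohort_features())
#>   feature level count  n   pct
#> 1      OP    OI    26 31 83.87
#> 2      OP   DVL     5 31 16.13
#> 3      EC     Y    26 31 83.87
#> 4      AL     Y    30 31 96.77
#> 5      HH     Y    25 31 80.65
#> 6      FV     Y     6 31 19.35
```

File-level entry points `run_quantify()`, `run_simulate()` and
`run_cohort()` wrap the same functions, and `inst/scripts/octamorph` exposes
them as `quantify` / `simulate` / `cohort` subcommands for shell use.

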