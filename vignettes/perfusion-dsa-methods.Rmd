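---
title: "Quantifying foot perfusion from 2D DSA: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying foot perfusion from 2D DSA: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfdsa)
```

## The problem

Digital subtraction angiography (DSA) of the foot, acquired during a
contrast bolus injection, shows *where* blood goes but not *how much* or
*how fast*. After infrapopliteal angioplasty for critical limb ischemia the
interventionalist wants a quantitative answer on the table: did tissue
perfusion actually improve? `perfdsa` turns a pair of DSA frame sequences
(pre- and post-intervention) into three parametric maps and a per-region
percent-change report:

* **PBV** (perfusion blood volume): the dimensionless ratio of the area
  under a pixel's concentration–time curve to the area under the arterial
  input curve,
  $\mathrm{PBV} = \int C_\mathrm{tissue}(t)\,dt \big/ \int C_\mathrm{artery}(t)\,dt$;
* **MTT** (mean transit time): operationalised as the full width at half
  maximum (FWHM) of the pixel's smoothed concentration curve, in seconds;
* **PBF** (perfusion blood flow): the central-volume quotient
  $\mathrm{PBF} = \mathrm{PBV} / \mathrm{MTT}$, in 1/s.

This is deliberately a deconvolution-free formulation: no impulse-response
estimation, no absolute calibration to mL/100g/min. The numbers are
relative, which is exactly what a pre/post comparison needs.

## Pipeline and assumptions

1. **Crop and complement.** The clinically informative region is cropped
   (user-specified rectangle; `suggest_crop()` offers a deterministic
   constant-border trim) and intensities are inverted,
   $p \mapsto (2^{b}-1) - p$, so contrast-filled vessels are high-valued.
   After inversion, pixel values are treated as contrast concentration in
   arbitrary units — linearly, with no Beer–Lambert correction, because
   subtraction imaging is already approximately linear in iodine
   concentration at these doses and the downstream quantities are ratios.
2. **Seeded fuzzy C-means (FCM) segmentation.** Two user regions — one on
   a major vessel, one on background — provide the initial cluster centres;
   a standard two-cluster FCM (fuzzifier $m = 2$, squared Euclidean
   distance on scalar intensity) is run over *every voxel of the 3D
   row × col × frame stack at once*. Seeding near the true centres makes
   the alternating updates converge in a handful of sweeps and makes the
   result reproducible run-to-run: there is no random initialisation
   anywhere in the analysis path.
3. **Pixel voting.** The 3D hard labels are projected to a 2D vessel mask
   by union over frames: a pixel is vessel if the bolus ever filled it.
   Maps are computed only on this mask.
4. **Curve analysis.** Per mask pixel, the time–intensity curve (TIC) is
   the pixel's value across frames at times $t_k = k\,\Delta t$. PBV uses
   trapezoidal areas of the *raw* samples over the acquisition window (the
   idealised integral to infinity is truncated at the window end — all the
   data there is). MTT fits a degree-5 polynomial to the TIC by least
   squares and takes the FWHM of the fitted curve on a dense grid
   (100 sub-samples per frame interval by default, crossings refined by
   linear interpolation, negative fitted values clamped to zero).
5. **Registration and reporting.** Analysis ROIs drawn on the pre-therapy
   maps are transferred to the post-therapy maps by a pure translation
   derived from one user-marked anchor point per series; ROI means
   (defined, on-mask pixels only) give the percent rise
   $100\,(I - I_0)/I_0$ per metric and region, then study-level summaries.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `fuzziness` (m) | 2 | — | conventional FCM fuzzifier; results are insensitive for well-separated clusters |
| `tol` | 1e-5 | membership | stop when the largest membership change falls below this |
| `max_iter` | 100 | sweeps | safety bound; seeded runs converge in ~10 |
| `frame_interval` | from metadata | s | times are $k\,\Delta t$; MTT is reported in seconds |
| `fwhm resolution` | 100 | sub-samples/frame | half-max grid density; the linear-interpolated crossing makes finer grids immaterial |
| degree | 5 | — | the polynomial order used for TIC smoothing (reduced to $n-1$ below 6 samples) |

Design decisions that were genuinely open:

* **"Distance between the two half-maximum points"** is read as *temporal*
  distance. A 2D Euclidean distance on the time–intensity plane would mix
  seconds with arbitrary intensity units and change with amplitude
  rescaling; the temporal reading makes MTT amplitude-invariant and
  time-dilation-equivariant, which the test suite asserts.
* **Arterial input curve.** The mean TIC over a user-designated arterial
  ROI, defaulting to the FCM vessel-seed region — that region is by
  construction on a major feeding vessel. On the post series the seed and
  arterial regions follow the anchor translation, like the analysis ROIs,
  so the same vessel segment feeds both denominators.
* **Raw vs smoothed areas.** The polynomial is used *only* for the FWHM;
  areas come from raw samples. Smoothing areas would couple PBV to the
  polynomial's edge behaviour for no benefit, since trapezoidal error on a
  smooth bolus at 0.5 s sampling is far below the other error sources.
* **Ties and degenerates.** Membership ties defuzzify to background; a
  voxel exactly at a cluster centre gets membership 1 there; flat or
  non-positive fitted curves yield undefined MTT/PBF (`NA`), never 0, and
  undefined pixels are excluded from ROI means with the contributing count
  reported.
* **Coordinates** are 1-based `(row, col)` throughout, the host language's
  convention; rectangles are `(row0, col0, n_rows, n_cols)`.
* **Registration is translation-only** — one anchor pair supports nothing
  richer, and the clinical procedure immobilises the limb; sub-pixel
  anchors round half-up to the nearest pixel.

## The phantom: what it emulates, what it does not

`generate_phantom()` builds synthetic stacks in which every pipeline claim
is checkable against exact ground truth. Vessel segments are thick line
rasters whose pixels share a gamma-variate bolus
$C(t) = A\,x^{\alpha} e^{\alpha(1-x)}$, $x = (t-t_0)/t_p$ — the standard
angiographic bolus model, normalised so the peak is exactly $A$ at
$t_0 + t_p$. Ground truth carries the closed-form FWHM (root-finding on the
analytic curve, machine precision) and windowed AUC ratios (adaptive
quadrature), entirely independent of the polynomial/trapezoid estimation
path.

Default study conditions (fixed once, at design time): 64 × 64 pixels,
24 frames at 0.5 s — a 12 s acquisition typical of foot DSA — three
parallel 3-px vessels, amplitudes 200/180/160 (8-bit), arrival at the first
frame, times-to-peak 3.5/4.0/4.5 s with shape $\alpha = 1.3$, background 0
(subtraction leaves near-zero background), noise $\sigma = 2$. The broad,
low-$\alpha$ kinetics mirror the long transit times seen in ischemic distal
limbs and — importantly — keep both half-maximum crossings inside the
acquisition window, which is a *requirement of the FWHM definition itself*:
a bolus whose wash-out leaves the window has no measurable width, only a
flagged truncated one.

A degree-5 polynomial is a biased smoother. Its FWHM error measured against
the closed-form oracle is ≈ 0.5 % on the default kinetics, ≤ 5 % across the
phantom's kinetic envelope (arrival within one frame, $t_p$ 3.5–4.5 s,
$\alpha$ 1.2–1.5), and grows steeply once the bolus becomes narrow relative
to the window or acquires long flat tails: a Gaussian sampled over ±4σ is
estimated ~40 % too wide because flat tails are outside the quintic's
approximation class, while the same Gaussian over ±2σ is within 2.5 %.
The tests therefore exercise the Gaussian case on a window the polynomial
can represent, and clinical users should expect MTT bias whenever the
bolus occupies a small fraction of the acquisition.

What the phantom does **not** emulate: motion (the clinical protocol
excludes motion-corrupted runs rather than correcting them), bone and
soft-tissue background structure, mask-frame misregistration, correlated
noise, and partial-volume effects at vessel edges. Passing phantom tests
therefore demonstrates algorithmic correctness — not robustness to these
clinical nuisances.

## Sizes and budgets

The bundled tests and the acceptance script run phantoms at 48–64 px and
24 frames — sizes chosen so the whole suite completes in well under a
minute while every stage (segmentation with ~100k voxels, ~500-pixel map
computations, full pre/post pipelines) is exercised at realistic
signal-to-noise. Clinical 512 × 512 × 24 stacks run in seconds: FCM
memberships depend on a voxel only through its intensity, so sweeps cost
O(distinct intensities), and the per-pixel polynomial fits share one QR
factorisation.

## Known limitations

* MTT is an FWHM, not a true mean transit time; the two agree only up to a
  shape-dependent factor, which cancels in pre/post ratios of similar
  boluses but not across very different bolus shapes.
* PBV depends on the arterial ROI placement; a partially off-vessel
  arterial region dilutes the denominator and inflates every PBV.
* The printed percentages of the bundled cohort are reproduced from its
  printed per-ROI rises; a few of that table's internal rows are not
  mutually consistent with its own formula (values were evidently computed
  at full precision and rounded independently), so recomputation from
  rounded inputs matches to ~0.1 % rather than exactly.
* Translation-only registration cannot express rotation or scale; large
  repositioning between runs invalidates the transferred ROIs.
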