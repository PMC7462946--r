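# perfdsa

Quantitative two-dimensional perfusion digital subtraction angiography
(DSA) in R.

After endovascular treatment of critical limb ischemia, the question on the
table is whether tissue perfusion actually improved. `perfdsa` answers it
from the DSA sequences already acquired during the procedure: it segments
the perfused vessels, analyses every pixel's time–intensity curve (TIC)
during the contrast bolus passage, and reports per-region percent changes
between the pre- and post-intervention runs.

## The model

For a pixel with concentration curve $C_\mathrm{tissue}(t)$ (complemented
DSA intensity) and an arterial input curve $C_\mathrm{artery}(t)$ (mean TIC
over a user-chosen arterial region):

* **PBV** $= \dfrac{\int C_\mathrm{tissue}(t)\,dt}{\int
  C_\mathrm{artery}(t)\,dt}$ — perfusion blood volume, dimensionless,
  trapezoidal areas of the raw samples over the acquisition window;
* **MTT** — mean transit time, the full width at half maximum of the
  degree-5 polynomial fitted to the pixel TIC, in seconds;
* **PBF** $= \mathrm{PBV} / \mathrm{MTT}$ — perfusion blood flow, 1/s.

Vessels are found by a *seeded* two-cluster fuzzy C-means run on the whole
3D (row × col × frame) stack — the user marks one vessel and one background
region whose mean intensities initialise the cluster centres — followed by
pixel voting: a pixel enters the 2D vessel mask if it was labelled vessel
on any frame. Analysis ROIs drawn on the pre-therapy maps are transferred
to the post-therapy maps by the translation between two user-marked anchor
points, and each region's mean map values give the percent rise
$100\,(I - I_0)/I_0$. The analysis path contains no randomness: identical
inputs give byte-identical reports.

A synthetic phantom generator (`generate_phantom()`,
`make_pre_post_pair()`) builds DSA stacks with straight vessels carrying
gamma-variate boluses and exact ground truth (closed-form bolus widths,
quadrature AUC ratios), so the whole pipeline is testable without clinical
data.

## Worked example

Generate a pre/post phantom study (treatment halves every time-to-peak,
the foot shifts by 2 px down / 1 px right between runs) and quantify it:

```r
library(perfdsa)
cfg <- run_phantom(phantom_spec(), "demo", amp_mult = 1, tp_div = 2,
                   shift = c(2, 1))
res <- run_pipeline(cfg)
res$comparison[, 1:6]
#>  metric artery_label roi_id pre_value post_value percent_rise
#>     MTT    segment 1      1   7.42702     3.8289    -48.44593
#>     MTT    segment 2      2   8.51531     4.3547    -48.85977
#>     MTT    segment 3      3   9.61637     4.8986    -49.05950
#>     PBF    segment 1      1   0.13462     0.2612     94.00541
#>     PBF    segment 2      2   0.11406     0.2353    106.25757
#>     PBF    segment 3      3   0.09457     0.2074    119.34196
#>     PBV    segment 1      1   0.99975     1.0000      0.01998
#>     PBV    segment 2      2   0.97116     1.0244      5.48657
#>     PBV    segment 3      3   0.90937     1.0161     11.73212
res$summary
#> Study summary
#>   MTT: improved in 3/3 ROIs (100.0%), mean rise -48.8%
#>   PBF: improved in 3/3 ROIs (100.0%), mean rise 106.5%
#>   PBV: improved in 3/3 ROIs (100.0%), mean rise 5.7%
```

Reading the output: the three phantom vessels have true (closed-form)
bolus widths of 7.44, 8.51 and 9.57 s, recovered here within 0.5 %.
Halving every time-to-peak halves the true transit time, and the reported
MTT rises sit at −48 to −49 %; blood flow roughly doubles; blood volume is
nearly unchanged because tissue and arterial areas scale together (the
small positive PBV rises reflect reduced wash-out truncation at the window
end, which the ground truth reproduces). `run_pipeline()` also writes the
six parametric maps as 32-bit float TIFFs with colour PNG renderings, the
vessel masks, `report.csv` and `summary.json` into the output directory.

For clinical data, point the same configuration at multi-frame DICOM XA
files (or multi-page TIFF / PNG directories) and supply the regions in the
JSON sidecar — see `?read_run_config` for the schema, and
`inst/cli/perfdsa.R` for a shell entry point
(`Rscript inst/cli/perfdsa.R run --config cfg.json`).

The package also bundles the per-ROI values of a published five-patient
infrapopliteal angioplasty feasibility cohort (`angioplasty_cohort()`) as
a worked dataset for the reporting layer.

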