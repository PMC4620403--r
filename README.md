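# lgescar

Automatic quantification and localization of ischemic scars on late
gadolinium-enhancement cardiac MR (LGE-CMR).

## The problem

After a myocardial infarction, scar tissue retains gadolinium contrast and
appears hyperintense on LGE-CMR while healthy myocardium is nulled. Clinical
questions — how big is the scar, how transmural, which wall, which coronary
artery territory — require reproducible numbers, but manual scar marking is
slow and observer-dependent. Given only the routinely drawn endocardial and
epicardial contours and a marked RV–LV junction point per short-axis slice,
`lgescar` computes every scar quantity automatically and deterministically.

## Method

For each slice, every myocardial pixel `x` gets polar coordinates relative to
the **heart axis** (the line from the myocardial centroid to the RV–LV
junction):

- **phase** `φ(x) ∈ [0, 360)` degrees, counterclockwise from the axis;
- **radial wall position** `λ(x) ∈ [0, 1]`, 0 at the endocardium and 1 at
  the epicardium, normalized per angular bin by the local minimum/maximum
  wall radii.

Scar is segmented by the **FWHM criterion**: a pixel is scar when its signal
intensity is at least half the study-wide maximum myocardial intensity
(**3DmaxSI**, the maximum over the merged myocardial pixels of all slices).
Connected groups of ≥ 2 scar pixels form **scar segments**; only segments
touching the endocardium (`λ_min = 0`, within one radial pixel layer) are
used for localization, matching the ischemic scar pattern.

Per segment, the package reports the **endocardial extent** `Δφ` (span of the
smallest enclosing sector of the pixel phases), the **transmurality**
`Δλ = λ_max − λ_min`, and per study the **scar size** (% of analyzed LV
myocardium), the **extent as % of LV circumference**, and the **scarring
fraction** (scar area over the full-wall sectors spanned by scar). Each
adherent scar's sector is then split across the in-plane segments of the
**AHA 17-segment model** (6 basal, 6 mid, 4 apical; slices assigned
apex-to-base by thirds), and per-segment scar degrees can be aggregated
across a cohort by **infarct-related artery** (LAD/RCA/LCX).

Inputs are a DICOM series (or plain R matrices) plus a JSON annotation
sidecar; outputs are per-scar and per-study CSV/JSON reports. Because
patient images cannot be distributed, the package ships a **phantom
generator** that renders annular myocardium with scar sectors of known
geometry, which the test suite uses to verify end-to-end parameter recovery.
See the `methods` vignette (`vignettes/methods.Rmd`) for the full
definitions, parameter defaults and their rationale.

## Worked example

A 6-slice phantom with one scar sector spanning φ = 20°–80° at transmural
depth 0.6 on the three apical-most slices:

```r
library(lgescar)

spec <- phantom_spec(
  n_slices = 6L,
  scars = list(list(slice_indices = 1:3, phi_start_deg = 20,
                    phi_end_deg = 80, lambda_depth = 0.6)),
  seed = 7L
)
ph  <- generate_phantom(spec, patient_id = "demo", ira_label = "LAD")
res <- analyze_study(ph$study, run_config(assume_scar = TRUE))
res$metrics
#> <study_metrics 'demo'>
#>   slices analyzed: 6 (3 with scar)
#>   scar size: 4.57 %LV (462 of 10104 myocardial px)
#>   mean delta-phi: 59.5 deg; endocardial extent: 16.52 % of circumference
#>   mean transmurality: 0.601; scarring fraction: 0.550
res$segments[[1]]
#> <scar_segment> slice 1, 154 px, dphi 59.5 deg, lambda [0.000, 0.601], endocardium-adherent
```

The generated 60°-wide, 0.6-deep scar is recovered as Δφ = 59.5° and
Δλ = 0.601 despite 2% Gaussian noise. The angular allocation of a basal
scar sector spanning counterclockwise from 315° through 0° to 115°:

```r
split_sector_across_segments(315, 115, "basal")
#>  3  4  5
#> 45 60 55
```

`write_report()` writes the per-scar and summary tables; `cohort_table()`
aggregates many reports by infarct-related artery. The same pipeline is
scriptable end-to-end via the CLI (`inst/cli/lgescar.R`, installed under
`system.file("cli", "lgescar.R", package = "lgescar")`) with subcommands
`phantom`, `analyze` and `cohort`.

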