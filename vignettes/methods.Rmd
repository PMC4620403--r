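---
title: "Methods: automatic localization and characterization of ischemic scars on LGE-CMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic localization and characterization of ischemic scars on LGE-CMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(lgescar)
```

## Problem

On late gadolinium-enhancement cardiac MR (LGE-CMR), ischemic scar tissue
retains contrast and appears hyperintense against nulled normal myocardium.
Given a short-axis image stack with manually drawn endocardial and epicardial
contours and a marked RV–LV junction point, `lgescar` automatically

1. parameterizes every myocardial pixel by an angular phase
   $\varphi(x) \in [0, 360)$ degrees and a normalized radial wall position
   $\lambda(x) \in [0, 1]$,
2. segments scar by the full-width-at-half-maximum (FWHM) criterion against
   the study-wide maximum myocardial signal intensity,
3. quantifies each scar (endocardial extent $\Delta\varphi$, transmurality
   $\Delta\lambda$, size, scarring fraction) and allocates its angular
   footprint to the 16 in-plane segments of the AHA 17-segment model, and
4. aggregates per-segment scar degrees across a cohort by infarct-related
   artery (IRA).

Only the contour drawing and the junction point are manual inputs; every
subsequent step is deterministic arithmetic.

## Polar parameterization

**Centroid and heart axis.** The centroid of a slice's rasterized myocardial
mask, together with the marked RV–LV junction point, defines the heart axis:
the $\varphi = 0$ direction. Angles increase counterclockwise in the screen
convention (with image rows growing downward, "up" on screen is $+90°$).
Slices without a visible junction inherit the *angle* from the nearest
already-processed slice (preferring earlier, more apical slices) while always
using their own centroid, because centroids drift between slices whereas the
axis direction is the invariant the method relies on.

**Phase.** $\varphi(x)$ is the counterclockwise angle from the heart axis to
the centroid-to-pixel direction, wrapped to $[0, 360)$. It is continuous (no
binning) and exactly equivariant under rotation of the junction point.

**Radial position.** $\lambda(x)$ normalizes each pixel's distance from the
centroid between the local endocardial and epicardial wall radii. The wall
radii are estimated per *angular bin*: within the bin containing
$\varphi(x)$, the minimum and maximum centroid distance over myocardial
pixels define $\lambda = 0$ and $\lambda = 1$, and the pixel interpolates
linearly. Degenerate bins (a single radius) give $\lambda = 0$.

### Choice of the angular bin width

The bin must be wide enough that its arc at the *endocardial* radius spans
about two pixels, i.e. `angular_bin_deg >= 2 * 180 / (pi * r_endo_px)`;
narrower bins can miss entire radial layers of the wall, biasing the per-bin
minimum/maximum radii and hence $\lambda$. At a typical endocardial radius of
~19 px (≈ 15.6 mm at 0.82 mm pixels) this gives ≈ 6°; the package default is
10°, which is also safe for smaller test geometries. On a rendered annulus
the binned $\lambda$ then agrees with the analytic closed form within one
pixel width. Two caveats follow from the definition:

* $\lambda$ is exactly rotation-invariant only for rotations of the reference
  axis that are multiples of the bin width (other rotations move the bin
  boundaries across pixels); $\varphi$ equivariance is exact for any
  rotation.
* $\Delta\varphi$ and all phase-based quantities are *unaffected* by the bin
  width, since they use the continuous per-pixel phases.

A separate, coarser binning (`coverage_bin_deg`, default 10°) implements the
slice-inclusion rule: a slice is analyzed only when myocardium is present in
every angular coverage bin around the centroid (full 360° wall).

## Scar segmentation

The maximum signal intensity over the merged myocardial pixels of all
retained slices is the study-wide reference, *3DmaxSI*. A pixel is scar when

$$\mathrm{SI}(x) \ge 0.5 \times \mathrm{3DmaxSI},$$

with an *inclusive* boundary (a pixel exactly at half maximum is scar). Scar
pixels are grouped per slice into connected components; a *scar segment* is a
component of at least two pixels (singletons are discarded). The default
connectivity is 8 (configurable to 4) — the standard choice for lesion blobs.
Components are per-slice (2-D), because all reported quantities are per-slice.

**Endocardial adherence.** Ischemic scars touch the endocardium, so only
segments with $\lambda_{\min} = 0$ are used for localization. Because exact
zero is attained by only the single innermost pixel of each bin, the default
tolerance is adaptive: a segment is adherent when
$\lambda_{\min} \le 1 / (\text{radial bin thickness in pixels})$, i.e. its
innermost pixel lies in the innermost discrete radial layer. An explicit
`adherence_tolerance` overrides this. Non-adherent (e.g. mid-wall) segments
are still reported, flagged `adherent = FALSE`, but excluded from
localization metrics.

The FWHM criterion presupposes that a scar *exists* (it is a relative
threshold); the pipeline therefore expects an operator attestation
(`assume_scar = TRUE`, CLI flag `--assume-scar`) and warns without it.

## Scar metrics

For one scar segment with pixel phases $\{\varphi_i\}$ and radial positions
$\{\lambda_i\}$:

* **Endocardial extent** $\Delta\varphi$: the span of the smallest sector
  enclosing all pixel phases, computed as $360°$ minus the largest gap
  between circularly sorted phases (ties resolved toward the smallest sector
  start). A single distinct phase gives $\Delta\varphi = 0$.
* **Transmurality** $\Delta\lambda = \lambda_{\max} - \lambda_{\min}$.

Per study:

* **Scar size (%LV)**: $100 \times$ scar pixels / analyzed myocardial pixels.
* **Endocardial extent (% of LV circumference)**:
  $100 \times \sum_s \Delta\varphi_s / (360 \times$ number of slices with
  scar$)$.
* **Scarring fraction**: scar pixels divided by the pixel count of the
  full-wall myocardial sectors spanned by the scars (ratio in $[0,1]$;
  reported $\times 100$). For a concentric wall with inner radius $r_1$,
  outer radius $r_2$ and a scar reaching depth $d$ of the wall, the analytic
  value is $(r_m^2 - r_1^2)/(r_2^2 - r_1^2)$ with $r_m = r_1 + d (r_2 -
  r_1)$ — note this exceeds $d$ itself because the outer wall holds more
  area per degree.

## AHA segment allocation

Each myocardial region uses half-open in-plane angular intervals
(degrees of $\varphi$, counterclockwise from the junction):

* **Basal / mid**: six 60° segments; segment 4 (basal, resp. 10 mid) starts
  at 0°, proceeding 4, 5, 6, 1, 2, 3 counterclockwise (so segment 3 is
  $[300°, 360°)$).
* **Apical**: four 90° segments. Their absolute anchoring is not fully
  determined by the in-plane geometry alone; the package anchors the
  segment 14/15 border at 345° by default (`apical_anchor_deg`), which
  places the junction inside segment 15 (septum adjacent to the RV).
  This remains a documented open choice and is configurable.

Slices are assigned to regions apex-to-base: with $n$ slices, each region
gets $\lfloor n/3 \rfloor$; one leftover slice goes to the mid region, two
leftovers add one mid and one basal slice (so $n=6 \to 2/2/2$, $7 \to
2/3/2$, $8 \to 2/3/3$).

An adherent scar's enclosing sector is split across its region's segment
intervals; contributions conserve the sector span exactly. The worked
reference case: a basal sector from 315° to 115° (wrapping through 0°)
splits as 45° to segment 3, 60° to segment 4 and 55° to segment 5.

Cohort aggregation sums the per-segment degrees per patient and reports, for
each segment, the percentage of total scarred degrees contributed by each
IRA (LAD/RCA/LCX); rows with any scar sum to 100%. The apical cap
(segment 17) is visible only on long-axis views, which the package does not
process; `segment17_visual_scar()` documents the proxy rule (scar when the
summed apical extent exceeds 180°).

## Synthetic phantoms and validation

Patient images cannot ship with the package, so validation uses a phantom
generator: an annular myocardium (defaults: 512×512 at 0.82 mm pixels,
radii 19→30 px, 6 slices, junction at 90°) with scar sectors painted from a
given $\lambda$ offset to a given depth, contour annotations, and additive
Gaussian noise (default sd = 2% of scar SI) under a fixed seed. Ground truth
(span, depth, area fraction) is returned alongside, and the test suite
checks end-to-end recovery: $\Delta\varphi$ within ±2 angular bins,
$\Delta\lambda$ within ±1 radial pixel layer, and scar size within ±1%
absolute across a grid of spans (30°–180°) and depths (0.3–1.0). Property
tests back every geometric primitive with an independent oracle (brute-force
smallest sector, flood-fill component labeling, fine-grid sector splitting,
exact partition-of-the-circle sweeps).

The phantom makes no attempt at MR realism (no partial-volume effects beyond
rasterization, no coil profiles); it exists to give every pipeline stage a
known answer.

## Limitations

* Myocardial contours and the junction point are inputs; no automatic
  segmentation is attempted.
* Only the FWHM criterion is implemented; *n*-SD-above-remote thresholds are
  out of scope.
* DICOM support is deliberately minimal (uncompressed explicit-VR
  little-endian monochrome, one file per slice); plain R matrices plus the
  annotation JSON are the equivalent, fully supported input path.
* The apical anchoring and the adaptive adherence tolerance are documented
  conventions, not physiologic ground truth; both are configurable.
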