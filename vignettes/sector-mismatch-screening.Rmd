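---
title: "Sectoral mismatch screening between circumpapillary RNFL and BMO-MRW"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sectoral mismatch screening between circumpapillary RNFL and BMO-MRW}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(sectormatch)
```

## The problem

Two structural OCT biomarkers are routinely used to monitor glaucomatous
loss of retinal ganglion cell axons at the optic nerve head (ONH): the
circumpapillary retinal nerve fiber layer thickness (RNFL, measured on a
12° circle of 768 A-scans centered on the Bruch's membrane opening
centroid) and the Bruch's membrane opening minimum rim width (BMO-MRW, the
minimum distance from the BMO rim to the internal limiting membrane,
measured on 24 radial B-scans that yield 48 values at 7.5° spacing).
Both should thin as axons are lost, and in areas of advanced damage they
mostly agree. Where they disagree — one parameter deep in the abnormal
range while the other looks preserved — the disagreement itself is
informative: it usually marks an anatomical confounder (a blood vessel
lumped into one measurement but not the other, focal retinoschisis,
inclusion of outer retinal layers in the rim measurement) or a difference
in the two parameters' measurement floors. This package implements the
sector geometry, normative classification, and two-stage screen needed to
find such *true mismatch* sectors, plus the cohort-level prevalence and
cause-attribution summaries, and a synthetic-cohort generator with ground
truth so the whole pipeline is testable without patient data.

## Coordinate system and sectorization

All angles are TSNIT (temporal–superior–nasal–inferior–temporal) in
right-eye format: 0° temporal, 90° superior, 180° nasal, 270° inferior.
Device-native TSNIT exports are already laterality-normalized; data in
absolute screen orientation are mirrored about the vertical axis for left
eyes (`normalize_laterality()`). The reported peak locations of the two
mismatch types (superotemporal/inferotemporal for MRW-thickening
artifacts, the vertical poles for arcade vessels) are only interpretable
under this convention.

The 768-point RNFL profile is reduced to the 48-sector resolution of the
BMO-MRW by averaging the 16 contiguous A-scans centered on each radial cut
angle, i.e. the half-open window `[7.5k − 3.75°, 7.5k + 3.75°)` maps to
sector *k* (`sectorize_rnfl()`). Two choices here are genuinely open and
are fixed as follows:

* **Phase anchor.** Whether the device aligns A-scan 0 exactly with the
  temporal radial cut is not documented; we anchor A-scan 0 at 0° with
  windows centered on the cut angles, which matches the "centered on the
  radial cuts" description of the sector averaging. The alignment is a
  pure index shift, so any future correction is a one-line rotation.
* **Missing data.** A missing A-scan makes its sector missing (with a
  count of missing A-scans) rather than being imputed; session-level
  quality control is the intended guard, and silent fill would bias the
  screen toward agreement.

The analysis wedge spans 225° through temporal to 135°, both endpoints
inclusive — 37 sectors covering the temporal 180° plus the superonasal and
inferonasal 45°. The nasal 90° (sectors 142.5°–217.5°) is excluded: BMO-MRW
is noisy there (vessel crowding at the nasal rim) and the region is less
clinically relevant. The endpoint-inclusive reading is forced by the
sector count: 37 × 7.5° spans 270° of arc only if both ends are kept.

## Normative percentile classification

Clinical displays render a sector red when its value is below the 1st
percentile of a healthy reference population, yellow between the 1st and
5th, green above the 5th. The commercial normative database is
proprietary (and for cross-sectional BMO-MRW not even exportable), so the
package ships a configurable parametric model (`band_config()`,
`build_default_bands()`) and accepts user-supplied per-angle threshold
tables (`read_bands()`):

* mean curve: `m(θ) = level + Σ aⱼ cos(oⱼ (θ − φⱼ))`, by default a single
  second-order harmonic producing the double-hump TSNIT shape with peaks
  at the vertical poles (RNFL: level 100 µm, amplitude 30 µm; BMO-MRW:
  level 330 µm, amplitude 35 µm);
* Gaussian dispersion (RNFL 15 µm, BMO-MRW 50 µm), so
  `p1 = m + z₀.₀₁ σ` and `p5 = m + z₀.₀₅ σ`, clamped at a positive floor;
* a linear age slope applied to the thresholds (RNFL −0.2 µm/yr, BMO-MRW
  −1.0 µm/yr, reference age 50), the literature-typical order of
  magnitude for age-related decline.

These defaults make the angle dependence of the cutoffs concrete: 70 µm of
RNFL is red at a superotemporal cut yet green at a temporal cut.

```{r}
b <- build_default_bands("RNFL")
classify(70, 75, b)
classify(70, 0, b)
```

Boundary ties follow the display semantics: red is strictly *below* the
1st percentile, so a value exactly at `p1` is yellow. Classification is
monotone in the value and the three classes partition `[0, ∞)` at every
angle — both are enforced by tests.

## The two-stage screen

Stage 1 sorts each analyzed sector by fixed cutoffs into group 1
(RNFL ≥ 65 µm and BMO-MRW ≥ 130 µm), group 2 (RNFL ≤ 50, BMO-MRW ≥ 130),
group 3 (both low), group 4 (RNFL ≥ 65, BMO-MRW ≤ 100). Values inside the
open gaps (RNFL 50–65 µm, BMO-MRW 100–130 µm) are indeterminate and
excluded from candidacy — implied by the four printed group definitions,
which leave those bands unassigned. Only groups 2 and 4 are mismatch
candidates.

Stage 2 confirms a candidate as a *true mismatch* when the low member is
red (below the 1st percentile) while its counterpart is not (yellow or
green). Group-3 sectors — both parameters possibly at their measurement
floors — never reach stage 2, and a candidate in which both classes are
red is rejected for the same reason: a shared floor is agreement, not
discordance. The screen is deliberately specificity-first: a
pure-percentile screen could flag more sectors, but the numeric stage-1
gate keeps the candidates comparable between the two parameters. Stage 2
classifies the sector-averaged values (the screen's working resolution);
whether the original device display would color an individual radial cut
differently is below this pipeline's resolution.

`screen_eye()` applies the chain sectorize → analysis mask → stage 1 →
stage 2 per sector; sectors with missing data are dropped individually and
counted, so per-eye group counts plus missing always total 37.
`screen_cohort()` adds session-level quality control (reject when quality
factor < 15 or missing-data fraction > 10%, both strict as printed;
rejection drops both parameters for the session) and returns a classed
object with `print`, `summary`, `plot` and `as.data.frame` methods.

## Prevalence and attribution

`build_prevalence()` tabulates records per angle and per mismatch type
over the 37 analyzed angles; within-type fractions sum to 1 and peak
angles are reported as the argmax of the within-type fraction (ties in
wedge order). Peaks are *fractions of that mismatch type*, not of all
sectors — that is how peak shares are meaningfully compared between types
of very different total counts. Adjacency and separation use the shortest
circular arc (`circular_distance()`); `cooccurrence()` summarizes eyes
carrying both mismatch types and their minimum within-eye separation.
Windowed (multi-sector) peak areas are left to the caller: the per-angle
table is the contract, and whether a "15° area" means two or three sectors
is a presentation choice.

Cause attribution is bookkeeping over an annotation table — the actual
cause determination is a manual review of raw B-scans and is out of scope.
`attribute_causes()` cross-tabulates mismatch type × cause, with a
detailed five-cause view and the folded three-column view (large vessels /
small vessels / other) in which retinoschisis and outer-retina inclusion
count as "other"; percentages are reported to one decimal. On synthetic
cohorts, `truth_annotations()` plays the reviewer by matching records to
the nearest injected artifact.

## The synthetic cohort generator

`generate_cohort()` is a forward model of the mismatch mechanisms, not a
renderer of realistic OCT images. Per eye:

1. **Clean profiles** are the age-adjusted normative mean curves.
2. **Glaucomatous damage** enters as wedge defects: angular sector runs
   scaled toward per-parameter measurement floors (RNFL 40 µm, BMO-MRW
   60 µm) by a severity in `[0, 1]` (`floor_model()`). Wedges concentrate
   at the arcades (67.5°/292.5°), with 2–4 wedges of 4–9 sectors per eye
   and severities drawn per disease stage (early 0.45–0.70, moderate
   0.60–0.78, advanced 0.92–1.00; stage mix 56/23/21). Early and moderate
   eyes additionally carry a deep focal notch (severity ≥ 0.92) with
   probability 0.62 / 0.70 — this cohort is dominated by eyes with at
   least some near-floor damage, which is precisely where mismatches live.
3. **Artifacts** are injected with von Mises-concentrated placement
   (κ = 60) around anatomically motivated centers: large arcade vessels
   (rate 5/eye, near 82.5°/277.5°) add ~75 µm to the RNFL at the vessel's
   retinal trajectory and ~12 µm to the BMO-MRW at its insertion, offset
   by ±15° — the angular offset between insertion and trajectory is itself
   a mismatch mechanism; small circumlinear vessels (rate 4/eye, near
   45°/322.5°) add ~180 µm to the BMO-MRW only; retinoschisis and
   outer-retina inclusion add focal BMO-MRW-only thickening (~200/150 µm)
   at uniform analyzed angles. Magnitudes are order-of-magnitude choices
   — no published figures exist — and all are configurable.
4. **Ground truth** is computed by running the screen on the noiseless
   profiles, so the truth labels are exactly what a noise-free screen
   would say and test failures separate screen defects from noise flips.
5. **Measurement noise** is then added: independent Gaussian per A-scan
   (sd 4 µm, so sector means see 1 µm) and per BMO-MRW cut (sd 4 µm).

Wedges and artifacts are aligned to whole 7.5° sector windows; a sector is
wholly inside or outside a defect. This radial-cut-aligned simplification
keeps truth labels sharp and is the main respect (besides the absence of
B-scan imagery, segmentation error, and smooth defect borders) in which
the generator under-represents real data. Passing recovery tests
therefore demonstrate the pipeline's correctness and noise robustness
under the modeled mechanisms — they do not certify performance on real
exports, where boundary-straddling sectors are more common.

Under the default conditions, roughly 3–4% of analyzed sectors are truth
mismatches (somewhat below the rate observed in severely damaged clinical
cohorts; the shortfall is the price of keeping artifact placement
anatomically concentrated rather than painting artifacts wherever damage
happens to be).

```{r}
cohort <- generate_cohort(cohort_config(n_eyes = 25), seed = 1)
screen <- screen_cohort(cohort)
evaluate_recovery(screen, cohort)
```

## Numerical choices and degenerate inputs

* All group cutoffs, QC thresholds and the wedge are configurable but
  default to their standard values (65/50 µm, 130/100 µm, QF 15, 10%,
  225°–135°).
* `p1 ≥ p5` (e.g. zero dispersion) is rejected at band construction; so
  are non-positive `p1` and positive age slopes.
* Stage-2 contract: calling `stage2_confirm()` outside groups 2/4 is a
  programming error and raises, rather than silently returning "no
  mismatch".
* Empty cohorts (e.g. everything rejected by QC) produce structurally
  valid empty reports with a warning.
* Generator clipping: noise or extreme configurations can drive values
  negative; they are clipped at 0 µm (thickness cannot be negative).
* Determinism: one R RNG stream per `generate_cohort(seed=)` call; the
  same seed gives bit-identical cohorts.

## Problem sizes in the test suite

The suite validates recovery on a 100-eye default cohort (the size at
which per-type mismatch counts, ~100–150, make peak locations and rate
estimates stable), stability across seeds at 50 eyes, and unit properties
on 4–30-eye cohorts. A full 100-eye generate–screen–evaluate cycle runs
in about a second.

## Known limitations

* The parametric normative bands are a modeling device, not a reproduction
  of any device database; absolute classification of real exports requires
  user-supplied threshold tables.
* BMO-area, refraction and fovea–BMO axis corrections are not modeled.
* The screen is cross-sectional; longitudinal mismatch tracking and
  progression analysis are out of scope.
* Cause attribution requires external annotations; the package never
  infers causes from the thickness data themselves.
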