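# sectormatch

Sectoral mismatch screening between the two structural OCT biomarkers used
to monitor glaucoma at the optic nerve head (ONH): circumpapillary retinal
nerve fiber layer thickness (RNFL) and Bruch's membrane opening minimum
rim width (BMO-MRW). The package is aimed at glaucoma imaging researchers
who export per-eye thickness profiles from ONH volume scans and want to
find, map, and explain the sectors where the two biomarkers *disagree* —
one deep in the abnormal range while the other looks preserved. Such
discordant sectors usually mark anatomical confounders (blood vessels,
focal retinoschisis, inclusion of outer retinal layers in the rim
measurement) or differing measurement floors, and they matter wherever the
two parameters are combined to detect progression.

## Method

All angles θ are TSNIT in right-eye format (0° temporal, 90° superior,
180° nasal, 270° inferior). The measurement geometry is:

* 768 A-scans on the measurement circle, A-scan *i* at θ = *i* · 360/768;
* 24 radial B-scans → 48 BMO-MRW sectors at 7.5° spacing; RNFL sector *k*
  is the mean of the 16 A-scans in [7.5·k − 3.75°, 7.5·k + 3.75°);
* the analysis wedge runs 225° → 0° → 135° inclusive (37 sectors); the
  nasal 90° is excluded. 186 eyes × 37 sectors = 6882 analyzed sectors.

Each analyzed sector pair (RNFL, MRW) passes a two-stage screen:

1. **Stage 1 (numeric gate).** Group 1: RNFL ≥ 65 µm and MRW ≥ 130 µm;
   group 2: RNFL ≤ 50, MRW ≥ 130; group 3: both low; group 4: RNFL ≥ 65,
   MRW ≤ 100. Values in the open gaps are indeterminate. Only groups 2
   and 4 are mismatch candidates.
2. **Stage 2 (percentile confirmation).** Against angle-dependent
   normative bands (p1/p5 thresholds, red < p1 ≤ yellow < p5 ≤ green), a
   candidate is a *true mismatch* iff the low member is red while its
   counterpart is yellow or green. Both-red sectors are a shared
   measurement floor, not discordance.

Cohort-level outputs are a per-angle prevalence map with within-type
fractions and peak angles, within-eye co-occurrence of the two mismatch
types (shortest circular arc), and a cause-attribution cross-tab
(large vessels / small vessels / other, with retinoschisis and
outer-retina inclusion folded into "other"). A seedable synthetic-cohort
generator injects wedge defects and vessel/schisis artifacts with known
ground truth so the pipeline's sensitivity and false-positive rate are
measurable. See the vignette (`vignettes/sector-mismatch-screening.Rmd`)
for the full model account.

## Worked example

```r
library(sectormatch)

cohort <- generate_cohort(cohort_config(), seed = 1)   # 100 eyes
screen <- screen_cohort(cohort)                        # QC + two-stage screen
summary(screen)
```

```
Two-stage RNFL / BMO-MRW mismatch screen
  eyes screened:   100
  sectors analyzed: 3700 
  true mismatches: 134 (3.6% of sectors)
    high BMO-MRW / low RNFL: 70
    high RNFL / low BMO-MRW: 64
  stage-1 groups (cohort totals):
       G1        G2        G3        G4 UNGROUPED   MISSING 
     2764        75       321        64       476         0 
  peak high-MRW/low-RNFL at 322.5, 45 deg (16% of type)
  peak high-RNFL/low-MRW at 277.5, 82.5 deg (20% of type)
  eyes with both mismatch types: 20 (80 sectors, 60% of mismatches)
  minimum within-eye separation of opposite types: 15 deg
```

134 of 3700 sectors (3.6%) are confirmed mismatches. MRW-thickening
mismatches peak at the superotemporal/inferotemporal sectors where the
small circumlinear vessels were injected; RNFL-thickening mismatches peak
at the vertical poles where the arcade trunks were injected — the
generator's ground truth lets us verify that directly:

```r
evaluate_recovery(screen, cohort)
```

```
Recovery vs ground truth: 134/135 truth mismatches detected (sensitivity 99.3%);
  0 false positives over 3565 truth-negative sectors (0.00%)
```

```r
tab <- attribute_causes(screen, truth_annotations(cohort, screen))
tab
```

```
Mismatch cause attribution (row % in parentheses)
                              Large vessels      Small vessels              Other    Total 
High BMO-MRW, low RNFL           0 (  0.0%)        68 ( 97.1%)         2 (  2.9%)       70
High RNFL, low BMO-MRW          64 (100.0%)         0 (  0.0%)         0 (  0.0%)       64
```

As designed into this synthetic cohort, RNFL-thickening mismatches are
caused by large vessels and MRW-thickening mismatches overwhelmingly by
small vessels (the "Other" entries here are retinoschisis / outer-retina
patches). `plot(screen)` draws the polar prevalence chart;
`run_pipeline()` (or `inst/scripts/sectormatch-pipeline.R` from a shell)
drives simulate → screen → prevalence → attribute end to end and writes
all tables as CSV.

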