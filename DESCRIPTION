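Package: sectormatch
Title: Sectoral Mismatch Screening Between Circumpapillary RNFL and
    BMO-MRW OCT Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing the two structural optic-nerve-head OCT
    biomarkers used in glaucoma care: circumpapillary retinal nerve fiber
    layer (RNFL) thickness and Bruch's membrane opening minimum rim width
    (BMO-MRW).  Maps the 768-point RNFL thickness profile onto the 48
    radial BMO-MRW sectors, classifies sector values against
    angle-dependent normative percentile bands (TSNIT red/yellow/green),
    and applies a two-stage screen that flags "true mismatch" sectors
    where one biomarker is below the first percentile while its
    counterpart is not.  Includes cohort-level prevalence mapping on the
    37-sector analysis wedge, cause-attribution cross-tabulation, quality
    control filtering, delimited-text readers and writers, and a seedable
    synthetic-cohort generator with vessel and retinoschisis artifact
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
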