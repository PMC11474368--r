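# Fixtures built in code: flat normative bands and eyes constructed from
# per-sector values, so screen decisions are fully determined by hand.

flat_bands <- function(parameter, p1, p5, age_slope = 0, reference_age = 50) {
  normative_bands(parameter, sector_grid()$sector_angles,
                  rep(p1, 48), rep(p5, 48),
                  reference_age = reference_age, age_slope = age_slope,
                  provenance = "test fixture")
}

# expand 48 sector values into a 768-point profile (constant within sector)
profile_from_sectors <- function(vals48) {
  stopifnot(length(vals48) == 48)
  prof <- numeric(768)
  for (k in 0:47) prof[sector_ascan_indices(k) + 1L] <- vals48[k + 1L]
  prof
}

make_eye <- function(rnfl48 = rep(100, 48), mrw48 = rep(330, 48),
                     eye_id = "test-eye", age = 50, laterality = "right",
                     quality_factor = 25, missing_fraction = 0) {
  eye_record(eye_id = eye_id, laterality = laterality, age = age,
             rnfl_profile = profile_from_sectors(rnfl48),
             mrw_sectors = mrw48, bmo_area = 1.9,
             quality_factor = quality_factor,
             missing_fraction = missing_fraction)
}

# Independent restatement of the two-stage flow chart as literal nested
# conditionals over the printed cutoffs; used as the oracle the pipeline is
# compared against.  Returns the mismatch type or NA.
oracle_decision <- function(rnfl, mrw, rnfl_class, mrw_class) {
  not_red <- function(cl) cl == "YELLOW" || cl == "GREEN"
  if (rnfl >= 65 && mrw >= 130) return(NA_character_)          # group 1
  if (rnfl <= 50 && mrw >= 130) {                              # group 2
    if (rnfl_class == "RED" && not_red(mrw_class))
      return("HIGH_MRW_LOW_RNFL")
    return(NA_character_)
  }
  if (rnfl <= 50 && mrw <= 100) return(NA_character_)          # group 3
  if (rnfl >= 65 && mrw <= 100) {                              # group 4
    if (mrw_class == "RED" && not_red(rnfl_class))
      return("HIGH_RNFL_LOW_MRW")
    return(NA_character_)
  }
  NA_character_                                                # ungrouped
}

# pipeline-side decision from the exported stage functions
pipeline_decision <- function(rnfl, mrw, rnfl_class, mrw_class) {
  grp <- stage1_group(rnfl, mrw)
  if (!grp %in% c("G2", "G4")) return(NA_character_)
  stage2_confirm(grp, rnfl_class, mrw_class)
}
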