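test_that("stage 1 groups sectors by the printed cutoffs", {
  expect_equal(stage1_group(70, 90), "G4")
  expect_equal(stage1_group(45, 140), "G2")
  expect_equal(stage1_group(60, 115), "UNGROUPED")
  expect_equal(stage1_group(70, 140), "G1")
  expect_equal(stage1_group(45, 90), "G3")
  # cutoff boundaries are inclusive on the group side
  expect_equal(stage1_group(65, 130), "G1")
  expect_equal(stage1_group(50, 130), "G2")
  expect_equal(stage1_group(50, 100), "G3")
  expect_equal(stage1_group(65, 100), "G4")
  # the open gaps are indeterminate whichever side the partner lies on
  expect_equal(stage1_group(50.1, 140), "UNGROUPED")
  expect_equal(stage1_group(64.9, 90), "UNGROUPED")
  expect_equal(stage1_group(70, 100.1), "UNGROUPED")
  expect_true(is.na(stage1_group(NA, 90)))
  expect_error(stage1_group(-5, 90), "non-negative")
})

test_that("stage 2 confirms only red-vs-not-red pairs in groups 2 and 4", {
  expect_equal(stage2_confirm("G2", "RED", "GREEN"), "HIGH_MRW_LOW_RNFL")
  expect_equal(stage2_confirm("G2", "RED", "YELLOW"), "HIGH_MRW_LOW_RNFL")
  expect_true(is.na(stage2_confirm("G2", "YELLOW", "GREEN")))
  expect_true(is.na(stage2_confirm("G2", "RED", "RED")))   # shared floor
  expect_equal(stage2_confirm("G4", "GREEN", "RED"), "HIGH_RNFL_LOW_MRW")
  expect_true(is.na(stage2_confirm("G4", "RED", "RED")))
  expect_true(is.na(stage2_confirm("G4", "GREEN", "GREEN")))
  expect_error(stage2_confirm("G1", "GREEN", "GREEN"), "G2 and G4")
  expect_error(stage2_confirm("G3", "RED", "RED"), "G2 and G4")
})

test_that("pipeline decisions equal the exhaustive truth-table oracle", {
  rnfl_vals <- c(0, 40, 45, 49.9, 50, 50.1, 57.5, 64.9, 65, 65.1, 70, 90, 140)
  mrw_vals <- c(0, 60, 80, 99.9, 100, 100.1, 115, 129.9, 130, 130.1, 150, 300)
  classes <- c("RED", "YELLOW", "GREEN")
  n_checked <- 0L
  for (r in rnfl_vals) for (m in mrw_vals)
    for (rc in classes) for (mc in classes) {
      expect_identical(pipeline_decision(r, m, rc, mc),
                       oracle_decision(r, m, rc, mc))
      n_checked <- n_checked + 1L
    }
  expect_equal(n_checked, length(rnfl_vals) * length(mrw_vals) * 9L)
})

test_that("screen_eye flags exactly the constructed mismatch sector", {
  b_rnfl <- flat_bands("RNFL", p1 = 60, p5 = 80)
  b_mrw <- flat_bands("BMO_MRW", p1 = 120, p5 = 180)
  # one candidate sector at 45 degrees: RNFL 45 (G2, red), MRW 200 (green)
  rnfl48 <- rep(100, 48); mrw48 <- rep(330, 48)
  k45 <- match(45, sector_grid()$sector_angles)
  rnfl48[k45] <- 45; mrw48[k45] <- 200
  scr <- screen_eye(make_eye(rnfl48, mrw48), b_rnfl, b_mrw)
  expect_equal(nrow(scr$records), 1L)
  expect_equal(scr$records$angle_deg, 45)
  expect_equal(scr$records$type, "HIGH_MRW_LOW_RNFL")
  expect_equal(scr$records$stage1_group, "G2")
  expect_equal(scr$records$rnfl_class, "RED")
  expect_equal(scr$records$mrw_class, "GREEN")
  # brute force: no other sector can be flagged
  expect_equal(sum(scr$group_counts[c("G2", "G4")]), 1)
})

test_that("eyes at the normative mean or uniformly at the floor yield no mismatches", {
  b_rnfl <- flat_bands("RNFL", p1 = 60, p5 = 80)
  b_mrw <- flat_bands("BMO_MRW", p1 = 120, p5 = 180)
  at_mean <- screen_eye(make_eye(), b_rnfl, b_mrw)
  expect_equal(nrow(at_mean$records), 0L)
  expect_equal(unname(at_mean$group_counts[["G1"]]), 37)
  # both parameters below both p1 thresholds: group 3 never reaches stage 2
  at_floor <- screen_eye(make_eye(rep(40, 48), rep(80, 48)), b_rnfl, b_mrw)
  expect_equal(nrow(at_floor$records), 0L)
  expect_equal(unname(at_floor$group_counts[["G3"]]), 37)
})

test_that("group counts conserve the 37 analyzed sectors", {
  b_rnfl <- flat_bands("RNFL", p1 = 60, p5 = 80)
  b_mrw <- flat_bands("BMO_MRW", p1 = 120, p5 = 180)
  set.seed(3)
  for (rep_i in 1:5) {
    rnfl48 <- runif(48, 30, 130)
    mrw48 <- runif(48, 50, 350)
    scr <- screen_eye(make_eye(rnfl48, mrw48), b_rnfl, b_mrw)
    expect_equal(sum(scr$group_counts), 37)
  }
  # a missing sector moves one count into MISSING
  rnfl48 <- rep(100, 48)
  prof <- profile_from_sectors(rnfl48)
  prof[sector_ascan_indices(6) + 1L][3] <- NA     # sector 6 = 45 deg
  eye <- eye_record("m", laterality = "right", age = 50,
                    rnfl_profile = prof, mrw_sectors = rep(330, 48),
                    quality_factor = 25, missing_fraction = 0.001)
  scr <- screen_eye(eye, b_rnfl, b_mrw)
  expect_equal(unname(scr$group_counts[["MISSING"]]), 1)
  expect_equal(sum(scr$group_counts), 37)
})

test_that("no flagged sector lies in the excluded nasal wedge", {
  b_rnfl <- flat_bands("RNFL", p1 = 60, p5 = 80)
  b_mrw <- flat_bands("BMO_MRW", p1 = 120, p5 = 180)
  # mismatch pattern at every sector, including nasal ones
  scr <- screen_eye(make_eye(rep(45, 48), rep(200, 48)), b_rnfl, b_mrw)
  expect_equal(nrow(scr$records), 37L)
  expect_true(all(scr$records$angle_deg %in% analysis_angles()))
  expect_false(any(scr$records$angle_deg %in% seq(142.5, 217.5, 7.5)))
})

test_that("screen output is invariant to eye processing order", {
  coh <- generate_cohort(cohort_config(n_eyes = 8), seed = 5)
  fwd <- screen_cohort(coh$eyes)
  rev_ <- screen_cohort(rev(coh$eyes))
  key <- function(d) sort(paste(d$eye_id, d$angle_deg, d$type))
  expect_identical(key(fwd$records), key(rev_$records))
  expect_equal(fwd$n_eyes, rev_$n_eyes)
})
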