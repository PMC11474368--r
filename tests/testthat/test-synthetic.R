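quiet_cfg <- function(...) {
  # no defects, no artifacts, no noise
  cohort_config(
    n_eyes = 4,
    severity_range = list(early = c(0, 0), moderate = c(0, 0),
                          advanced = c(0, 0)),
    central_damage_prob = c(early = 0, moderate = 0, advanced = 0),
    large_vessel_rate = 0, small_vessel_rate = 0,
    retinoschisis_rate = 0, outer_retina_rate = 0,
    rnfl_ascan_noise_sd = 0, mrw_noise_sd = 0, ...)
}

test_that("identical seeds give bit-identical cohorts", {
  c1 <- generate_cohort(cohort_config(n_eyes = 6), seed = 42)
  c2 <- generate_cohort(cohort_config(n_eyes = 6), seed = 42)
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_config(n_eyes = 6), seed = 43)
  expect_false(identical(c1$eyes[[1]]$rnfl_profile,
                         c3$eyes[[1]]$rnfl_profile))
})

test_that("a defect-free, artifact-free, noiseless cohort screens clean", {
  coh <- generate_cohort(quiet_cfg(), seed = 3)
  expect_true(all(coh$truth$expected$expected_type == "NONE"))
  scr <- screen_cohort(coh)
  expect_equal(nrow(scr$records), 0L)
  expect_equal(unname(colSums(scr$group_counts)[["G1"]]), 4 * 37)
})

test_that("floor model interpolates between normative mean and floor", {
  cfg <- cohort_config()
  expect_equal(floor_model(0, "RNFL", config = cfg),
               cfg$bands_rnfl$mean_level)
  expect_equal(floor_model(1, "RNFL", config = cfg), cfg$rnfl_floor)
  expect_equal(floor_model(1, "BMO_MRW", config = cfg), cfg$mrw_floor)
  s <- seq(0, 1, by = 0.05)
  v <- floor_model(s, "RNFL", config = cfg)
  expect_true(all(diff(v) < 0))
  expect_true(all(v >= cfg$rnfl_floor & v <= cfg$bands_rnfl$mean_level))
  expect_equal(floor_model(0.5, "RNFL", mean_um = 100, floor_um = 40), 70)
  expect_error(floor_model(1.2, "RNFL"), "\\[0, 1\\]")
})

test_that("a small vessel atop a deep wedge creates exactly one high-MRW/low-RNFL truth label", {
  # deterministic construction through the generator's own building blocks:
  # normative curves, a severity-1 wedge at 45 deg, one MRW-only bump there
  cfg <- cohort_config()
  age <- cfg$bands_rnfl$reference_age
  grid <- sector_grid()
  rnfl48 <- normative_mean(grid$sector_angles, cfg$bands_rnfl, age = age)
  mrw48 <- normative_mean(grid$sector_angles, cfg$bands_mrw, age = age)
  k45 <- match(45, grid$sector_angles)
  rnfl48[k45] <- floor_model(1, "RNFL", mean_um = rnfl48[k45], config = cfg)
  mrw48[k45] <- floor_model(1, "BMO_MRW", mean_um = mrw48[k45], config = cfg) +
    cfg$small_mrw_bump[["mean"]]
  scr <- screen_eye(make_eye(rnfl48, mrw48, age = age),
                    build_default_bands(config = cfg$bands_rnfl),
                    build_default_bands(config = cfg$bands_mrw))
  expect_equal(nrow(scr$records), 1L)
  expect_equal(scr$records$angle_deg, 45)
  expect_equal(scr$records$type, "HIGH_MRW_LOW_RNFL")
})

test_that("truth labels equal the screen's decisions on noiseless data", {
  coh <- generate_cohort(cohort_config(n_eyes = 25, rnfl_ascan_noise_sd = 0,
                                       mrw_noise_sd = 0), seed = 17)
  scr <- screen_cohort(coh)
  ev <- evaluate_recovery(scr, coh)
  expect_gt(ev$n_truth_positive, 0)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$n_false_positive, 0)
})

test_that("recovery degrades monotonically with measurement noise", {
  cfg_hi <- cohort_config(n_eyes = 40, rnfl_ascan_noise_sd = 40,
                          mrw_noise_sd = 30)
  cfg_lo <- cohort_config(n_eyes = 40)
  ev_lo <- evaluate_recovery(screen_cohort(generate_cohort(cfg_lo, seed = 23)),
                             generate_cohort(cfg_lo, seed = 23))
  ev_hi <- evaluate_recovery(screen_cohort(generate_cohort(cfg_hi, seed = 23)),
                             generate_cohort(cfg_hi, seed = 23))
  expect_gte(ev_lo$sensitivity, ev_hi$sensitivity)
  expect_lte(ev_lo$false_positive_rate, ev_hi$false_positive_rate)
})

test_that("summary statistics are stable across seeds", {
  rates <- vapply(1:3, function(s) {
    coh <- generate_cohort(cohort_config(n_eyes = 50), seed = 100 + s)
    prev <- build_prevalence(screen_cohort(coh))
    prev$grand_total / prev$total_sectors
  }, numeric(1))
  expect_true(all(rates > 0))
  expect_lt(sd(rates) / mean(rates), 0.5)   # bounded coefficient of variation
})

test_that("eye records validate their structure", {
  expect_error(eye_record("e", age = 50, rnfl_profile = rep(100, 767),
                          mrw_sectors = rep(300, 48)), "768")
  expect_error(eye_record("e", age = 50, rnfl_profile = rep(100, 768),
                          mrw_sectors = rep(300, 47)), "48")
  expect_error(eye_record("e", age = 50, rnfl_profile = rep(-1, 768),
                          mrw_sectors = rep(300, 48)), "non-negative")
  coh <- generate_cohort(cohort_config(n_eyes = 5), seed = 2)
  for (e in coh$eyes) {
    expect_length(e$rnfl_profile, 768)
    expect_length(e$mrw_sectors, 48)
    expect_true(all(e$rnfl_profile >= 0) && all(e$mrw_sectors >= 0))
    expect_true(e$age >= 40 && e$age <= 80)
  }
})
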