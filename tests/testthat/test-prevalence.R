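rec_row <- function(eye_id, angle, type) {
  n <- length(eye_id)
  data.frame(eye_id = eye_id, angle_deg = angle, type = type,
             rnfl_um = rep(NA_real_, n), mrw_um = rep(NA_real_, n),
             stage1_group = rep(NA_character_, n),
             rnfl_class = rep(NA_character_, n),
             mrw_class = rep(NA_character_, n), stringsAsFactors = FALSE)
}

test_that("prevalence maps count per angle and normalize within type", {
  empty <- build_prevalence(rec_row(character(), numeric(), character()),
                            n_eyes = 10)
  expect_equal(empty$total_sectors, 370)
  expect_equal(empty$grand_total, 0)
  expect_true(all(empty$table[-1] == 0))

  rec <- rbind(rec_row("e1", 45, "HIGH_MRW_LOW_RNFL"),
               rec_row("e1", 45, "HIGH_RNFL_LOW_MRW"))
  m <- build_prevalence(rec, n_eyes = 1)
  i <- match(45, m$table$angle_deg)
  expect_equal(m$table$frac_high_mrw_low_rnfl[i], 1)
  expect_equal(m$table$frac_high_rnfl_low_mrw[i], 1)
  expect_equal(m$grand_total, 2)
  expect_equal(sum(m$totals), m$grand_total)
  expect_error(build_prevalence(rec_row("e1", 180, "HIGH_MRW_LOW_RNFL"), 1),
               "off the analyzed")
})

test_that("per-type fractions sum to one whenever the type occurs", {
  coh <- generate_cohort(cohort_config(n_eyes = 30), seed = 9)
  scr <- screen_cohort(coh)
  m <- build_prevalence(scr)
  for (ty in names(m$totals)) {
    f <- m$table[[paste0("frac_", tolower(ty))]]
    if (m$totals[[ty]] > 0) expect_equal(sum(f), 1)
    expect_true(all(f >= 0))
  }
  cnt <- m$table$count_high_mrw_low_rnfl + m$table$count_high_rnfl_low_mrw
  expect_true(all(cnt == floor(cnt) & cnt >= 0))
  expect_equal(m$total_sectors, scr$n_eyes * 37)
})

test_that("peak angles return the maximal within-type fraction, ties in wedge order", {
  rec <- do.call(rbind, c(
    lapply(1:10, function(i) rec_row(paste0("e", i), 75, "HIGH_RNFL_LOW_MRW")),
    lapply(1:9, function(i) rec_row(paste0("f", i), 90, "HIGH_RNFL_LOW_MRW"))))
  m <- build_prevalence(rec, n_eyes = 19)
  pk <- peak_angles(m, "HIGH_RNFL_LOW_MRW")
  expect_equal(pk$angle_deg, 75)
  expect_equal(pk$frac_of_type, 10 / 19)
  # uniform counts tie across all 37 angles
  recu <- do.call(rbind, lapply(analysis_angles(), function(a)
    rec_row("u", a, "HIGH_MRW_LOW_RNFL")))
  mu <- build_prevalence(recu, n_eyes = 1)
  pku <- peak_angles(mu, "HIGH_MRW_LOW_RNFL")
  expect_equal(pku$angle_deg, analysis_angles())
  expect_equal(unique(pku$frac_of_type), 1 / 37)
  # absent type: empty result
  expect_equal(nrow(peak_angles(mu, "HIGH_RNFL_LOW_MRW")), 0)
})

test_that("co-occurrence measures circular separation within eyes", {
  rec <- rbind(rec_row("e1", 45, "HIGH_MRW_LOW_RNFL"),
               rec_row("e1", 60, "HIGH_RNFL_LOW_MRW"),
               rec_row("e2", 352.5, "HIGH_MRW_LOW_RNFL"),
               rec_row("e2", 7.5, "HIGH_RNFL_LOW_MRW"),
               rec_row("e3", 90, "HIGH_MRW_LOW_RNFL"))
  co <- cooccurrence(rec)
  expect_equal(co$n_dual_eyes, 2)
  expect_equal(co$n_sectors_dual_eyes, 4)
  expect_equal(co$share_of_mismatch_sectors, 4 / 5)
  expect_equal(co$min_separation_deg, 15)   # both directly and across 0 deg
  expect_equal(sort(co$per_eye$min_separation_deg), c(15, 15))
  # single-type records only: no dual eyes
  co0 <- cooccurrence(rec_row("e3", 90, "HIGH_MRW_LOW_RNFL"))
  expect_equal(co0$n_dual_eyes, 0)
  expect_equal(co0$n_sectors_dual_eyes, 0)
})

test_that("circular distance wraps through zero", {
  expect_equal(circular_distance(352.5, 7.5), 15)
  expect_equal(circular_distance(0, 180), 180)
  expect_equal(circular_distance(45, 45), 0)
  expect_equal(circular_distance(350, 10), 20)
})

test_that("mirroring record angles about the horizontal meridian mirrors the map", {
  coh <- generate_cohort(cohort_config(n_eyes = 20), seed = 13)
  rec <- screen_cohort(coh)$records
  mirrored <- rec
  mirrored$angle_deg <- (360 - rec$angle_deg) %% 360
  m1 <- build_prevalence(rec, 20)$table
  m2 <- build_prevalence(mirrored, 20)$table
  i <- match((360 - m1$angle_deg) %% 360, m2$angle_deg)
  expect_equal(m1$count_high_mrw_low_rnfl, m2$count_high_mrw_low_rnfl[i])
  expect_equal(m1$count_high_rnfl_low_mrw, m2$count_high_rnfl_low_mrw[i])
})
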