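#' @name synthetic_data
#' @title Seedable synthetic cohorts with mismatch ground truth
#'
#' @description
#' Forward model of the mechanisms that produce RNFL / BMO-MRW mismatches,
#' used to validate every pipeline stage without patient data.  Clean
#' profiles are normative TSNIT mean curves with glaucomatous wedge defects
#' (sector-aligned angular regions scaled toward a per-parameter measurement
#' floor).  Artifacts are then injected: large arcade vessels add a bump to
#' the RNFL at the vessel's retinal trajectory and a smaller bump to the
#' BMO-MRW at its (angularly offset) insertion at the nerve head; small
#' circumlinear vessels, focal retinoschisis and inclusion of outer retinal
#' layers thicken the BMO-MRW only.  Ground-truth mismatch labels are
#' computed by running the screen on the noiseless profiles, so tests can
#' separate screen errors from noise effects; measurement noise is added
#' afterwards.
NULL

#' One eye's measurements and metadata
#'
#' @param eye_id,patient_id Identifiers.
#' @param laterality `"right"` or `"left"`.
#' @param age Age in years.
#' @param rnfl_profile 768 circumpapillary RNFL thicknesses (µm), TSNIT
#'   right-eye order; `NA` marks missing A-scans.
#' @param mrw_sectors 48 BMO-MRW sector thicknesses (µm).
#' @param bmo_area BMO area in mm^2.
#' @param quality_factor Scan quality factor (dimensionless).
#' @param missing_fraction Fraction of missing data in the session.
#' @return An object of class `eye_record`.
#' @export
eye_record <- function(eye_id, patient_id = eye_id, laterality = "right",
                       age, rnfl_profile, mrw_sectors, bmo_area = NA_real_,
                       quality_factor = NA_real_, missing_fraction = NA_real_) {
  if (length(rnfl_profile) != 768L)
    stop("rnfl_profile must have 768 values, got ", length(rnfl_profile))
  if (length(mrw_sectors) != 48L)
    stop("mrw_sectors must have 48 values, got ", length(mrw_sectors))
  if (any(rnfl_profile < 0, na.rm = TRUE) || any(mrw_sectors < 0, na.rm = TRUE))
    stop("thicknesses must be non-negative")
  structure(list(eye_id = as.character(eye_id),
                 patient_id = as.character(patient_id),
                 laterality = laterality, age = age,
                 rnfl_profile = as.numeric(rnfl_profile),
                 mrw_sectors = as.numeric(mrw_sectors),
                 bmo_area = bmo_area, quality_factor = quality_factor,
                 missing_fraction = missing_fraction),
            class = "eye_record")
}

#' @export
print.eye_record <- function(x, ...) {
  cat("Eye", x$eye_id, "(", x$laterality, ", age", round(x$age, 1), "):",
      "mean RNFL", round(mean(x$rnfl_profile, na.rm = TRUE), 1), "um,",
      "mean BMO-MRW", round(mean(x$mrw_sectors, na.rm = TRUE), 1), "um\n")
  invisible(x)
}

#' Residual thickness under the measurement-floor model
#'
#' Glaucomatous loss scales thickness linearly from the normative mean down
#' to a per-parameter floor: the residual value below which the biomarker no
#' longer decreases despite further neural loss.  The RNFL and BMO-MRW
#' floors differ, which is one reason their percentile classes can disagree
#' in advanced damage.
#'
#' @param severity Loss severity in `[0, 1]` (0 = healthy, 1 = at floor).
#' @param parameter `"RNFL"` or `"BMO_MRW"`.
#' @param mean_um Healthy thickness; defaults to the parameter's normative
#'   mean level.
#' @param floor_um Measurement floor; defaults from `config`.
#' @param config A [cohort_config()].
#' @return Residual thickness in µm, `floor + (mean - floor) * (1 - severity)`.
#' @examples
#' floor_model(0, "RNFL")  # normative mean
#' floor_model(1, "RNFL")  # the floor
#' @export
floor_model <- function(severity, parameter = c("RNFL", "BMO_MRW"),
                        mean_um = NULL, floor_um = NULL,
                        config = cohort_config()) {
  parameter <- match.arg(parameter)
  if (any(severity < 0) || any(severity > 1))
    stop("severity must lie in [0, 1]")
  if (is.null(mean_um))
    mean_um <- if (parameter == "RNFL") config$bands_rnfl$mean_level
               else config$bands_mrw$mean_level
  if (is.null(floor_um))
    floor_um <- if (parameter == "RNFL") config$rnfl_floor else config$mrw_floor
  floor_um + (mean_um - floor_um) * (1 - severity)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a glaucoma cohort with early/moderate/advanced disease
#' in a 56/23/21 mix, arcade-centered wedge defects, and artifact rates,
#' locations and magnitudes consistent with the anatomy of the reported
#' mismatch mechanisms.  Artifact bump magnitudes are order-of-magnitude
#' choices (no published figures exist) and are fully configurable.
#'
#' @param n_eyes Number of eyes.
#' @param severity_mix Named proportions for `early`, `moderate`,
#'   `advanced` disease.
#' @param severity_range Named list of `c(min, max)` wedge severities per
#'   disease stage.
#' @param central_damage_prob Per-stage probability of an additional deep
#'   focal notch (severity `notch_severity_range`).
#' @param notch_severity_range,notch_width_sectors Deep-notch severity range
#'   and width (sectors).
#' @param n_wedges_range `c(min, max)` wedge defects per eye.
#' @param wedge_centers Arcade centers (degrees) wedge locations concentrate
#'   around.
#' @param wedge_kappa von Mises concentration of wedge centers.
#' @param wedge_width_sectors `c(min, max)` wedge width in sectors.
#' @param age_mean,age_sd,age_range Age distribution (years), truncated.
#' @param large_vessel_rate,small_vessel_rate,retinoschisis_rate,outer_retina_rate
#'   Poisson rates per eye for each artifact kind.
#' @param large_vessel_centers,small_vessel_centers Angular centers
#'   (degrees) the vessels concentrate around (large: vertical poles;
#'   small: superotemporal/inferotemporal).
#' @param artifact_kappa von Mises concentration of artifact placement.
#' @param large_rnfl_bump,large_mrw_bump,small_mrw_bump,retinoschisis_bump,outer_retina_bump
#'   `c(mean, sd)` bump magnitudes in µm.
#' @param insertion_offset_deg Angular offset between a large vessel's ONH
#'   insertion (BMO-MRW bump) and retinal trajectory (RNFL bump); sign is
#'   drawn at random per vessel.
#' @param focal_width_sectors `c(min, max)` extent of retinoschisis /
#'   outer-retina patches, in sectors.
#' @param rnfl_floor,mrw_floor Measurement floors (µm).
#' @param rnfl_ascan_noise_sd Measurement noise sd per RNFL A-scan (µm);
#'   sector means see `sd / 4`.
#' @param mrw_noise_sd Measurement noise sd per BMO-MRW cut (µm).
#' @param bmo_area_mean,bmo_area_sd BMO area distribution (mm^2).
#' @param quality_range Uniform range of the scan quality factor.
#' @param two_eye_prob Probability a patient contributes both eyes.
#' @param bands_rnfl,bands_mrw [band_config()]s defining the normative
#'   curves the clean profiles are drawn from and the truth labels use.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_eyes = 100L,
    severity_mix = c(early = 0.56, moderate = 0.23, advanced = 0.21),
    severity_range = list(early = c(0.45, 0.70), moderate = c(0.60, 0.78),
                          advanced = c(0.92, 1.00)),
    central_damage_prob = c(early = 0.62, moderate = 0.70, advanced = 0),
    notch_severity_range = c(0.92, 1.00),
    notch_width_sectors = c(2L, 5L),
    n_wedges_range = c(2L, 4L),
    wedge_centers = c(67.5, 292.5),
    wedge_kappa = 8,
    wedge_width_sectors = c(4L, 9L),
    age_mean = 68.1, age_sd = 9.1, age_range = c(40, 80),
    large_vessel_rate = 5.0, small_vessel_rate = 4.0,
    retinoschisis_rate = 0.08, outer_retina_rate = 0.15,
    large_vessel_centers = c(82.5, 277.5),
    small_vessel_centers = c(45, 322.5),
    artifact_kappa = 60,
    large_rnfl_bump = c(mean = 75, sd = 8),
    large_mrw_bump = c(mean = 12, sd = 4),
    insertion_offset_deg = 15,
    small_mrw_bump = c(mean = 180, sd = 20),
    retinoschisis_bump = c(mean = 200, sd = 30),
    outer_retina_bump = c(mean = 150, sd = 25),
    focal_width_sectors = c(1L, 2L),
    rnfl_floor = 40, mrw_floor = 60,
    rnfl_ascan_noise_sd = 4, mrw_noise_sd = 4,
    bmo_area_mean = 1.92, bmo_area_sd = 0.48,
    quality_range = c(18, 35),
    two_eye_prob = 0.58,
    bands_rnfl = band_config("RNFL"),
    bands_mrw = band_config("BMO_MRW")) {
  severity_mix <- severity_mix / sum(severity_mix)
  structure(as.list(environment()), class = "cohort_config")
}

# von Mises sampler (Best & Fisher 1979), angles in degrees
rvonmises_deg <- function(n, mu_deg, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      z <- cos(pi * stats::runif(1))
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      u2 <- stats::runif(1)
      if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) break
    }
    theta <- sign(stats::runif(1) - 0.5) * acos(pmin(pmax(f, -1), 1))
    out[i] <- (mu_deg + theta * 180 / pi) %% 360
  }
  out
}

# sector index (0-based) of each A-scan index 0..767
.ascan_sector <- function() as.integer(floor((0:767 + 8) / 16) %% 48)

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

.sector_span <- function(center_k, width) {
  (center_k - floor((width - 1) / 2) + 0:(width - 1)) %% 48
}

#' Generate a synthetic cohort with mismatch ground truth
#'
#' Deterministic for a fixed seed.  See [cohort_config()] for the forward
#' model and its parameters.
#'
#' @param config A [cohort_config()].
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_cohort`: list with `eyes` (list of
#'   [eye_record()]s) and `truth`, itself a list with `artifacts` (data
#'   frame `eye_id`, `angle_deg`, `kind`, `magnitude_um`, `offset_deg`;
#'   kinds include `GLAUCOMA_WEDGE` for the injected defects),
#'   `expected` (data frame `eye_id`, `angle_deg`, `expected_type` over all
#'   analyzed sectors, `"NONE"` where the screen should stay silent),
#'   `config` and `seed`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_eyes = 3), seed = 7)
#' table(coh$truth$expected$expected_type)
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  grid <- sector_grid()
  ang48 <- grid$sector_angles
  ang768 <- ascan_angle(0:767)
  asec <- .ascan_sector()
  bands_rnfl <- build_default_bands(config = config$bands_rnfl, grid = grid)
  bands_mrw <- build_default_bands(config = config$bands_mrw, grid = grid)
  cutoffs <- screen_cutoffs()
  aang <- analysis_angles(grid)
  k_analysis <- match(aang, ang48)

  eyes <- vector("list", config$n_eyes)
  artifacts <- list(); expected <- list()
  pat_i <- 0L; eyes_left_for_pat <- 0L
  stages <- sample(names(config$severity_mix), config$n_eyes,
                   replace = TRUE, prob = config$severity_mix)

  for (i in seq_len(config$n_eyes)) {
    if (eyes_left_for_pat == 0L) {
      pat_i <- pat_i + 1L
      eyes_left_for_pat <- 1L +
        stats::rbinom(1, 1, config$two_eye_prob)
    }
    eyes_left_for_pat <- eyes_left_for_pat - 1L
    eye_id <- sprintf("eye%04d", i)
    patient_id <- sprintf("pat%04d", pat_i)
    laterality <- sample(c("right", "left"), 1)
    age <- .rtrunc_norm(1, config$age_mean, config$age_sd,
                        config$age_range[1], config$age_range[2])
    stage <- stages[i]

    rnfl <- normative_mean(ang768, config$bands_rnfl, age = age)
    mrw <- normative_mean(ang48, config$bands_mrw, age = age)

    # glaucomatous wedge defects, sector-aligned, deepest wedge wins
    sev <- numeric(48)
    art_eye <- list()
    add_wedge <- function(center_deg, width, s) {
      ks <- .sector_span(round(center_deg / 7.5) %% 48, width)
      sev[ks + 1L] <<- pmax(sev[ks + 1L], s)
      art_eye[[length(art_eye) + 1L]] <<- data.frame(
        eye_id = eye_id, angle_deg = (round(center_deg / 7.5) %% 48) * 7.5,
        kind = "GLAUCOMA_WEDGE", magnitude_um = NA_real_, offset_deg = 0)
    }
    n_w <- sample(config$n_wedges_range[1]:config$n_wedges_range[2], 1)
    for (w in seq_len(n_w)) {
      ctr <- rvonmises_deg(1, sample(config$wedge_centers, 1),
                           config$wedge_kappa)
      wid <- sample(config$wedge_width_sectors[1]:config$wedge_width_sectors[2], 1)
      s <- stats::runif(1, config$severity_range[[stage]][1],
                        config$severity_range[[stage]][2])
      add_wedge(ctr, wid, s)
    }
    if (stats::runif(1) < config$central_damage_prob[[stage]]) {
      ctr <- rvonmises_deg(1, sample(config$wedge_centers, 1),
                           config$wedge_kappa)
      wid <- sample(config$notch_width_sectors[1]:config$notch_width_sectors[2], 1)
      s <- stats::runif(1, config$notch_severity_range[1],
                        config$notch_severity_range[2])
      add_wedge(ctr, wid, s)
    }
    rnfl <- config$rnfl_floor +
      pmax(rnfl - config$rnfl_floor, 0) * (1 - sev[asec + 1L])
    mrw <- config$mrw_floor + pmax(mrw - config$mrw_floor, 0) * (1 - sev)

    bump <- function(spec) max(stats::rnorm(1, spec[["mean"]], spec[["sd"]]), 0)
    # large arcade vessels: RNFL bump at the trajectory sector, smaller
    # BMO-MRW bump at the offset insertion sector
    for (v in seq_len(stats::rpois(1, config$large_vessel_rate))) {
      k <- round(rvonmises_deg(1, sample(config$large_vessel_centers, 1),
                               config$artifact_kappa) / 7.5) %% 48
      off <- sample(c(-1, 1), 1) * config$insertion_offset_deg
      ki <- (k + round(off / 7.5)) %% 48
      b_r <- bump(config$large_rnfl_bump)
      rnfl[asec == k] <- rnfl[asec == k] + b_r
      mrw[ki + 1L] <- mrw[ki + 1L] + bump(config$large_mrw_bump)
      art_eye[[length(art_eye) + 1L]] <- data.frame(
        eye_id = eye_id, angle_deg = k * 7.5, kind = "LARGE_VESSEL",
        magnitude_um = b_r, offset_deg = off)
    }
    # small circumlinear vessels and focal MRW-only thickening
    focal <- function(rate, centers, kind, bspec, width_range) {
      for (v in seq_len(stats::rpois(1, rate))) {
        ctr <- if (is.null(centers)) sample(aang, 1)
               else rvonmises_deg(1, sample(centers, 1), config$artifact_kappa)
        k <- round(ctr / 7.5) %% 48
        wid <- sample(width_range[1]:width_range[2], 1)
        b <- bump(bspec)
        ks <- .sector_span(k, wid)
        mrw[ks + 1L] <<- mrw[ks + 1L] + b
        art_eye[[length(art_eye) + 1L]] <<- data.frame(
          eye_id = eye_id, angle_deg = k * 7.5, kind = kind,
          magnitude_um = b, offset_deg = 0)
      }
    }
    focal(config$small_vessel_rate, config$small_vessel_centers,
          "SMALL_VESSEL", config$small_mrw_bump, c(1L, 1L))
    focal(config$retinoschisis_rate, NULL, "RETINOSCHISIS",
          config$retinoschisis_bump, config$focal_width_sectors)
    focal(config$outer_retina_rate, NULL, "OUTER_RETINA_INCLUSION",
          config$outer_retina_bump, config$focal_width_sectors)

    # ground truth: the screen applied to the noiseless profiles
    sect_clean <- as.numeric(sectorize_rnfl(rnfl))
    exp_type <- rep("NONE", length(aang))
    grp <- stage1_group(sect_clean[k_analysis], mrw[k_analysis], cutoffs)
    for (j in which(grp %in% c("G2", "G4"))) {
      rc <- classify(sect_clean[k_analysis[j]], aang[j], bands_rnfl, age)
      mc <- classify(mrw[k_analysis[j]], aang[j], bands_mrw, age)
      ty <- stage2_confirm(grp[j], rc, mc)
      if (!is.na(ty)) exp_type[j] <- ty
    }
    expected[[i]] <- data.frame(eye_id = eye_id, angle_deg = aang,
                                expected_type = exp_type,
                                stringsAsFactors = FALSE)
    artifacts[[i]] <- do.call(rbind, art_eye)

    eyes[[i]] <- eye_record(
      eye_id = eye_id, patient_id = patient_id, laterality = laterality,
      age = age,
      rnfl_profile = pmax(rnfl + stats::rnorm(768, 0, config$rnfl_ascan_noise_sd), 0),
      mrw_sectors = pmax(mrw + stats::rnorm(48, 0, config$mrw_noise_sd), 0),
      bmo_area = max(stats::rnorm(1, config$bmo_area_mean, config$bmo_area_sd), 0.5),
      quality_factor = stats::runif(1, config$quality_range[1],
                                    config$quality_range[2]),
      missing_fraction = 0)
  }
  structure(list(eyes = eyes,
                 truth = list(artifacts = do.call(rbind, artifacts),
                              expected = do.call(rbind, expected),
                              config = config, seed = as.integer(seed))),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  np <- sum(x$truth$expected$expected_type != "NONE")
  cat("Synthetic cohort:", length(x$eyes), "eyes (seed", x$truth$seed, ");",
      np, "truth-labeled mismatch sectors\n")
  invisible(x)
}

#' Map synthetic truth artifacts onto mismatch records as cause annotations
#'
#' Stands in for the manual image review on synthetic data: each mismatch
#' record is annotated with the kind of the nearest injected artifact within
#' `max_distance_deg` (glaucoma wedges are not causes and are skipped);
#' records with no nearby artifact are left unannotated and will fall into
#' OTHER in [attribute_causes()].
#'
#' @param cohort A [generate_cohort()] result.
#' @param records Mismatch records data frame or `mismatch_screen`.
#' @param max_distance_deg Maximal circular distance for a match (degrees).
#' @return A [cause_annotations()] table.
#' @export
truth_annotations <- function(cohort, records, max_distance_deg = 15) {
  if (inherits(records, "mismatch_screen")) records <- records$records
  art <- cohort$truth$artifacts
  art <- art[art$kind != "GLAUCOMA_WEDGE", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(records))) {
    a <- art[art$eye_id == records$eye_id[i], , drop = FALSE]
    if (!nrow(a)) next
    d <- circular_distance(a$angle_deg, records$angle_deg[i])
    if (min(d) <= max_distance_deg)
      out[[length(out) + 1L]] <- data.frame(
        eye_id = records$eye_id[i], angle_deg = records$angle_deg[i],
        cause = a$kind[which.min(d)], stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, c(list(data.frame(eye_id = character(),
                                        angle_deg = numeric(),
                                        cause = character())), out))
  cause_annotations(d$eye_id, d$angle_deg, d$cause)
}

#' Compare a screen's detections against synthetic ground truth
#'
#' @param screen A [screen_cohort()] result on a synthetic cohort.
#' @param cohort The [generate_cohort()] result that produced the eyes.
#' @return A list of class `recovery_evaluation`: `n_truth_positive`,
#'   `n_detected`, `n_recovered` (detected with the correct type),
#'   `sensitivity`, `n_false_positive` (detections at truth-negative
#'   sectors or with the wrong type), `false_positive_rate` (over
#'   truth-negative analyzed sectors), and `n_negative`.
#' @export
evaluate_recovery <- function(screen, cohort) {
  kept <- screen$qc$kept
  tr <- cohort$truth$expected
  tr <- tr[tr$eye_id %in% kept, , drop = FALSE]
  tkey <- paste(tr$eye_id, tr$angle_deg, tr$expected_type)
  pos <- tr$expected_type != "NONE"
  det <- screen$records
  dkey <- paste(det$eye_id, det$angle_deg, det$type)
  n_recovered <- sum(tkey[pos] %in% dkey)
  n_fp <- sum(!(dkey %in% tkey[pos]))
  n_neg <- sum(!pos)
  structure(list(
    n_truth_positive = sum(pos),
    n_detected = nrow(det),
    n_recovered = n_recovered,
    sensitivity = if (sum(pos)) n_recovered / sum(pos) else NA_real_,
    n_false_positive = n_fp,
    false_positive_rate = if (n_neg) n_fp / n_neg else NA_real_,
    n_negative = n_neg),
    class = "recovery_evaluation")
}

#' @export
print.recovery_evaluation <- function(x, ...) {
  cat(sprintf(
    "Recovery vs ground truth: %d/%d truth mismatches detected (sensitivity %.1f%%);\n  %d false positives over %d truth-negative sectors (%.2f%%)\n",
    x$n_recovered, x$n_truth_positive, 100 * x$sensitivity,
    x$n_false_positive, x$n_negative, 100 * x$false_positive_rate))
  invisible(x)
}
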