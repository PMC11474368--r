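#' @name io
#' @title Delimited-text data contracts, quality control and pipeline driver
#'
#' @description
#' All interchange is plain comma-separated text (UTF-8, header row, dot
#' decimal): a cohort is a directory with `manifest.csv` (metadata),
#' `rnfl_profiles.csv` (one row per eye, 768 A-scan columns `a000`..`a767`),
#' `mrw_sectors.csv` (48 columns `s00`..`s47`) and, for synthetic cohorts,
#' `truth_artifacts.csv` / `truth_expected.csv`.  Quality control rejects a
#' whole session -- both RNFL and BMO-MRW -- when the quality factor is
#' below 15 or more than 10% of data are missing.
NULL

#' Session quality-control rule
#'
#' @param min_quality_factor Sessions with quality factor strictly below
#'   this are rejected (default 15).
#' @param max_missing_fraction Sessions with missing-data fraction strictly
#'   above this are rejected (default 0.10).
#' @return A list of class `qc_rule`.
#' @export
qc_rule <- function(min_quality_factor = 15, max_missing_fraction = 0.10) {
  stopifnot(is.finite(min_quality_factor), is.finite(max_missing_fraction))
  structure(list(min_quality_factor = min_quality_factor,
                 max_missing_fraction = max_missing_fraction),
            class = "qc_rule")
}

#' Apply session quality control to a cohort
#'
#' Rejection drops both the RNFL and BMO-MRW data for the session.  The
#' boundary semantics are strict as stated: quality factor exactly 15 and
#' missing fraction exactly 0.10 are kept.  Eyes without QC metadata are
#' rejected.
#'
#' @param eyes List of [eye_record()]s.
#' @param rule A [qc_rule()].
#' @return List with `kept` (eye records) and `rejected` (data frame
#'   `eye_id`, `reason`).
#' @export
apply_qc <- function(eyes, rule = qc_rule()) {
  kept <- list(); rej <- list()
  for (e in eyes) {
    reason <- NULL
    if (is.na(e$quality_factor) || is.na(e$missing_fraction))
      reason <- "no QC metadata"
    else if (e$quality_factor < rule$min_quality_factor)
      reason <- sprintf("quality factor %.1f < %g", e$quality_factor,
                        rule$min_quality_factor)
    else if (e$missing_fraction > rule$max_missing_fraction)
      reason <- sprintf("missing fraction %.3f > %g", e$missing_fraction,
                        rule$max_missing_fraction)
    if (is.null(reason)) kept[[length(kept) + 1L]] <- e
    else rej[[length(rej) + 1L]] <- data.frame(eye_id = e$eye_id,
                                               reason = reason,
                                               stringsAsFactors = FALSE)
  }
  list(kept = kept,
       rejected = do.call(rbind, c(list(data.frame(eye_id = character(),
                                                   reason = character())),
                                   rej)))
}

#' Save a cohort as delimited text
#'
#' @param cohort A `synthetic_cohort`, or a plain list of [eye_record()]s.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  eyes <- if (!is.null(cohort$eyes)) cohort$eyes else cohort
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- do.call(rbind, lapply(eyes, function(e)
    data.frame(eye_id = e$eye_id, patient_id = e$patient_id,
               laterality = e$laterality, age = e$age,
               bmo_area_mm2 = e$bmo_area, quality_factor = e$quality_factor,
               missing_fraction = e$missing_fraction,
               stringsAsFactors = FALSE)))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  rn <- do.call(rbind, lapply(eyes, `[[`, "rnfl_profile"))
  colnames(rn) <- sprintf("a%03d", 0:767)
  utils::write.csv(data.frame(eye_id = man$eye_id, rn, check.names = FALSE),
                   file.path(dir, "rnfl_profiles.csv"), row.names = FALSE)
  mw <- do.call(rbind, lapply(eyes, `[[`, "mrw_sectors"))
  colnames(mw) <- sprintf("s%02d", 0:47)
  utils::write.csv(data.frame(eye_id = man$eye_id, mw, check.names = FALSE),
                   file.path(dir, "mrw_sectors.csv"), row.names = FALSE)
  if (!is.null(cohort$truth)) {
    utils::write.csv(cohort$truth$artifacts,
                     file.path(dir, "truth_artifacts.csv"), row.names = FALSE)
    utils::write.csv(cohort$truth$expected,
                     file.path(dir, "truth_expected.csv"), row.names = FALSE)
  }
  invisible(dir)
}

.read_wide <- function(path, prefix, n, what) {
  d <- utils::read.csv(path, check.names = FALSE)
  # tolerate any column naming as long as the count matches
  val_cols <- setdiff(names(d), "eye_id")
  if (length(val_cols) != n)
    stop(basename(path), ": expected ", n, " ", what, " columns, found ",
         length(val_cols))
  for (cn in val_cols)
    if (!is.numeric(d[[cn]]))
      stop(basename(path), ": non-numeric thickness in column ", cn)
  m <- as.matrix(d[val_cols])
  rownames(m) <- d$eye_id
  if (any(m < 0, na.rm = TRUE))
    stop(basename(path), ": negative thickness value")
  m
}

#' Load a cohort from delimited text
#'
#' Reads the directory layout written by [save_cohort()], validates every
#' record (profile lengths, non-negative thicknesses) and normalizes
#' laterality via [normalize_laterality()].
#'
#' @param dir Cohort directory.
#' @param input_convention Angular convention of the stored profiles:
#'   `"tsnit"` (device-native, default) or `"absolute-clockwise"`.
#' @return A list with `eyes` (list of [eye_record()]s) and, when truth
#'   tables are present, `truth` (list `artifacts`, `expected`).
#' @export
load_cohort <- function(dir, input_convention = "tsnit") {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("no manifest.csv in ", dir)
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  rn <- .read_wide(file.path(dir, "rnfl_profiles.csv"), "a", 768L, "A-scan")
  mw <- .read_wide(file.path(dir, "mrw_sectors.csv"), "s", 48L, "sector")
  eyes <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    id <- man$eye_id[i]
    if (!id %in% rownames(rn))
      stop("manifest row ", i, " (", id, "): no RNFL profile")
    if (!id %in% rownames(mw))
      stop("manifest row ", i, " (", id, "): no BMO-MRW sectors")
    eyes[[i]] <- eye_record(
      eye_id = id, patient_id = man$patient_id[i],
      laterality = man$laterality[i], age = man$age[i],
      rnfl_profile = normalize_laterality(rn[id, ], man$laterality[i],
                                          input_convention, what = "profile"),
      mrw_sectors = normalize_laterality(mw[id, ], man$laterality[i],
                                         input_convention, what = "profile"),
      bmo_area = man$bmo_area_mm2[i],
      quality_factor = man$quality_factor[i],
      missing_fraction = man$missing_fraction[i])
  }
  out <- list(eyes = eyes)
  ta <- file.path(dir, "truth_artifacts.csv")
  te <- file.path(dir, "truth_expected.csv")
  if (file.exists(ta) && file.exists(te))
    out$truth <- list(artifacts = utils::read.csv(ta, stringsAsFactors = FALSE),
                      expected = utils::read.csv(te, stringsAsFactors = FALSE))
  out
}

#' Run the full mismatch pipeline
#'
#' Orchestrates simulate/load -> quality control -> two-stage screen ->
#' prevalence -> attribution and writes all outputs as delimited text plus
#' a plain-text run log.
#'
#' @param config Either a YAML file path or a list with elements:
#'   `seed` (integer); one of `simulate` (list of [cohort_config()]
#'   overrides) or `input_dir`; optionally `bands` (list with `rnfl` /
#'   `mrw` CSV paths; default parametric bands otherwise), `annotations`
#'   (`"truth"` to derive causes from synthetic ground truth, a CSV path,
#'   or `"none"`), and `out_dir` (required).
#' @return Invisibly, a list with `screen`, `prevalence`, `attribution`
#'   (possibly `NULL`), `recovery` (for simulated cohorts with truth) and
#'   `out_dir`.
#' @examples
#' \donttest{
#' out <- run_pipeline(list(seed = 1, simulate = list(n_eyes = 5),
#'                          out_dir = tempfile()))
#' out$prevalence
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  log <- c(paste("sectormatch", as.character(utils::packageVersion("sectormatch"))),
           paste("run at", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           paste("seed", seed))

  truth <- NULL
  if (!is.null(config$simulate)) {
    cc <- do.call(cohort_config, config$simulate)
    cohort <- generate_cohort(cc, seed = seed)
    save_cohort(cohort, file.path(config$out_dir, "cohort"))
    eyes <- cohort$eyes; truth <- cohort
    log <- c(log, paste("simulated cohort of", length(eyes), "eyes"))
  } else if (!is.null(config$input_dir)) {
    loaded <- load_cohort(config$input_dir)
    eyes <- loaded$eyes
    log <- c(log, paste("loaded", length(eyes), "eyes from", config$input_dir))
  } else stop("config must provide either simulate: or input_dir:")

  if (!is.null(config$bands)) {
    bands_rnfl <- read_bands(config$bands$rnfl, "RNFL")
    bands_mrw <- read_bands(config$bands$mrw, "BMO_MRW")
    log <- c(log, "bands: user-supplied tables")
  } else {
    bands_rnfl <- build_default_bands("RNFL")
    bands_mrw <- build_default_bands("BMO_MRW")
    log <- c(log, "bands: default parametric (RNFL level 100, BMO-MRW level 330)")
  }

  scr <- screen_cohort(eyes, bands_rnfl, bands_mrw)
  if (scr$n_eyes == 0L)
    warning("no eyes left after quality control; reports will be empty")
  if (nrow(scr$qc$rejected))
    log <- c(log, paste0("QC rejected ", nrow(scr$qc$rejected), " eye(s): ",
                         paste(scr$qc$rejected$eye_id, collapse = ", ")))
  write_records(scr, file.path(config$out_dir, "mismatch_records.csv"))
  prev <- build_prevalence(scr)
  write_prevalence(prev, file.path(config$out_dir, "prevalence.csv"))
  log <- c(log, sprintf("%d true mismatches over %d analyzed sectors",
                        prev$grand_total, prev$total_sectors))

  attribution <- NULL
  ann_src <- if (is.null(config$annotations)) {
    if (!is.null(truth)) "truth" else "none"
  } else config$annotations
  if (identical(ann_src, "truth") && !is.null(truth)) {
    ann <- truth_annotations(truth, scr)
    attribution <- suppressWarnings(attribute_causes(scr, ann))
    log <- c(log, "attribution: causes from synthetic ground truth")
  } else if (!identical(ann_src, "none") && !identical(ann_src, "truth")) {
    ann <- read_annotations(ann_src)
    attribution <- attribute_causes(scr, ann)
    log <- c(log, paste("attribution: causes from", ann_src))
  }
  if (!is.null(attribution))
    write_attribution(attribution, file.path(config$out_dir, "attribution.csv"))

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- evaluate_recovery(scr, truth)
    log <- c(log, sprintf("recovery: sensitivity %.1f%%, FPR %.2f%%",
                          100 * recovery$sensitivity,
                          100 * recovery$false_positive_rate))
  }
  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  invisible(list(screen = scr, prevalence = prev, attribution = attribution,
                 recovery = recovery, out_dir = config$out_dir))
}
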