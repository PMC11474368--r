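#' @name screening
#' @title Two-stage mismatch screen
#'
#' @description
#' Within each eye the 37 analyzed sector pairs (RNFL, BMO-MRW) pass a
#' two-stage screen.  Stage 1 sorts sectors into four groups by fixed
#' numeric cutoffs: group 1 (RNFL >= 65 µm; BMO-MRW >= 130 µm), group 2
#' (RNFL <= 50; BMO-MRW >= 130), group 3 (RNFL <= 50; BMO-MRW <= 100),
#' group 4 (RNFL >= 65; BMO-MRW <= 100); sectors falling in the open gaps
#' (RNFL 50--65 or BMO-MRW 100--130) are UNGROUPED.  Only groups 2 and 4 --
#' the candidate mismatches -- reach stage 2, which confirms a *true
#' mismatch* when the low member is below the 1st normative percentile
#' (red on the TSNIT curve) while its counterpart is not (yellow or green).
#' Sectors where both members are red are interpreted as a shared
#' measurement floor, not a mismatch.
NULL

.GROUPS <- c("G1", "G2", "G3", "G4", "UNGROUPED")
.MM_TYPES <- c("HIGH_MRW_LOW_RNFL", "HIGH_RNFL_LOW_MRW")

#' Stage-1 cutoffs of the mismatch screen
#'
#' @param rnfl_low,rnfl_high RNFL cutoffs in µm (low <= 50 band, high >= 65
#'   band by default).
#' @param mrw_low,mrw_high BMO-MRW cutoffs in µm (100 / 130 by default).
#' @return A named list of class `screen_cutoffs`.
#' @export
screen_cutoffs <- function(rnfl_low = 50, rnfl_high = 65,
                           mrw_low = 100, mrw_high = 130) {
  if (rnfl_low >= rnfl_high || mrw_low >= mrw_high)
    stop("low cutoffs must be below high cutoffs")
  structure(list(rnfl_low = rnfl_low, rnfl_high = rnfl_high,
                 mrw_low = mrw_low, mrw_high = mrw_high),
            class = "screen_cutoffs")
}

#' Stage 1: group a sector by its paired thickness values
#'
#' @param rnfl_um,mrw_um Sector thicknesses in µm (vectorized, finite,
#'   non-negative; `NA` returns `NA`).
#' @param cutoffs A [screen_cutoffs()].
#' @return Character vector over
#'   `c("G1","G2","G3","G4","UNGROUPED")`.
#' @examples
#' stage1_group(70, 90)    # "G4"
#' stage1_group(45, 140)   # "G2"
#' stage1_group(60, 115)   # "UNGROUPED"
#' @export
stage1_group <- function(rnfl_um, mrw_um, cutoffs = screen_cutoffs()) {
  n <- max(length(rnfl_um), length(mrw_um))
  r <- rep_len(rnfl_um, n); m <- rep_len(mrw_um, n)
  if (any(r < 0, na.rm = TRUE) || any(m < 0, na.rm = TRUE) ||
      any(is.infinite(r)) || any(is.infinite(m)))
    stop("thicknesses must be finite and non-negative")
  rh <- r >= cutoffs$rnfl_high; rl <- r <= cutoffs$rnfl_low
  mh <- m >= cutoffs$mrw_high;  ml <- m <= cutoffs$mrw_low
  out <- rep("UNGROUPED", n)
  out[rh & mh] <- "G1"
  out[rl & mh] <- "G2"
  out[rl & ml] <- "G3"
  out[rh & ml] <- "G4"
  out[is.na(r) | is.na(m)] <- NA_character_
  out
}

#' Stage 2: confirm a candidate mismatch by percentile class
#'
#' Applied only to stage-1 groups 2 and 4.  A group-2 sector is a confirmed
#' `HIGH_MRW_LOW_RNFL` mismatch iff its RNFL class is RED and its BMO-MRW
#' class is not; a group-4 sector is `HIGH_RNFL_LOW_MRW` iff its BMO-MRW
#' class is RED and its RNFL class is not.  Anything else is not a mismatch.
#'
#' @param group Stage-1 group, `"G2"` or `"G4"`.
#' @param rnfl_class,mrw_class TSNIT percentile classes
#'   (`"RED"`, `"YELLOW"`, `"GREEN"`).
#' @return The mismatch type, or `NA_character_` if not confirmed.
#' @examples
#' stage2_confirm("G2", "RED", "GREEN")    # HIGH_MRW_LOW_RNFL
#' stage2_confirm("G2", "YELLOW", "GREEN") # NA
#' @export
stage2_confirm <- function(group, rnfl_class, mrw_class) {
  if (!group %in% c("G2", "G4"))
    stop("stage 2 applies only to stage-1 groups G2 and G4, got ", group)
  stopifnot(rnfl_class %in% .PCLASS, mrw_class %in% .PCLASS)
  if (group == "G2" && rnfl_class == "RED" && mrw_class != "RED")
    return("HIGH_MRW_LOW_RNFL")
  if (group == "G4" && mrw_class == "RED" && rnfl_class != "RED")
    return("HIGH_RNFL_LOW_MRW")
  NA_character_
}

.empty_records <- function() {
  data.frame(eye_id = character(), angle_deg = numeric(),
             type = character(), rnfl_um = numeric(), mrw_um = numeric(),
             stage1_group = character(), rnfl_class = character(),
             mrw_class = character(), stringsAsFactors = FALSE)
}

#' Screen one eye for true mismatch sectors
#'
#' Sectorizes the RNFL profile, restricts to the 37 analyzed sectors,
#' applies the two-stage screen against the supplied normative bands and
#' returns the confirmed mismatch records.  Sectors with missing data are
#' dropped individually and counted; whole-session quality control happens
#' upstream in [apply_qc()].
#'
#' @param eye An [eye_record()].
#' @param bands_rnfl,bands_mrw [normative_bands()] for each parameter.
#' @param grid A [sector_grid()].
#' @param cutoffs A [screen_cutoffs()].
#' @return A list of class `eye_screen`: `records` (data frame with one row
#'   per confirmed mismatch, in analysis-wedge order), `group_counts`
#'   (named counts over G1..G4, UNGROUPED and MISSING; sums to 37) and
#'   `eye_id`.
#' @export
screen_eye <- function(eye, bands_rnfl, bands_mrw, grid = sector_grid(),
                       cutoffs = screen_cutoffs()) {
  stopifnot(inherits(eye, "eye_record"))
  sect <- as.numeric(sectorize_rnfl(eye$rnfl_profile))
  mrw <- eye$mrw_sectors
  ang <- analysis_angles(grid)
  k <- match(ang, grid$sector_angles)
  r <- sect[k]; m <- mrw[k]
  miss <- is.na(r) | is.na(m)
  grp <- stage1_group(r, m, cutoffs)
  counts <- c(table(factor(grp[!miss], levels = .GROUPS)),
              MISSING = sum(miss))
  rec <- .empty_records()
  cand <- which(!miss & grp %in% c("G2", "G4"))
  for (j in cand) {
    rc <- classify(r[j], ang[j], bands_rnfl, age = eye$age)
    mc <- classify(m[j], ang[j], bands_mrw, age = eye$age)
    ty <- stage2_confirm(grp[j], rc, mc)
    if (!is.na(ty))
      rec <- rbind(rec, data.frame(
        eye_id = eye$eye_id, angle_deg = ang[j], type = ty,
        rnfl_um = r[j], mrw_um = m[j], stage1_group = grp[j],
        rnfl_class = rc, mrw_class = mc, stringsAsFactors = FALSE))
  }
  structure(list(eye_id = eye$eye_id, records = rec, group_counts = counts),
            class = "eye_screen")
}

#' Screen a cohort of eyes for RNFL vs BMO-MRW mismatches
#'
#' The central entry point: applies quality control, screens every retained
#' eye with [screen_eye()] and collects the results into a single object.
#'
#' @param eyes A list of [eye_record()]s (or a cohort as returned by
#'   [generate_cohort()], whose `$eyes` element is used).
#' @param bands_rnfl,bands_mrw Normative bands; defaults are the parametric
#'   bands of [build_default_bands()].
#' @param grid A [sector_grid()].
#' @param cutoffs A [screen_cutoffs()].
#' @param qc A [qc_rule()], or `NULL` to skip quality control.
#' @return An object of class `mismatch_screen`: list with `records` (all
#'   confirmed mismatch rows), `group_counts` (eyes x groups matrix),
#'   `n_eyes` (screened), `qc` (list `kept`, `rejected`), `grid`, `cutoffs`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_eyes = 5), seed = 1)
#' scr <- screen_cohort(coh)
#' scr
#' @export
screen_cohort <- function(eyes,
                          bands_rnfl = build_default_bands("RNFL"),
                          bands_mrw = build_default_bands("BMO_MRW"),
                          grid = sector_grid(),
                          cutoffs = screen_cutoffs(),
                          qc = qc_rule()) {
  if (!is.null(eyes$eyes) && !inherits(eyes, "eye_record")) eyes <- eyes$eyes
  stopifnot(length(eyes) > 0L, all(vapply(eyes, inherits, TRUE, "eye_record")))
  if (!is.null(qc)) {
    q <- apply_qc(eyes, qc)
    eyes <- q$kept
    rejected <- q$rejected
  } else rejected <- data.frame(eye_id = character(), reason = character())
  per <- lapply(eyes, screen_eye, bands_rnfl = bands_rnfl,
                bands_mrw = bands_mrw, grid = grid, cutoffs = cutoffs)
  records <- do.call(rbind, c(list(.empty_records()),
                              lapply(per, `[[`, "records")))
  gc <- do.call(rbind, lapply(per, `[[`, "group_counts"))
  if (length(per)) rownames(gc) <- vapply(per, `[[`, "", "eye_id")
  structure(list(records = records, group_counts = gc,
                 n_eyes = length(eyes),
                 qc = list(kept = vapply(eyes, `[[`, "", "eye_id"),
                           rejected = rejected),
                 grid = grid, cutoffs = cutoffs,
                 bands_rnfl = bands_rnfl, bands_mrw = bands_mrw),
            class = "mismatch_screen")
}

#' @export
print.mismatch_screen <- function(x, ...) {
  n_sect <- x$n_eyes * sum(x$grid$analysis_mask)
  cat("Two-stage RNFL / BMO-MRW mismatch screen\n")
  cat("  eyes screened:   ", x$n_eyes,
      if (nrow(x$qc$rejected)) paste0(" (", nrow(x$qc$rejected), " rejected by QC)"),
      "\n", sep = "")
  cat("  sectors analyzed:", n_sect, "\n")
  cat("  true mismatches: ", nrow(x$records),
      sprintf(" (%.1f%% of sectors)", 100 * nrow(x$records) / n_sect), "\n", sep = "")
  tt <- table(factor(x$records$type, levels = .MM_TYPES))
  cat("    high BMO-MRW / low RNFL: ", tt[["HIGH_MRW_LOW_RNFL"]], "\n",
      "    high RNFL / low BMO-MRW: ", tt[["HIGH_RNFL_LOW_MRW"]], "\n", sep = "")
  invisible(x)
}

#' @export
summary.mismatch_screen <- function(object, ...) {
  prev <- build_prevalence(object$records, object$n_eyes, object$grid)
  co <- cooccurrence(object$records)
  out <- list(screen = object, prevalence = prev, cooccurrence = co,
              group_totals = colSums(object$group_counts))
  class(out) <- "summary.mismatch_screen"
  out
}

#' @export
print.summary.mismatch_screen <- function(x, ...) {
  print(x$screen)
  cat("  stage-1 groups (cohort totals):\n")
  print(x$group_totals)
  pk_a <- peak_angles(x$prevalence, "HIGH_MRW_LOW_RNFL")
  pk_b <- peak_angles(x$prevalence, "HIGH_RNFL_LOW_MRW")
  if (nrow(pk_a))
    cat(sprintf("  peak high-MRW/low-RNFL at %s deg (%.0f%% of type)\n",
                paste(pk_a$angle_deg, collapse = ", "), 100 * pk_a$frac_of_type[1]))
  if (nrow(pk_b))
    cat(sprintf("  peak high-RNFL/low-MRW at %s deg (%.0f%% of type)\n",
                paste(pk_b$angle_deg, collapse = ", "), 100 * pk_b$frac_of_type[1]))
  cat(sprintf("  eyes with both mismatch types: %d (%d sectors, %.0f%% of mismatches)\n",
              x$cooccurrence$n_dual_eyes, x$cooccurrence$n_sectors_dual_eyes,
              100 * x$cooccurrence$share_of_mismatch_sectors))
  if (is.finite(x$cooccurrence$min_separation_deg))
    cat("  minimum within-eye separation of opposite types:",
        x$cooccurrence$min_separation_deg, "deg\n")
  invisible(x)
}

#' @export
as.data.frame.mismatch_screen <- function(x, ...) x$records

#' @export
plot.mismatch_screen <- function(x, ...) {
  plot(build_prevalence(x$records, x$n_eyes, x$grid), ...)
}

#' Write mismatch records as delimited text
#'
#' Columns: `eye_id, angle_deg, type, rnfl_um, mrw_um, stage1_group,
#' rnfl_class, mrw_class`.
#'
#' @param x A `mismatch_screen` object or a records data frame.
#' @param path Output CSV path.
#' @export
write_records <- function(x, path) {
  rec <- if (inherits(x, "mismatch_screen")) x$records else x
  utils::write.csv(rec, path, row.names = FALSE)
  invisible(path)
}
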