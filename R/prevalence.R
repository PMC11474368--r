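#' @name prevalence
#' @title Cohort-level prevalence mapping of mismatch sectors
#'
#' @description
#' Aggregates mismatch records over a cohort into per-angle counts and
#' within-type fractions on the 37 analyzed sector angles, locates the peak
#' angles of each mismatch type, and summarizes within-eye co-occurrence of
#' the two types (circular separation between opposite-type sectors).
NULL

#' Circular distance between angles
#'
#' Shortest arc between two angles on the circle, in degrees.
#'
#' @param a,b Angles in degrees (vectorized).
#' @return Distance in `[0, 180]`.
#' @export
circular_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Build a per-angle prevalence map from mismatch records
#'
#' @param records Mismatch records data frame (as in
#'   `mismatch_screen$records`), or a `mismatch_screen` object.
#' @param n_eyes Number of eyes screened (denominator for total sectors).
#' @param grid A [sector_grid()].
#' @return An object of class `prevalence_map`: list with `table` (data
#'   frame `angle_deg`, `count_high_mrw_low_rnfl`, `count_high_rnfl_low_mrw`,
#'   `frac_high_mrw_low_rnfl`, `frac_high_rnfl_low_mrw`, rows in analysis
#'   wedge order), `totals` (per type), `grand_total`, `total_sectors`.
#' @export
build_prevalence <- function(records, n_eyes, grid = sector_grid()) {
  if (inherits(records, "mismatch_screen")) {
    if (missing(n_eyes)) n_eyes <- records$n_eyes
    records <- records$records
  }
  ang <- analysis_angles(grid)
  if (nrow(records) && !all(records$angle_deg %in% ang))
    stop("record angle off the analyzed sector grid")
  cnt <- function(type) {
    r <- records[records$type == type, , drop = FALSE]
    as.numeric(table(factor(r$angle_deg, levels = ang)))
  }
  ca <- cnt("HIGH_MRW_LOW_RNFL"); cb <- cnt("HIGH_RNFL_LOW_MRW")
  ta <- sum(ca); tb <- sum(cb)
  tab <- data.frame(
    angle_deg = ang,
    count_high_mrw_low_rnfl = ca,
    count_high_rnfl_low_mrw = cb,
    frac_high_mrw_low_rnfl = if (ta > 0) ca / ta else rep(0, length(ang)),
    frac_high_rnfl_low_mrw = if (tb > 0) cb / tb else rep(0, length(ang)))
  structure(list(table = tab,
                 totals = c(HIGH_MRW_LOW_RNFL = ta, HIGH_RNFL_LOW_MRW = tb),
                 grand_total = ta + tb,
                 total_sectors = n_eyes * length(ang),
                 n_eyes = n_eyes),
            class = "prevalence_map")
}

#' @export
print.prevalence_map <- function(x, ...) {
  cat("Mismatch prevalence over", x$n_eyes, "eyes,",
      x$total_sectors, "analyzed sectors\n")
  cat(sprintf("  true mismatches: %d (%.1f%% of total)\n", x$grand_total,
              100 * x$grand_total / max(x$total_sectors, 1)))
  cat(sprintf("  high BMO-MRW / low RNFL: %d (%.1f%%); high RNFL / low BMO-MRW: %d (%.1f%%)\n",
              x$totals[1], 100 * x$totals[1] / max(x$total_sectors, 1),
              x$totals[2], 100 * x$totals[2] / max(x$total_sectors, 1)))
  invisible(x)
}

#' Peak angles of a mismatch type
#'
#' Angles achieving the maximal within-type fraction; ties are returned in
#' ascending TSNIT wedge order.
#'
#' @param map A [build_prevalence()] result.
#' @param type `"HIGH_MRW_LOW_RNFL"` or `"HIGH_RNFL_LOW_MRW"`.
#' @return Data frame `angle_deg`, `frac_of_type` (empty if the type has no
#'   records).
#' @export
peak_angles <- function(map, type = .MM_TYPES) {
  type <- match.arg(type)
  if (map$totals[[type]] == 0)
    return(data.frame(angle_deg = numeric(), frac_of_type = numeric()))
  f <- switch(type,
              HIGH_MRW_LOW_RNFL = map$table$frac_high_mrw_low_rnfl,
              HIGH_RNFL_LOW_MRW = map$table$frac_high_rnfl_low_mrw)
  i <- which(f == max(f))
  data.frame(angle_deg = map$table$angle_deg[i], frac_of_type = f[i])
}

#' Within-eye co-occurrence of the two mismatch types
#'
#' @param records Mismatch records data frame or `mismatch_screen` object.
#' @return A list of class `cooccurrence_summary`: `n_dual_eyes` (eyes with
#'   both types), `n_sectors_dual_eyes` (mismatch sectors in such eyes),
#'   `share_of_mismatch_sectors`, `min_separation_deg` (smallest circular
#'   separation between opposite-type sectors in any eye; `Inf` if none)
#'   and `per_eye` (data frame `eye_id`, `min_separation_deg`).
#' @export
cooccurrence <- function(records) {
  if (inherits(records, "mismatch_screen")) records <- records$records
  per <- list()
  for (id in unique(records$eye_id)) {
    r <- records[records$eye_id == id, , drop = FALSE]
    a <- r$angle_deg[r$type == "HIGH_MRW_LOW_RNFL"]
    b <- r$angle_deg[r$type == "HIGH_RNFL_LOW_MRW"]
    if (length(a) && length(b)) {
      d <- outer(a, b, circular_distance)
      per[[id]] <- data.frame(eye_id = id, n_sectors = nrow(r),
                              min_separation_deg = min(d))
    }
  }
  per <- do.call(rbind, c(list(data.frame(eye_id = character(),
                                          n_sectors = integer(),
                                          min_separation_deg = numeric())),
                          per))
  n_dual_sect <- sum(per$n_sectors)
  structure(list(
    n_dual_eyes = nrow(per),
    n_sectors_dual_eyes = n_dual_sect,
    share_of_mismatch_sectors =
      if (nrow(records)) n_dual_sect / nrow(records) else 0,
    min_separation_deg = if (nrow(per)) min(per$min_separation_deg) else Inf,
    per_eye = per[c("eye_id", "min_separation_deg")]),
    class = "cooccurrence_summary")
}

#' @export
print.cooccurrence_summary <- function(x, ...) {
  cat("Eyes with both mismatch types:", x$n_dual_eyes,
      "(", x$n_sectors_dual_eyes, "sectors,",
      sprintf("%.0f%%", 100 * x$share_of_mismatch_sectors), "of mismatches)\n")
  if (is.finite(x$min_separation_deg))
    cat("Minimum within-eye circular separation:", x$min_separation_deg, "deg\n")
  invisible(x)
}

#' Polar plot of a prevalence map
#'
#' Base-graphics polar chart of per-angle mismatch counts over the analysis
#' wedge, in right-eye format (temporal to the right, superior up).
#'
#' @param x A `prevalence_map`.
#' @param type Mismatch type to draw, or `"both"`.
#' @param ... Passed to [graphics::segments()].
#' @export
plot.prevalence_map <- function(x, type = c("both", .MM_TYPES), ...) {
  type <- match.arg(type)
  tab <- x$table
  mx <- max(tab$count_high_mrw_low_rnfl, tab$count_high_rnfl_low_mrw, 1)
  graphics::plot(NA, xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Mismatch prevalence (right-eye format)")
  th <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(cos(th), sin(th), col = "grey70")
  graphics::text(c(1.1, 0, -1.1, 0), c(0, 1.1, 0, -1.1),
                 c("T", "S", "N", "I"), cex = 0.8)
  draw <- function(counts, col) {
    r <- counts / mx
    a <- tab$angle_deg * pi / 180
    graphics::segments(0, 0, r * cos(a), r * sin(a), col = col, lwd = 3, ...)
  }
  if (type != "HIGH_RNFL_LOW_MRW") draw(tab$count_high_mrw_low_rnfl, "#d95f02")
  if (type != "HIGH_MRW_LOW_RNFL") draw(tab$count_high_rnfl_low_mrw, "#1b9e77")
  graphics::legend("topleft", bty = "n", cex = 0.8, lwd = 3,
                   col = c("#d95f02", "#1b9e77"),
                   legend = c("high MRW / low RNFL", "high RNFL / low MRW"))
  invisible(x)
}

#' Write a prevalence table as delimited text
#'
#' @param map A `prevalence_map`.
#' @param path Output CSV path.
#' @export
write_prevalence <- function(map, path) {
  utils::write.csv(map$table, path, row.names = FALSE)
  invisible(path)
}
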