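#' @name normative
#' @title Angle-dependent normative percentile bands
#'
#' @description
#' Circumpapillary thickness displays classify each sector against a
#' normative database: below the 1st percentile renders red on the TSNIT
#' curve, between the 1st and 5th percentile yellow, above the 5th green.
#' The device's database is proprietary, so this module ships a parametric
#' stand-in -- a harmonic TSNIT mean curve with Gaussian dispersion and a
#' linear age slope -- and also loads user-supplied per-angle threshold
#' tables.  The double-hump RNFL shape (peaks at the superior and inferior
#' poles, troughs temporally and nasally) makes the percentile cutoffs
#' strongly angle-dependent: a value that is red at a superotemporal cut can
#' be green at a temporal cut.
NULL

.PCLASS <- c("RED", "YELLOW", "GREEN")

#' Configuration for the parametric normative band generator
#'
#' @param parameter `"RNFL"` or `"BMO_MRW"`.
#' @param mean_level Mean thickness level of the TSNIT curve (µm).
#' @param harmonics Data frame with columns `order`, `amplitude` (µm) and
#'   `phase_deg`; the mean curve is
#'   `mean_level + sum(amplitude * cos(order * (theta - phase_deg)))`.
#'   The defaults place the double hump at the vertical poles.
#' @param dispersion_sd Gaussian dispersion of the healthy population (µm).
#' @param reference_age Age (years) at which the thresholds are tabulated.
#' @param age_slope Threshold change per year of age (µm/yr, must be <= 0).
#' @param floor_um Positive floor thresholds are clamped at (µm).
#' @return A list of class `band_config`.
#' @export
band_config <- function(parameter = c("RNFL", "BMO_MRW"),
                        mean_level = NULL, harmonics = NULL,
                        dispersion_sd = NULL, reference_age = 50,
                        age_slope = NULL, floor_um = 5) {
  parameter <- match.arg(parameter)
  if (parameter == "RNFL") {
    if (is.null(mean_level)) mean_level <- 100
    if (is.null(harmonics))
      harmonics <- data.frame(order = 2, amplitude = 30, phase_deg = 90)
    if (is.null(dispersion_sd)) dispersion_sd <- 15
    if (is.null(age_slope)) age_slope <- -0.2
  } else {
    if (is.null(mean_level)) mean_level <- 330
    if (is.null(harmonics))
      harmonics <- data.frame(order = 2, amplitude = 35, phase_deg = 90)
    if (is.null(dispersion_sd)) dispersion_sd <- 50
    if (is.null(age_slope)) age_slope <- -1.0
  }
  if (age_slope > 0) stop("age_slope must be <= 0 (thickness declines with age)")
  if (dispersion_sd < 0) stop("dispersion_sd must be non-negative")
  structure(list(parameter = parameter, mean_level = mean_level,
                 harmonics = harmonics, dispersion_sd = dispersion_sd,
                 reference_age = reference_age, age_slope = age_slope,
                 floor_um = floor_um),
            class = "band_config")
}

#' Normative mean thickness at given angles
#'
#' @param angle_deg Angles in degrees (vectorized).
#' @param config A [band_config()].
#' @param age Optional age in years; if supplied the linear age adjustment
#'   `age_slope * (age - reference_age)` is applied.
#' @return Mean thickness in µm.
#' @export
normative_mean <- function(angle_deg, config, age = NULL) {
  h <- config$harmonics
  m <- rep(config$mean_level, length(angle_deg))
  for (j in seq_len(nrow(h)))
    m <- m + h$amplitude[j] *
      cos(h$order[j] * (angle_deg - h$phase_deg[j]) * pi / 180)
  if (!is.null(age)) m <- m + config$age_slope * (age - config$reference_age)
  m
}

#' Build normative percentile bands from a parametric configuration
#'
#' Thresholds are `mean + z * dispersion_sd` with `z` the 1st / 5th
#' standard-normal quantile, tabulated at the 48 sector angles at the
#' reference age and clamped at a positive floor.
#'
#' @param parameter `"RNFL"` or `"BMO_MRW"` (ignored when `config` given).
#' @param config A [band_config()]; defaults are built from `parameter`.
#' @param grid A [sector_grid()].
#' @return An object of class `normative_bands`: list with `parameter`,
#'   `angle_deg`, `p1_um`, `p5_um`, `reference_age`, `age_slope`,
#'   `provenance`.
#' @examples
#' b <- build_default_bands("RNFL")
#' range(b$p5_um - b$p1_um)
#' @export
build_default_bands <- function(parameter = c("RNFL", "BMO_MRW"),
                                config = NULL, grid = sector_grid()) {
  if (is.null(config)) config <- band_config(match.arg(parameter))
  ang <- grid$sector_angles
  m <- normative_mean(ang, config)
  p1 <- pmax(m + stats::qnorm(0.01) * config$dispersion_sd, config$floor_um)
  p5 <- pmax(m + stats::qnorm(0.05) * config$dispersion_sd, config$floor_um)
  b <- normative_bands(config$parameter, ang, p1, p5,
                       reference_age = config$reference_age,
                       age_slope = config$age_slope,
                       provenance = "parametric harmonic model")
  b
}

#' Construct a normative band table
#'
#' @param parameter `"RNFL"` or `"BMO_MRW"`.
#' @param angle_deg Sector angles in degrees (all 48 required).
#' @param p1_um,p5_um Per-angle 1st and 5th percentile thresholds (µm).
#' @param reference_age Age the thresholds refer to (years).
#' @param age_slope Linear age adjustment (µm/yr, <= 0).
#' @param provenance Free-text origin of the thresholds.
#' @return An object of class `normative_bands`.
#' @export
normative_bands <- function(parameter, angle_deg, p1_um, p5_um,
                            reference_age = 50, age_slope = 0,
                            provenance = "user-supplied") {
  if (length(angle_deg) != 48L)
    stop("bands must be defined for all 48 sector angles")
  if (length(p1_um) != 48L || length(p5_um) != 48L)
    stop("p1_um and p5_um must each have 48 values")
  if (any(!is.finite(p1_um)) || any(!is.finite(p5_um)))
    stop("thresholds must be finite")
  if (any(p1_um <= 0))
    stop("p1 thresholds must be positive")
  if (any(p1_um >= p5_um))
    stop("non-monotone percentile thresholds: p1 must be < p5 at every angle")
  if (age_slope > 0) stop("age_slope must be <= 0")
  o <- order(angle_deg)
  structure(list(parameter = parameter,
                 angle_deg = angle_deg[o],
                 p1_um = p1_um[o], p5_um = p5_um[o],
                 reference_age = reference_age, age_slope = age_slope,
                 provenance = provenance),
            class = "normative_bands")
}

#' @export
print.normative_bands <- function(x, ...) {
  cat("Normative bands (", x$parameter, "), ", length(x$angle_deg),
      " angles; p1 ", round(min(x$p1_um), 1), "-", round(max(x$p1_um), 1),
      " um, p5 ", round(min(x$p5_um), 1), "-", round(max(x$p5_um), 1),
      " um; reference age ", x$reference_age, ", slope ", x$age_slope,
      " um/yr [", x$provenance, "]\n", sep = "")
  invisible(x)
}

.band_row <- function(bands, angle_deg) {
  i <- match(TRUE, abs(bands$angle_deg - (angle_deg %% 360)) < 1e-6)
  if (is.na(i))
    stop("angle ", angle_deg, " is not on the 7.5-degree sector grid")
  i
}

#' Classify a sector value into the TSNIT percentile class
#'
#' RED if the value is below the (age-adjusted) 1st percentile, YELLOW if at
#' or above the 1st but below the 5th, GREEN at or above the 5th.  A value
#' exactly at p1 is YELLOW: red is strictly "less than first percentile".
#'
#' @param value Thickness in µm (vectorized; finite, >= 0).
#' @param angle_deg Sector angle(s) in degrees, on the 7.5-degree grid.
#' @param bands A [normative_bands()] object.
#' @param age Age in years; defaults to the bands' reference age.
#' @return Character vector in `c("RED","YELLOW","GREEN")`.
#' @examples
#' b <- build_default_bands("RNFL")
#' classify(70, 75, b)   # red at a superotemporal cut
#' classify(70, 0, b)    # green at the temporal cut
#' @export
classify <- function(value, angle_deg, bands, age = bands$reference_age) {
  if (any(!is.finite(value)) || any(value < 0))
    stop("values must be finite and non-negative")
  n <- max(length(value), length(angle_deg))
  value <- rep_len(value, n); angle_deg <- rep_len(angle_deg, n)
  adj <- bands$age_slope * (age - bands$reference_age)
  i <- vapply(angle_deg, function(a) .band_row(bands, a), integer(1))
  p1 <- bands$p1_um[i] + adj
  p5 <- bands$p5_um[i] + adj
  ifelse(value < p1, "RED", ifelse(value < p5, "YELLOW", "GREEN"))
}

#' Read / write a normative band table
#'
#' Delimited-text contract: comma-separated, header row, columns
#' `angle_deg`, `p1_um`, `p5_um`.
#'
#' @param path File path.
#' @param parameter,reference_age,age_slope Metadata for the loaded bands
#'   (not stored in the table itself).
#' @return `read_bands` returns a [normative_bands()] object; `write_bands`
#'   returns `path` invisibly.
#' @export
read_bands <- function(path, parameter = "RNFL", reference_age = 50,
                       age_slope = 0) {
  d <- utils::read.csv(path)
  need <- c("angle_deg", "p1_um", "p5_um")
  if (!all(need %in% names(d)))
    stop("band table must have columns angle_deg, p1_um, p5_um")
  normative_bands(parameter, d$angle_deg, d$p1_um, d$p5_um,
                  reference_age = reference_age, age_slope = age_slope,
                  provenance = paste("file:", basename(path)))
}

#' @rdname read_bands
#' @param bands A [normative_bands()] object to write.
#' @export
write_bands <- function(bands, path) {
  utils::write.csv(
    data.frame(angle_deg = bands$angle_deg,
               p1_um = bands$p1_um, p5_um = bands$p5_um),
    path, row.names = FALSE)
  invisible(path)
}
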