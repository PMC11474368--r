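#' Angular sector grid for the optic nerve head scan pattern
#'
#' The ONH volume scan acquires 24 radial B-scans centered on the Bruch's
#' membrane opening (BMO) centroid, yielding 48 BMO-MRW measurements at 7.5
#' degree increments, and a 768 A-scan circle for the circumpapillary RNFL
#' profile.  Angles follow the TSNIT convention in right-eye format:
#' 0 = temporal, 90 = superior, 180 = nasal, 270 = inferior.  The nasal
#' wedge (142.5--217.5 degrees) is excluded from mismatch analysis, leaving
#' 37 analyzed sectors spanning 225 degrees through temporal to 135 degrees.
#'
#' @param n_radial_cuts Number of radial B-scans (default 24).
#' @param excluded_wedge Length-2 numeric, inclusive angular range (degrees)
#'   of sectors excluded from analysis. Default `c(142.5, 217.5)`, the nasal
#'   90 degrees plus its flanking sectors.
#' @return An object of class `sector_grid`: a list with `n_radial_cuts`,
#'   `n_sectors`, `sector_spacing`, `sector_angles` (degrees) and
#'   `analysis_mask` (logical, TRUE for analyzed sectors).
#' @examples
#' g <- sector_grid()
#' sum(g$analysis_mask)  # 37
#' @export
sector_grid <- function(n_radial_cuts = 24L,
                        excluded_wedge = c(142.5, 217.5)) {
  n_radial_cuts <- as.integer(n_radial_cuts)
  if (n_radial_cuts < 1L) stop("n_radial_cuts must be positive")
  n_sectors <- 2L * n_radial_cuts
  spacing <- 360 / n_sectors
  angles <- (seq_len(n_sectors) - 1L) * spacing
  mask <- !(angles >= excluded_wedge[1] & angles <= excluded_wedge[2])
  structure(
    list(n_radial_cuts = n_radial_cuts,
         n_sectors = n_sectors,
         sector_spacing = spacing,
         sector_angles = angles,
         analysis_mask = mask),
    class = "sector_grid")
}

#' @export
print.sector_grid <- function(x, ...) {
  cat("Sector grid:", x$n_radial_cuts, "radial cuts ->", x$n_sectors,
      "sectors every", x$sector_spacing, "deg;",
      sum(x$analysis_mask), "analyzed (nasal wedge excluded)\n")
  invisible(x)
}

N_ASCANS <- 768L

#' Angle of an A-scan on the measurement circle
#'
#' The 12-degree circumpapillary measurement circle consists of 768 A-scans;
#' A-scan 0 is anchored at the temporal position (0 degrees) and angles
#' increase in TSNIT order.
#'
#' @param index Integer A-scan index (0 to 767), vectorized.
#' @return Angle in degrees, in `[0, 360)`.
#' @examples
#' ascan_angle(16)  # 7.5
#' @export
ascan_angle <- function(index) {
  if (any(index != floor(index)) || any(index < 0L) || any(index > N_ASCANS - 1L))
    stop("A-scan index must be an integer in 0..767")
  index * (360 / N_ASCANS)
}

#' A-scan indices mapped to one BMO-MRW sector
#'
#' Each of the 48 sectors averages 16 contiguous A-scans centered on the
#' radial-cut angle `7.5 * k`: the A-scans whose angles lie in the half-open
#' window `[7.5 k - 3.75, 7.5 k + 3.75)`, i.e. indices `(16k - 8) ...
#' (16k + 7)` modulo 768.  Over all 48 sectors this partitions the 768
#' A-scans exactly.
#'
#' @param sector_k Sector index, 0 to 47 (scalar).
#' @return Integer vector of 16 A-scan indices (0-based).
#' @examples
#' sector_ascan_indices(0)  # 760..767, 0..7
#' @export
sector_ascan_indices <- function(sector_k) {
  if (length(sector_k) != 1L || sector_k != floor(sector_k) ||
      sector_k < 0L || sector_k > 47L)
    stop("sector index must be a single integer in 0..47")
  as.integer((16L * sector_k - 8L):(16L * sector_k + 7L) %% N_ASCANS)
}

# 768 x 1 profile -> 48 x 16 index matrix (1-based), column k+1 = sector k
.sector_index_matrix <- function() {
  vapply(0:47, function(k) sector_ascan_indices(k) + 1L, integer(16))
}

#' Average a 768-point RNFL profile into 48 sector means
#'
#' Reduces the circumpapillary RNFL thickness profile to the resolution of
#' the 48 radial BMO-MRW sectors: sector k is the arithmetic mean of its 16
#' mapped A-scans.  Missing A-scans (`NA`) are not imputed; any sector
#' containing one is returned `NA` and its missing count recorded, so that
#' quality control rather than silent fill decides its fate.
#'
#' @param profile Numeric vector of 768 RNFL thicknesses in micrometers;
#'   `NA` marks missing A-scans, all finite values must be non-negative.
#' @return Numeric vector of 48 sector means (µm) with attribute
#'   `n_missing`, the per-sector count of missing A-scans.
#' @examples
#' x <- rep(100, 768)
#' unique(sectorize_rnfl(x))  # 100
#' @export
sectorize_rnfl <- function(profile) {
  if (length(profile) != N_ASCANS)
    stop("RNFL profile must have exactly 768 values, got ", length(profile))
  if (any(profile < 0, na.rm = TRUE) || any(is.infinite(profile)))
    stop("RNFL profile values must be finite and non-negative (NA = missing)")
  idx <- .sector_index_matrix()
  m <- matrix(profile[idx], nrow = 16L)
  out <- colMeans(m)                     # NA propagates per sector
  structure(out, n_missing = colSums(is.na(m)))
}

#' Ordered angles of the 37 analyzed sectors
#'
#' The analysis wedge runs from 225 degrees through the temporal position
#' (0 degrees) to 135 degrees, both endpoints inclusive: the temporal 180
#' degrees plus the superonasal and inferonasal 45 degrees.  The nasal 90
#' degrees is excluded because BMO-MRW measurements there are noisy and less
#' clinically relevant.
#'
#' @param grid A [sector_grid()].
#' @return Numeric vector of 37 angles in TSNIT wedge order:
#'   225, 232.5, ..., 352.5, 0, 7.5, ..., 135.
#' @export
analysis_angles <- function(grid = sector_grid()) {
  ang <- grid$sector_angles[grid$analysis_mask]
  # order around the circle starting at the inferonasal end of the wedge
  start <- 225
  key <- (ang - start) %% 360
  ang[order(key)]
}

#' Normalize laterality to TSNIT right-eye format
#'
#' All analyses are carried out in right-eye format (temporal = 0 degrees).
#' Device-native TSNIT exports are already laterality-normalized, so the
#' `"tsnit"` convention is an identity for both eyes.  Data recorded in
#' absolute screen orientation (`"absolute-clockwise"`) have left eyes
#' mirrored about the vertical axis so that temporal maps to 0 degrees and
#' superior stays superior.
#'
#' @param x Numeric vector: either angles in degrees, or a thickness profile
#'   of length 768 (A-scan resolution) or 48 (sector resolution) when
#'   `what = "profile"`.
#' @param laterality `"right"` or `"left"` (`"OD"`/`"OS"` accepted).
#' @param input_convention `"tsnit"` (default, identity) or
#'   `"absolute-clockwise"`.
#' @param what `"angles"` or `"profile"`.
#' @return `x` in TSNIT right-eye format.
#' @export
normalize_laterality <- function(x, laterality,
                                 input_convention = c("tsnit", "absolute-clockwise"),
                                 what = c("angles", "profile")) {
  input_convention <- match.arg(input_convention)
  what <- match.arg(what)
  lat <- switch(tolower(laterality),
                "right" = , "od" = "right",
                "left" = , "os" = "left",
                stop("laterality must be 'right'/'OD' or 'left'/'OS'"))
  if (input_convention == "tsnit" || lat == "right") return(x)
  # mirror about the vertical axis: angle -> (180 - angle) mod 360
  if (what == "angles") return((180 - x) %% 360)
  n <- length(x)
  if (!n %in% c(48L, N_ASCANS))
    stop("profile length must be 768 (A-scans) or 48 (sectors)")
  i <- seq_len(n) - 1L
  x[((n / 2L - i) %% n) + 1L]
}
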