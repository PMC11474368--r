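#' @name attribution
#' @title Cause attribution of mismatch sectors
#'
#' @description
#' The anatomical cause of each mismatch sector (large or small blood
#' vessel, focal retinoschisis, inclusion of outer retinal layers) is
#' determined by review of the raw cross-sectional OCT images -- a manual
#' step outside this package.  This module is the bookkeeping around that
#' review: it joins an annotation table onto mismatch records and
#' cross-tabulates mismatch type by cause, in both a detailed five-cause
#' view and the folded three-column view (large vessels / small vessels /
#' other) in which retinoschisis and outer-retina inclusion count as
#' "other".
NULL

.CAUSES <- c("LARGE_VESSEL", "SMALL_VESSEL", "RETINOSCHISIS",
             "OUTER_RETINA_INCLUSION", "OTHER")
.FOLDED <- c("LARGE_VESSEL", "SMALL_VESSEL", "OTHER")

#' Construct a cause-annotation table
#'
#' @param eye_id,angle_deg,cause Equal-length vectors; `cause` must be one
#'   of `"LARGE_VESSEL"`, `"SMALL_VESSEL"`, `"RETINOSCHISIS"`,
#'   `"OUTER_RETINA_INCLUSION"`, `"OTHER"`.  At most one cause per
#'   (eye, angle).
#' @return A data frame of class `cause_annotations`.
#' @export
cause_annotations <- function(eye_id, angle_deg, cause) {
  stopifnot(length(eye_id) == length(angle_deg),
            length(eye_id) == length(cause))
  if (!all(cause %in% .CAUSES))
    stop("unknown cause; allowed: ", paste(.CAUSES, collapse = ", "))
  key <- paste(eye_id, angle_deg)
  if (anyDuplicated(key))
    stop("at most one cause per (eye, angle)")
  structure(data.frame(eye_id = as.character(eye_id),
                       angle_deg = as.numeric(angle_deg),
                       cause = as.character(cause),
                       stringsAsFactors = FALSE),
            class = c("cause_annotations", "data.frame"))
}

#' Cross-tabulate mismatch records by annotated cause
#'
#' Records without an annotation fall into `OTHER` with a warning;
#' annotations that match no record are ignored with a warning.
#'
#' @param records Mismatch records data frame or `mismatch_screen` object.
#' @param annotations A [cause_annotations()] table (or data frame with
#'   columns `eye_id`, `angle_deg`, `cause`).
#' @return An object of class `attribution_table`: list with `detailed`
#'   (counts, mismatch type x five causes), `folded` (three columns, with
#'   retinoschisis and outer-retina inclusion folded into OTHER),
#'   `row_totals`, and `pct` (folded percentages of row totals, one
#'   decimal).
#' @examples
#' rec <- data.frame(eye_id = "e1", angle_deg = c(45, 75),
#'                   type = c("HIGH_MRW_LOW_RNFL", "HIGH_RNFL_LOW_MRW"),
#'                   stringsAsFactors = FALSE)
#' ann <- cause_annotations("e1", c(45, 75), c("SMALL_VESSEL", "LARGE_VESSEL"))
#' attribute_causes(rec, ann)
#' @export
attribute_causes <- function(records, annotations) {
  if (inherits(records, "mismatch_screen")) records <- records$records
  rkey <- paste(records$eye_id, records$angle_deg)
  akey <- paste(annotations$eye_id, annotations$angle_deg)
  orphan <- !(akey %in% rkey)
  if (any(orphan))
    warning(sum(orphan), " annotation(s) reference no mismatch record; ignored")
  cause <- annotations$cause[match(rkey, akey)]
  if (anyNA(cause)) {
    warning(sum(is.na(cause)),
            " unannotated mismatch record(s) attributed to OTHER")
    cause[is.na(cause)] <- "OTHER"
  }
  detailed <- table(factor(records$type, levels = .MM_TYPES),
                    factor(cause, levels = .CAUSES))
  folded <- cbind(detailed[, c("LARGE_VESSEL", "SMALL_VESSEL"), drop = FALSE],
                  OTHER = rowSums(detailed[, c("RETINOSCHISIS",
                                               "OUTER_RETINA_INCLUSION",
                                               "OTHER"), drop = FALSE]))
  rt <- rowSums(folded)
  pct <- round(100 * sweep(folded, 1, pmax(rt, 1), "/"), 1)
  structure(list(detailed = unclass(detailed), folded = folded,
                 row_totals = rt, pct = pct),
            class = "attribution_table")
}

#' Shares within the folded "Other" column
#'
#' Breakdown of the non-vessel causes of one mismatch type, as percentages
#' of that type's folded OTHER count (one decimal).
#'
#' @param x An [attribute_causes()] result.
#' @param type Mismatch type.
#' @return Named numeric: percentage of the OTHER column attributed to
#'   retinoschisis, outer-retina inclusion, and unexplained.
#' @export
other_breakdown <- function(x, type = .MM_TYPES) {
  type <- match.arg(type)
  oth <- x$folded[type, "OTHER"]
  d <- x$detailed[type, c("RETINOSCHISIS", "OUTER_RETINA_INCLUSION", "OTHER")]
  names(d)[3] <- "UNEXPLAINED"
  round(100 * d / max(oth, 1), 1)
}

#' @export
print.attribution_table <- function(x, ...) {
  cat("Mismatch cause attribution (row % in parentheses)\n")
  lab <- c(HIGH_MRW_LOW_RNFL = "High BMO-MRW, low RNFL",
           HIGH_RNFL_LOW_MRW = "High RNFL, low BMO-MRW")
  hdr <- sprintf("%-24s %18s %18s %18s %8s", "",
                 "Large vessels", "Small vessels", "Other", "Total")
  cat(hdr, "\n")
  for (ty in rownames(x$folded)) {
    cells <- sprintf("%6d (%5.1f%%)", x$folded[ty, ], x$pct[ty, ])
    cat(sprintf("%-24s %18s %18s %18s %8d\n", lab[[ty]],
                cells[1], cells[2], cells[3], x$row_totals[[ty]]))
  }
  invisible(x)
}

#' Write an attribution table as delimited text
#'
#' @param x An `attribution_table`.
#' @param path Output CSV path.
#' @param view `"folded"` (three causes) or `"detailed"` (five causes).
#' @export
write_attribution <- function(x, path, view = c("folded", "detailed")) {
  view <- match.arg(view)
  tab <- x[[view]]
  d <- data.frame(type = rownames(tab), tab, total = rowSums(tab),
                  row.names = NULL, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a cause-annotation table from delimited text
#'
#' Columns: `eye_id, angle_deg, cause`.
#'
#' @param path CSV path.
#' @return A [cause_annotations()] table.
#' @export
read_annotations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "angle_deg", "cause")
  if (!all(need %in% names(d)))
    stop("annotation table must have columns eye_id, angle_deg, cause")
  cause_annotations(d$eye_id, d$angle_deg, d$cause)
}

#' Write a cause-annotation table
#'
#' @param annotations A [cause_annotations()] table.
#' @param path CSV path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(as.data.frame(annotations)[c("eye_id", "angle_deg", "cause")],
                   path, row.names = FALSE)
  invisible(path)
}
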