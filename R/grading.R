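# Severity grading (0-3), region assignment (8 labels) and the 18-member
# combined category lattice.

#' Grading thresholds
#'
#' @param near_mm half-width of the "approaching the line" band: a posterior
#'   disc margin within `near_mm` mm anterior of the inter-facet line (without
#'   crossing it) is grade 1. Default 3 mm.
#' @param index_cut cut on the anteroposterior sagittal diameter index
#'   separating grade 2 from grade 3. Default 0.3.
#' @return object of class `ldh_thresholds`.
#' @export
grading_thresholds <- function(near_mm = 3, index_cut = 0.3) {
  stopifnot(near_mm > 0, index_cut > 0)
  structure(list(near_mm = near_mm, index_cut = index_cut),
            class = "ldh_thresholds")
}

#' Assign the severity grade from a herniation measurement
#'
#' Grade 0: posterior margin more than `near_mm` anterior of the inter-facet
#' line (`D < -near_mm`). Grade 1: within `near_mm` of the line without
#' crossing it (`-near_mm <= D <= 0`). Grade 2: beyond the line into the
#' ligamentum-flavum zone with index `I <= index_cut`. Grade 3: `I >
#' index_cut`. Boundary conventions are inclusive exactly as written: D =
#' -near_mm and D = 0 are grade 1; I = index_cut is grade 2.
#'
#' @param m an `ldh_measurement` (or any list with `D` and `I`).
#' @param thresholds an [grading_thresholds()] object.
#' @return integer grade 0-3.
#' @export
assign_grade <- function(m, thresholds = grading_thresholds()) {
  D <- m$D; I <- m$I
  if (D < -thresholds$near_mm) 0L
  else if (D <= 0) 1L
  else if (I <= thresholds$index_cut) 2L
  else 3L
}

.regions <- c("NONE", "LEFZ", "LFZ", "LSAZ", "CCZ", "RSAZ", "RFZ", "REFZ")
.zone_to_region <- c(EFZ_L = "LEFZ", FZ_L = "LFZ", SAZ_L = "LSAZ", CCZ = "CCZ",
                     SAZ_R = "RSAZ", FZ_R = "RFZ", EFZ_R = "REFZ")

#' Assign the anatomical region of a herniation
#'
#' Grade 0 maps to `NONE`; otherwise the zone of the apex's along-line
#' coordinate, prefixed with the patient side (L/R).
#'
#' @param m an `ldh_measurement`.
#' @param frame the `ldh_frame` used for the measurement.
#' @param grade grade from [assign_grade()].
#' @param orientation display orientation (defaults to the frame's).
#' @return one of `NONE, LEFZ, LFZ, LSAZ, CCZ, RSAZ, RFZ, REFZ`.
#' @export
assign_region <- function(m, frame, grade, orientation = frame$orientation) {
  if (grade == 0L) return("NONE")
  unname(.zone_to_region[[zone_of(frame, m$u_apex, orientation)]])
}

#' The 18-member (region, grade) category lattice
#'
#' A herniation category is a (region, grade) pair. Grade 0 exists only as
#' `NONE` (no herniation), the foraminal-zone regions carry only grade 1
#' (a protrusion reaching beyond the inter-facet line is by construction
#' medial to the foramen), and every other region carries grades 1-3:
#' 1 + 3 + 1 + 3 + 3 + 3 + 1 + 3 = 18 categories.
#'
#' @return data.frame with columns `code` (0-17), `region`, `grade`, in
#'   canonical code order NONE0, LEFZ1-3, LFZ1, LSAZ1-3, CCZ1-3, RSAZ1-3,
#'   RFZ1, REFZ1-3. Attributes `grades` (0-3) and `regions` (8 labels) carry
#'   the two marginal projections.
#' @export
enumerate_categories <- function() {
  grades_by_region <- list(NONE = 0L, LEFZ = 1:3, LFZ = 1L, LSAZ = 1:3,
                           CCZ = 1:3, RSAZ = 1:3, RFZ = 1L, REFZ = 1:3)
  df <- do.call(rbind, lapply(names(grades_by_region), function(r)
    data.frame(region = r, grade = grades_by_region[[r]],
               stringsAsFactors = FALSE)))
  df <- data.frame(code = seq_len(nrow(df)) - 1L, df, stringsAsFactors = FALSE)
  attr(df, "grades") <- 0:3
  attr(df, "regions") <- .regions
  df
}

#' Encode a (region, grade) pair as a canonical category
#'
#' Pairs outside the 18-member lattice (a foraminal region with grade > 1, or
#' a grade-0 pair other than `NONE`) are either clamped to the nearest valid
#' pair with `valid = FALSE` recorded and a warning, or rejected.
#'
#' @param region one of the 8 region labels.
#' @param grade integer 0-3.
#' @param policy `"clamp"` (default) or `"reject"`.
#' @return object of class `ldh_category`: `region`, `grade`, `code` (0-17),
#'   `valid`.
#' @export
encode_category <- function(region, grade, policy = c("clamp", "reject")) {
  policy <- match.arg(policy)
  region <- match.arg(region, .regions)
  grade <- as.integer(grade)
  stopifnot(grade %in% 0:3)
  lat <- enumerate_categories()
  valid <- TRUE
  if (region %in% c("LFZ", "RFZ") && grade > 1L) {
    if (policy == "reject")
      stop("no such classification exists: (", region, ", grade ", grade, ")")
    warning("clamping out-of-lattice pair (", region, ", grade ", grade,
            ") to grade 1")
    grade <- 1L; valid <- FALSE
  }
  if ((grade == 0L) != (region == "NONE")) {
    if (policy == "reject")
      stop("invalid pair: grade 0 exists only as region NONE (got ",
           region, ", grade ", grade, ")")
    warning("clamping inconsistent pair (", region, ", grade ", grade,
            ") to (NONE, 0)")
    region <- "NONE"; grade <- 0L; valid <- FALSE
  }
  code <- lat$code[lat$region == region & lat$grade == grade]
  structure(list(region = region, grade = grade, code = code, valid = valid),
            class = "ldh_category")
}

#' @export
print.ldh_category <- function(x, ...) {
  cat(sprintf("<ldh_category> %s grade %d (code %d%s)\n", x$region, x$grade,
              x$code, if (x$valid) "" else ", clamped"))
  invisible(x)
}

#' Category label string(s) from codes
#' @param code integer vector of codes 0-17.
#' @return character like `"CCZ:2"`.
#' @export
category_label <- function(code) {
  lat <- enumerate_categories()
  i <- match(code, lat$code)
  if (anyNA(i)) stop("unknown category code(s): ",
                     paste(code[is.na(i)], collapse = ", "))
  paste0(lat$region[i], ":", lat$grade[i])
}

#' Project category codes onto the grade or region margin
#' @param code integer vector of codes 0-17.
#' @param scheme `"grade4"` or `"region8"`.
#' @return integer grades or character regions.
#' @export
project_category <- function(code, scheme = c("grade4", "region8")) {
  scheme <- match.arg(scheme)
  lat <- enumerate_categories()
  i <- match(code, lat$code)
  if (anyNA(i)) stop("unknown category code(s)")
  if (scheme == "grade4") lat$grade[i] else lat$region[i]
}
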