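# Canal coordinate frame and geometric quantification.
#
# All geometry is done in millimetres: points are converted from px to mm
# before any distance is taken, so anisotropic spacing and the 3 mm grading
# threshold are handled uniformly.

#' Build the canal coordinate frame from the nine keypoints
#'
#' The inter-facet line is the straight chord through the two facet apices
#' (in mm). Its unit direction is chosen so that the along-line coordinate u
#' increases with image x; the unit normal points posteriorly (toward the
#' spinous point). Each of the six zone-boundary points is replaced by its
#' perpendicular foot on the line and expressed as a scalar u; the sagittal
#' diameter of the ligamentum-flavum zone, `L_sag`, is the perpendicular
#' distance from the spinous point to the line.
#'
#' @param kp an `ldh_keypoints` (px coordinates).
#' @param spacing `c(row_mm, col_mm)`.
#' @param orientation `"radiological"` (image right = patient left) or
#'   `"neurological"`; carried into zone naming.
#' @return object of class `ldh_frame` with fields `line_point`, `line_dir`,
#'   `n_post` (mm), `boundaries_u` (6 sorted mm scalars), `L_sag` (mm),
#'   `orientation`.
#' @export
build_frame <- function(kp, spacing, orientation = c("radiological", "neurological")) {
  orientation <- match.arg(orientation)
  fl <- px_to_mm(kp$facet_left, spacing)
  fr <- px_to_mm(kp$facet_right, spacing)
  sp <- px_to_mm(kp$spinous, spacing)
  d <- fl - fr
  len <- sqrt(sum(d^2))
  if (len < 1)
    stop("degenerate facet pair: apices ", format(len), " mm apart (< 1 mm)")
  dir <- d / len
  # orient u to increase with image x (ties: with image y)
  if (dir[1] < 0 || (abs(dir[1]) < 1e-12 && dir[2] < 0)) dir <- -dir
  origin <- (fl + fr) / 2
  n <- c(-dir[2], dir[1])
  l_sag <- sum((sp - origin) * n)
  if (l_sag < 0) { n <- -n; l_sag <- -l_sag }
  if (l_sag < 0.5)
    stop("geometric degeneracy: spinous point lies on the inter-facet line ",
         "(L_sag = ", format(l_sag), " mm < 0.5 mm)")
  bu <- sort(as.numeric(px_to_mm(kp$boundaries, spacing) %*% cbind(dir) -
                          sum(origin * dir)))
  if (any(diff(bu) <= 0))
    stop("zone boundary points project to coincident positions on the line")
  structure(list(line_point = origin, line_dir = dir, n_post = n,
                 boundaries_u = bu, L_sag = l_sag, orientation = orientation),
            class = "ldh_frame")
}

#' @export
print.ldh_frame <- function(x, ...) {
  cat(sprintf("<ldh_frame> L_sag %.2f mm, boundaries_u [%s] mm, %s\n",
              x$L_sag, paste(sprintf("%.1f", x$boundaries_u), collapse = ", "),
              x$orientation))
  invisible(x)
}

#' Signed perpendicular distance from the inter-facet line
#'
#' Positive posterior to the line (on the spinous side), negative anterior.
#'
#' @param frame an `ldh_frame`.
#' @param p point in mm, `c(x, y)` or n x 2 matrix.
#' @return mm scalar (or vector for a matrix of points).
#' @export
signed_distance <- function(frame, p) {
  if (is.matrix(p)) {
    as.numeric((p[, 1] - frame$line_point[1]) * frame$n_post[1] +
                 (p[, 2] - frame$line_point[2]) * frame$n_post[2])
  } else {
    sum((p - frame$line_point) * frame$n_post)
  }
}

#' Along-line coordinate u of a point (mm)
#'
#' u is measured along the inter-facet line from the facet midpoint,
#' increasing with image x.
#' @inheritParams signed_distance
#' @return mm scalar (or vector).
#' @export
u_of <- function(frame, p) {
  if (is.matrix(p)) {
    as.numeric((p[, 1] - frame$line_point[1]) * frame$line_dir[1] +
                 (p[, 2] - frame$line_point[2]) * frame$line_dir[2])
  } else {
    sum((p - frame$line_point) * frame$line_dir)
  }
}

#' Perpendicular foot of a point on the inter-facet line (mm)
#' @inheritParams signed_distance
#' @return point in mm.
#' @export
project_to_line <- function(frame, p) {
  u <- u_of(frame, p)
  if (is.matrix(p)) {
    cbind(frame$line_point[1] + u * frame$line_dir[1],
          frame$line_point[2] + u * frame$line_dir[2])
  } else {
    frame$line_point + u * frame$line_dir
  }
}

#' Measure the herniation of a disc mask against a canal frame
#'
#' The apex is the foreground pixel center with maximal signed posterior
#' distance D from the inter-facet line; ties on D are broken toward the
#' most central apex (smallest |u|), then the smallest u. The
#' anteroposterior sagittal diameter index is `I = max(D, 0) / L_sag`.
#'
#' @param frame an `ldh_frame`.
#' @param disc an `ldh_mask`.
#' @param spacing `c(row_mm, col_mm)` of the grid the mask lives on.
#' @return object of class `ldh_measurement`: `apex` (mm), `apex_px`,
#'   `D` (mm, signed), `I`, `u_apex` (mm).
#' @export
measure_herniation <- function(frame, disc, spacing) {
  idx <- which(disc$mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty disc mask")
  # pixel centers, 0-based px -> mm
  pmm <- cbind((idx[, 2] - 1) * spacing[2], (idx[, 1] - 1) * spacing[1])
  d <- signed_distance(frame, pmm)
  u <- u_of(frame, pmm)
  best <- order(-d, abs(u), u)[1]
  D <- d[best]
  structure(list(apex = unname(pmm[best, ]),
                 apex_px = unname(c(idx[best, 2] - 1, idx[best, 1] - 1)),
                 D = D, I = max(D, 0) / frame$L_sag, u_apex = u[best]),
            class = "ldh_measurement")
}

#' @export
print.ldh_measurement <- function(x, ...) {
  cat(sprintf("<ldh_measurement> D = %+.2f mm, I = %.3f, u_apex = %+.2f mm\n",
              x$D, x$I, x$u_apex))
  invisible(x)
}

.zones_lowu_first <- c("EFZ_R", "FZ_R", "SAZ_R", "CCZ", "SAZ_L", "FZ_L", "EFZ_L")

#' Anatomical zone of an along-line coordinate
#'
#' The six projected boundary scalars delimit seven half-open intervals
#' `[b_i, b_{i+1})`; the outermost zones are unbounded. Patient left/right is
#' resolved from the display orientation: radiological means larger u
#' (image right) is the patient's left.
#'
#' @param frame an `ldh_frame`.
#' @param u along-line coordinate(s), mm.
#' @param orientation override of the frame's orientation.
#' @return character zone name(s) in
#'   `{EFZ_R, FZ_R, SAZ_R, CCZ, SAZ_L, FZ_L, EFZ_L}` (patient sides).
#' @export
zone_of <- function(frame, u, orientation = frame$orientation) {
  idx <- findInterval(u, frame$boundaries_u) + 1L  # 1..7
  z <- .zones_lowu_first
  if (identical(orientation, "neurological")) z <- rev(z)
  z[idx]
}
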