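#' @keywords internal
"_PACKAGE"

# Shared coordinate conventions
# ------------------------------
# Pixel coordinates are 0-based, origin at the top-left pixel CENTER,
# x = column index (mediolateral), y = row index (anteroposterior,
# increasing posteriorly on an axial display). `spacing` is always
# c(row_mm, col_mm), so a pixel point p = c(x, y) maps to millimetres as
# c(x * spacing[2], y * spacing[1]).

#' Convert a pixel point (or matrix of points) to millimetres
#'
#' @param p numeric length-2 vector `c(x, y)` or an n x 2 matrix.
#' @param spacing numeric `c(row_mm, col_mm)` physical pixel size.
#' @return same shape as `p`, in mm.
#' @export
px_to_mm <- function(p, spacing) {
  stopifnot(length(spacing) == 2, all(is.finite(spacing)), all(spacing > 0))
  if (is.matrix(p)) {
    cbind(p[, 1] * spacing[2], p[, 2] * spacing[1])
  } else {
    c(p[1] * spacing[2], p[2] * spacing[1])
  }
}

#' @rdname px_to_mm
#' @export
mm_to_px <- function(p, spacing) {
  stopifnot(length(spacing) == 2, all(spacing > 0))
  if (is.matrix(p)) {
    cbind(p[, 1] / spacing[2], p[, 2] / spacing[1])
  } else {
    c(p[1] / spacing[2], p[2] / spacing[1])
  }
}

#' Image record: pixel grid plus physical spacing and provenance
#'
#' The unit every stage of the toolchain consumes. Pixels are stored as a
#' numeric matrix in row-major display order (rows = image rows, top first).
#'
#' @param pixels numeric matrix of intensities.
#' @param spacing numeric `c(row_mm, col_mm)`, strictly positive.
#' @param source_id opaque provenance string.
#' @param orientation `"radiological"` (image right = patient left, the
#'   default axial display convention) or `"neurological"`.
#' @return an object of class `ldh_image`.
#' @export
image_record <- function(pixels, spacing, source_id = "",
                         orientation = c("radiological", "neurological")) {
  orientation <- match.arg(orientation)
  if (!is.matrix(pixels) || any(dim(pixels) == 0L))
    stop("pixels must be a non-empty matrix")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2 || !all(is.finite(spacing)) || !all(spacing > 0))
    stop("spacing must be two strictly positive finite mm values (row_mm, col_mm)")
  structure(list(pixels = pixels, spacing = spacing,
                 source_id = as.character(source_id),
                 orientation = orientation),
            class = "ldh_image")
}

#' @export
print.ldh_image <- function(x, ...) {
  cat(sprintf("<ldh_image> %d x %d px, spacing (%.4g, %.4g) mm, %s, source '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing[1], x$spacing[2],
              x$orientation, x$source_id))
  invisible(x)
}

#' The nine named anatomical keypoints of an axial lumbar slice
#'
#' Two facet apices (the most anterior vertex of each articular process),
#' one point anterior to the spinous process inside the canal, and six
#' zone-boundary points (the internal edges separating EFZ|FZ, FZ|SAZ and
#' SAZ|CCZ on each side), ordered patient-right to patient-left (b1..b6).
#'
#' @param facet_left,facet_right,spinous length-2 pixel points `c(x, y)`.
#'   "left"/"right" are PATIENT sides.
#' @param boundaries 6 x 2 matrix of pixel points, rows b1..b6.
#' @param bounds optional `c(width, height)` in px; when given, all points
#'   are checked to lie inside the image.
#' @return object of class `ldh_keypoints`.
#' @export
keypoint_set <- function(facet_left, facet_right, spinous, boundaries,
                         bounds = NULL) {
  boundaries <- as.matrix(boundaries)
  if (nrow(boundaries) != 6L || ncol(boundaries) != 2L)
    stop("exactly 6 boundary points (6 x 2 matrix) are required")
  if (isTRUE(all.equal(as.numeric(facet_left), as.numeric(facet_right))))
    stop("facet_left and facet_right must be distinct points")
  rownames(boundaries) <- paste0("b", 1:6)
  kp <- structure(list(facet_left = as.numeric(facet_left),
                       facet_right = as.numeric(facet_right),
                       spinous = as.numeric(spinous),
                       boundaries = boundaries),
                  class = "ldh_keypoints")
  if (!is.null(bounds)) {
    m <- keypoint_matrix(kp)
    if (any(m[, 1] < 0 | m[, 1] > bounds[1] - 1 |
            m[, 2] < 0 | m[, 2] > bounds[2] - 1))
      stop("keypoints fall outside the image bounds")
  }
  kp
}

#' All nine keypoints as a 9 x 2 matrix with role rownames
#' @param kp an `ldh_keypoints` object.
#' @return 9 x 2 numeric matrix, rows facet_left, facet_right, spinous, b1..b6.
#' @export
keypoint_matrix <- function(kp) {
  m <- rbind(facet_left = kp$facet_left, facet_right = kp$facet_right,
             spinous = kp$spinous, kp$boundaries)
  rownames(m) <- c("facet_left", "facet_right", "spinous", paste0("b", 1:6))
  m
}

#' Rebuild a keypoint set from a 9 x 2 role-named matrix
#' @param m 9 x 2 matrix with rownames as in [keypoint_matrix()].
#' @return `ldh_keypoints`.
#' @export
keypoints_from_matrix <- function(m) {
  need <- c("facet_left", "facet_right", "spinous", paste0("b", 1:6))
  if (!all(need %in% rownames(m))) {
    miss <- setdiff(need, rownames(m))
    stop("missing keypoint role(s): ", paste(miss, collapse = ", "))
  }
  keypoint_set(m["facet_left", ], m["facet_right", ], m["spinous", ],
               m[paste0("b", 1:6), , drop = FALSE])
}

#' @export
print.ldh_keypoints <- function(x, ...) {
  cat("<ldh_keypoints> 9 points (px):\n")
  print(round(keypoint_matrix(x), 2))
  invisible(x)
}

#' Binary disc mask, optionally carrying the polygon it was rasterized from
#'
#' @param mask logical matrix congruent with its image.
#' @param polygon optional closed n x 2 vertex list in px (x, y).
#' @return object of class `ldh_mask`.
#' @export
disc_mask <- function(mask, polygon = NULL) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  mask <- mask > 0
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    stopifnot(ncol(polygon) == 2)
  }
  structure(list(mask = mask, polygon = polygon), class = "ldh_mask")
}

#' @export
print.ldh_mask <- function(x, ...) {
  cat(sprintf("<ldh_mask> %d x %d, %d foreground px%s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              if (is.null(x$polygon)) "" else sprintf(", polygon (%d vertices)", nrow(x$polygon))))
  invisible(x)
}

#' Coordinate transform between the original and canonical pixel frames
#'
#' A pure axis scaling: `x' = x * col_factor`, `y' = y * row_factor`. With the
#' spacing rescaled by the inverse factors, mm positions are preserved exactly.
#'
#' @param row_factor,col_factor new-size / old-size scale factors.
#' @return object of class `ldh_transform`.
#' @export
coord_transform <- function(row_factor, col_factor) {
  stopifnot(row_factor > 0, col_factor > 0)
  structure(list(scale = c(row_factor = row_factor, col_factor = col_factor)),
            class = "ldh_transform")
}

#' Apply (or invert) a coordinate transform to points
#' @param tr an `ldh_transform`.
#' @param p length-2 point or n x 2 matrix of px points (x, y).
#' @param inverse map canonical -> original instead.
#' @return transformed points, same shape as `p`.
#' @export
transform_point <- function(tr, p, inverse = FALSE) {
  s <- if (inverse) 1 / tr$scale else tr$scale
  if (is.matrix(p)) cbind(p[, 1] * s[["col_factor"]], p[, 2] * s[["row_factor"]])
  else c(p[1] * s[["col_factor"]], p[2] * s[["row_factor"]])
}

#' Apply a coordinate transform to an annotation object
#' @param tr an `ldh_transform`.
#' @param ann an `ldh_keypoints`, `ldh_mask`, or n x 2 point matrix.
#' @param new_dim target grid `c(nrow, ncol)` (needed for masks).
#' @return the transformed annotation.
#' @export
transform_annotation <- function(tr, ann, new_dim = NULL) {
  if (inherits(ann, "ldh_keypoints")) {
    keypoints_from_matrix(transform_point(tr, keypoint_matrix(ann)))
  } else if (inherits(ann, "ldh_mask")) {
    if (is.null(new_dim))
      new_dim <- round(dim(ann$mask) * tr$scale)
    if (!is.null(ann$polygon)) {
      poly <- transform_point(tr, ann$polygon)
      disc_mask(rasterize_polygon(poly, new_dim), polygon = poly)
    } else {
      img <- EBImage::Image(t(ann$mask * 1))
      res <- EBImage::resize(img, w = new_dim[2], h = new_dim[1], filter = "none")
      disc_mask(t(res@.Data) > 0.5)
    }
  } else if (is.matrix(ann)) {
    transform_point(tr, ann)
  } else stop("unsupported annotation type")
}
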