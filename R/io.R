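# Image and annotation I/O, plus canonicalization to the 512 x 512 working
# frame shared by every downstream stage.

#' Default label-name map from annotation files to keypoint roles
#'
#' File labels `facet_L`/`facet_R` refer to PATIENT left/right; `b1..b6` are
#' the zone-boundary points ordered patient-right to patient-left.
#' @return named character vector: file label -> role name.
#' @export
default_label_map <- function() {
  c(facet_L = "facet_left", facet_R = "facet_right", spinous = "spinous",
    b1 = "b1", b2 = "b2", b3 = "b3", b4 = "b4", b5 = "b5", b6 = "b6")
}

#' Read an image (PNG or single-frame DICOM) into an [image_record()]
#'
#' @param path file path; format chosen by extension (`.dcm`/`.dicom` vs
#'   `.png`), with a DICOM magic-number fallback.
#' @param spacing_override optional `c(row_mm, col_mm)`; required for PNG
#'   unless `default_spacing` is given, and overrides the DICOM PixelSpacing.
#' @param default_spacing config-level fallback spacing for PNGs.
#' @param orientation display convention of the source image.
#' @return an `ldh_image`. DICOM intensities are kept as stored; PNG
#'   intensities are the codec-normalized values in `[0, 1]`.
#' @export
read_image <- function(path, spacing_override = NULL, default_spacing = NULL,
                       orientation = "radiological") {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  is_dicom <- ext %in% c("dcm", "dicom")
  if (!is_dicom && !(ext %in% c("png"))) {
    hdr <- readBin(path, "raw", n = 132)
    is_dicom <- length(hdr) == 132 && rawToChar(hdr[129:132]) == "DICM"
  }
  if (is_dicom) {
    d <- read_dicom(path)
    spacing <- if (!is.null(spacing_override)) spacing_override else d$spacing
    if (is.null(spacing))
      stop("DICOM file has no PixelSpacing (0028,0030) attribute and no ",
           "spacing_override was supplied")
    image_record(d$pixels, spacing, source_id = basename(path),
                 orientation = orientation)
  } else {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3) px <- px[, , 1]
    spacing <- if (!is.null(spacing_override)) spacing_override else default_spacing
    if (is.null(spacing))
      stop("PNG images carry no physical spacing; supply spacing_override ",
           "or a config default")
    image_record(px, spacing, source_id = basename(path),
                 orientation = orientation)
  }
}

#' Rasterize a closed polygon onto a pixel grid (inclusive boundary)
#'
#' Even-odd (crossing-number) test at each pixel center; a pixel whose center
#' lies exactly on a polygon edge is foreground. This inclusive tie rule makes
#' an axis-aligned square with integer corners (x0,y0)-(x1,y1) cover
#' (x1-x0+1) x (y1-y0+1) pixels.
#'
#' @param polygon n x 2 matrix of vertices (x, y) in 0-based px.
#' @param dim grid dimensions `c(nrow, ncol)`.
#' @return logical matrix of the given dimensions.
#' @export
rasterize_polygon <- function(polygon, dim) {
  polygon <- as.matrix(polygon)
  n <- nrow(polygon)
  if (n < 3) stop("polygon needs at least 3 vertices")
  # restrict the test to the polygon bounding box
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  xs <- max(0L, floor(xr[1])):min(dim[2] - 1L, ceiling(xr[2]))
  ys <- max(0L, floor(yr[1])):min(dim[1] - 1L, ceiling(yr[2]))
  out <- matrix(FALSE, dim[1], dim[2])
  if (length(xs) == 0 || length(ys) == 0) return(out)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  eps <- 1e-9
  for (k in seq_len(n)) {
    a <- polygon[k, ]; b <- polygon[if (k == n) 1L else k + 1L, ]
    # edge-crossing for the even-odd rule (half-open in y)
    cross <- ((a[2] > py) != (b[2] > py))
    if (any(cross)) {
      xint <- a[1] + (py[cross] - a[2]) / (b[2] - a[2]) * (b[1] - a[1])
      flip <- xint > px[cross]
      inside[cross][flip] <- !inside[cross][flip]
    }
    # point-on-segment test (inclusive boundary)
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 < eps) {
      onedge <- onedge | (abs(px - a[1]) < eps & abs(py - a[2]) < eps)
    } else {
      t <- ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (a[1] + t * ab[1] - px)^2 + (a[2] + t * ab[2] - py)^2
      onedge <- onedge | (d2 < eps)
    }
  }
  fg <- inside | onedge
  out[cbind(py + 1L, px + 1L)] <- fg
  out
}

#' Parse an annotation file into a disc mask or keypoint set
#'
#' @param path annotation file.
#' @param dialect `"labelme"` (JSON), `"yolo_seg"` (class + normalized polygon
#'   x y pairs) or `"yolo_pose"` (class, box, then normalized keypoint
#'   triplets x y v in role order facet_left, facet_right, spinous, b1..b6).
#' @param image the `ldh_image` the annotation belongs to (needed to
#'   de-normalize YOLO coordinates and to rasterize polygons).
#' @param label_map named vector mapping file labels to roles (LabelMe only);
#'   see [default_label_map()]. The disc polygon label defaults to `"disc"`.
#' @param what for LabelMe files containing both: `"auto"`, `"mask"`, or
#'   `"keypoints"`.
#' @return an `ldh_mask` or `ldh_keypoints`.
#' @export
parse_annotations <- function(path, dialect = c("labelme", "yolo_seg", "yolo_pose"),
                              image, label_map = default_label_map(),
                              what = c("auto", "mask", "keypoints")) {
  dialect <- match.arg(dialect)
  what <- match.arg(what)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  dims <- dim(image$pixels)
  if (dialect == "labelme") {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(doc$shapes)) stop("malformed LabelMe JSON: no 'shapes'")
    polys <- list(); pts <- list()
    for (sh in doc$shapes) {
      coords <- do.call(rbind, lapply(sh$points, function(p) as.numeric(unlist(p))))
      if (identical(sh$shape_type, "polygon")) polys[[sh$label]] <- coords
      else if (identical(sh$shape_type, "point")) pts[[sh$label]] <- coords[1, ]
    }
    want_mask <- what == "mask" || (what == "auto" && length(polys) > 0 && length(pts) == 0)
    if (want_mask) {
      if (length(polys) == 0) stop("no polygon shapes in ", path)
      poly <- polys[["disc"]] %||% polys[[1]]
      return(disc_mask(rasterize_polygon(poly, dims), polygon = poly))
    }
    roles <- stats::setNames(names(label_map), label_map)  # role -> file label
    m <- matrix(NA_real_, 9, 2,
                dimnames = list(c("facet_left", "facet_right", "spinous",
                                  paste0("b", 1:6)), NULL))
    for (r in rownames(m)) {
      lab <- roles[[r]]
      if (is.null(pts[[lab]]))
        stop("missing required keypoint role '", r, "' (label '", lab, "') in ", path)
      m[r, ] <- pts[[lab]]
    }
    return(keypoints_from_matrix(clamp_to_bounds(m, dims)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty YOLO label file: ", path)
  vals <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (dialect == "yolo_seg") {
    v <- vals[[1]]
    xy <- v[-1]
    if (length(xy) < 6 || length(xy) %% 2 != 0)
      stop("malformed YOLO segmentation line in ", path)
    xn <- xy[seq(1, length(xy), 2)]; yn <- xy[seq(2, length(xy), 2)]
    if (any(xn < 0 | xn > 1 | yn < 0 | yn > 1))
      stop("YOLO normalized coordinates outside [0, 1] in ", path)
    poly <- cbind(xn * dims[2], yn * dims[1])
    disc_mask(rasterize_polygon(poly, dims), polygon = poly)
  } else {
    v <- vals[[1]]
    kxyv <- v[-(1:5)]  # strip class + box
    if (length(kxyv) < 27) stop("YOLO pose line needs 9 keypoint triplets in ", path)
    kx <- kxyv[seq(1, 27, 3)]; ky <- kxyv[seq(2, 27, 3)]
    if (any(kx < 0 | kx > 1 | ky < 0 | ky > 1))
      stop("YOLO normalized coordinates outside [0, 1] in ", path)
    m <- cbind(kx * dims[2], ky * dims[1])
    rownames(m) <- c("facet_left", "facet_right", "spinous", paste0("b", 1:6))
    keypoints_from_matrix(clamp_to_bounds(m, dims))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp_to_bounds <- function(m, dims) {
  m[, 1] <- pmin(pmax(m[, 1], 0), dims[2] - 1)
  m[, 2] <- pmin(pmax(m[, 2], 0), dims[1] - 1)
  m
}

#' Write annotations in LabelMe JSON or YOLO label dialects
#'
#' @param ann an `ldh_mask` (requires a polygon) and/or `ldh_keypoints`,
#'   given as a list for LabelMe (both shapes land in one JSON file).
#' @param path output path.
#' @param dialect see [parse_annotations()].
#' @param image the `ldh_image` (for dimensions / YOLO normalization).
#' @param label_map role -> file label naming, as in [default_label_map()].
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path, dialect = c("labelme", "yolo_seg", "yolo_pose"),
                              image, label_map = default_label_map()) {
  dialect <- match.arg(dialect)
  dims <- dim(image$pixels)
  if (dialect == "labelme") {
    if (!is.list(ann) || inherits(ann, c("ldh_mask", "ldh_keypoints"))) ann <- list(ann)
    shapes <- list()
    for (a in ann) {
      if (inherits(a, "ldh_mask")) {
        if (is.null(a$polygon)) stop("LabelMe export needs a polygon-backed mask")
        shapes[[length(shapes) + 1]] <- list(
          label = "disc", shape_type = "polygon",
          points = lapply(seq_len(nrow(a$polygon)), function(i) as.numeric(a$polygon[i, ])))
      } else if (inherits(a, "ldh_keypoints")) {
        m <- keypoint_matrix(a)
        roles <- stats::setNames(names(label_map), label_map)
        for (r in rownames(m)) {
          shapes[[length(shapes) + 1]] <- list(
            label = unname(roles[[r]]), shape_type = "point",
            points = list(as.numeric(m[r, ])))
        }
      }
    }
    doc <- list(version = "5.0.1", shapes = shapes,
                imagePath = image$source_id,
                imageHeight = dims[1], imageWidth = dims[2])
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else if (dialect == "yolo_seg") {
    stopifnot(inherits(ann, "ldh_mask"), !is.null(ann$polygon))
    xn <- ann$polygon[, 1] / dims[2]; yn <- ann$polygon[, 2] / dims[1]
    xn <- pmin(pmax(xn, 0), 1); yn <- pmin(pmax(yn, 0), 1)
    writeLines(paste(c(0, sprintf("%.8f", as.numeric(rbind(xn, yn)))),
                     collapse = " "), path)
  } else {
    stopifnot(inherits(ann, "ldh_keypoints"))
    m <- keypoint_matrix(ann)
    xn <- m[, 1] / dims[2]; yn <- m[, 2] / dims[1]
    box <- c(mean(range(xn)), mean(range(yn)),
             diff(range(xn)) + 0.02, diff(range(yn)) + 0.02)
    trip <- as.numeric(rbind(xn, yn, rep(2, 9)))
    writeLines(paste(c(0, sprintf("%.8f", c(box, trip))), collapse = " "), path)
  }
  invisible(path)
}

#' Canonicalize an image and its annotations to the working frame
#'
#' Resamples the image to `size` x `size` (bilinear), rescales the spacing by
#' the inverse factors so every mm distance is preserved, maps all annotation
#' coordinates through the same [coord_transform()], and min-max normalizes
#' the intensities to `[0, 1]` (geometry never uses intensities; the
#' normalization only standardizes display).
#'
#' @param image an `ldh_image`.
#' @param annotations list of `ldh_keypoints` / `ldh_mask` objects.
#' @param size canonical edge length in px (default 512).
#' @return list `(image, annotations, transform)`.
#' @export
canonicalize <- function(image, annotations = list(), size = 512L) {
  d <- dim(image$pixels)
  if (any(d == 0)) stop("zero-sized input image")
  tr <- coord_transform(row_factor = size / d[1], col_factor = size / d[2])
  if (all(d == size)) {
    px <- image$pixels
  } else {
    img <- EBImage::Image(t(image$pixels))
    px <- t(EBImage::resize(img, w = size, h = size)@.Data)
  }
  rng <- range(px)
  px <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  out_img <- image_record(px, spacing = image$spacing * c(d[1] / size, d[2] / size),
                          source_id = image$source_id,
                          orientation = image$orientation)
  anns <- lapply(annotations, transform_annotation, tr = tr, new_dim = c(size, size))
  list(image = out_img, annotations = anns, transform = tr)
}

#' Write per-disc quantification results to JSON or CSV
#'
#' The schema is one row per disc: `source_id`, `region`, `grade`, `code`,
#' `valid`, `D_mm`, `I`, `u_mm`, `provenance`. Reading the file back with
#' [read_results()] reproduces the records.
#'
#' @param records data.frame with the columns above (or a list of
#'   [case_result][quantify_case] objects).
#' @param path output file.
#' @param format `"json"` or `"csv"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "json"
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, lapply(records, as.data.frame.case_result))
  if (is.null(records)) records <- empty_results()
  stopifnot(is.data.frame(records))
  if (format == "json") {
    jsonlite::write_json(records, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.csv(records, path, row.names = FALSE)
  }
  invisible(path)
}

empty_results <- function() {
  data.frame(source_id = character(), region = character(), grade = integer(),
             code = integer(), valid = logical(), D_mm = numeric(),
             I = numeric(), u_mm = numeric(), provenance = character(),
             stringsAsFactors = FALSE)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "json"
  df <- if (format == "json") {
    d <- jsonlite::fromJSON(path)
    if (length(d) == 0) empty_results() else as.data.frame(d)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (nrow(df)) {
    df$grade <- as.integer(df$grade)
    df$code <- as.integer(df$code)
    df$valid <- as.logical(df$valid)
  }
  df
}
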