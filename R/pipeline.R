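# Dual-branch multi-stage workflow with pluggable detector stages.
#
# Branch 1: locate the disc (box) -> segment it (mask).
# Branch 2: locate the facet/spinous region (box) -> detect the 9 keypoints.
# Stage outputs are expressed in CROP coordinates and mapped back to the full
# canonical frame by the branch runners, so external detectors only ever see
# the region they were given.

#' Construct a detector stage
#'
#' @param kind `"box"`, `"mask"`, or `"keypoints"`.
#' @param predict function `(crop)` where `crop` is a list with `pixels`
#'   (matrix), `origin` (`c(x0, y0)` of the crop in the full frame, 0-based px)
#'   and `spacing`. Must return, in crop coordinates:
#'   box stages - a data.frame `x0, y0, x1, y1, conf`;
#'   mask stages - an `ldh_mask` congruent with the crop;
#'   keypoint stages - an `ldh_keypoints`.
#' @param label free-text provenance tag.
#' @return object of class `ldh_detector`.
#' @export
detector_stage <- function(kind = c("box", "mask", "keypoints"), predict,
                           label = "plugin") {
  kind <- match.arg(kind)
  stopifnot(is.function(predict))
  structure(list(kind = kind, predict = predict, label = label),
            class = "ldh_detector")
}

crop_region <- function(image, box = NULL) {
  d <- dim(image$pixels)
  if (is.null(box)) box <- c(0, 0, d[2] - 1, d[1] - 1)
  box <- c(floor(box[1:2]), ceiling(box[3:4]))
  box[1] <- max(box[1], 0); box[2] <- max(box[2], 0)
  box[3] <- min(box[3], d[2] - 1); box[4] <- min(box[4], d[1] - 1)
  list(pixels = image$pixels[(box[2] + 1):(box[4] + 1),
                             (box[1] + 1):(box[3] + 1), drop = FALSE],
       origin = box[1:2], box = box, spacing = image$spacing)
}

expand_box <- function(box, margin) {
  w <- box[3] - box[1]; h <- box[4] - box[2]
  c(box[1] - margin * w, box[2] - margin * h,
    box[3] + margin * w, box[4] + margin * h)
}

pick_box <- function(boxes, conf_threshold) {
  if (is.null(boxes) || nrow(boxes) == 0) return(NULL)
  boxes <- boxes[boxes$conf >= conf_threshold, , drop = FALSE]
  if (nrow(boxes) == 0) return(NULL)
  if (nrow(boxes) > 1)
    message(nrow(boxes), " candidate boxes above threshold; keeping the most confident")
  as.numeric(boxes[which.max(boxes$conf), c("x0", "y0", "x1", "y1")])
}

#' Oracle detector stages backed by ground-truth annotations
#'
#' `oracle_box_detector` returns the tight bounding box (confidence 1) of the
#' truth object; `oracle_mask_detector` and `oracle_keypoint_detector` replay
#' the truth restricted to / shifted into the crop they are given.
#'
#' @param truth an `ldh_mask` (box/mask oracles) or `ldh_keypoints`
#'   (box/keypoint oracles), in full-frame px.
#' @return an [detector_stage()].
#' @export
oracle_box_detector <- function(truth) {
  detector_stage("box", label = "oracle", predict = function(crop) {
    if (inherits(truth, "ldh_mask")) {
      idx <- which(truth$mask, arr.ind = TRUE)
      if (nrow(idx) == 0)
        return(data.frame(x0 = numeric(), y0 = numeric(), x1 = numeric(),
                          y1 = numeric(), conf = numeric()))
      b <- c(min(idx[, 2]) - 1, min(idx[, 1]) - 1,
             max(idx[, 2]) - 1, max(idx[, 1]) - 1)
    } else {
      m <- keypoint_matrix(truth)
      b <- c(min(m[, 1]), min(m[, 2]), max(m[, 1]), max(m[, 2]))
    }
    data.frame(x0 = b[1] - crop$origin[1], y0 = b[2] - crop$origin[2],
               x1 = b[3] - crop$origin[1], y1 = b[4] - crop$origin[2],
               conf = 1)
  })
}

#' @rdname oracle_box_detector
#' @export
oracle_mask_detector <- function(truth) {
  stopifnot(inherits(truth, "ldh_mask"))
  detector_stage("mask", label = "oracle", predict = function(crop) {
    b <- crop$box
    disc_mask(truth$mask[(b[2] + 1):(b[4] + 1), (b[1] + 1):(b[3] + 1),
                         drop = FALSE])
  })
}

#' @rdname oracle_box_detector
#' @export
oracle_keypoint_detector <- function(truth) {
  stopifnot(inherits(truth, "ldh_keypoints"))
  detector_stage("keypoints", label = "oracle", predict = function(crop) {
    m <- keypoint_matrix(truth)
    m[, 1] <- m[, 1] - crop$origin[1]
    m[, 2] <- m[, 2] - crop$origin[2]
    keypoints_from_matrix(m)
  })
}

#' Detector stage that replays stored prediction files
#'
#' Lets externally produced predictions (YOLO label text or LabelMe JSON) be
#' pushed through the same pipeline as oracle or plugin detectors.
#'
#' @param path prediction file for this image.
#' @param dialect as in [parse_annotations()].
#' @param image the full-frame `ldh_image` the predictions refer to.
#' @param label_map label -> role map for LabelMe files.
#' @return an [detector_stage()] of kind `"mask"` or `"keypoints"`.
#' @export
file_detector <- function(path, dialect = c("labelme", "yolo_seg", "yolo_pose"),
                          image, label_map = default_label_map()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("missing prediction file: ", path)
  ann <- parse_annotations(path, dialect, image, label_map)
  if (inherits(ann, "ldh_mask")) {
    detector_stage("mask", label = "file", predict = function(crop) {
      b <- crop$box
      disc_mask(ann$mask[(b[2] + 1):(b[4] + 1), (b[1] + 1):(b[3] + 1),
                         drop = FALSE])
    })
  } else {
    detector_stage("keypoints", label = "file", predict = function(crop) {
      m <- keypoint_matrix(ann)
      m[, 1] <- m[, 1] - crop$origin[1]
      m[, 2] <- m[, 2] - crop$origin[2]
      keypoints_from_matrix(m)
    })
  }
}

#' Run branch 1: disc localization then segmentation
#'
#' The locator's most confident box (above `conf_threshold`) is expanded by
#' `margin` on each side, cropped, segmented, and the crop mask is mapped
#' back into the full canonical frame.
#'
#' @param image canonical `ldh_image`.
#' @param locator box-kind [detector_stage()].
#' @param segmenter mask-kind [detector_stage()].
#' @param margin relative box expansion per side (default 0.1).
#' @param conf_threshold minimum box confidence (default 0.25).
#' @return full-frame `ldh_mask`; when no box clears the threshold, an empty
#'   mask with attribute `no_disc = TRUE`.
#' @export
run_branch1 <- function(image, locator, segmenter, margin = 0.1,
                        conf_threshold = 0.25) {
  stopifnot(locator$kind == "box", segmenter$kind == "mask")
  d <- dim(image$pixels)
  boxes <- locator$predict(crop_region(image))
  box <- pick_box(boxes, conf_threshold)
  if (is.null(box)) {
    out <- disc_mask(matrix(FALSE, d[1], d[2]))
    attr(out, "no_disc") <- TRUE
    return(out)
  }
  crop <- crop_region(image, expand_box(box, margin))
  sub <- segmenter$predict(crop)
  full <- matrix(FALSE, d[1], d[2])
  b <- crop$box
  full[(b[2] + 1):(b[4] + 1), (b[1] + 1):(b[3] + 1)] <- sub$mask
  disc_mask(full)
}

#' Run branch 2: facet/spinous localization then keypoint detection
#'
#' @inheritParams run_branch1
#' @param pose keypoints-kind [detector_stage()].
#' @return full-frame `ldh_keypoints`, or `NULL` with a warning when no box
#'   clears the threshold.
#' @export
run_branch2 <- function(image, locator, pose, margin = 0.1,
                        conf_threshold = 0.25) {
  stopifnot(locator$kind == "box", pose$kind == "keypoints")
  boxes <- locator$predict(crop_region(image))
  box <- pick_box(boxes, conf_threshold)
  if (is.null(box)) {
    warning("branch 2: no canal box above confidence threshold")
    return(NULL)
  }
  crop <- crop_region(image, expand_box(box, margin))
  kp <- pose$predict(crop)
  m <- keypoint_matrix(kp)
  m[, 1] <- m[, 1] + crop$origin[1]
  m[, 2] <- m[, 2] + crop$origin[2]
  keypoints_from_matrix(m)
}

#' Quantify one case: merge segmentation and keypoints, measure and classify
#'
#' Builds the canal frame from the keypoints, measures the herniation of the
#' disc mask against it, grades it, assigns the region and encodes the
#' 18-category label. All intermediates are retained for audit.
#'
#' @param image canonical `ldh_image`.
#' @param disc full-frame `ldh_mask`.
#' @param kp full-frame `ldh_keypoints`.
#' @param thresholds [grading_thresholds()].
#' @param policy lattice policy for [encode_category()].
#' @param provenance free-text tag recording which detectors produced the
#'   inputs.
#' @return object of class `case_result`: `category`, `measurement`, `frame`,
#'   `disc`, `keypoints`, `provenance`, `flags`.
#' @export
quantify_case <- function(image, disc, kp, thresholds = grading_thresholds(),
                          policy = "clamp", provenance = "oracle") {
  flags <- character()
  if (isTRUE(attr(disc, "no_disc")) || sum(disc$mask) == 0) {
    return(structure(list(category = NULL, measurement = NULL, frame = NULL,
                          disc = disc, keypoints = kp,
                          provenance = provenance, flags = "no_disc"),
                     class = "case_result"))
  }
  frame <- build_frame(kp, image$spacing, image$orientation)
  m <- measure_herniation(frame, disc, image$spacing)
  g <- assign_grade(m, thresholds)
  r <- assign_region(m, frame, g)
  cat_ <- encode_category(r, g, policy)
  if (!cat_$valid) flags <- c(flags, "clamped")
  structure(list(category = cat_, measurement = m, frame = frame,
                 disc = disc, keypoints = kp, provenance = provenance,
                 flags = flags),
            class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  if (is.null(x$category)) {
    cat("<case_result> flagged:", paste(x$flags, collapse = ","), "\n")
  } else {
    cat(sprintf("<case_result> %s grade %d (D %+.2f mm, I %.3f, u %+.2f mm) [%s]\n",
                x$category$region, x$category$grade, x$measurement$D,
                x$measurement$I, x$measurement$u_apex, x$provenance))
  }
  invisible(x)
}

#' @export
as.data.frame.case_result <- function(x, row.names = NULL, optional = FALSE,
                                      source_id = "", ...) {
  if (is.null(x$category)) {
    return(data.frame(source_id = source_id, region = NA_character_,
                      grade = NA_integer_, code = NA_integer_, valid = NA,
                      D_mm = NA_real_, I = NA_real_, u_mm = NA_real_,
                      provenance = paste(c(x$provenance, x$flags), collapse = ";"),
                      stringsAsFactors = FALSE))
  }
  data.frame(source_id = source_id, region = x$category$region,
             grade = x$category$grade, code = x$category$code,
             valid = x$category$valid, D_mm = x$measurement$D,
             I = x$measurement$I, u_mm = x$measurement$u_apex,
             provenance = x$provenance, stringsAsFactors = FALSE)
}

#' Run the full dual-branch workflow on one case with given stages
#'
#' Convenience wrapper: branch 1 (disc), branch 2 (keypoints), then
#' [quantify_case()].
#'
#' @param image canonical `ldh_image`.
#' @param disc_locator,segmenter,canal_locator,pose detector stages.
#' @inheritParams quantify_case
#' @param margin,conf_threshold see [run_branch1()].
#' @return a `case_result`.
#' @export
run_pipeline <- function(image, disc_locator, segmenter, canal_locator, pose,
                         thresholds = grading_thresholds(), policy = "clamp",
                         margin = 0.1, conf_threshold = 0.25,
                         provenance = "pipeline") {
  disc <- run_branch1(image, disc_locator, segmenter, margin, conf_threshold)
  kp <- run_branch2(image, canal_locator, pose, margin, conf_threshold)
  if (is.null(kp)) {
    return(structure(list(category = NULL, measurement = NULL, frame = NULL,
                          disc = disc, keypoints = NULL,
                          provenance = provenance, flags = "no_canal"),
                     class = "case_result"))
  }
  quantify_case(image, disc, kp, thresholds, policy, provenance)
}
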