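# Parameterized axial-slice phantoms with known ground truth.
#
# Everything is constructed in a canal-aligned (u, v) mm frame: u runs along
# the inter-facet line (patient-right negative under radiological display),
# v is the signed posterior distance from it. The whole construction is then
# rotated/translated into the image, so rigid-motion invariance of the
# geometry is exercised for free.

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

default_depth_for_grade <- function(grade, L_sag, thresholds = grading_thresholds()) {
  switch(as.character(grade),
         "0" = -10,
         "1" = -1.5,
         "2" = 0.5 * thresholds$index_cut * L_sag,
         "3" = (thresholds$index_cut + 0.1) * L_sag + 1)
}

zone_center_u <- function(region, boundary_offsets) {
  b <- boundary_offsets
  switch(region,
    NONE = 0,
    CCZ  = (b[3] + b[4]) / 2,
    LSAZ = (b[4] + b[5]) / 2, RSAZ = (b[2] + b[3]) / 2,
    LFZ  = (b[5] + b[6]) / 2, RFZ  = (b[1] + b[2]) / 2,
    LEFZ = b[6] + 8,          REFZ = b[1] - 8,
    stop("unknown region: ", region))
}

#' Specify an axial-slice phantom
#'
#' Defaults describe a plausible adult lumbar level on a 512 x 512 grid at
#' 0.5 mm isotropic spacing: facet apices 104 mm apart, ligamentum-flavum
#' sagittal diameter 20 mm, zone boundaries at -40, -24, -12, 12, 24, 40 mm
#' along the inter-facet line, and a disc modelled as a 55 x 15 mm
#' semi-axis ellipse whose posterior margin sits 6 mm anterior of the line.
#' A herniation is a parabolic-cap posterior bump whose apex lies exactly at
#' `(u_target, D_target)`.
#'
#' @param image_size edge length in px.
#' @param spacing `c(row_mm, col_mm)`.
#' @param facet_sep_mm inter-facet distance.
#' @param L_sag_mm spinous-to-line perpendicular distance.
#' @param boundary_offsets_mm 6 sorted along-line boundary positions (mm).
#' @param disc_semiaxes_mm ellipse semi-axes `c(a_u, b_v)`.
#' @param disc_base_margin_mm posterior margin of the un-herniated ellipse
#'   (signed distance from the line; negative = anterior).
#' @param target_region,target_grade the ground-truth category.
#' @param D_target signed apex distance (mm); default consistent with the
#'   grade (see Details).
#' @param bump_rho_mm curvature radius of the parabolic cap (controls bump
#'   width).
#' @param rotation_deg,translation_mm rigid pose of the whole construction.
#' @param intensity_sigma Gaussian intensity noise (cosmetic).
#' @param kp_jitter_sigma_mm Gaussian jitter applied to the returned
#'   keypoints (truth is recorded pre-jitter).
#' @param seed integer; the phantom is deterministic for a fixed seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 512L, spacing = c(0.5, 0.5),
                         facet_sep_mm = 104, L_sag_mm = 20,
                         boundary_offsets_mm = c(-40, -24, -12, 12, 24, 40),
                         disc_semiaxes_mm = c(55, 15),
                         disc_base_margin_mm = -6,
                         target_region = "CCZ", target_grade = 2L,
                         D_target = NULL, bump_rho_mm = 8,
                         rotation_deg = 0, translation_mm = c(0, 0),
                         intensity_sigma = 0, kp_jitter_sigma_mm = 0,
                         seed = NULL) {
  thresholds <- grading_thresholds()
  target_region <- match.arg(target_region, .regions)
  target_grade <- as.integer(target_grade)
  stopifnot(target_grade %in% 0:3)
  if ((target_grade == 0L) != (target_region == "NONE"))
    stop("grade 0 pairs only with region NONE")
  if (target_region %in% c("LFZ", "RFZ") && target_grade > 1L)
    stop("no such classification exists: (", target_region, ", grade ",
         target_grade, ")")
  if (is.null(D_target))
    D_target <- default_depth_for_grade(target_grade, L_sag_mm, thresholds)
  I <- max(D_target, 0) / L_sag_mm
  g <- if (D_target < -thresholds$near_mm) 0L else if (D_target <= 0) 1L
       else if (I <= thresholds$index_cut) 2L else 3L
  if (g != target_grade)
    stop("D_target = ", D_target, " mm implies grade ", g,
         ", not the requested grade ", target_grade)
  structure(list(image_size = as.integer(image_size), spacing = spacing,
                 facet_sep_mm = facet_sep_mm, L_sag_mm = L_sag_mm,
                 boundary_offsets_mm = sort(boundary_offsets_mm),
                 disc_semiaxes_mm = disc_semiaxes_mm,
                 disc_base_margin_mm = disc_base_margin_mm,
                 target_region = target_region, target_grade = target_grade,
                 D_target = D_target, I_target = I,
                 bump_rho_mm = bump_rho_mm,
                 rotation_deg = rotation_deg, translation_mm = translation_mm,
                 intensity_sigma = intensity_sigma,
                 kp_jitter_sigma_mm = kp_jitter_sigma_mm, seed = seed),
            class = "phantom_spec")
}

#' Render a phantom case from its specification
#'
#' Produces the image, the disc mask (with a traced boundary polygon), the
#' keypoint set (jittered when `kp_jitter_sigma_mm > 0`; the un-jittered set
#' is kept alongside) and the ground truth recorded pre-jitter.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_case`: `image` (`ldh_image`), `disc`
#'   (`ldh_mask`), `keypoints`, `keypoints_true` (`ldh_keypoints`), `truth`
#'   (list: `region`, `grade`, `code`, `D`, `I`, `u_apex`), `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_seed(spec$seed, {
    S <- spec$image_size
    sp <- spec$spacing
    th <- spec$rotation_deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    center <- c(S * sp[2] / 2, S * sp[1] / 2 + 22) + spec$translation_mm
    uv_to_mm <- function(uv) {
      if (!is.matrix(uv)) uv <- matrix(uv, ncol = 2)
      sweep(uv %*% t(R), 2, center, `+`)
    }
    # keypoints in (u, v): facets on the line, boundaries slightly off it
    # (they get projected back by build_frame)
    b_off <- c(-2, -1, -0.5, -0.5, -1, -2)
    kp_uv <- rbind(
      facet_left = c(spec$facet_sep_mm / 2, 0),
      facet_right = c(-spec$facet_sep_mm / 2, 0),
      spinous = c(0, spec$L_sag_mm),
      cbind(spec$boundary_offsets_mm, b_off))
    rownames(kp_uv) <- c("facet_left", "facet_right", "spinous", paste0("b", 1:6))
    kp_mm <- uv_to_mm(kp_uv)
    kp_px <- cbind(kp_mm[, 1] / sp[2], kp_mm[, 2] / sp[1])
    rownames(kp_px) <- rownames(kp_uv)
    kp_true <- keypoints_from_matrix(kp_px)

    # disc geometry in (u, v)
    a <- spec$disc_semiaxes_mm[1]; b <- spec$disc_semiaxes_mm[2]
    u_t <- zone_center_u(spec$target_region, spec$boundary_offsets_mm)
    has_bump <- spec$target_grade > 0L
    v_c <- if (has_bump) spec$disc_base_margin_mm - b else spec$D_target - b
    if (has_bump && abs(u_t) > a - 4)
      a <- abs(u_t) + 4  # keep the bump attached to the ellipse body
    # rasterize over the bounding box of the construction
    v_max <- max(v_c + b, spec$D_target)
    corners_uv <- as.matrix(expand.grid(u = c(-a, a), v = c(v_c - b, v_max)))
    corners_mm <- uv_to_mm(corners_uv)
    x_rng <- range(corners_mm[, 1] / sp[2]); y_rng <- range(corners_mm[, 2] / sp[1])
    xs <- max(0L, floor(x_rng[1] - 1)):min(S - 1L, ceiling(x_rng[2] + 1))
    ys <- max(0L, floor(y_rng[1] - 1)):min(S - 1L, ceiling(y_rng[2] + 1))
    px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
    pm <- cbind(px * sp[2], py * sp[1])
    quv <- sweep(pm, 2, center, `-`) %*% R  # inverse rotation
    u <- quv[, 1]; v <- quv[, 2]
    fg <- ((u / a)^2 + ((v - v_c) / b)^2) <= 1
    if (has_bump) {
      cap <- spec$D_target - (u - u_t)^2 / (2 * spec$bump_rho_mm)
      fg <- fg | (v >= v_c & v <= cap)
    }
    mask <- matrix(FALSE, S, S)
    mask[cbind(py + 1L, px + 1L)] <- fg
    if (!any(mask)) stop("degenerate phantom: disc rasterized to nothing")
    poly <- trace_boundary(mask)
    disc <- disc_mask(mask, polygon = poly)

    # cosmetic intensity rendering
    img <- matrix(0.15, S, S)
    img[mask] <- 0.9
    smm <- uv_to_mm(c(0, spec$L_sag_mm / 2))
    spx <- c(smm[1] / sp[2], smm[2] / sp[1])
    all_x <- matrix(rep(0:(S - 1), each = S), S, S)   # [row, col] = col index
    all_y <- matrix(rep(0:(S - 1), times = S), S, S)  # [row, col] = row index
    canal <- ((all_x - spx[1])^2 + (all_y - spx[2])^2) < (12 / mean(sp))^2
    img[canal & !mask] <- 0.45
    if (spec$intensity_sigma > 0)
      img <- img + matrix(stats::rnorm(S * S, 0, spec$intensity_sigma), S, S)

    kp_out <- kp_true
    if (spec$kp_jitter_sigma_mm > 0) {
      jit <- matrix(stats::rnorm(18, 0, spec$kp_jitter_sigma_mm), 9, 2)
      m <- keypoint_matrix(kp_true) + cbind(jit[, 1] / sp[2], jit[, 2] / sp[1])
      kp_out <- keypoints_from_matrix(clamp_to_bounds(m, c(S, S)))
    }

    code <- encode_category(spec$target_region, spec$target_grade)$code
    structure(list(
      image = image_record(img, sp, source_id = sprintf("phantom_%s", spec$seed %||% "x")),
      disc = disc, keypoints = kp_out, keypoints_true = kp_true,
      truth = list(region = spec$target_region, grade = spec$target_grade,
                   code = code, D = spec$D_target, I = spec$I_target,
                   u_apex = if (has_bump) u_t else 0),
      spec = spec), class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> truth %s grade %d (D %+.2f mm), %d fg px\n",
              x$truth$region, x$truth$grade, x$truth$D, sum(x$disc$mask)))
  invisible(x)
}

# Trace the outer boundary of a mask as an ordered polygon (boundary pixel
# centers, via EBImage's contour follower).
trace_boundary <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(t(mask * 1)))
  poly <- oc[[which.max(vapply(oc, nrow, 1L))]]
  # ocontour returns (x, y) already 0-based on the transposed image
  cbind(poly[, 1], poly[, 2])
}

#' Default 18-category mix used by [sample_cohort()]
#'
#' Proportions of the orthopedist's external reader-study distribution
#' shipped with the package (see [reader_study_counts()]).
#' @return named numeric vector of 18 probabilities (names `REGION:grade`).
#' @export
default_category_mix <- function() {
  rc <- reader_study_counts()
  rc <- rc[rc$dataset == "external" & rc$rater == "orthopedist", ]
  lat <- enumerate_categories()
  i <- match(paste0(lat$region, ":", lat$grade), paste0(rc$region, ":", rc$grade))
  p <- rc$count[i] / sum(rc$count[i])
  stats::setNames(p, paste0(lat$region, ":", lat$grade))
}

sample_depth_for_grade <- function(grade, L_sag) {
  # ranges keep |D| at least 1 mm away from every grading boundary
  switch(as.character(grade),
         "0" = stats::runif(1, -12, -4.5),
         "1" = stats::runif(1, -2, -1),
         "2" = stats::runif(1, 1.5, 4.5),
         "3" = stats::runif(1, 0.3 * L_sag + 1.5, 0.3 * L_sag + 5))
}

#' Sample a cohort of phantoms from a category mix
#'
#' Categories are drawn from `mix`; per case, the apex depth is drawn
#' uniformly inside a grade-consistent range that stays at least 1 mm away
#' from every grading boundary, and the pose is a random rotation in
#' +/- 15 degrees with a +/- 5 mm translation.
#'
#' @param n number of phantoms.
#' @param mix probabilities over the 18 categories (canonical code order or
#'   named `REGION:grade`); must sum to 1.
#' @param noise list with `kp_jitter_sigma_mm` and `intensity_sigma`.
#' @param seed cohort seed (each case derives its own sub-seed).
#' @param image_size,spacing forwarded to [phantom_spec()].
#' @return list with `cases` (list of `phantom_case`) and `manifest`
#'   (data.frame: case_id, region, grade, code, D, I, u_apex, rotation_deg,
#'   seed).
#' @export
sample_cohort <- function(n, mix = default_category_mix(),
                          noise = list(kp_jitter_sigma_mm = 0, intensity_sigma = 0),
                          seed = 1L, image_size = 512L, spacing = c(0.5, 0.5)) {
  mix <- as.numeric(mix)
  lat <- enumerate_categories()
  if (length(mix) != 18 || any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
    stop("mix must be 18 non-negative probabilities summing to 1")
  with_local_seed(seed, {
    codes <- if (n > 0) sample(lat$code, n, replace = TRUE, prob = mix) else integer()
    case_seeds <- if (n > 0) sample.int(2^30, n) else integer()
    cases <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      reg <- lat$region[lat$code == codes[i]]
      grd <- lat$grade[lat$code == codes[i]]
      sp <- phantom_spec(
        image_size = image_size, spacing = spacing,
        target_region = reg, target_grade = grd,
        D_target = sample_depth_for_grade(grd, 20),
        rotation_deg = stats::runif(1, -15, 15),
        translation_mm = stats::runif(2, -5, 5),
        kp_jitter_sigma_mm = noise$kp_jitter_sigma_mm %||% 0,
        intensity_sigma = noise$intensity_sigma %||% 0,
        seed = case_seeds[i])
      cases[[i]] <- make_phantom(sp)
      rows[[i]] <- data.frame(case_id = sprintf("case_%04d", i),
                              region = reg, grade = grd, code = codes[i],
                              D = sp$D_target, I = sp$I_target,
                              u_apex = cases[[i]]$truth$u_apex,
                              rotation_deg = sp$rotation_deg,
                              seed = case_seeds[i],
                              stringsAsFactors = FALSE)
    }
    manifest <- if (n > 0) do.call(rbind, rows) else
      data.frame(case_id = character(), region = character(), grade = integer(),
                 code = integer(), D = numeric(), I = numeric(),
                 u_apex = numeric(), rotation_deg = numeric(), seed = integer(),
                 stringsAsFactors = FALSE)
    list(cases = cases, manifest = manifest)
  })
}
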