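# Shared fixtures: a reference canal frame, random fixture generators, and
# independent brute-force oracles used to cross-check the vectorized paths.

# The reference frame used throughout: 0.5 mm spacing, horizontal inter-facet
# line at y = 300 px (150 mm), spinous 40 px (20 mm) posterior, symmetric
# boundaries at +/- 12, 24, 40 mm.
ref_keypoints <- function() {
  keypoint_set(facet_left = c(360, 300), facet_right = c(152, 300),
               spinous = c(256, 340),
               boundaries = cbind(c(176, 208, 232, 280, 304, 336), rep(250, 6)))
}

ref_frame <- function() build_frame(ref_keypoints(), c(0.5, 0.5))

circle_mask <- function(dim, cx, cy, r) {
  outer(0:(dim[1] - 1), 0:(dim[2] - 1), function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
}

# Random valid keypoint set on a grid, under a random rigid pose.
random_keypoints <- function(dim = c(256, 256), spacing = c(0.5, 0.5)) {
  th <- runif(1, -pi / 6, pi / 6)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- c(dim[2] / 2 * spacing[2], dim[1] / 2 * spacing[1]) + runif(2, -3, 3)
  sep <- runif(1, 40, 60)
  lsag <- runif(1, 10, 20)
  off <- sort(runif(6, -sep / 2 + 2, sep / 2 - 2))
  while (min(diff(off)) < 2) off <- sort(runif(6, -sep / 2 + 2, sep / 2 - 2))
  uv <- rbind(c(sep / 2, 0), c(-sep / 2, 0), c(0, lsag),
              cbind(off, runif(6, -3, 3)))
  mm <- sweep(uv %*% t(R), 2, ctr, `+`)
  m <- cbind(mm[, 1] / spacing[2], mm[, 2] / spacing[1])
  rownames(m) <- c("facet_left", "facet_right", "spinous", paste0("b", 1:6))
  keypoints_from_matrix(m)
}

random_blob_mask <- function(dim = c(256, 256)) {
  m <- matrix(FALSE, dim[1], dim[2])
  for (k in seq_len(sample(1:3, 1))) {
    cx <- runif(1, 40, dim[2] - 40); cy <- runif(1, 40, dim[1] - 40)
    m <- m | circle_mask(dim, cx, cy, runif(1, 5, 20))
  }
  m
}

# Independent brute-force oracle: plain double loop over foreground pixels,
# explicit tie rule (max D, then min |u|, then min u).
brute_measure <- function(frame, mask, spacing) {
  best <- NULL
  for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    if (!mask[r, cc]) next
    p <- c((cc - 1) * spacing[2], (r - 1) * spacing[1])
    d <- sum((p - frame$line_point) * frame$n_post)
    u <- sum((p - frame$line_point) * frame$line_dir)
    better <- is.null(best) || d > best$D + 1e-12 ||
      (abs(d - best$D) <= 1e-12 &&
         (abs(u) < abs(best$u_apex) - 1e-12 ||
            (abs(abs(u) - abs(best$u_apex)) <= 1e-12 && u < best$u_apex - 1e-12)))
    if (better) best <- list(D = d, u_apex = u)
  }
  best
}

# Shoelace polygon area.
shoelace <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
}

# Rigidly move a keypoint set and mask by (theta, t) in px units.
rigid_move_keypoints <- function(kp, theta, tpx, center_px) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  m <- keypoint_matrix(kp)
  m2 <- sweep(sweep(m, 2, center_px, `-`) %*% t(R), 2, center_px + tpx, `+`)
  rownames(m2) <- rownames(m)
  keypoints_from_matrix(m2)
}

rigid_move_points <- function(pts, theta, tpx, center_px) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(sweep(pts, 2, center_px, `-`) %*% t(R), 2, center_px + tpx, `+`)
}
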