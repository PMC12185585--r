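test_that("the canal frame matches hand geometry on the reference layout", {
  fr <- ref_frame()
  expect_equal(fr$L_sag, 20)
  expect_equal(fr$n_post, c(0, 1))
  expect_equal(fr$line_dir, c(1, 0))
  expect_equal(fr$boundaries_u, c(-40, -24, -12, 12, 24, 40))
  # boundary point (200, 250) px projects to foot (200, 300) px: u = x relative
  # to the facet midpoint, perpendicular offset discarded
  foot <- project_to_line(fr, px_to_mm(c(200, 250), c(0.5, 0.5)))
  expect_equal(foot, c(100, 150))
})

test_that("degenerate keypoint layouts raise geometric errors", {
  kp <- ref_keypoints()
  kp$facet_left <- kp$facet_right + c(1, 0)  # 0.5 mm apart
  expect_error(build_frame(kp, c(0.5, 0.5)), "degenerate facet pair")
  kp2 <- ref_keypoints()
  kp2$spinous <- c(256, 300.4)  # 0.2 mm off the line
  expect_error(build_frame(kp2, c(0.5, 0.5)), "L_sag")
})

test_that("signed distance is positive posterior, zero on the line, L_sag at spinous", {
  fr <- ref_frame()
  expect_equal(signed_distance(fr, c(128, 155)), 5)
  expect_equal(signed_distance(fr, c(100, 150)), 0)
  expect_equal(signed_distance(fr, px_to_mm(c(256, 340), c(0.5, 0.5))), fr$L_sag)
  expect_equal(signed_distance(fr, c(128, 140)), -10)
})

test_that("herniation measurement matches hand geometry on a circular disc", {
  fr <- ref_frame()
  disc <- disc_mask(circle_mask(c(512, 512), 256, 290, 24))
  m <- measure_herniation(fr, disc, c(0.5, 0.5))
  expect_equal(m$D, 7)          # (314 - 300) * 0.5
  expect_equal(m$I, 0.35)
  expect_equal(m$apex_px[2], 314)
  # disc entirely anterior: D = -10, I = 0
  disc2 <- disc_mask(circle_mask(c(512, 512), 256, 256, 24))
  m2 <- measure_herniation(fr, disc2, c(0.5, 0.5))
  expect_equal(m2$D, -10)
  expect_equal(m2$I, 0)
  expect_error(measure_herniation(fr, disc_mask(matrix(FALSE, 8, 8)), c(0.5, 0.5)),
               "empty")
})

test_that("apex ties break to the most central u, then the smallest u", {
  fr <- ref_frame()
  mask <- matrix(FALSE, 512, 512)
  mask[311, c(240 + 1, 272 + 1)] <- TRUE  # y=310 px at u = -8 and +8 mm
  m <- measure_herniation(fr, disc_mask(mask), c(0.5, 0.5))
  expect_equal(m$u_apex, -8)  # equal |u|: smaller u wins
  mask[311, 250 + 1] <- TRUE  # add u = -3 mm, same D
  m2 <- measure_herniation(fr, disc_mask(mask), c(0.5, 0.5))
  expect_equal(m2$u_apex, -3)  # most central wins
})

test_that("zone lookup partitions the u axis into the seven Wiltse zones", {
  fr <- ref_frame()
  expect_equal(zone_of(fr, 0), "CCZ")
  expect_equal(zone_of(fr, 20), "SAZ_L")
  expect_equal(zone_of(fr, -100), "EFZ_R")
  expect_equal(zone_of(fr, 100), "EFZ_L")
  # half-open boundaries: b_i belongs to the interval it opens
  expect_equal(zone_of(fr, 12), "SAZ_L")
  expect_equal(zone_of(fr, -12 - 1e-9), "SAZ_R")
  # neurological orientation mirrors patient sides
  expect_equal(zone_of(fr, 20, orientation = "neurological"), "SAZ_R")
  # every u maps to exactly one zone
  us <- seq(-60, 60, by = 0.25)
  expect_true(all(zone_of(fr, us) %in%
                    c("EFZ_R", "FZ_R", "SAZ_R", "CCZ", "SAZ_L", "FZ_L", "EFZ_L")))
  expect_equal(length(zone_of(fr, us)), length(us))
})

test_that("measurement is invariant under rigid motion and anisotropic spacing", {
  set.seed(21)
  spacing <- c(0.5, 0.5)
  kp <- ref_keypoints()
  mask <- circle_mask(c(512, 512), 256, 290, 24)
  fr <- build_frame(kp, spacing)
  m <- measure_herniation(fr, disc_mask(mask), spacing)
  for (theta in c(pi / 6, -pi / 4)) {
    ctr <- c(256, 300)
    kp2 <- rigid_move_keypoints(kp, theta, c(5, -8), ctr)
    fr2 <- build_frame(kp2, spacing)
    # move the mask by moving each foreground pixel's center exactly
    idx <- which(mask, arr.ind = TRUE)
    pts <- rigid_move_points(cbind(idx[, 2] - 1, idx[, 1] - 1), theta, c(5, -8), ctr)
    d2 <- signed_distance(fr2, px_to_mm(pts, spacing))
    expect_equal(max(d2), m$D, tolerance = 1e-9)
    expect_equal(fr2$L_sag, fr$L_sag, tolerance = 1e-9)
    expect_equal(diff(fr2$boundaries_u), diff(fr$boundaries_u), tolerance = 1e-9)
  }
  # anisotropic spacing: same mm geometry expressed on a stretched grid
  sp2 <- c(0.25, 0.5)
  kpm <- keypoint_matrix(kp)
  kpm[, 2] <- kpm[, 2] * 2  # same mm y at half the row spacing
  fr3 <- build_frame(keypoints_from_matrix(kpm), sp2)
  expect_equal(fr3$L_sag, fr$L_sag)
  expect_equal(fr3$boundaries_u, fr$boundaries_u)
})

test_that("projection of a boundary point onto the line is idempotent", {
  set.seed(33)
  for (k in 1:20) {
    kp <- random_keypoints()
    fr <- build_frame(kp, c(0.5, 0.5))
    p <- px_to_mm(c(runif(1, 0, 255), runif(1, 0, 255)), c(0.5, 0.5))
    f1 <- project_to_line(fr, p)
    f2 <- project_to_line(fr, f1)
    expect_lt(sqrt(sum((f2 - f1)^2)), 1e-9)
    expect_lt(abs(signed_distance(fr, f1)), 1e-9)
  }
})

test_that("vectorized measurement equals the exhaustive pixel scan", {
  set.seed(99)
  for (k in 1:10) {
    kp <- random_keypoints(c(128, 128))
    fr <- build_frame(kp, c(0.5, 0.5))
    mask <- random_blob_mask(c(128, 128))
    if (!any(mask)) next
    m <- measure_herniation(fr, disc_mask(mask), c(0.5, 0.5))
    b <- brute_measure(fr, mask, c(0.5, 0.5))
    expect_equal(m$D, b$D, tolerance = 1e-12)
    expect_equal(m$u_apex, b$u_apex, tolerance = 1e-12)
  }
})
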