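test_that("IoU closed forms and invariants", {
  a <- matrix(FALSE, 40, 40); a[6:15, 6:15] <- TRUE         # 10 x 10 square
  b <- matrix(FALSE, 40, 40); b[6:15, 11:20] <- TRUE        # shifted 5 px
  expect_equal(iou(a, b), 1 / 3)                            # 50 / 150
  expect_equal(iou(a, a), 1)
  expect_equal(iou(b, a), iou(a, b))                        # symmetric
  d <- matrix(FALSE, 40, 40); d[30:35, 30:35] <- TRUE
  expect_equal(iou(a, d), 0)
  expect_warning(expect_equal(iou(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)), 1),
                 "empty")
  expect_error(iou(a, matrix(FALSE, 10, 10)), "mismatch")
})

test_that("keypoint mean error in mm, overall and per role", {
  kp <- ref_keypoints()
  expect_equal(keypoint_me(kp, kp, c(0.5, 0.5))$me, 0)
  m <- keypoint_matrix(kp)
  m[, 1] <- m[, 1] + 3; m[, 2] <- m[, 2] + 4                # 5 px offset each
  expect_equal(keypoint_me(keypoints_from_matrix(m), kp, c(0.5, 0.5))$me, 2.5)
  m2 <- keypoint_matrix(kp); m2["spinous", 1] <- m2["spinous", 1] + 1
  r <- keypoint_me(keypoints_from_matrix(m2), kp, c(0.5, 0.5))
  expect_equal(r$me, 0.5 / 9)
  expect_equal(unname(r$per_role["spinous"]), 0.5)
  expect_equal(sum(r$per_role > 0), 1L)
})

test_that("classification metrics match the hand confusion matrix", {
  r <- classification_metrics(c("A", "B", "B", "B"), c("A", "A", "B", "B"))
  expect_equal(r$accuracy, 75)
  expect_equal(r$precision, 100 * (0.5 * 1 + 0.5 * 2 / 3))       # 83.33
  expect_equal(r$f1, 100 * (0.5 * 2 / 3 + 0.5 * 0.8))            # 73.33
  # perfect agreement is 100/100/100 under any scheme
  for (labels in list(c("A", "B", "C", "A"), rep("X", 5), 0:3)) {
    p <- classification_metrics(labels, labels)
    expect_equal(c(p$accuracy, p$precision, p$f1), c(100, 100, 100))
  }
  # macro differs from weighted on unbalanced refs
  rm_ <- classification_metrics(c("A", "B", "B", "B"), c("A", "A", "B", "B"),
                                average = "macro")
  expect_equal(rm_$precision, 100 * mean(c(1, 2 / 3)))
  expect_error(classification_metrics(c("A"), c("A", "B")), "mismatch")
})

test_that("Cohen's kappa matches hand computation, with asymptotic SE and CI", {
  k <- cohens_kappa(c("A", "A", "B", "A"), c("A", "A", "B", "B"))
  expect_equal(k$p_o, 0.75)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0.5)
  expect_equal(k$band, "moderate")
  # frozen against an independent large-sample implementation
  expect_equal(k$se, 0.375, tolerance = 1e-6)
  expect_equal(k$z, 1.1547, tolerance = 1e-4)
  expect_equal(k$p_value, 0.2482, tolerance = 1e-4)
  expect_equal(k$ci95, pmin(1, pmax(-1, 0.5 + c(-1, 1) * 1.96 * 0.375)))
  expect_false(k$significant)

  k1 <- cohens_kappa(c("A", "B", "A", "B"), c("A", "B", "A", "B"))
  expect_equal(k1$kappa, 1)
  expect_equal(k1$band, "excellent")
  expect_error(cohens_kappa(rep("A", 5), rep("A", 5)), "p_e = 1")
})

test_that("kappa is invariant under relabeling and near zero for independent labels", {
  set.seed(1234)
  x <- sample(letters[1:4], 200, replace = TRUE)
  y <- sample(letters[1:4], 200, replace = TRUE)
  k <- cohens_kappa(x, y)
  perm <- c(a = "w", b = "x", c = "y", d = "z")
  k2 <- cohens_kappa(unname(perm[x]), unname(perm[y]))
  expect_equal(k2$kappa, k$kappa)
  expect_equal(k2$se, k$se)
  xi <- sample(LETTERS[1:3], 1e4, replace = TRUE)
  yi <- sample(LETTERS[1:3], 1e4, replace = TRUE)
  expect_lt(abs(cohens_kappa(xi, yi)$kappa), 0.05)
})

test_that("agreement bands follow the stated cut-points on constructed vectors", {
  # balanced 2-class design: p_e = 0.5, so kappa = 2 p_o - 1 by construction
  ref <- rep(c("A", "B"), each = 50)
  flip <- function(nA, nB) {
    p <- ref; p[seq_len(nA)] <- "B"; p[50 + seq_len(nB)] <- "A"; p
  }
  expect_equal(cohens_kappa(flip(5, 5), ref)$kappa, 0.8)
  expect_equal(cohens_kappa(flip(5, 5), ref)$band, "high")        # 0.8 inclusive
  expect_equal(cohens_kappa(flip(4, 4), ref)$band, "excellent")   # 0.84
  expect_equal(cohens_kappa(flip(15, 15), ref)$kappa, 0.4)
  expect_equal(cohens_kappa(flip(15, 15), ref)$band, "poor")      # <= 0.4 is poor
  expect_equal(cohens_kappa(flip(12, 12), ref)$band, "moderate")  # 0.52
})

test_that("distribution tables carry counts, 2-decimal percentages and dashes", {
  # 198 of 400 at grade 0
  codes <- c(rep(0L, 198), rep(9L, 202))  # rest at CCZ grade 2
  t1 <- distribution_table(codes, rater = "orthopedist")
  expect_equal(t1$cells["NONE", "grade0"], "198(49.50)")
  expect_equal(t1$cells["CCZ", "grade2"], "202(50.50)")
  expect_equal(t1$cells["NONE", "grade1"], "-")
  expect_equal(t1$cells["LFZ", "grade2"], "-")
  expect_equal(sum(t1$counts), 400)
  expect_equal(sum(t1$pct, na.rm = TRUE), 100, tolerance = 0.01)
  # 137 of 1500 at (LFZ, 1)
  codes2 <- c(rep(4L, 137), rep(0L, 1363))
  t2 <- distribution_table(codes2)
  expect_equal(t2$cells["LFZ", "grade1"], "137(9.13)")
  # empty input -> all-zero table
  t0 <- distribution_table(integer())
  expect_equal(sum(t0$counts), 0)
  expect_true(all(t0$pct[!is.na(t0$pct)] == 0))
  # a count in a structural-dash cell is rejected
  bad <- matrix(0L, 8, 4); bad[3, 3] <- 5L  # LFZ grade 2
  expect_error(distribution_table(counts = bad), "no such classification")
})

test_that("agreement_report projects codes through the three schemes", {
  set.seed(8)
  lat <- enumerate_categories()
  ref <- sample(lat$code, 300, replace = TRUE)
  pred <- ifelse(runif(300) < 0.8, ref, sample(lat$code, 300, replace = TRUE))
  r18 <- agreement_report(pred, ref, "cat18")
  r4 <- agreement_report(pred, ref, "grade4")
  r8 <- agreement_report(pred, ref, "region8")
  expect_gte(r4$accuracy, r18$accuracy)  # margins can only agree more
  expect_gte(r8$accuracy, r18$accuracy)
  expect_true(r18$kappa$kappa <= 1 && r18$kappa$kappa >= -1)
  expect_true(r18$kappa$ci95[1] <= r18$kappa$kappa &&
                r18$kappa$kappa <= r18$kappa$ci95[2])
})
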