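test_that("phantoms are deterministic for a fixed seed", {
  s <- phantom_spec(target_region = "CCZ", target_grade = 3, seed = 42,
                    intensity_sigma = 0.05, kp_jitter_sigma_mm = 0.5)
  a <- make_phantom(s); b <- make_phantom(s)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$disc$mask, b$disc$mask)
  expect_identical(keypoint_matrix(a$keypoints), keypoint_matrix(b$keypoints))
})

test_that("inconsistent grade/depth specifications are rejected", {
  expect_error(phantom_spec(target_grade = 2, D_target = 8), "implies grade")
  expect_error(phantom_spec(target_grade = 0, target_region = "CCZ"), "NONE")
  expect_error(phantom_spec(target_region = "LFZ", target_grade = 2),
               "no such classification")
})

test_that("noise-free phantoms round-trip their category and depth", {
  # grade 3 in the central canal: D 8 mm, I 0.4
  ph <- make_phantom(phantom_spec(target_region = "CCZ", target_grade = 3,
                                  D_target = 8, seed = 9))
  res <- quantify_case(ph$image, ph$disc, ph$keypoints)
  expect_equal(res$category$region, "CCZ")
  expect_equal(res$category$grade, 3L)
  # measured D within one pixel diagonal (0.71 mm at 0.5 mm/px) of target
  expect_lt(abs(res$measurement$D - 8), sqrt(2) * 0.5)
  expect_lt(abs(res$measurement$u_apex - ph$truth$u_apex), sqrt(2) * 0.5)
  # truth is what the quantification reproduces
  expect_equal(res$category$code, ph$truth$code)
})

test_that("the jittered keypoints differ from truth but truth is pre-jitter", {
  ph <- make_phantom(phantom_spec(target_region = "LSAZ", target_grade = 2,
                                  kp_jitter_sigma_mm = 0.5, seed = 10))
  expect_false(identical(keypoint_matrix(ph$keypoints),
                         keypoint_matrix(ph$keypoints_true)))
  res_true <- quantify_case(ph$image, ph$disc, ph$keypoints_true)
  expect_equal(res_true$category$code, ph$truth$code)
})

test_that("a degenerate mix yields a single-category cohort with manifest", {
  mix <- rep(0, 18); mix[enumerate_categories()$code[
    enumerate_categories()$region == "CCZ" &
      enumerate_categories()$grade == 1] + 1] <- 1
  coh <- sample_cohort(20, mix = mix, seed = 11, image_size = 256)
  expect_length(coh$cases, 20)
  expect_true(all(coh$manifest$region == "CCZ"))
  expect_true(all(coh$manifest$grade == 1L))
  expect_equal(nrow(coh$manifest), 20)
  # empty cohort is valid
  c0 <- sample_cohort(0, seed = 1)
  expect_length(c0$cases, 0)
  expect_equal(nrow(c0$manifest), 0)
  expect_error(sample_cohort(5, mix = rep(0.1, 18)), "summing to 1")
})

test_that("cohort category frequencies follow the sampling mix", {
  mix <- default_category_mix()
  expect_equal(sum(mix), 1, tolerance = 1e-12)
  coh <- sample_cohort(600, seed = 12, image_size = 128, spacing = c(2, 2))
  tab <- table(factor(coh$manifest$code, levels = 0:17)) / 600
  # within 3 binomial SEs per category
  se <- sqrt(mix * (1 - mix) / 600)
  expect_true(all(abs(as.numeric(tab) - mix) <= 3 * se + 1e-9))
})

test_that("cohort determinism: same seed gives identical manifests", {
  a <- sample_cohort(15, seed = 77, image_size = 128, spacing = c(2, 2))
  b <- sample_cohort(15, seed = 77, image_size = 128, spacing = c(2, 2))
  expect_identical(a$manifest, b$manifest)
})
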