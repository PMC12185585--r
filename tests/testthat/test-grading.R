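mk_meas <- function(D, L_sag = 20) list(D = D, I = max(D, 0) / L_sag, u_apex = 0)

test_that("the grade rule and its boundary conventions", {
  th <- grading_thresholds()
  expect_equal(assign_grade(mk_meas(-10), th), 0L)
  expect_equal(assign_grade(mk_meas(-2), th), 1L)
  expect_equal(assign_grade(mk_meas(4), th), 2L)    # I = 0.2
  expect_equal(assign_grade(mk_meas(7), th), 3L)    # I = 0.35
  # boundaries: D = -3 and D = 0 are grade 1; I = 0.3 exactly is grade 2
  expect_equal(assign_grade(mk_meas(-3), th), 1L)
  expect_equal(assign_grade(mk_meas(0), th), 1L)
  expect_equal(assign_grade(mk_meas(6), th), 2L)    # I = 0.3
  expect_equal(assign_grade(mk_meas(6 + 1e-9), th), 3L)
})

test_that("grade is monotone non-decreasing in D for fixed L_sag", {
  th <- grading_thresholds()
  D <- seq(-12, 12, by = 0.05)
  g <- vapply(D, function(d) assign_grade(mk_meas(d), th), integer(1))
  expect_true(all(diff(g) >= 0))
  expect_setequal(unique(g), 0:3)
})

test_that("region assignment maps grade 0 to NONE and the apex zone otherwise", {
  fr <- ref_frame()
  expect_equal(assign_region(mk_meas(-10), fr, 0L), "NONE")
  expect_equal(assign_region(list(D = 4, I = 0.2, u_apex = 0), fr, 2L), "CCZ")
  expect_equal(assign_region(list(D = -1, I = 0, u_apex = 20), fr, 1L), "LSAZ")
  expect_equal(assign_region(list(D = -1, I = 0, u_apex = -30), fr, 1L), "RFZ")
  expect_equal(assign_region(list(D = -1, I = 0, u_apex = 45), fr, 1L), "LEFZ")
})

test_that("the category lattice has exactly 18 members with 4/8 projections", {
  lat <- enumerate_categories()
  expect_equal(nrow(lat), 18L)
  expect_equal(lat$code, 0:17)
  expect_equal(length(attr(lat, "grades")), 4L)
  expect_equal(length(attr(lat, "regions")), 8L)
  # row structure: 1 + 3 + 1 + 3 + 3 + 3 + 1 + 3
  expect_equal(as.integer(table(factor(lat$region, attr(lat, "regions")))),
               c(1L, 3L, 1L, 3L, 3L, 3L, 1L, 3L))
  # grade 0 exists only as NONE; foraminal zones only carry grade 1
  expect_true(all((lat$grade == 0) == (lat$region == "NONE")))
  expect_true(all(lat$grade[lat$region %in% c("LFZ", "RFZ")] == 1L))
})

test_that("encoding is a bijection between valid pairs and codes 0-17", {
  lat <- enumerate_categories()
  codes <- mapply(function(r, g) encode_category(r, g)$code, lat$region, lat$grade)
  expect_equal(sort(as.integer(codes)), 0:17)
  # projections commute with encoding
  for (i in seq_len(nrow(lat))) {
    ct <- encode_category(lat$region[i], lat$grade[i])
    expect_true(ct$valid)
    expect_equal(project_category(ct$code, "grade4"), lat$grade[i])
    expect_equal(project_category(ct$code, "region8"), lat$region[i])
  }
})

test_that("out-of-lattice pairs clamp with an audit flag or reject", {
  expect_warning(ct <- encode_category("LFZ", 2, policy = "clamp"), "clamp")
  expect_equal(ct$grade, 1L)
  expect_false(ct$valid)
  expect_equal(ct$region, "LFZ")
  expect_error(encode_category("RFZ", 3, policy = "reject"), "no such classification")
  expect_error(encode_category("CCZ", 0, policy = "reject"), "NONE")
})

test_that("every (D, I, u) input yields exactly one category", {
  fr <- ref_frame()
  th <- grading_thresholds()
  set.seed(13)
  for (k in 1:200) {
    m <- list(D = runif(1, -15, 12), u_apex = runif(1, -55, 55))
    m$I <- max(m$D, 0) / fr$L_sag
    g <- assign_grade(m, th)
    r <- assign_region(m, fr, g)
    ct <- suppressWarnings(encode_category(r, g))
    expect_true(ct$code %in% 0:17)
    expect_equal((ct$grade == 0), (ct$region == "NONE"))
  }
})
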