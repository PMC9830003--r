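test_that("roi_mean_curve averages frames over mask pixels", {
  fr <- array(5, dim = c(4, 3, 3))
  st <- image_stack(fr, 1, "swir")
  expect_equal(roi_mean_curve(st, matrix(TRUE, 3, 3)), rep(5, 4))

  # single-pixel mask returns that pixel's series
  fr2 <- array(0, dim = c(3, 2, 2))
  fr2[, 2, 1] <- c(0.1, 0.4, 0.9)
  st2 <- image_stack(fr2, 1, "swir")
  m <- matrix(FALSE, 2, 2); m[2, 1] <- TRUE
  expect_equal(roi_mean_curve(st2, m), c(0.1, 0.4, 0.9))

  # two-pixel mask with series (1,3) and (3,5) -> (2,4)
  fr3 <- array(0, dim = c(2, 2, 2))
  fr3[, 1, 1] <- c(1, 3); fr3[, 1, 2] <- c(3, 5)
  st3 <- image_stack(fr3, 1, "swir")
  m3 <- matrix(FALSE, 2, 2); m3[1, ] <- TRUE
  expect_equal(roi_mean_curve(st3, m3), c(2, 4))

  expect_error(roi_mean_curve(st, matrix(FALSE, 3, 3)), "empty")
  expect_error(roi_mean_curve(st, matrix(TRUE, 2, 2)), "mask is")
})

test_that("delta_I and delta_Q match brute-force summation and frozen examples", {
  expect_identical(delta_I(c(5, 5, 5)), 0)
  expect_identical(delta_I(c(1, 2, 3)), 3)
  expect_identical(delta_I(c(3, 1, 2)), 3)  # min is global, not first-frame
  expect_identical(delta_Q(c(294, 294)), 0)
  expect_identical(delta_Q(c(294, 292, 293)), 3)

  set.seed(101)
  for (i in 1:100) {
    # integer-valued curves: summation is exact, so identity must be exact
    curve <- round(rnorm(sample(2:80, 1), mean = 10000, sd = 1000))
    expect_identical(delta_I(curve), oracle_delta_I(curve))
    expect_identical(delta_Q(curve), oracle_delta_Q(curve))
    # continuous curves: agreement to accumulation rounding
    curve2 <- rnorm(sample(2:80, 1), mean = 100, sd = 10)
    expect_equal(delta_I(curve2), oracle_delta_I(curve2), tolerance = 1e-12)
    expect_equal(delta_Q(curve2), oracle_delta_Q(curve2), tolerance = 1e-12)
  }

  expect_error(delta_I(c(1, NA, 3)), "non-finite")
  expect_error(delta_Q(c(1, Inf)), "non-finite")
  expect_error(delta_I(5), "at least 2")
})

test_that("delta statistics obey duality, shift invariance and homogeneity", {
  set.seed(7)
  for (i in 1:50) {
    x <- rnorm(30)
    expect_equal(delta_Q(x), delta_I(-x))
    expect_equal(delta_I(x + 17.3), delta_I(x))
    c_pos <- runif(1, 0.1, 5)
    expect_equal(delta_I(c_pos * x), c_pos * delta_I(x))
  }
})

test_that("contrast_metrics forms L-C and L/C, flagging a zero control", {
  cm <- contrast_metrics(10, 4)
  expect_equal(cm$diff, 6)
  expect_equal(cm$ratio, 2.5)
  expect_true(cm$ratio_defined)

  cm2 <- contrast_metrics(4, 4)
  expect_equal(cm2$diff, 0)
  expect_equal(cm2$ratio, 1)

  cm3 <- contrast_metrics(4, 0)
  expect_equal(cm3$diff, 4)
  expect_true(is.na(cm3$ratio))
  expect_false(cm3$ratio_defined)

  expect_error(contrast_metrics(-1, 2), "non-negative")
})

test_that("integrated_heatmap computes per-pixel deltas", {
  fr <- array(2, dim = c(3, 4, 5))
  st <- image_stack(fr, 1, "swir")
  expect_equal(integrated_heatmap(st), matrix(0, 4, 5))

  fr[, 2, 3] <- c(1, 2, 3)
  st <- image_stack(fr, 1, "swir")
  hm <- integrated_heatmap(st)
  expect_equal(hm[2, 3], 3)
  expect_equal(sum(hm), 3)

  # thermal twin uses the max-anchored integral
  frt <- array(294, dim = c(3, 2, 2))
  frt[, 1, 1] <- c(294, 292, 293)
  hmt <- integrated_heatmap(image_stack(frt, 1, "thermal"))
  expect_equal(hmt[1, 1], 3)
  expect_equal(sum(hmt), 3)
})

test_that("ROI-averaged heatmap dominates the ROI-curve delta (SWIR)", {
  # per-pixel minima <= pixel values at the curve's argmin, so the
  # average of per-pixel deltas >= delta of the mean curve
  set.seed(33)
  for (i in 1:25) {
    fr <- array(runif(5 * 4 * 4), dim = c(5, 4, 4))
    st <- image_stack(fr, 1, "swir")
    mask <- matrix(runif(16) < 0.6, 4, 4)
    if (!any(mask)) mask[1, 1] <- TRUE
    hm_avg <- mean(integrated_heatmap(st)[mask])
    roi_delta <- delta_I(roi_mean_curve(st, mask))
    expect_gte(hm_avg, roi_delta - 1e-12)
  }
})

test_that("stack and ROI validation reject malformed inputs", {
  expect_error(image_stack(array(1, dim = c(1, 4, 4)), 1, "swir"), "2 frames")
  expect_error(image_stack(array(NA_real_, dim = c(3, 4, 4)), 1, "swir"), "non-finite")
  expect_error(image_stack(array(100, dim = c(3, 4, 4)), 1, "thermal"), "kelvin")
  les <- matrix(FALSE, 4, 4); les[1:2, 1:2] <- TRUE
  expect_error(roi_pair(les, les), "disjoint")
  expect_error(roi_pair(les, matrix(FALSE, 4, 4)), "empty")
  expect_error(roi_pair(matrix(0.5, 4, 4), les), "non-binary")
})
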