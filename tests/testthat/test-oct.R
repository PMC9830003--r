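test_that("detect_surface finds flat and tilted boundaries, flags empty columns", {
  b <- manual_bscan(surface_row = 10)
  expect_equal(detect_surface(b), rep(10L, 40))

  # tilted surface: rows 10 -> 20 across 40 columns
  img <- matrix(0, 120, 40)
  rows <- round(seq(10, 20, length.out = 40))
  for (j in 1:40) img[rows[j]:120, j] <- 0.5
  surf <- detect_surface(bscan(img, 5))
  expect_true(all(diff(surf) >= 0))
  expect_equal(surf[1], 10L)
  expect_equal(surf[40], 20L)

  allzero <- bscan(matrix(0, 50, 20), 5)
  expect_true(all(is.na(detect_surface(allzero))))
})

test_that("segment_lesion isolates the body band and stays below the surface", {
  # sound tissue: Otsu will split the attenuation tail, validation rejects it
  sound <- manual_bscan()
  expect_false(any(segment_lesion(sound)))

  body_rows <- 11:42
  les <- manual_bscan(body_rows = body_rows)
  mask <- segment_lesion(les)
  truth_mask <- matrix(FALSE, 120, 40); truth_mask[body_rows, ] <- TRUE
  expect_gte(sum(mask & truth_mask) / sum(truth_mask), 0.9)
  surf <- detect_surface(les)
  for (j in which(colSums(mask) > 0))
    expect_gt(min(which(mask[, j])), surf[j])
})

test_that("lesion depth applies the 1.6 refractive correction exactly", {
  # 32 body rows below the surface at 5 um optical pitch -> 100 um tissue
  b <- manual_bscan(surface_row = 10, body_rows = 11:42, pitch = 5)
  mask <- segment_lesion(b)
  ld <- lesion_depth(mask, b)
  expect_equal(ld$depth_um, 32 * 5 / 1.6)
  expect_equal(ld$depth_um, 100)
  expect_true(ld$lesion_present)

  # doubling the axial pitch doubles the reported depth
  b2 <- manual_bscan(surface_row = 10, body_rows = 11:42, pitch = 10)
  expect_equal(lesion_depth(mask, b2)$depth_um, 200)

  empty <- matrix(FALSE, 120, 40)
  ld0 <- lesion_depth(empty, b)
  expect_equal(ld0$depth_um, 0)
  expect_false(ld0$lesion_present)
})

test_that("integrated reflectivity is the plain mask mean", {
  b <- bscan(matrix(0.5, 10, 10), 5)
  expect_equal(integrated_reflectivity(b, matrix(TRUE, 10, 10)), 0.5)

  img <- matrix(0, 10, 10); img[3, 4] <- 0.1; img[5, 6] <- 0.3
  m <- img > 0
  expect_equal(integrated_reflectivity(bscan(img, 5), m), 0.2)
  expect_error(integrated_reflectivity(b, matrix(FALSE, 10, 10)), "empty")

  # lesion rendering outshines sound tissue over the same geometry
  les <- render_oct_bscan(make_truth(depth = 120, ml = 0.2))
  snd <- render_oct_bscan(make_truth(depth = 120, ml = 0))
  roi <- matrix(FALSE, nrow(les$image), ncol(les$image))
  roi[21:50, attr(les, "roi_cols")] <- TRUE
  expect_gt(integrated_reflectivity(les, roi),
            integrated_reflectivity(bscan(snd$image[1:nrow(roi), 1:ncol(roi)], 5), roi))
})

test_that("detect_tsl measures the transparent band and honors the detection floor", {
  none <- render_oct_bscan(make_truth(tsl = 0, depth = 150, ml = 0.2))
  r0 <- detect_tsl(none, attr(none, "roi_cols"))
  expect_false(r0$tsl_detected)
  expect_equal(r0$tsl_thickness_um, 0)

  fifty <- render_oct_bscan(make_truth(tsl = 50, depth = 180, ml = 0.2),
                            axial_pitch_um_optical = 5)
  r50 <- detect_tsl(fifty, attr(fifty, "roi_cols"))
  expect_true(r50$tsl_detected)
  expect_lt(abs(r50$tsl_thickness_um - 50), 5 / 1.6)

  # a 10 um TSL at a pitch that yields < 2 rows is below the floor
  thin <- render_oct_bscan(make_truth(tsl = 10, depth = 150, ml = 0.2),
                           axial_pitch_um_optical = 15)
  rt <- detect_tsl(thin, attr(thin, "roi_cols"))
  expect_false(rt$tsl_detected)
  expect_equal(rt$tsl_thickness_um, 0)

  sound <- render_oct_bscan(make_truth(ml = 0))
  expect_error(detect_tsl(sound, attr(sound, "roi_cols")), "lesion")
})

test_that("OCT morphometry recovers depth and TSL from noisy B-scans", {
  cfg <- cohort_config(n_lesions = 15, seed = 21, tsl_range_um = c(15, 90))
  cohort <- sample_cohort(cfg)
  pitch <- cfg$oct_pitch_um
  # noise-free: recovery within one axial pixel over 1.6
  for (i in seq_len(nrow(cohort))) {
    b <- render_oct_bscan(cohort[i, ], axial_pitch_um_optical = pitch, noise_sd = 0)
    m <- measure_bscan(b)
    expect_lt(abs(m$lesion_depth_um - cohort$lesion_depth_um[i]), pitch / 1.6 + 1e-9)
    if (cohort$tsl_thickness_um[i] > 0) {
      expect_true(m$tsl_detected)
      expect_lt(abs(m$tsl_thickness_um - cohort$tsl_thickness_um[i]), pitch / 1.6 + 1e-9)
    }
  }
  # noise at 10% of body contrast: median absolute error within 2 px / 1.6
  errs_ld <- errs_tsl <- numeric(0)
  for (i in seq_len(nrow(cohort))) {
    b <- render_oct_bscan(cohort[i, ], axial_pitch_um_optical = pitch, noise_sd = 0.09)
    m <- measure_bscan(b)
    errs_ld <- c(errs_ld, abs(m$lesion_depth_um - cohort$lesion_depth_um[i]))
    if (cohort$tsl_thickness_um[i] > 0 && m$tsl_detected)
      errs_tsl <- c(errs_tsl, abs(m$tsl_thickness_um - cohort$tsl_thickness_um[i]))
  }
  expect_lte(median(errs_ld), 2 * pitch / 1.6)
  expect_lte(median(errs_tsl), 2 * pitch / 1.6)
})
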