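test_that("permeability decays with TSL thickness and hits the arrest regime", {
  expect_equal(permeability_from_tsl(0, 1), 1)
  expect_lte(permeability_from_tsl(70, 1), 0.05)
  expect_equal(permeability_from_tsl(70, 1), 0.05)  # calibration of the decay
  expect_gte(permeability_from_tsl(35, 1), permeability_from_tsl(36, 1))
  tsl <- seq(0, 200, by = 0.5)
  p <- permeability_from_tsl(tsl)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0))
  expect_equal(permeability_from_tsl(35, 2), 2 * permeability_from_tsl(35, 1))
  expect_error(permeability_from_tsl(-1), ">= 0")
  expect_error(permeability_from_tsl(10, baseline = 0), "positive")
})

test_that("sample_cohort is seed-deterministic and respects its ranges", {
  cfg <- cohort_config(n_lesions = 5, seed = 7)
  expect_identical(sample_cohort(cfg), sample_cohort(cfg))

  one <- sample_cohort(cohort_config(n_lesions = 1, seed = 3))
  expect_equal(nrow(one), 1)
  expect_true(one$mineral_loss_frac >= 0 && one$mineral_loss_frac <= 1)
  expect_true(one$water_pool_frac >= 0 && one$water_pool_frac <= 1)
  expect_gte(one$lesion_depth_um, one$tsl_thickness_um)

  big <- sample_cohort(cohort_config(n_lesions = 100, tsl_range_um = c(0, 100), seed = 5))
  expect_lt(min(big$tsl_thickness_um), 20)
  expect_gt(max(big$tsl_thickness_um), 80)
  expect_equal(big$permeability, permeability_from_tsl(big$tsl_thickness_um))
  expect_true(all(big$water_pool_frac[big$surface_type == "smooth"] == 0))
  expect_true(all(big$lesion_depth_um >= big$tsl_thickness_um + 40))

  expect_error(cohort_config(tsl_range_um = c(50, 10)), "interval")
  expect_error(cohort_config(n_lesions = 0), "n_lesions")
})

test_that("SWIR rendering: null lesion, monotone drying, permeability-dependent rate", {
  cfg <- quiet_config()
  # zero mineral loss, zero pooling: lesion and control curves identical
  null_out <- render_swir_stack(make_truth(ml = 0), cfg)
  cl <- roi_mean_curve(null_out$stack, null_out$rois$lesion_mask)
  cc <- roi_mean_curve(null_out$stack, null_out$rois$control_mask)
  expect_equal(cl, cc, tolerance = 1e-12)

  # noise-free lesion curve is nondecreasing with its minimum at frame 0
  act <- render_swir_stack(make_truth(tsl = 20, ml = 0.25), cfg)
  curve <- roi_mean_curve(act$stack, act$rois$lesion_mask)
  expect_true(all(diff(curve) >= -1e-12))
  expect_equal(which.min(curve), 1L)

  # control near-flat: amplitude <= 10% of an active lesion's
  ctl <- roi_mean_curve(act$stack, act$rois$control_mask)
  expect_lte(diff(range(ctl)), 0.1 * diff(range(curve)))

  # high-permeability lesion reaches 90% of its plateau earlier
  t90 <- function(tsl) {
    out <- render_swir_stack(make_truth(tsl = tsl, ml = 0.2), cfg)
    cv <- roi_mean_curve(out$stack, out$rois$lesion_mask)
    amp <- cv - cv[1]
    which(amp >= 0.9 * max(amp))[1]
  }
  expect_lt(t90(0), t90(60))
})

test_that("SWIR ROI curve equals the stated logistic model evaluated analytically", {
  cfg <- quiet_config()
  truth <- make_truth(tsl = 30, ml = 0.2, seed = 9)
  out <- render_swir_stack(truth, cfg)
  curve <- roi_mean_curve(out$stack, out$rois$lesion_mask)
  # independent evaluation of the documented model
  t <- 0:59
  p <- exp(-30 / (70 / log(20)))
  rise <- function(k, t50) (plogis(k * (t - t50)) - plogis(-k * t50)) / (1 - plogis(-k * t50))
  wet <- withr::with_seed(9, runif(1, 0.5, 1.5))
  expected <- 0.2 + 0.004 * wet * rise(0.5, 5) +
    0.5 * 0.2 * rise(0.25 * p + 0.005, 8 + 30 * (1 - p))
  expect_equal(curve, expected, tolerance = 1e-10)
})

test_that("thermal rendering: drop-then-recover, pooling effect, dry null", {
  cfg <- quiet_config()
  out <- render_thermal_stack(make_truth(tsl = 10, ml = 0.25), cfg)
  curve <- roi_mean_curve(out$stack, out$rois$lesion_mask)
  expect_equal(curve[1], 294.15, tolerance = 1e-9)  # starts at ambient
  expect_gt(which.min(curve), 1)                    # minimum after onset
  expect_gt(curve[length(curve)], min(curve))       # recovery under way
  # lesion cools more than control for an active lesion
  ctl <- roi_mean_curve(out$stack, out$rois$control_mask)
  expect_gt(delta_Q(curve), delta_Q(ctl))

  # water pooling on an occlusal surface deepens the drop
  dry <- render_thermal_stack(make_truth(ml = 0.2, pool = 0, surface = "occlusal"), cfg)
  wet <- render_thermal_stack(make_truth(ml = 0.2, pool = 1, surface = "occlusal"), cfg)
  expect_lt(min(roi_mean_curve(wet$stack, wet$rois$lesion_mask)),
            min(roi_mean_curve(dry$stack, dry$rois$lesion_mask)))

  # arrested (permeability ~ 0) lesion on a dry surface stays at ambient
  arr <- make_truth(tsl = 300, ml = 0.2)
  out0 <- render_thermal_stack(arr, cfg, base_drop_K = 0)
  c0 <- roi_mean_curve(out0$stack, out0$rois$lesion_mask)
  expect_lt(max(abs(c0 - 294.15)), 0.01)
  # and under the default wet surface it matches its own control
  outw <- render_thermal_stack(arr, cfg)
  expect_equal(roi_mean_curve(outw$stack, outw$rois$lesion_mask),
               roi_mean_curve(outw$stack, outw$rois$control_mask),
               tolerance = 0.02)
})

test_that("OCT rendering places bands in optical units with saturating reflectivity", {
  # no TSL: the brightest band starts at the surface row
  b0 <- render_oct_bscan(make_truth(tsl = 0, depth = 100, ml = 0.2),
                         axial_pitch_um_optical = 5)
  j <- attr(b0, "roi_cols")[5]
  col <- b0$image[, j]
  body_rows <- which(col == max(col))
  expect_equal(min(body_rows), 20)  # surface_row default
  # depth 100 um at 5 um optical pitch: body spans 160/5 = 32 rows
  expect_equal(length(body_rows), 33)  # rows s0 .. s0 + 32 inclusive
  expect_equal(max(body_rows) - min(body_rows), 32)

  # a TSL renders as a dark band of tsl * 1.6 / pitch rows under the surface
  b1 <- render_oct_bscan(make_truth(tsl = 50, depth = 150, ml = 0.2),
                         axial_pitch_um_optical = 5)
  col1 <- b1$image[, attr(b1, "roi_cols")[5]]
  expect_equal(sum(col1 == 0.06), round(50 * 1.6 / 5))

  # body reflectivity saturates at 15% mineral loss
  b15 <- render_oct_bscan(make_truth(depth = 100, ml = 0.15))
  b30 <- render_oct_bscan(make_truth(depth = 100, ml = 0.30))
  expect_equal(max(b15$image), max(b30$image))
  b05 <- render_oct_bscan(make_truth(depth = 100, ml = 0.05))
  expect_lt(max(b05$image), max(b15$image))
})

test_that("MicroCT rendering: flat sound null, SL band width, gray ordering", {
  ct0 <- render_microct_slice(make_truth(ml = 0), pitch_um = 10)
  below <- ct0$image[20:nrow(ct0$image), ]
  expect_true(all(below == 0.75))

  ct <- render_microct_slice(make_truth(depth = 200, ml = 0.2), pitch_um = 10,
                             sl_thickness_um = 70)
  col <- ct$image[, attr(ct, "roi_cols")[5]]
  expect_equal(sum(col == max(col)), 7)  # 70 um / 10 um = 7 elevated px
  sound <- 0.75
  body <- min(col[col > 0.05])
  expect_lt(body, sound)
  expect_gt(max(col), sound)
})

test_that("rendering is bit-identical under a fixed seed and config", {
  cfg <- cohort_config(n_lesions = 1, seed = 4)  # default (noisy) settings
  truth <- make_truth(tsl = 25, ml = 0.2, seed = 77)
  a <- render_swir_stack(truth, cfg)
  b <- render_swir_stack(truth, cfg)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(render_thermal_stack(truth, cfg)$stack$frames,
                   render_thermal_stack(truth, cfg)$stack$frames)
  expect_identical(render_oct_bscan(truth, noise_sd = 0.02)$image,
                   render_oct_bscan(truth, noise_sd = 0.02)$image)
  expect_identical(render_microct_slice(truth, noise_sd = 0.02)$image,
                   render_microct_slice(truth, noise_sd = 0.02)$image)
})

test_that("thicker TSL yields smaller noise-free dehydration contrasts", {
  cfg <- quiet_config()
  contrasts <- vapply(c(0, 20, 45, 70, 100), function(tsl) {
    tr <- make_truth(tsl = tsl, depth = tsl + 120, ml = 0.2)
    sw <- render_swir_stack(tr, cfg)
    th <- render_thermal_stack(tr, cfg)
    c(analyze_dehydration(sw$stack, sw$rois)$diff,
      analyze_dehydration(th$stack, th$rois)$diff)
  }, numeric(2))
  expect_true(all(diff(contrasts[1, ]) < 0))
  expect_true(all(diff(contrasts[2, ]) < 0))
})
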