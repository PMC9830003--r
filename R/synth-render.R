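#' Noise-free SWIR drying curve model
#'
#' During forced-air drying, water leaves the pores of a lesion and stops
#' absorbing the incident SWIR light, so reflectance rises along a
#' sigmoid. The model is a logistic rise anchored at the wet state:
#' `I(t) = base + sound_amp * sound_scale * g_s(t) +
#'  lesion_amp * mineral_loss_frac * g_p(t)`
#' where `g(t) = (s(k(t - t50)) - s(-k t50)) / (1 - s(-k t50))` is a
#' logistic normalized so `g(0) = 0` and `g(Inf) = 1` (`s` the standard
#' logistic). The lesion rate constant and delay follow permeability:
#' `k = 0.25 p_rel + 0.005` per second and `t50 = 8 + 30 (1 - p_rel)`
#' seconds with `p_rel = permeability / baseline` clamped to \[0, 1\], so
#' arrested lesions both rise slowly and rise late, and the plateau
#' amplitude scales with mineral loss (scattering volume). Sound enamel
#' dries too, but with a small fixed amplitude (`k = 0.5`, `t50 = 5`).
#'
#' @param t_s Time in seconds (vectorized), `>= 0`.
#' @param permeability Lesion permeability, `>= 0` (see
#'   [permeability_from_tsl()]).
#' @param mineral_loss_frac Mineral loss fraction in \[0, 1\]; 0 means
#'   sound tissue.
#' @param baseline Permeability scale that maps to `p_rel = 1`.
#' @param base_intensity Wet reflectance level.
#' @param sound_amp Drying amplitude of sound enamel.
#' @param sound_scale Per-tooth multiplier on the sound term (surface
#'   wetness varies tooth to tooth; shared by lesion and control ROIs).
#' @param lesion_amp Reflectance gain of a fully demineralized, fully
#'   dried lesion.
#' @return Reflectance values in \[0, 1\], same length as `t_s`.
#' @export
swir_drying_curve <- function(t_s, permeability, mineral_loss_frac,
                              baseline = 1, base_intensity = 0.2,
                              sound_amp = 0.004, sound_scale = 1,
                              lesion_amp = 0.5) {
  stopifnot(all(t_s >= 0), permeability >= 0,
            mineral_loss_frac >= 0, mineral_loss_frac <= 1)
  p_rel <- min(max(permeability / baseline, 0), 1)
  k <- 0.25 * p_rel + 0.005
  t50 <- 8 + 30 * (1 - p_rel)
  base_intensity +
    sound_amp * sound_scale * logistic_rise(t_s, 0.5, 5) +
    lesion_amp * mineral_loss_frac * logistic_rise(t_s, k, t50)
}

# Logistic rise normalized to start at 0 at t = 0 and saturate at 1.
logistic_rise <- function(t, k, t50) {
  s0 <- stats::plogis(-k * t50)
  (stats::plogis(k * (t - t50)) - s0) / (1 - s0)
}

#' Noise-free thermal drying curve model
#'
#' Evaporative cooling during forced-air drying produces an initial
#' temperature drop followed by recovery to ambient, modelled as a double
#' exponential `T(t) = T_amb - A * h(t)` with
#' `h(t) = (exp(-t/15) - exp(-t/3)) / max(h)` so `A` is the peak drop in
#' kelvin. The drop decomposes into a uniform surface-water term (the
#' whole tooth is wet when it leaves the water bath; `base_drop_K`,
#' scaled per tooth by `base_scale`), an evaporative term proportional to
#' permeability and to pore volume (mineral loss, saturating at 15%), and
#' a crevice-pooling term proportional to `water_pool_frac`.
#'
#' @inheritParams swir_drying_curve
#' @param water_pool_frac Extra retained surface water in \[0, 1\]
#'   (crevices, margins; mostly an occlusal/incisal phenomenon).
#' @param ambient_K Ambient temperature (default 294.15 K).
#' @param base_drop_K Peak drop of a sound wet surface, kelvin.
#' @param base_scale Per-tooth multiplier on the surface-water term.
#' @param evap_drop_K Peak drop of a fully permeable, fully porous lesion.
#' @param pool_drop_K Peak drop contributed by complete crevice pooling.
#' @return Temperatures in kelvin, same length as `t_s`.
#' @export
thermal_cooling_curve <- function(t_s, permeability, mineral_loss_frac,
                                  water_pool_frac = 0, baseline = 1,
                                  ambient_K = 294.15, base_drop_K = 0.3,
                                  base_scale = 1, evap_drop_K = 1.2,
                                  pool_drop_K = 1.5) {
  stopifnot(all(t_s >= 0), permeability >= 0,
            mineral_loss_frac >= 0, mineral_loss_frac <= 1,
            water_pool_frac >= 0, water_pool_frac <= 1)
  p_rel <- min(max(permeability / baseline, 0), 1)
  f_ml <- min(mineral_loss_frac, 0.15) / 0.15
  a <- base_drop_K * base_scale + evap_drop_K * p_rel * f_ml +
    pool_drop_K * water_pool_frac
  ambient_K - a * cooling_shape(t_s)
}

# Drop-then-recover shape, normalized to peak 1.
cooling_shape <- function(t, tau_slow = 15, tau_fast = 3) {
  t_peak <- log(tau_slow / tau_fast) / (1 / tau_fast - 1 / tau_slow)
  h_peak <- exp(-t_peak / tau_slow) - exp(-t_peak / tau_fast)
  (exp(-t / tau_slow) - exp(-t / tau_fast)) / h_peak
}

# Rectangular ROI geometry on the frame grid, by fractions of the image.
# The lesion and control ROIs are disjoint; when a composite restoration
# is present it occupies a lateral band excluded from both.
roi_geometry <- function(shape, has_composite = FALSE) {
  h <- shape[1]; w <- shape[2]
  rows <- seq(max(1L, round(0.35 * h)), round(0.65 * h))
  lesion_cols <- seq(round(0.26 * w), round(0.48 * w))
  control_cols <- seq(round(0.62 * w), round(0.86 * w))
  composite_cols <- if (has_composite) seq(max(1L, round(0.06 * w)), round(0.18 * w)) else integer(0)
  list(rows = rows, lesion_cols = lesion_cols, control_cols = control_cols,
       composite_cols = composite_cols)
}

as_lesion_truth <- function(truth) {
  if (inherits(truth, "data.frame")) {
    stopifnot(nrow(truth) == 1L)
    truth <- as.list(truth)
  }
  needed <- c("lesion_depth_um", "tsl_thickness_um", "mineral_loss_frac",
              "permeability", "water_pool_frac")
  missing <- setdiff(needed, names(truth))
  if (length(missing))
    stop("lesion truth lacks fields: ", paste(missing, collapse = ", "))
  if (is.null(truth$surface_type)) truth$surface_type <- "smooth"
  if (is.null(truth$has_composite)) truth$has_composite <- FALSE
  if (is.null(truth$render_seed)) truth$render_seed <- 1L
  stopifnot(truth$lesion_depth_um >= 0, truth$tsl_thickness_um >= 0,
            truth$mineral_loss_frac >= 0, truth$mineral_loss_frac <= 1,
            truth$permeability >= 0,
            truth$water_pool_frac >= 0, truth$water_pool_frac <= 1)
  truth
}

# Assemble a T x H x W stack from per-class curves (1 = sound, 2 = lesion,
# 3 = composite) plus additive Gaussian pixel noise.
stack_from_classes <- function(curves, class_map, noise_sd) {
  tt <- nrow(curves)
  frames <- curves[, as.vector(class_map), drop = FALSE]
  if (noise_sd > 0)
    frames <- frames + stats::rnorm(length(frames), 0, noise_sd)
  array(frames, dim = c(tt, dim(class_map)))
}

#' Render a SWIR dehydration stack for one lesion
#'
#' Produces the frame series plus the lesion/control ROI masks. Lesion-ROI
#' pixels follow [swir_drying_curve()] with the lesion's permeability and
#' mineral loss; all other (sound) tooth pixels follow the same model with
#' zero mineral loss; when `has_composite` is set, a lateral band of
#' static, bright composite is added and excluded from both ROIs. One
#' per-tooth surface-wetness factor (uniform on \[0.5, 1.5\], drawn from
#' the lesion's `render_seed`) scales the sound drying term in both ROIs.
#'
#' @param truth One cohort row from [sample_cohort()] (or an equivalent
#'   named list).
#' @param config A [cohort_config()].
#' @return List with `stack` (an [image_stack()]) and `rois`
#'   (an [roi_pair()]).
#' @export
render_swir_stack <- function(truth, config) {
  truth <- as_lesion_truth(truth)
  stopifnot(inherits(config, "cohort_config"))
  geom <- roi_geometry(config$image_shape, truth$has_composite)
  t_s <- (seq_len(config$frame_count) - 1L) * config$frame_interval_s
  with_local_seed(truth$render_seed, {
    wet <- stats::runif(1, 0.5, 1.5)
    curves <- cbind(
      sound = swir_drying_curve(t_s, truth$permeability, 0, sound_scale = wet),
      lesion = swir_drying_curve(t_s, truth$permeability,
                                 truth$mineral_loss_frac, sound_scale = wet),
      composite = rep(0.9, length(t_s))
    )
    class_map <- matrix(1L, config$image_shape[1], config$image_shape[2])
    class_map[geom$rows, geom$lesion_cols] <- 2L
    if (length(geom$composite_cols)) class_map[, geom$composite_cols] <- 3L
    frames <- stack_from_classes(curves, class_map, config$noise_sd_swir)
    frames <- pmin(pmax(frames, 0), 1)
    masks <- roi_masks(config$image_shape, geom)
    list(stack = image_stack(frames, config$frame_interval_s, "swir"),
         rois = masks)
  })
}

#' Render a thermal dehydration stack for one lesion
#'
#' Same geometry as [render_swir_stack()]; pixel classes follow
#' [thermal_cooling_curve()]. The lesion ROI adds evaporative cooling
#' (permeability x pore volume) and crevice pooling on top of the shared
#' surface-water term; the composite band, which retains extra surface
#' water, cools 1.5x the sound base drop.
#'
#' @inheritParams render_swir_stack
#' @param base_drop_K Peak drop of a wet sound surface (kelvin). Set to 0
#'   to render a fully dry surface.
#' @return List with `stack` and `rois`, as for [render_swir_stack()].
#' @export
render_thermal_stack <- function(truth, config, base_drop_K = 0.3) {
  truth <- as_lesion_truth(truth)
  stopifnot(inherits(config, "cohort_config"))
  geom <- roi_geometry(config$image_shape, truth$has_composite)
  t_s <- (seq_len(config$frame_count) - 1L) * config$frame_interval_s
  with_local_seed(truth$render_seed + 1L, {
    wet <- stats::runif(1, 0.8, 1.2)
    curves <- cbind(
      sound = thermal_cooling_curve(t_s, truth$permeability, 0,
                                    base_drop_K = base_drop_K, base_scale = wet),
      lesion = thermal_cooling_curve(t_s, truth$permeability,
                                     truth$mineral_loss_frac,
                                     truth$water_pool_frac,
                                     base_drop_K = base_drop_K, base_scale = wet),
      composite = thermal_cooling_curve(t_s, 0, 0, base_drop_K = base_drop_K,
                                        base_scale = 1.5 * wet)
    )
    class_map <- matrix(1L, config$image_shape[1], config$image_shape[2])
    class_map[geom$rows, geom$lesion_cols] <- 2L
    if (length(geom$composite_cols)) class_map[, geom$composite_cols] <- 3L
    frames <- stack_from_classes(curves, class_map, config$noise_sd_thermal)
    list(stack = image_stack(frames, config$frame_interval_s, "thermal"),
         rois = roi_masks(config$image_shape, geom))
  })
}

roi_masks <- function(shape, geom) {
  lm <- matrix(FALSE, shape[1], shape[2])
  cm <- lm
  lm[geom$rows, geom$lesion_cols] <- TRUE
  cm[geom$rows, geom$control_cols] <- TRUE
  roi_pair(lm, cm)
}

#' Render an OCT B-scan for one lesion
#'
#' Builds the axial (rows) x lateral (cols) reflectivity image the OCT
#' analysis expects, in *optical* depth units: all boundaries sit at
#' `true depth x 1.6` (the refractive index of enamel) divided by the
#' axial pitch. From the surface downward, lesion columns show an
#' air/enamel surface reflection, a low-reflectivity transparent band of
#' optical thickness `tsl x 1.6` (if any), a high-reflectivity lesion body
#' down to optical depth `lesion_depth x 1.6`, and attenuated background
#' below. When the TSL is absent the bright body starts at the surface
#' row. Body reflectivity rises with mineral loss but saturates at 15%
#' loss (pores connect without adding scatterers above that). Sound
#' columns show the surface peak plus exponential attenuation only. A
#' lesion with zero mineral loss renders as sound tissue.
#'
#' @param truth Cohort row or named list (see [render_swir_stack()]).
#' @param axial_pitch_um_optical Axial pixel pitch in optical micrometres.
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param n_rows,n_cols Image size; rows auto-extend to fit the lesion.
#' @param surface_row Row of the air/enamel boundary.
#' @param roi_cols Columns occupied by the lesion; default the central
#'   40%–75% lateral band.
#' @param seed RNG seed for the noise (default derived from the truth's
#'   `render_seed`).
#' @return A [bscan()] whose `"roi_cols"` attribute records the lesion
#'   column range.
#' @export
render_oct_bscan <- function(truth, axial_pitch_um_optical = 5, noise_sd = 0,
                             n_rows = 160, n_cols = 128, surface_row = 20,
                             roi_cols = NULL, seed = NULL) {
  truth <- as_lesion_truth(truth)
  stopifnot(axial_pitch_um_optical > 0, noise_sd >= 0)
  if (is.null(roi_cols)) roi_cols <- seq(round(0.4 * n_cols), round(0.75 * n_cols))
  if (is.null(seed)) seed <- truth$render_seed + 2L
  ri <- 1.6
  pitch <- axial_pitch_um_optical
  n_tsl <- round(truth$tsl_thickness_um * ri / pitch)
  n_body <- round(truth$lesion_depth_um * ri / pitch)
  n_rows <- max(n_rows, surface_row + n_body + 20L)
  att <- function(depth_rows, top) top * exp(-depth_rows * pitch / 250)
  img <- matrix(0, n_rows, n_cols)
  below <- (surface_row + 1L):n_rows
  img[below, ] <- att(below - surface_row, 0.18)
  img[surface_row, ] <- 0.35
  lesion_here <- truth$mineral_loss_frac > 0
  if (lesion_here) {
    body_val <- 0.45 + 0.45 * min(truth$mineral_loss_frac, 0.15) / 0.15
    for (j in roi_cols) {
      img[below, j] <- 0
      if (n_tsl > 0) {
        img[surface_row, j] <- 0.35
        tsl_rows <- surface_row + seq_len(n_tsl)
        img[tsl_rows, j] <- 0.06
        body_rows <- (surface_row + n_tsl + 1L):(surface_row + n_body)
      } else {
        body_rows <- surface_row:(surface_row + n_body)
      }
      img[body_rows, j] <- body_val
      deeper <- (surface_row + n_body + 1L):n_rows
      img[deeper, j] <- att(deeper - surface_row - n_body, 0.10)
    }
  }
  if (noise_sd > 0)
    img <- with_local_seed(seed,
      pmin(pmax(img + stats::rnorm(length(img), 0, noise_sd), 0), 1))
  b <- bscan(img, axial_pitch_um_optical)
  attr(b, "roi_cols") <- roi_cols
  b
}

#' Render a MicroCT slice for one lesion
#'
#' Gray values encode mineral density on \[0, 1\] at true spatial scale
#' (no refractive correction). Along depth under the lesion: a
#' higher-than-sound surface layer (SL) of thickness `sl_thickness_um`, a
#' demineralized body down to `lesion_depth_um`, then sound mineral
#' level. Noise-free gray ordering is body < sound < SL by construction.
#' Zero mineral loss renders as uniform sound tissue below the surface.
#'
#' @param truth Cohort row or named list.
#' @param pitch_um Pixel pitch in micrometres (10 by default).
#' @param sl_thickness_um Surface-layer thickness; defaults to the
#'   cohort-drawn `sl_thickness_um` field.
#' @param noise_sd Additive Gaussian noise sd.
#' @param n_rows,n_cols Image size; rows auto-extend to fit.
#' @param surface_row Row of the air/tissue boundary.
#' @param roi_cols Lateral extent of the lesion.
#' @param seed RNG seed for the noise.
#' @return A [ct_slice()] with a `"roi_cols"` attribute.
#' @export
render_microct_slice <- function(truth, pitch_um = 10, sl_thickness_um = NULL,
                                 noise_sd = 0, n_rows = 110, n_cols = 128,
                                 surface_row = 20, roi_cols = NULL, seed = NULL) {
  truth <- as_lesion_truth(truth)
  stopifnot(pitch_um > 0, noise_sd >= 0)
  if (is.null(sl_thickness_um)) {
    sl_thickness_um <- if (!is.null(truth$sl_thickness_um)) truth$sl_thickness_um else 0
  }
  stopifnot(sl_thickness_um >= 0)
  if (is.null(roi_cols)) roi_cols <- seq(round(0.4 * n_cols), round(0.75 * n_cols))
  if (is.null(seed)) seed <- truth$render_seed + 3L
  sound_val <- 0.75; air_val <- 0.05; sl_val <- 0.95
  n_sl <- round(sl_thickness_um / pitch_um)
  n_ld <- round(truth$lesion_depth_um / pitch_um)
  n_rows <- max(n_rows, surface_row + n_ld + 15L)
  img <- matrix(air_val, n_rows, n_cols)
  img[surface_row:n_rows, ] <- sound_val
  if (truth$mineral_loss_frac > 0) {
    body_val <- 0.55 - 0.10 * min(truth$mineral_loss_frac / 0.3, 1)
    for (j in roi_cols) {
      if (n_sl > 0)
        img[surface_row + seq_len(n_sl) - 1L, j] <- sl_val
      if (n_ld > n_sl)
        img[(surface_row + n_sl):(surface_row + n_ld - 1L), j] <- body_val
    }
  }
  if (noise_sd > 0)
    img <- with_local_seed(seed,
      pmin(pmax(img + stats::rnorm(length(img), 0, noise_sd), 0), 1))
  ct <- ct_slice(img, pitch_um)
  attr(ct, "roi_cols") <- roi_cols
  ct
}
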