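#' Lesion permeability as a function of surface-layer thickness
#'
#' The transparent surface layer (TSL) that forms when a lesion
#' remineralizes is a diffusion barrier: fluid exchange falls off sharply
#' with its thickness, and lesions with a TSL of about 70 um or more behave
#' as arrested. The generator encodes this as an exponential decay
#' `p(tsl) = baseline * exp(-tsl / tau)` with `tau = 70 / log(20)`, chosen
#' so that permeability at 70 um is exactly 5% of the zero-TSL baseline.
#' The value is strictly positive for all finite thicknesses (a barrier
#' slows diffusion, it never makes it exactly zero).
#'
#' @param tsl_thickness_um TSL thickness in micrometres (tissue scale),
#'   `>= 0`; vectorized.
#' @param baseline Permeability of a TSL-free (active) lesion, `> 0`.
#' @return Permeability on the same scale as `baseline`.
#' @examples
#' permeability_from_tsl(0)    # baseline
#' permeability_from_tsl(70)   # 0.05 * baseline: arrest regime
#' @export
permeability_from_tsl <- function(tsl_thickness_um, baseline = 1) {
  if (!is.numeric(tsl_thickness_um) || any(!is.finite(tsl_thickness_um)) ||
      any(tsl_thickness_um < 0))
    stop("`tsl_thickness_um` must be finite and >= 0")
  if (!is.numeric(baseline) || length(baseline) != 1L || baseline <= 0)
    stop("`baseline` must be a single positive number")
  # exp(-tsl / tau) with tau = 70 / log(20), written so the calibration
  # point p(70) = 0.05 * baseline is exact in floating point
  baseline * 0.05^(tsl_thickness_um / 70)
}

#' Synthetic cohort configuration
#'
#' Study-level parameters for the synthetic lesion cohort. The defaults
#' emulate the acquisition conditions of the extracted-tooth protocol the
#' package is written for: 60 frames at 1 frame/s during forced-air drying,
#' thermal noise at the 50 mK sensitivity of the thermography camera,
#' 294.15 K ambient, OCT axial sampling of 5 um (optical) and MicroCT at
#' 10 um/px, a surface-type mix of roughly 13% occlusal / 81% smooth /
#' 6% incisal, and about 22% of lesions carrying no detectable TSL.
#'
#' @param n_lesions Number of lesions in the cohort.
#' @param tsl_range_um Range (min, max) from which detectable TSL
#'   thicknesses are drawn uniformly; a fraction `p_no_tsl` of lesions get
#'   TSL = 0 instead (active, no barrier).
#' @param depth_range_um Range of lesion depths (um, true tissue scale).
#' @param noise_sd_swir Additive Gaussian pixel noise sd on SWIR frames
#'   (reflectance units on \[0, 1\]).
#' @param noise_sd_thermal Additive Gaussian pixel noise sd on thermal
#'   frames (kelvin).
#' @param noise_sd_oct,noise_sd_ct Additive pixel noise sd for the OCT and
#'   MicroCT renderings (intensity units on \[0, 1\]).
#' @param frame_count Frames per dehydration series (`>= 2`).
#' @param frame_interval_s Seconds between frames.
#' @param seed Integer seed; fully determines the cohort and every
#'   rendered image.
#' @param image_shape `(H, W)` of the dehydration frames.
#' @param surface_type_weights Named probabilities for
#'   occlusal/smooth/incisal surface assignment.
#' @param p_no_tsl Probability that a lesion has no detectable TSL.
#' @param oct_pitch_um Axial OCT pixel pitch in *optical* micrometres.
#' @param ct_pitch_um MicroCT pixel pitch in true micrometres.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_lesions = 100,
                          tsl_range_um = c(10, 100),
                          depth_range_um = c(60, 300),
                          noise_sd_swir = 0.01,
                          noise_sd_thermal = 0.05,
                          noise_sd_oct = 0.02,
                          noise_sd_ct = 0.02,
                          frame_count = 60,
                          frame_interval_s = 1,
                          seed = 1,
                          image_shape = c(128, 128),
                          surface_type_weights = c(occlusal = 11, smooth = 69, incisal = 5) / 85,
                          p_no_tsl = 0.22,
                          oct_pitch_um = 5,
                          ct_pitch_um = 10) {
  stopifnot(length(n_lesions) == 1L, n_lesions >= 1,
            length(frame_count) == 1L, frame_count >= 2,
            frame_interval_s > 0,
            length(seed) == 1L, is.finite(seed),
            length(image_shape) == 2L, all(image_shape >= 16),
            noise_sd_swir >= 0, noise_sd_thermal >= 0,
            noise_sd_oct >= 0, noise_sd_ct >= 0,
            p_no_tsl >= 0, p_no_tsl < 1,
            oct_pitch_um > 0, ct_pitch_um > 0)
  if (length(tsl_range_um) != 2L || diff(tsl_range_um) < 0 || any(tsl_range_um < 0))
    stop("`tsl_range_um` must be a non-decreasing, non-negative interval")
  if (length(depth_range_um) != 2L || diff(depth_range_um) < 0 || any(depth_range_um <= 0))
    stop("`depth_range_um` must be a positive, non-decreasing interval")
  if (length(surface_type_weights) != 3L ||
      !setequal(names(surface_type_weights), c("occlusal", "smooth", "incisal")) ||
      any(surface_type_weights < 0) || sum(surface_type_weights) <= 0)
    stop("`surface_type_weights` must name occlusal/smooth/incisal probabilities")
  structure(list(
    n_lesions = as.integer(n_lesions),
    tsl_range_um = as.numeric(tsl_range_um),
    depth_range_um = as.numeric(depth_range_um),
    noise_sd_swir = noise_sd_swir,
    noise_sd_thermal = noise_sd_thermal,
    noise_sd_oct = noise_sd_oct,
    noise_sd_ct = noise_sd_ct,
    frame_count = as.integer(frame_count),
    frame_interval_s = frame_interval_s,
    seed = as.integer(seed),
    image_shape = as.integer(image_shape),
    surface_type_weights = surface_type_weights[c("occlusal", "smooth", "incisal")],
    p_no_tsl = p_no_tsl,
    oct_pitch_um = oct_pitch_um,
    ct_pitch_um = ct_pitch_um
  ), class = "cohort_config")
}

#' Draw a ground-truth lesion cohort
#'
#' Samples one `lesion_truth` row per lesion. TSL thickness is 0 with
#' probability `p_no_tsl` and otherwise uniform over `tsl_range_um`;
#' permeability follows [permeability_from_tsl()]; lesion depth is uniform
#' over `depth_range_um` but always at least 40 um deeper than the TSL
#' (the TSL is the capping zone of the lesion, not the whole of it);
#' mineral loss is uniform on \[0.05, 0.30\]; water pooling affects only
#' occlusal and incisal surfaces (crevice anatomy), uniform on \[0, 0.6\]
#' there and 0 on smooth surfaces; the MicroCT surface layer is drawn as
#' `15 + 0.35 * TSL + N(0, 28)` clamped to \[8, 160\] um, giving the weak
#' positive TSL–SL coupling seen between the two modalities.
#'
#' Each lesion also receives its own `render_seed`, drawn once from the
#' cohort seed, so renderings are reproducible lesion-by-lesion regardless
#' of the order in which they are generated.
#'
#' @param config A [cohort_config()].
#' @return A `data.frame` of class `lesion_cohort`, one row per lesion,
#'   with columns `lesion_id`, `surface_type`, `has_composite`,
#'   `lesion_depth_um`, `tsl_thickness_um`, `mineral_loss_frac`,
#'   `permeability`, `water_pool_frac`, `sl_thickness_um`, `render_seed`.
#' @examples
#' cohort <- sample_cohort(cohort_config(n_lesions = 5, seed = 7))
#' cohort$tsl_thickness_um
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_lesions
  with_local_seed(config$seed, {
    surface_type <- sample(c("occlusal", "smooth", "incisal"), n, replace = TRUE,
                           prob = config$surface_type_weights)
    has_composite <- stats::runif(n) < 0.5
    tsl <- stats::runif(n, config$tsl_range_um[1], config$tsl_range_um[2])
    tsl[stats::runif(n) < config$p_no_tsl] <- 0
    depth <- stats::runif(n, config$depth_range_um[1], config$depth_range_um[2])
    depth <- pmax(depth, tsl + 40)
    mineral <- stats::runif(n, 0.05, 0.30)
    pool <- ifelse(surface_type == "smooth", 0, stats::runif(n, 0, 0.6))
    sl <- pmin(pmax(15 + 0.35 * tsl + stats::rnorm(n, 0, 28), 8), 160)
    render_seed <- sample.int(.Machine$integer.max - 1L, n)
    out <- data.frame(
      lesion_id = seq_len(n),
      surface_type = surface_type,
      has_composite = has_composite,
      lesion_depth_um = depth,
      tsl_thickness_um = tsl,
      mineral_loss_frac = mineral,
      permeability = permeability_from_tsl(tsl),
      water_pool_frac = pool,
      sl_thickness_um = sl,
      render_seed = render_seed,
      stringsAsFactors = FALSE
    )
    class(out) <- c("lesion_cohort", "data.frame")
    out
  })
}

# Evaluate `expr` under a given RNG seed without disturbing the caller's
# RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
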