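#' Simulate and measure one lesion end to end
#'
#' Renders the four modalities for a single ground-truth lesion, runs the
#' dehydration, OCT and MicroCT analyses, and joins the results into one
#' record row. Ground-truth fields are carried along with a `truth_`
#' prefix so recovery can be audited.
#'
#' @param truth One row of a [sample_cohort()] cohort.
#' @param config The [cohort_config()] used to draw the cohort.
#' @return One-row `data.frame` following the record schema (see
#'   [write_records()]).
#' @export
simulate_lesion_record <- function(truth, config) {
  truth_l <- as_lesion_truth(truth)
  sw <- render_swir_stack(truth_l, config)
  res_i <- analyze_dehydration(sw$stack, sw$rois)
  th <- render_thermal_stack(truth_l, config)
  res_q <- analyze_dehydration(th$stack, th$rois)
  b <- render_oct_bscan(truth_l, axial_pitch_um_optical = config$oct_pitch_um,
                        noise_sd = config$noise_sd_oct)
  om <- measure_bscan(b)
  ct <- render_microct_slice(truth_l, pitch_um = config$ct_pitch_um,
                             noise_sd = config$noise_sd_ct)
  cm <- line_profile_depth(ct)
  data.frame(
    lesion_id = truth_l$lesion_id %||% NA_integer_,
    surface_type = truth_l$surface_type,
    has_composite = truth_l$has_composite,
    dI_lesion = res_i$delta_lesion, dI_control = res_i$delta_control,
    dI_diff = res_i$diff, dI_ratio = res_i$ratio,
    dQ_lesion = res_q$delta_lesion, dQ_control = res_q$delta_control,
    dQ_diff = res_q$diff, dQ_ratio = res_q$ratio,
    ld_oct_um = om$lesion_depth_um, delta_R = om$delta_R,
    tsl_um = om$tsl_thickness_um, tsl_detected = om$tsl_detected,
    ld_ct_um = cm$lesion_depth_um, sl_um = cm$sl_thickness_um,
    activity = as.character(classify_activity(om$tsl_thickness_um, om$tsl_detected)),
    truth_lesion_depth_um = truth_l$lesion_depth_um,
    truth_tsl_um = truth_l$tsl_thickness_um,
    truth_mineral_loss_frac = truth_l$mineral_loss_frac,
    truth_permeability = truth_l$permeability,
    truth_water_pool_frac = truth_l$water_pool_frac,
    truth_sl_um = truth_l$sl_thickness_um %||% NA_real_,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-cohort analysis pipeline
#'
#' Draws a ground-truth cohort, simulates and measures every lesion
#' ([simulate_lesion_record()]), and runs the statistical stage:
#' cohort-level correlations, the TSL threshold-band analysis, the
#' surface-type stratification, and activity classification counts. The
#' run is fully determined by `config$seed`.
#'
#' When `out_dir` is given, the joined record table
#' (`lesion_records.csv`), the correlation report
#' (`correlation_report.csv`), the band analyses
#' (`tsl_band_within.csv`, `tsl_band_between.csv`), the stratified report
#' (`surface_strata.csv`) and a JSON run summary (`summary.json`, with
#' seed, package version and the md5 hash of the serialized config) are
#' written there.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional report directory (created if needed).
#' @param tsl_cut_um Arrest threshold for the band analysis and
#'   classification.
#' @param var_equal Use the pooled-variance t-test variant.
#' @return List of class `cariometry_report`: `records`, `cohort`,
#'   `correlations`, `band`, `strata`, `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL, tsl_cut_um = 70,
                         var_equal = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  cohort <- sample_cohort(config)
  records <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i)
    simulate_lesion_record(cohort[i, ], config)))
  records$activity <- as.character(
    classify_activity(records$tsl_um, records$tsl_detected, tsl_cut_um))
  correlations <- correlation_report(records)
  band <- tsl_band_analysis(records, cut_um = tsl_cut_um, var_equal = var_equal)
  strata <- stratify_by_surface(records)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  summary <- list(
    n_lesions = nrow(records),
    seed = config$seed,
    tsl_cut_um = tsl_cut_um,
    package_version = as.character(utils::packageVersion("cariometry")),
    config_md5 = cfg_hash,
    activity_counts = as.list(table(records$activity))
  )
  report <- structure(list(records = records, cohort = cohort,
                           correlations = correlations, band = band,
                           strata = strata, summary = summary),
                      class = "cariometry_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_records(records, file.path(out_dir, "lesion_records.csv"))
    utils::write.csv(correlations, file.path(out_dir, "correlation_report.csv"),
                     row.names = FALSE)
    utils::write.csv(band$within, file.path(out_dir, "tsl_band_within.csv"),
                     row.names = FALSE)
    utils::write.csv(band$between, file.path(out_dir, "tsl_band_between.csv"),
                     row.names = FALSE)
    utils::write.csv(strata, file.path(out_dir, "surface_strata.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.cariometry_report <- function(x, ...) {
  cat(sprintf("<cariometry_report> %d lesions (seed %d)\n",
              x$summary$n_lesions, x$summary$seed))
  cat("activity:", paste(names(x$summary$activity_counts),
                         unlist(x$summary$activity_counts),
                         sep = "=", collapse = ", "), "\n")
  print(x$correlations)
  invisible(x)
}

#' Monte-Carlo noise floor for the contrast statistics
#'
#' Estimates the magnitude a lesion-minus-control statistic reaches from
#' pixel noise alone, by repeatedly simulating two sound (control-grade)
#' ROI-mean curves and taking the resulting |L − C| contrast. The floor is
#' the 95th percentile of that null distribution; a genuine lesion signal
#' should stand well above it, and a zero-mineral-loss lesion should stay
#' within a small multiple of it.
#'
#' @param config A [cohort_config()] (noise levels, frame count, ROI size
#'   are taken from it).
#' @param modality `"swir"` or `"thermal"`.
#' @param n_rep Monte-Carlo repeats.
#' @param seed RNG seed.
#' @return Scalar noise floor in the statistic's units.
#' @export
contrast_noise_floor <- function(config, modality = c("swir", "thermal"),
                                 n_rep = 500, seed = 1) {
  modality <- match.arg(modality)
  stopifnot(inherits(config, "cohort_config"), n_rep >= 10)
  geom <- roi_geometry(config$image_shape, FALSE)
  n_px <- length(geom$rows) * length(geom$lesion_cols)
  sd_px <- if (modality == "swir") config$noise_sd_swir else config$noise_sd_thermal
  sd_curve <- sd_px / sqrt(n_px)
  tt <- config$frame_count
  delta <- if (modality == "swir") delta_I else delta_Q
  base <- if (modality == "swir") 0.5 else 294
  with_local_seed(seed, {
    diffs <- vapply(seq_len(n_rep), function(i) {
      a <- base + stats::rnorm(tt, 0, sd_curve)
      b <- base + stats::rnorm(tt, 0, sd_curve)
      abs(delta(a) - delta(b))
    }, numeric(1))
    unname(stats::quantile(diffs, 0.95))
  })
}
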