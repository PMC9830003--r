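#' Mean intensity of an ROI at each time point
#'
#' Collapses a dehydration stack to a single time–intensity (or
#' time–temperature) curve by averaging each frame over the mask pixels.
#' This ROI-first aggregation is the default analysis path; see
#' [integrated_heatmap()] for the per-pixel-first alternative.
#'
#' @param stack An [image_stack()].
#' @param mask Logical `H x W` matrix, non-empty, matching the frame grid.
#' @return Numeric vector of length `T`.
#' @examples
#' st <- image_stack(array(rep(1:3, each = 4), dim = c(3, 2, 2)), 1, "swir")
#' roi_mean_curve(st, matrix(TRUE, 2, 2))
#' @export
roi_mean_curve <- function(stack, mask) {
  stopifnot(inherits(stack, "image_stack"))
  mask <- as_mask(mask)
  check_mask_compatible(stack, mask)
  if (!any(mask)) stop("mask is empty")
  d <- dim(stack$frames)
  flat <- matrix(stack$frames, nrow = d[1L])  # T x (H*W), column-major over (row, col)
  rowMeans(flat[, as.vector(mask), drop = FALSE])
}

#' Integrated SWIR intensity change ΔI
#'
#' The area under the time–intensity drying curve above its minimum,
#' `ΔI = Σ_t (I_t − I_min)`, where `I_min` is the global minimum of the
#' curve over the acquisition window (typically, but not necessarily, the
#' wet first frame). Porous, permeable (active) lesions dry fast and gain
#' reflectance, giving large ΔI; arrested lesions capped by a mineralized
#' surface layer barely change.
#'
#' The sum runs over every available frame, so truncated acquisitions
#' remain analyzable; with the canonical 60-frame, 1-s protocol this is the
#' t = 1..60 sum.
#'
#' @param curve Numeric vector of length `>= 2`, finite.
#' @return Non-negative scalar; exactly 0 iff the curve is constant.
#' @examples
#' delta_I(c(1, 2, 3))  # min 1: 0 + 1 + 2 = 3
#' @seealso [delta_Q()] for the thermal analogue.
#' @export
delta_I <- function(curve) {
  check_curve(curve)
  sum(curve - min(curve))
}

#' Integrated evaporative cooling ΔQ
#'
#' The area enclosed by the time–temperature curve below its maximum,
#' `ΔQ = Σ_t (Temp_max − Temp_t)` in kelvin-seconds (for 1-s frame
#' spacing). Evaporation of water drawn out of a permeable lesion cools the
#' surface, so ΔQ is proportional to the fluid lost during drying.
#' Identity: `delta_Q(x) == delta_I(-x)`.
#'
#' @param curve Numeric temperature vector of length `>= 2`, finite.
#' @return Non-negative scalar; 0 iff constant.
#' @examples
#' delta_Q(c(294, 292, 293))  # max 294: 0 + 2 + 1 = 3
#' @export
delta_Q <- function(curve) {
  check_curve(curve)
  sum(max(curve) - curve)
}

check_curve <- function(curve) {
  if (!is.numeric(curve) || length(curve) < 2L)
    stop("curve must be a numeric vector with at least 2 time points")
  if (!all(is.finite(curve))) stop("curve contains non-finite values")
  invisible(TRUE)
}

#' Lesion-vs-control contrast statistics
#'
#' Combines a lesion-ROI integral with the control-ROI integral from the
#' same tooth into the difference `L - C` and the ratio `L / C`. The
#' difference removes tooth-level additive effects; the ratio normalizes
#' them away, which also compresses real permeability contrast.
#'
#' @param lesion_value,control_value Non-negative scalars (ΔI or ΔQ).
#' @return List with `diff`, `ratio` (NA when undefined) and
#'   `ratio_defined`.
#' @examples
#' contrast_metrics(10, 4)  # diff 6, ratio 2.5
#' @export
contrast_metrics <- function(lesion_value, control_value) {
  stopifnot(is.numeric(lesion_value), length(lesion_value) == 1L,
            is.numeric(control_value), length(control_value) == 1L,
            is.finite(lesion_value), is.finite(control_value))
  if (lesion_value < 0 || control_value < 0)
    stop("integrated dehydration values are non-negative by construction")
  ratio_defined <- control_value > 0
  list(diff = lesion_value - control_value,
       ratio = if (ratio_defined) lesion_value / control_value else NA_real_,
       ratio_defined = ratio_defined)
}

#' Per-pixel integrated dehydration heat map
#'
#' Applies [delta_I()] (SWIR) or [delta_Q()] (thermal) to every pixel's own
#' time series, producing the `H x W` map used to visualize where a sample
#' dried and to guide manual ROI designation.
#'
#' Note the two estimators are genuinely different: averaging this map over
#' an ROI is not the same as computing the delta of the ROI-mean curve,
#' because each pixel takes its own extremum (for SWIR the per-pixel
#' average is always `>=` the ROI-curve value). The ROI-curve estimator is
#' the default for reported statistics; the map is for display and ROI
#' placement.
#'
#' @param stack An [image_stack()].
#' @return Numeric `H x W` matrix of per-pixel integrals.
#' @examples
#' fr <- array(0, dim = c(3, 2, 2)); fr[, 1, 1] <- 1:3
#' integrated_heatmap(image_stack(fr, 1, "swir"))
#' @export
integrated_heatmap <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  flat <- matrix(stack$frames, nrow = d[1L])
  v <- if (stack$modality == "swir") {
    colSums(flat) - d[1L] * apply(flat, 2L, min)
  } else {
    d[1L] * apply(flat, 2L, max) - colSums(flat)
  }
  matrix(v, nrow = d[2L], ncol = d[3L])
}

#' Full dehydration analysis of one stack + ROI pair
#'
#' Extracts the lesion and control ROI-mean curves, integrates them with
#' [delta_I()] or [delta_Q()] according to the stack modality, and forms
#' the L−C and L/C contrasts.
#'
#' @param stack An [image_stack()].
#' @param rois An [roi_pair()].
#' @return An object of class `dehydration_result`: list with
#'   `delta_lesion`, `delta_control`, `diff`, `ratio`, `ratio_defined`,
#'   `curve_lesion`, `curve_control`, `modality`.
#' @examples
#' fr <- array(0.2, dim = c(4, 4, 4)); fr[, 1:2, 1:2] <- rep(c(.2, .3, .5, .6), 16)
#' les <- matrix(FALSE, 4, 4); les[1:2, 1:2] <- TRUE
#' ctl <- matrix(FALSE, 4, 4); ctl[3:4, 3:4] <- TRUE
#' analyze_dehydration(image_stack(fr, 1, "swir"), roi_pair(les, ctl))
#' @export
analyze_dehydration <- function(stack, rois) {
  stopifnot(inherits(stack, "image_stack"), inherits(rois, "roi_pair"))
  check_mask_compatible(stack, rois$lesion_mask)
  cl <- roi_mean_curve(stack, rois$lesion_mask)
  cc <- roi_mean_curve(stack, rois$control_mask)
  delta <- if (stack$modality == "swir") delta_I else delta_Q
  dl <- delta(cl)
  dc <- delta(cc)
  cm <- contrast_metrics(dl, dc)
  structure(list(delta_lesion = dl, delta_control = dc,
                 diff = cm$diff, ratio = cm$ratio,
                 ratio_defined = cm$ratio_defined,
                 curve_lesion = cl, curve_control = cc,
                 modality = stack$modality),
            class = "dehydration_result")
}

#' @export
print.dehydration_result <- function(x, ...) {
  cat(sprintf("<dehydration_result> %s: delta L = %.4g, C = %.4g, L-C = %.4g, L/C = %s\n",
              x$modality, x$delta_lesion, x$delta_control, x$diff,
              if (x$ratio_defined) sprintf("%.4g", x$ratio) else "undefined"))
  invisible(x)
}
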