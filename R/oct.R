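# Refractive index of enamel: OCT measures optical path length, so every
# axial distance is divided by this before being reported in tissue um.
ENAMEL_RI <- 1.6

#' OCT B-scan container
#'
#' A cross-sectional OCT image with axial depth along rows and lateral
#' position along columns, plus the axial pixel pitch in *optical*
#' micrometres. All depths measured on a B-scan are optical path lengths;
#' the analysis functions convert to tissue scale by dividing by the
#' enamel refractive index 1.6.
#'
#' @param image Numeric matrix, rows = axial, cols = lateral, intensities
#'   nominally in \[0, 1\].
#' @param axial_pitch_um_optical Optical micrometres per row, `> 0`.
#' @param surface_row_per_col Optional integer vector of pre-detected
#'   air/enamel boundary rows (NA = not found); computed on demand by
#'   [detect_surface()] otherwise.
#' @return Object of class `bscan`.
#' @export
bscan <- function(image, axial_pitch_um_optical, surface_row_per_col = NULL) {
  stopifnot(is.matrix(image), is.numeric(image), all(is.finite(image)),
            length(axial_pitch_um_optical) == 1L, axial_pitch_um_optical > 0)
  if (!is.null(surface_row_per_col)) {
    stopifnot(length(surface_row_per_col) == ncol(image))
    ok <- !is.na(surface_row_per_col)
    if (any(surface_row_per_col[ok] < 1 | surface_row_per_col[ok] > nrow(image)))
      stop("surface rows outside image bounds")
  }
  structure(list(image = image,
                 axial_pitch_um_optical = axial_pitch_um_optical,
                 surface_row_per_col = surface_row_per_col),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan> %d axial x %d lateral px, pitch %g um (optical)\n",
              nrow(x$image), ncol(x$image), x$axial_pitch_um_optical))
  invisible(x)
}

#' Detect the air/enamel surface on each A-line
#'
#' Per column, the surface is the first axial row whose intensity exceeds
#' a noise-floor threshold estimated from the air region (mean + 3 sd of
#' the top `air_rows` rows). Columns with no suprathreshold pixel are
#' marked `NA` and excluded from downstream measurements. The detected
#' profile is smoothed with a running median across columns to suppress
#' single-column dropouts.
#'
#' @param bscan A [bscan()].
#' @param air_rows Number of top rows treated as pure air.
#' @param smooth_k Running-median window (odd; 1 disables smoothing).
#' @return Integer vector, one entry per column (NA = no surface found).
#' @export
detect_surface <- function(bscan, air_rows = 5, smooth_k = 5) {
  stopifnot(inherits(bscan, "bscan"))
  img <- bscan$image
  air <- img[seq_len(min(air_rows, nrow(img))), , drop = FALSE]
  thr <- mean(air) + 3 * stats::sd(air)
  if (!is.finite(thr)) thr <- 0
  surf <- apply(img, 2L, function(a) {
    i <- which(a > thr)
    if (length(i)) i[1L] else NA_integer_
  })
  ok <- !is.na(surf)
  if (smooth_k > 1 && sum(ok) >= smooth_k)
    surf[ok] <- as.integer(stats::runmed(surf[ok], smooth_k))
  as.integer(surf)
}

surface_of <- function(bscan) {
  if (!is.null(bscan$surface_row_per_col)) bscan$surface_row_per_col
  else detect_surface(bscan)
}

#' Segment the lesion body on a B-scan
#'
#' Demineralized enamel scatters strongly, so the lesion body is the
#' high-reflectivity connected region below the detected surface within
#' the analysed columns. The intensity threshold is chosen automatically
#' by Otsu's method over the below-surface pixels (override with
#' `threshold`); the largest suprathreshold connected component is kept
#' and then validated: its mean intensity must reach `min_body_intensity`,
#' otherwise the tissue is declared sound and an empty mask is returned
#' (Otsu always finds *some* split, even on sound enamel).
#'
#' @param bscan A [bscan()].
#' @param roi_cols Columns to analyse (default: all).
#' @param threshold Manual intensity threshold overriding Otsu.
#' @param min_body_intensity Minimum mean intensity for a credible lesion
#'   body, on the \[0, 1\] intensity scale.
#' @return Logical matrix of the image size; all-`FALSE` means sound
#'   tissue (a valid outcome, not an error).
#' @export
segment_lesion <- function(bscan, roi_cols = NULL, threshold = NULL,
                           min_body_intensity = 0.3) {
  stopifnot(inherits(bscan, "bscan"))
  img <- bscan$image
  if (is.null(roi_cols)) roi_cols <- seq_len(ncol(img))
  stopifnot(all(roi_cols >= 1), all(roi_cols <= ncol(img)))
  surf <- surface_of(bscan)
  cand <- matrix(FALSE, nrow(img), ncol(img))
  for (j in roi_cols) {
    s <- surf[j]
    if (is.na(s) || s >= nrow(img)) next
    cand[(s + 1L):nrow(img), j] <- TRUE
  }
  if (!any(cand)) return(cand)
  vals <- img[cand]
  if (is.null(threshold)) {
    threshold <- EBImage::otsu(matrix(pmin(pmax(vals, 0), 1), ncol = 1),
                               range = c(0, 1))
  }
  mask <- cand & img > threshold
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  if (mean(img[mask]) < min_body_intensity)
    mask[] <- FALSE
  mask
}

#' Lesion depth from a segmentation mask
#'
#' Per retained column, depth is `(deepest mask row - surface row) x
#' axial pitch / 1.6`: the optical path from the surface to the lesion
#' floor converted to tissue micrometres via the enamel refractive index.
#' The reported depth is the mean over columns containing lesion pixels.
#'
#' @param mask Logical matrix from [segment_lesion()].
#' @param bscan The [bscan()] the mask was computed on.
#' @return List with `depth_um` (0 when the mask is empty),
#'   `lesion_present`, and `per_column_um`.
#' @examples
#' # 32 rows of lesion at 5 um optical pitch -> 32 * 5 / 1.6 = 100 um
#' @export
lesion_depth <- function(mask, bscan) {
  stopifnot(inherits(bscan, "bscan"), is.logical(mask),
            identical(dim(mask), dim(bscan$image)))
  if (!any(mask))
    return(list(depth_um = 0, lesion_present = FALSE, per_column_um = numeric(0)))
  surf <- surface_of(bscan)
  cols <- which(colSums(mask) > 0)
  per <- vapply(cols, function(j) {
    if (is.na(surf[j])) return(NA_real_)
    (max(which(mask[, j])) - surf[j]) * bscan$axial_pitch_um_optical / ENAMEL_RI
  }, numeric(1))
  per <- per[!is.na(per)]
  list(depth_um = mean(per), lesion_present = TRUE, per_column_um = per)
}

#' Integrated reflectivity over a lesion ROI
#'
#' The mean OCT signal intensity over the mask pixels. Rises with
#' demineralization but saturates near 15% mineral loss, so it indexes
#' lesion severity only up to that point.
#'
#' @param bscan A [bscan()].
#' @param mask Non-empty logical matrix of the image size.
#' @return Scalar mean intensity.
#' @export
integrated_reflectivity <- function(bscan, mask) {
  stopifnot(inherits(bscan, "bscan"), is.logical(mask),
            identical(dim(mask), dim(bscan$image)))
  if (!any(mask)) stop("cannot average reflectivity over an empty mask")
  mean(bscan$image[mask])
}

#' Detect and measure the transparent surface layer
#'
#' A lesion that is remineralizing grows a near-sound-mineral surface zone
#' whose reflectivity is *low* compared with the scattering lesion body —
#' it appears transparent. Per analysed column, the TSL is the run of
#' consecutive rows between the surface reflection and the first
#' lesion-body row whose intensity stays below `body_frac` of that
#' column's body peak. Thickness is the median run length across columns
#' times `pitch / 1.6` (tissue scale); the layer counts as detected only
#' when the median run reaches `min_rows` axial pixels.
#'
#' @param bscan A [bscan()].
#' @param roi_cols Columns to analyse.
#' @param mask Optional precomputed segmentation (else [segment_lesion()]
#'   is run). An empty segmentation is an error: a TSL is defined only
#'   relative to a lesion body.
#' @param min_rows Minimum detectable median run, in axial pixels.
#' @param body_frac A TSL row must be darker than this fraction of the
#'   column's body peak.
#' @return List with `tsl_detected` and `tsl_thickness_um` (0 when not
#'   detected).
#' @export
detect_tsl <- function(bscan, roi_cols = NULL, mask = NULL,
                       min_rows = 2, body_frac = 0.5) {
  stopifnot(inherits(bscan, "bscan"))
  if (is.null(mask)) mask <- segment_lesion(bscan, roi_cols)
  if (!any(mask))
    stop("no lesion body segmented; a TSL is defined only relative to a lesion")
  surf <- surface_of(bscan)
  img <- bscan$image
  cols <- which(colSums(mask) > 0)
  runs <- vapply(cols, function(j) {
    s <- surf[j]
    if (is.na(s)) return(NA_real_)
    b <- min(which(mask[, j]))
    if (b <= s + 1L) return(0)
    peak <- max(img[mask[, j], j])
    gap <- (s + 1L):(b - 1L)
    below <- img[gap, j] < body_frac * peak
    run <- 0L
    for (v in below) { if (!v) break; run <- run + 1L }
    as.numeric(run)
  }, numeric(1))
  runs <- runs[!is.na(runs)]
  med <- stats::median(runs)
  if (length(runs) == 0 || med < min_rows)
    return(list(tsl_detected = FALSE, tsl_thickness_um = 0))
  list(tsl_detected = TRUE,
       tsl_thickness_um = med * bscan$axial_pitch_um_optical / ENAMEL_RI)
}

#' Complete OCT morphometry of one B-scan
#'
#' Runs surface detection, lesion segmentation, depth measurement,
#' integrated reflectivity and TSL detection, returning the per-lesion OCT
#' measurement row. All lengths are tissue-scale micrometres (optical
#' path / 1.6).
#'
#' @param bscan A [bscan()].
#' @param roi_cols Columns spanning the suspected lesion; defaults to the
#'   `"roi_cols"` attribute if present, else all columns.
#' @return Object of class `oct_morphometry`: list with `lesion_depth_um`,
#'   `delta_R` (NA when no lesion), `tsl_thickness_um`, `tsl_detected`,
#'   `lesion_present`.
#' @export
measure_bscan <- function(bscan, roi_cols = NULL) {
  stopifnot(inherits(bscan, "bscan"))
  if (is.null(roi_cols)) roi_cols <- attr(bscan, "roi_cols")
  mask <- segment_lesion(bscan, roi_cols)
  if (!any(mask)) {
    out <- list(lesion_depth_um = 0, delta_R = NA_real_,
                tsl_thickness_um = 0, tsl_detected = FALSE,
                lesion_present = FALSE)
  } else {
    ld <- lesion_depth(mask, bscan)
    tsl <- detect_tsl(bscan, roi_cols, mask = mask)
    out <- list(lesion_depth_um = ld$depth_um,
                delta_R = integrated_reflectivity(bscan, mask),
                tsl_thickness_um = tsl$tsl_thickness_um,
                tsl_detected = tsl$tsl_detected,
                lesion_present = TRUE)
  }
  structure(out, class = "oct_morphometry")
}

#' @export
print.oct_morphometry <- function(x, ...) {
  cat(sprintf("<oct_morphometry> LD = %.1f um, dR = %s, TSL = %s\n",
              x$lesion_depth_um,
              if (is.na(x$delta_R)) "NA" else sprintf("%.3f", x$delta_R),
              if (x$tsl_detected) sprintf("%.1f um", x$tsl_thickness_um) else "none"))
  invisible(x)
}
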