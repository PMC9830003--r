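#' MicroCT slice container
#'
#' A 2-D micro-computed-tomography slice: gray values proportional to
#' mineral density (arbitrary units, nominally \[0, 1\]) on a true
#' spatial grid. MicroCT lengths are physical — they never receive the
#' OCT refractive-index division.
#'
#' @param image Numeric matrix (rows = depth, cols = lateral), finite.
#' @param pitch_um Micrometres per pixel, `> 0` (10 by default, the
#'   scanner resolution the analysis assumes).
#' @return Object of class `ct_slice`.
#' @export
ct_slice <- function(image, pitch_um = 10) {
  stopifnot(is.matrix(image), is.numeric(image), all(is.finite(image)),
            length(pitch_um) == 1L, pitch_um > 0)
  structure(list(image = image, pitch_um = pitch_um), class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice> %d x %d px at %g um/px\n",
              nrow(x$image), ncol(x$image), x$pitch_um))
  invisible(x)
}

#' Median-filter smoothing of a CT slice
#'
#' 2-D median filtering removes shot noise while preserving the step
#' edges that the Sobel stage must localize (a Gaussian of matched width
#' would blur them; pass `family = "gaussian"` to use one anyway).
#' Radius 0 is the identity.
#'
#' @param slice A [ct_slice()].
#' @param median_radius_px Filter radius in pixels, `>= 0`.
#' @param family `"median"` (default) or `"gaussian"`.
#' @return A filtered [ct_slice()].
#' @export
ct_preprocess <- function(slice, median_radius_px = 1,
                          family = c("median", "gaussian")) {
  stopifnot(inherits(slice, "ct_slice"),
            length(median_radius_px) == 1L, median_radius_px >= 0)
  family <- match.arg(family)
  if (median_radius_px == 0) return(slice)
  img <- slice$image
  lo <- min(img); hi <- max(img)
  if (hi > lo) {
    scaled <- (img - lo) / (hi - lo)
    filtered <- if (family == "median") {
      EBImage::medianFilter(scaled, size = as.integer(median_radius_px))
    } else {
      EBImage::gblur(scaled, sigma = median_radius_px)
    }
    img <- filtered * (hi - lo) + lo
  }
  ct_slice(img, slice$pitch_um)
}

# 3x3 Sobel kernels; kx responds to lateral gradients, ky to depth.
SOBEL_KX <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
SOBEL_KY <- t(SOBEL_KX)

#' Sobel gradient magnitude of a CT slice
#'
#' Standard 3x3 Sobel operator (replicated borders):
#' `sqrt(gx^2 + gy^2)`. Mineral-density boundaries (air/surface-layer,
#' surface-layer/body, body/sound) appear as gradient ridges that the
#' line-profile stage localizes.
#'
#' @param slice A [ct_slice()] (or a plain numeric matrix) at least 3x3.
#' @return Numeric matrix of gradient magnitudes, same size as the input.
#' @export
sobel_edges <- function(slice) {
  img <- if (inherits(slice, "ct_slice")) slice$image else slice
  stopifnot(is.matrix(img), is.numeric(img))
  if (nrow(img) < 3 || ncol(img) < 3)
    stop("Sobel edge detection needs an image of at least 3 x 3 pixels")
  gx <- EBImage::filter2(img, SOBEL_KX, boundary = "replicate")
  gy <- EBImage::filter2(img, SOBEL_KY, boundary = "replicate")
  sqrt(gx^2 + gy^2)
}

# Boundary positions along a 1-D signed gradient profile: suprathreshold
# runs (relative to the profile |max|), additionally split wherever the
# gradient changes sign so that adjacent edges of opposite polarity (e.g.
# air->surface-layer then surface-layer->body) are not merged, collapsed
# to |magnitude|-weighted centroids for sub-pixel localization.
gradient_boundaries <- function(g, peak_frac = 0.15) {
  m <- max(abs(g))
  if (m <= 0) return(numeric(0))
  id <- ifelse(abs(g) > peak_frac * m, sign(g), 0)
  r <- rle(id)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values != 0)
  vapply(idx, function(i) {
    rows <- starts[i]:ends[i]
    w <- abs(g[rows])
    sum(rows * w) / sum(w)
  }, numeric(1))
}

#' Lesion depth and surface-layer thickness from line profiles
#'
#' Reproduces the median-filter + Sobel + line-profile workflow: the slice
#' is smoothed ([ct_preprocess()]), edges are extracted ([sobel_edges()]),
#' and `n_lines` depth profiles, evenly spaced across the lesion's lateral
#' extent, are measured. On each profile the air/tissue surface is the
#' first dominant gradient peak and the lesion floor the last; lesion
#' depth is their separation times `pitch_um` (true scale — no refractive
#' correction). The surface layer is the run of density values elevated
#' above the midpoint between sound level (estimated below the floor) and
#' the near-surface maximum. Profiles with fewer than two gradient peaks
#' carry no lesion; if all profiles are like that the result is the
#' absent-lesion row (depth 0).
#'
#' @param slice A [ct_slice()].
#' @param roi_cols Columns spanning the lesion laterally; defaults to the
#'   `"roi_cols"` attribute, else the full width.
#' @param n_lines Number of line profiles to average (`>= 1`).
#' @param median_radius_px Smoothing radius passed to [ct_preprocess()].
#' @param peak_frac Gradient-peak threshold as a fraction of the profile
#'   maximum.
#' @return Object of class `ct_morphometry`: list with `lesion_depth_um`,
#'   `sl_thickness_um`, `n_profiles`, `lesion_present`.
#' @export
line_profile_depth <- function(slice, roi_cols = NULL, n_lines = 5,
                               median_radius_px = 1, peak_frac = 0.15) {
  stopifnot(inherits(slice, "ct_slice"), n_lines >= 1)
  if (is.null(roi_cols)) roi_cols <- attr(slice, "roi_cols")
  if (is.null(roi_cols)) roi_cols <- seq_len(ncol(slice$image))
  stopifnot(all(roi_cols >= 1), all(roi_cols <= ncol(slice$image)))
  pre <- ct_preprocess(slice, median_radius_px)
  # line profiles run along depth, so boundaries are localized on the
  # signed vertical Sobel component; the sign split keeps the air/SL and
  # SL/body edges apart even when their suprathreshold rows touch
  grad_y <- EBImage::filter2(pre$image, SOBEL_KY, boundary = "replicate")
  # keep off the lateral lesion boundary, where gx contaminates the profile
  inner <- if (length(roi_cols) > 4) roi_cols[3:(length(roi_cols) - 2)] else roi_cols
  lines <- unique(round(seq(min(inner), max(inner), length.out = n_lines)))
  ld <- sl <- rep(NA_real_, length(lines))
  for (i in seq_along(lines)) {
    j <- lines[i]
    bounds <- gradient_boundaries(grad_y[, j], peak_frac)
    if (length(bounds) < 2) next
    surface <- bounds[1]
    floor_ <- bounds[length(bounds)]
    ld[i] <- (floor_ - surface) * slice$pitch_um
    # density runs are counted on the *raw* profile: the median filter
    # protects edge localization but erases plateaus at the filter scale
    # (a one-pixel surface layer would vanish from the smoothed image)
    d <- slice$image[, j]
    deep <- d[seq.int(min(nrow(pre$image), ceiling(floor_) + 2L), nrow(pre$image))]
    sound <- stats::median(deep)
    zone_rows <- seq(max(1L, floor(surface) - 1L), floor(floor_))
    zone <- d[zone_rows]
    peak <- max(zone)
    if (peak > sound + 0.05) {
      # elevated run = consecutive rows above the midpoint between sound
      # and peak density, located directly (the surface estimate can be
      # skewed by half a pixel when thin layers merge gradient peaks)
      thr <- (sound + peak) / 2
      above <- zone > thr
      first <- which(above)[1]
      run <- if (is.na(first)) 0L else {
        n <- 0L
        for (v in above[first:length(above)]) { if (!v) break; n <- n + 1L }
        n
      }
      sl[i] <- run * slice$pitch_um
    } else sl[i] <- 0
  }
  ok <- !is.na(ld)
  out <- if (!any(ok)) {
    list(lesion_depth_um = 0, sl_thickness_um = 0,
         n_profiles = length(lines), lesion_present = FALSE)
  } else {
    list(lesion_depth_um = mean(ld[ok]), sl_thickness_um = mean(sl[ok]),
         n_profiles = sum(ok), lesion_present = TRUE)
  }
  structure(out, class = "ct_morphometry")
}

#' @export
print.ct_morphometry <- function(x, ...) {
  cat(sprintf("<ct_morphometry> LD = %.1f um, SL = %.1f um over %d profiles%s\n",
              x$lesion_depth_um, x$sl_thickness_um, x$n_profiles,
              if (x$lesion_present) "" else " (no lesion)"))
  invisible(x)
}
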