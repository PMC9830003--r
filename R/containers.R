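#' Dehydration image stack
#'
#' Container for an image time series acquired during forced-air drying:
#' one frame per time point, either SWIR reflectance (arbitrary units,
#' nominally in \[0, 1\]) or thermal (kelvin).
#'
#' @param frames Numeric array of dimension `T x H x W` (time, rows, cols),
#'   with `T >= 2` finite frames. Thermal frames must lie within
#'   \[250, 350\] K — anything outside that band is not a plausible tooth
#'   surface temperature and indicates a units mistake.
#' @param frame_interval_s Time between consecutive frames in seconds.
#' @param modality `"swir"` or `"thermal"`.
#'
#' @return An object of class `image_stack`: a list with elements
#'   `frames`, `frame_interval_s`, `modality`.
#' @examples
#' st <- image_stack(array(0.5, dim = c(3, 4, 4)), 1, "swir")
#' dim(st$frames)
#' @export
image_stack <- function(frames, frame_interval_s = 1, modality = c("swir", "thermal")) {
  modality <- match.arg(modality)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a T x H x W array")
  if (dim(frames)[1L] < 2L)
    stop("an image stack needs at least 2 frames")
  if (!all(is.finite(frames)))
    stop("`frames` contains non-finite values")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      frame_interval_s <= 0)
    stop("`frame_interval_s` must be a single positive number")
  if (modality == "thermal" && (min(frames) < 250 || max(frames) > 350))
    stop("thermal frames must be in kelvin within [250, 350]")
  structure(
    list(frames = frames, frame_interval_s = frame_interval_s, modality = modality),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %s, %d frames of %d x %d, dt = %g s\n",
              x$modality, d[1], d[2], d[3], x$frame_interval_s))
  invisible(x)
}

#' Lesion/control ROI pair
#'
#' The unit of lesion-versus-control comparison: two non-empty, disjoint
#' binary masks on the same pixel grid as the stack frames. The lesion mask
#' covers the suspected lesion; the control mask covers sound tissue on the
#' same tooth. Excluding composite restorations (which are bright in SWIR
#' and retain surface water) from both masks is the caller's responsibility.
#'
#' @param lesion_mask,control_mask Logical `H x W` matrices (or 0/1 numeric,
#'   coerced).
#' @return An object of class `roi_pair`.
#' @examples
#' les <- matrix(FALSE, 4, 4); les[1:2, 1:2] <- TRUE
#' ctl <- matrix(FALSE, 4, 4); ctl[3:4, 3:4] <- TRUE
#' roi_pair(les, ctl)
#' @export
roi_pair <- function(lesion_mask, control_mask) {
  lesion_mask <- as_mask(lesion_mask, "lesion_mask")
  control_mask <- as_mask(control_mask, "control_mask")
  if (!identical(dim(lesion_mask), dim(control_mask)))
    stop("lesion and control masks must share one pixel grid")
  if (!any(lesion_mask)) stop("lesion mask is empty")
  if (!any(control_mask)) stop("control mask is empty")
  if (any(lesion_mask & control_mask))
    stop("lesion and control masks overlap; ROIs must be disjoint")
  structure(list(lesion_mask = lesion_mask, control_mask = control_mask),
            class = "roi_pair")
}

#' @export
print.roi_pair <- function(x, ...) {
  cat(sprintf("<roi_pair> %d lesion px, %d control px on %d x %d grid\n",
              sum(x$lesion_mask), sum(x$control_mask),
              nrow(x$lesion_mask), ncol(x$lesion_mask)))
  invisible(x)
}

# Coerce to a strictly binary logical matrix; anything not 0/1 is rejected.
as_mask <- function(m, what = "mask") {
  if (is.logical(m)) {
    if (anyNA(m)) stop(what, " contains NA")
    if (!is.matrix(m)) stop(what, " must be a matrix")
    return(m)
  }
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a logical or 0/1 numeric matrix")
  if (anyNA(m) || !all(m %in% c(0, 1)))
    stop(what, " has non-binary values; masks must be 0/1")
  array(m == 1, dim = dim(m))
}

check_mask_compatible <- function(stack, mask) {
  d <- dim(stack$frames)
  if (!identical(dim(mask), d[2:3]))
    stop(sprintf("mask is %d x %d but frames are %d x %d",
                 nrow(mask), ncol(mask), d[2], d[3]))
  invisible(TRUE)
}
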