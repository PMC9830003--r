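# TIFF samples are stored as 32-bit values, which quantizes intensities
# at ~5e-10 on [0, 1] — far below any noise floor in these images. The
# writer is deterministic: identical in-memory data always produces a
# byte-identical file.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing JSON sidecar for ", path)
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

#' Write / read a dehydration stack as multi-page TIFF
#'
#' One 32-bit TIFF page per frame plus a JSON sidecar (`<name>.json`)
#' holding modality, frame interval and the affine intensity transform:
#' SWIR frames are stored as-is on \[0, 1\]; thermal frames are mapped
#' from \[250, 350\] K onto \[0, 1\] with the offset/scale recorded in the
#' sidecar. Storage is 32-bit, which limits round-trip agreement to about
#' 1e-9 intensity units (1e-7 K for thermal stacks); writing the same
#' in-memory stack always yields a byte-identical file.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  if (stack$modality == "thermal") {
    offset <- 250; scale <- 100
  } else {
    offset <- 0; scale <- 1
    if (min(stack$frames) < 0 || max(stack$frames) > 1)
      stop("SWIR stacks must lie in [0, 1] for storage")
  }
  pages <- lapply(seq_len(d[1L]), function(t)
    (stack$frames[t, , ] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  write_sidecar(path, list(kind = "image_stack", modality = stack$modality,
                           frame_interval_s = stack$frame_interval_s,
                           offset = offset, scale = scale))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$kind, "image_stack"))
    stop(path, ": sidecar does not describe an image stack")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(length(pages), dim(pages[[1L]])))
  for (t in seq_along(pages))
    frames[t, , ] <- pages[[t]] * meta$scale + meta$offset
  image_stack(frames, meta$frame_interval_s, meta$modality)
}

#' Write / read a binary ROI mask as single-page TIFF
#'
#' Masks are stored as 0/1 images; on read anything that is not exactly
#' 0 or 1 is rejected.
#'
#' @param mask Logical matrix.
#' @param path TIFF path.
#' @return `path` invisibly / the logical matrix.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  tiff::writeTIFF(array(as.numeric(mask), dim = dim(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  if (!all(img %in% c(0, 1)))
    stop(path, ": mask has non-binary values; masks must be 0/1")
  array(img == 1, dim = dim(img))
}

#' Write / read an OCT B-scan with its pitch sidecar
#'
#' @param bscan A [bscan()] with intensities in \[0, 1\].
#' @param path TIFF path; the axial pitch travels in `<name>.json`.
#' @return `path` invisibly / a [bscan()].
#' @export
write_bscan <- function(bscan, path) {
  stopifnot(inherits(bscan, "bscan"))
  tiff::writeTIFF(pmin(pmax(bscan$image, 0), 1), path,
                  bits.per.sample = 32L)
  write_sidecar(path, list(kind = "bscan",
                           axial_pitch_um_optical = bscan$axial_pitch_um_optical))
  invisible(path)
}

#' @rdname write_bscan
#' @export
read_bscan <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$kind, "bscan"))
    stop(path, ": sidecar does not describe a B-scan")
  bscan(tiff::readTIFF(path), meta$axial_pitch_um_optical)
}

#' Write / read a MicroCT slice with its pitch sidecar
#'
#' @param slice A [ct_slice()] with gray values in \[0, 1\].
#' @param path TIFF path.
#' @return `path` invisibly / a [ct_slice()].
#' @export
write_ct_slice <- function(slice, path) {
  stopifnot(inherits(slice, "ct_slice"))
  tiff::writeTIFF(pmin(pmax(slice$image, 0), 1), path,
                  bits.per.sample = 32L)
  write_sidecar(path, list(kind = "ct_slice", pitch_um = slice$pitch_um))
  invisible(path)
}

#' @rdname write_ct_slice
#' @export
read_ct_slice <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$kind, "ct_slice"))
    stop(path, ": sidecar does not describe a CT slice")
  ct_slice(tiff::readTIFF(path), meta$pitch_um)
}

#' Write an integrated heat map to TIFF
#'
#' The per-pixel dehydration map from [integrated_heatmap()], min–max
#' normalized to \[0, 1\] for storage (the original range travels in the
#' sidecar).
#'
#' @param map Numeric matrix.
#' @param path TIFF path.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(map, path) {
  stopifnot(is.matrix(map), all(is.finite(map)))
  lo <- min(map); hi <- max(map)
  scaled <- if (hi > lo) (map - lo) / (hi - lo) else map * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  write_sidecar(path, list(kind = "heatmap", min = lo, max = hi))
  invisible(path)
}

# Column schema of the joined per-lesion record table.
RECORD_COLUMNS <- c("lesion_id", "surface_type", "has_composite",
                    "dI_lesion", "dI_control", "dI_diff", "dI_ratio",
                    "dQ_lesion", "dQ_control", "dQ_diff", "dQ_ratio",
                    "ld_oct_um", "delta_R", "tsl_um", "tsl_detected",
                    "ld_ct_um", "sl_um", "activity")

#' Write / read the joined lesion record table as CSV
#'
#' The CSV carries one row per lesion with the documented measurement
#' columns (plus any `truth_*` columns when the cohort is synthetic).
#' Reading validates that every required column is present and names the
#' missing ones otherwise.
#'
#' @param records Lesion record `data.frame`.
#' @param path CSV path.
#' @return `path` invisibly / the validated `data.frame`.
#' @export
write_records <- function(records, path) {
  missing <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing))
    stop("records lack required columns: ", paste(missing, collapse = ", "))
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("no such records file: ", path)
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing))
    stop(path, " lacks required columns: ", paste(missing, collapse = ", "))
  records$tsl_detected <- as.logical(records$tsl_detected)
  records
}
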