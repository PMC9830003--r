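# The four lesion-vs-control dehydration statistics carried by a record.
DEHYDRATION_STATS <- c("dI_diff", "dI_ratio", "dQ_diff", "dQ_ratio")

#' Pearson correlation with two-sided p-value
#'
#' Thin, validated wrapper around [stats::cor.test()]. Pairs with missing
#' values are dropped; a zero-variance input yields a flagged, undefined
#' result rather than an error so that stratified reports can carry on.
#'
#' @param x,y Numeric vectors of equal length (`n >= 3` after NA removal).
#' @return List with `r`, `p`, `n`, `defined`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    return(list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), defined = TRUE)
}

#' Unpaired two-sample t-test
#'
#' Welch's unequal-variance test by default (`var_equal = TRUE` for the
#' pooled Student variant), two-sided, via [stats::t.test()].
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return List with `t`, `p`, `df`.
#' @export
unpaired_t <- function(a, b, var_equal = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 finite observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (a[1] == b[1])
      stop("both groups are constant and equal; the t statistic is undefined")
    # zero within-group variance with separated means: the limiting case
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = length(a) + length(b) - 2))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Classify lesion activity from TSL thickness
#'
#' An active lesion has no transparent surface layer; a detected layer
#' thinner than the cut marks partial arrest (remineralization under way);
#' a layer at or beyond the cut marks arrest. The boundary itself (exactly
#' `cut_um`) is assigned to "arrested" — the inclusive convention.
#'
#' @param tsl_um TSL thickness in micrometres, `>= 0` (vectorized).
#' @param tsl_detected Logical, same length.
#' @param cut_um Arrest threshold, default 70 um.
#' @return Factor with levels `active`, `partially-arrested`, `arrested`.
#' @examples
#' classify_activity(c(0, 40, 70, 80), c(FALSE, TRUE, TRUE, TRUE))
#' @export
classify_activity <- function(tsl_um, tsl_detected, cut_um = 70) {
  stopifnot(is.numeric(tsl_um), all(tsl_um >= 0),
            is.logical(tsl_detected), length(tsl_um) == length(tsl_detected),
            cut_um >= 0)
  out <- ifelse(!tsl_detected, "active",
                ifelse(tsl_um >= cut_um, "arrested", "partially-arrested"))
  factor(out, levels = c("active", "partially-arrested", "arrested"))
}

tsl_for_analysis <- function(records, include_undetected) {
  stopifnot(is.data.frame(records),
            all(c("tsl_um", "tsl_detected") %in% names(records)))
  if (include_undetected) records else records[records$tsl_detected, , drop = FALSE]
}

#' Cohort-level correlation report
#'
#' Computes the standard measurement cross-correlations for a joined
#' lesion table: OCT lesion depth vs integrated reflectivity, reflectivity
#' vs the thermal ratio statistic, TSL thickness vs each of the four
#' dehydration statistics, and TSL vs the MicroCT surface layer. Lesions
#' without a detectable TSL are excluded from TSL correlations by default
#' (set `include_undetected` to enter them as zeros).
#'
#' @param records Lesion record `data.frame` (see [run_pipeline()] for the
#'   column schema).
#' @param include_undetected Include TSL-negative lesions as thickness 0.
#' @return `data.frame` with columns `var_x`, `var_y`, `r`, `p`, `n`,
#'   `stratum`.
#' @export
correlation_report <- function(records, include_undetected = FALSE) {
  pairs <- rbind(
    c("ld_oct_um", "delta_R"),
    c("delta_R", "dQ_ratio"),
    c("tsl_um", "dI_diff"),
    c("tsl_um", "dI_ratio"),
    c("tsl_um", "dQ_diff"),
    c("tsl_um", "dQ_ratio"),
    c("tsl_um", "sl_um")
  )
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    vx <- pairs[i, 1]; vy <- pairs[i, 2]
    d <- if (vx == "tsl_um") tsl_for_analysis(records, include_undetected) else records
    pc <- pearson_cor(d[[vx]], d[[vy]])
    data.frame(var_x = vx, var_y = vy, r = pc$r, p = pc$p, n = pc$n,
               stratum = "cohort", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' TSL threshold-band analysis
#'
#' Splits lesions at `cut_um` of TSL thickness and (a) correlates TSL with
#' each dehydration statistic *within* each band, (b) compares each
#' statistic *between* bands with an unpaired t-test. Below the cut a
#' thicker layer still reduces permeability, so negative within-band
#' correlations are expected there; at and beyond the cut the lesion is
#' effectively sealed and the correlation should vanish.
#'
#' @param records Lesion record `data.frame`.
#' @param cut_um Band boundary (default 70 um; the `>= cut` band is the
#'   arrest band).
#' @param include_undetected Include TSL-negative lesions (as 0 um) in the
#'   lower band.
#' @param var_equal Passed to [unpaired_t()].
#' @return List of class `tsl_band_analysis` with `within` and `between`
#'   data frames, band sizes, and an `empty_band` flag (degenerate cuts
#'   yield a partial report, not an error).
#' @export
tsl_band_analysis <- function(records, cut_um = 70, include_undetected = FALSE,
                              var_equal = FALSE) {
  stopifnot(cut_um >= 0)
  d <- tsl_for_analysis(records, include_undetected)
  lo <- d[d$tsl_um < cut_um, , drop = FALSE]
  hi <- d[d$tsl_um >= cut_um, , drop = FALSE]
  bands <- list(below = lo, at_or_above = hi)
  within <- do.call(rbind, lapply(names(bands), function(bn) {
    b <- bands[[bn]]
    do.call(rbind, lapply(DEHYDRATION_STATS, function(st) {
      pc <- pearson_cor(b$tsl_um, b[[st]])
      data.frame(band = bn, statistic = st, r = pc$r, p = pc$p, n = pc$n,
                 computed = pc$defined, stringsAsFactors = FALSE)
    }))
  }))
  between <- do.call(rbind, lapply(DEHYDRATION_STATS, function(st) {
    if (nrow(lo) >= 2 && nrow(hi) >= 2) {
      tt <- unpaired_t(lo[[st]], hi[[st]], var_equal = var_equal)
      data.frame(statistic = st, t = tt$t, p = tt$p, df = tt$df,
                 computed = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(statistic = st, t = NA_real_, p = NA_real_, df = NA_real_,
                 computed = FALSE, stringsAsFactors = FALSE)
    }
  }))
  structure(list(within = within, between = between,
                 n_below = nrow(lo), n_at_or_above = nrow(hi),
                 cut_um = cut_um,
                 empty_band = nrow(lo) == 0 || nrow(hi) == 0),
            class = "tsl_band_analysis")
}

#' @export
print.tsl_band_analysis <- function(x, ...) {
  cat(sprintf("<tsl_band_analysis> cut %g um: n < cut = %d, n >= cut = %d%s\n",
              x$cut_um, x$n_below, x$n_at_or_above,
              if (x$empty_band) " [empty band]" else ""))
  print(x$within)
  print(x$between)
  invisible(x)
}

#' Surface-type stratified correlations
#'
#' Correlates TSL thickness with each dehydration statistic separately per
#' surface type (occlusal / smooth / incisal). Water pools in occlusal and
#' incisal crevice anatomy and inflates the thermal signal there, so the
#' smooth-surface stratum is expected to carry the cleanest negative
#' correlations. Strata with fewer than 3 usable lesions are flagged
#' `computed = FALSE`.
#'
#' @param records Lesion record `data.frame` with a `surface_type` column.
#' @param include_undetected Include TSL-negative lesions as 0 um.
#' @return `data.frame` with columns `surface_type`, `statistic`, `r`,
#'   `p`, `n`, `computed`.
#' @export
stratify_by_surface <- function(records, include_undetected = FALSE) {
  stopifnot("surface_type" %in% names(records))
  d <- tsl_for_analysis(records, include_undetected)
  types <- unique(records$surface_type)
  do.call(rbind, lapply(types, function(ty) {
    b <- d[d$surface_type == ty, , drop = FALSE]
    do.call(rbind, lapply(DEHYDRATION_STATS, function(st) {
      pc <- pearson_cor(b$tsl_um, b[[st]])
      data.frame(surface_type = ty, statistic = st, r = pc$r, p = pc$p,
                 n = nrow(b), computed = pc$defined, stringsAsFactors = FALSE)
    }))
  }))
}
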