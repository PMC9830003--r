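# Independent brute-force oracles for the integrated dehydration
# statistics: explicit two-pass loops, no shared code with the package.
oracle_delta_I <- function(curve) {
  m <- curve[1]
  for (v in curve) if (v < m) m <- v
  s <- 0
  for (v in curve) s <- s + (v - m)
  s
}

oracle_delta_Q <- function(curve) {
  m <- curve[1]
  for (v in curve) if (v > m) m <- v
  s <- 0
  for (v in curve) s <- s + (m - v)
  s
}

# Direct-formula Pearson r with the two-sided p from the t transform.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

# Textbook Welch t-test.
oracle_welch_t <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df))
}

# A minimal lesion truth for renderer tests.
make_truth <- function(tsl = 0, depth = 150, ml = 0.2, pool = 0,
                       surface = "smooth", composite = FALSE, seed = 42) {
  list(lesion_id = 1L, surface_type = surface, has_composite = composite,
       lesion_depth_um = depth, tsl_thickness_um = tsl,
       mineral_loss_frac = ml, permeability = permeability_from_tsl(tsl),
       water_pool_frac = pool, sl_thickness_um = 40, render_seed = seed)
}

# Small quiet config for fast renderer tests.
quiet_config <- function(...) {
  cohort_config(n_lesions = 1, noise_sd_swir = 0, noise_sd_thermal = 0,
                noise_sd_oct = 0, noise_sd_ct = 0, seed = 1, ...)
}

# Hand-built B-scan: flat surface reflection plus a bright body band.
# Depth geometry is explicit so tests can assert exact row arithmetic.
manual_bscan <- function(n_rows = 120, n_cols = 40, surface_row = 10,
                         body_rows = NULL, body_val = 0.9, pitch = 5) {
  img <- matrix(0, n_rows, n_cols)
  img[surface_row, ] <- 0.35
  img[(surface_row + 1):n_rows, ] <- 0.15 * exp(-(1:(n_rows - surface_row)) / 40)
  if (!is.null(body_rows)) img[body_rows, ] <- body_val
  bscan(img, pitch)
}
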