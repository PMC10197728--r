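# truncate to the printed precision (floor with an epsilon guard); this is
# the reporting rule that reproduces the system's published resolution
# figures, e.g. 2 x 3.33 = 6.66 -> 6.6 nm and 1000/64 = 15.625 -> 15.6 um
report_trunc <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 1e-9) / s
}

#' USAF-1951 element spatial frequency
#'
#' Frequency of a three-bar element on the standard 1951 USAF resolution
#' target: `2^(group + (element - 1) / 6)` line pairs per mm.
#'
#' @param group integer group number (may be negative).
#' @param element element number, 1 to 6.
#' @return frequency in lp/mm (vectorized).
#' @export
usaf_frequency <- function(group, element) {
  if (any(element < 1 | element > 6))
    stop("element must be between 1 and 6")
  2^(group + (element - 1) / 6)
}

#' Full line-pair period of a spatial frequency
#'
#' `1000 / f` micrometres per line pair (one bar plus one gap); the figure
#' quoted as "spatial resolution" for a minimally resolvable element.
#' Reported at the printed precision of 1 decimal.
#'
#' @param f frequency in lp/mm, `> 0`.
#' @param digits reporting precision; `NULL` returns the exact period.
#' @return period in micrometres.
#' @export
frequency_to_period <- function(f, digits = 1) {
  if (any(f <= 0)) stop("frequency must be positive")
  p <- 1000 / f
  if (is.null(digits)) p else report_trunc(p, digits)
}

#' Michelson contrast of an intensity profile
#'
#' `(Imax - Imin) / (Imax + Imin)` across a 1D bar profile; scale-invariant
#' and in `[0, 1]` for non-negative profiles.
#'
#' @param profile non-empty, non-negative intensity sequence, not all zero.
#' @return contrast in `[0, 1]`.
#' @export
michelson_contrast <- function(profile) {
  if (length(profile) == 0) stop("profile must be non-empty")
  if (any(profile < 0)) stop("profile must be non-negative")
  hi <- max(profile); lo <- min(profile)
  if (hi + lo == 0) stop("contrast undefined for an all-zero profile")
  (hi - lo) / (hi + lo)
}

#' Resolvability decision at a contrast threshold
#'
#' A bar element counts as resolved when its contrast reaches the
#' threshold; ties at exactly the threshold resolve as resolvable.
#'
#' @param contrast contrast value(s) in `[0, 1]`.
#' @param threshold decision threshold (default 0.4).
#' @return logical.
#' @export
is_resolvable <- function(contrast, threshold = 0.4) {
  if (any(contrast < 0 | contrast > 1)) stop("contrast must be in [0, 1]")
  contrast >= threshold
}

#' Spectral resolution from dispersion power
#'
#' The spectral resolution at a wavelength equals the dispersion traversed
#' by the smallest coded feature: `feature_px * nm_per_pixel`. With the
#' standard 2-pixel feature the resolution is double the pixel dispersion.
#' Reported at the printed precision of 1 decimal.
#'
#' @param nm_per_pixel local dispersion power, `>= 0`.
#' @param feature_px smallest coded feature in camera pixels (default 2).
#' @param digits reporting precision; `NULL` returns the exact product.
#' @return resolution in nm (vectorized).
#' @export
spectral_resolution <- function(nm_per_pixel, feature_px = 2L, digits = 1) {
  if (any(nm_per_pixel < 0)) stop("nm_per_pixel must be non-negative")
  if (any(feature_px < 1)) stop("feature_px must be >= 1")
  r <- nm_per_pixel * feature_px
  if (is.null(digits)) r else report_trunc(r, digits)
}

#' Per-segment spectral resolution table of a dispersion model
#'
#' @param model a [dispersion_model()].
#' @param feature_px smallest coded feature (default 2).
#' @return tibble with `lambda_start_nm`, `lambda_end_nm`, `nm_per_pixel`,
#'   `spectral_resolution_nm` (reported at 1 decimal).
#' @export
dispersion_resolution_table <- function(model, feature_px = 2L) {
  seg <- model$segments
  tibble::tibble(
    lambda_start_nm = seg$lambda_start_nm,
    lambda_end_nm = seg$lambda_end_nm,
    nm_per_pixel = seg$nm_per_pixel,
    spectral_resolution_nm = spectral_resolution(seg$nm_per_pixel,
                                                 feature_px))
}

#' Bandwidth-weighted average spectral resolution
#'
#' Mean of per-band resolutions weighted by each band's wavelength extent;
#' reported rounded to the nearest integer nm with the exact value
#' alongside.
#'
#' @param table data frame with columns `lambda_start_nm`, `lambda_end_nm`,
#'   `spectral_resolution_nm` (as from [dispersion_resolution_table()]).
#' @return list with `nm` (rounded) and `exact`.
#' @export
average_spectral_resolution <- function(table) {
  table <- as.data.frame(table)
  if (nrow(table) == 0) stop("table must be non-empty")
  bw <- table$lambda_end_nm - table$lambda_start_nm
  if (sum(bw) <= 0) stop("total bandwidth must be positive")
  exact <- sum(bw * table$spectral_resolution_nm) / sum(bw)
  list(nm = round(exact), exact = exact)
}

#' System resolution report
#'
#' The package's metrology summary: the per-band spectral resolution table
#' derived from the prism calibration, the bandwidth-weighted average, and
#' the spatial periods of the minimally resolvable USAF elements along the
#' two bar orientations (vertical bars probe the horizontal direction and
#' vice versa).
#'
#' @param model a [dispersion_model()].
#' @param feature_px smallest coded feature in camera pixels.
#' @param usaf_horizontal `c(group, element)` of the limiting element with
#'   vertical bars (horizontal resolution); default `c(5, 6)`.
#' @param usaf_vertical `c(group, element)` of the limiting element with
#'   horizontal bars (vertical resolution); default `c(6, 1)`.
#' @param contrast_threshold resolvability threshold used (recorded).
#' @return a `resolution_report` list: `bands` tibble, `average_nm`,
#'   `average_exact_nm`, `horizontal_um`, `vertical_um`, element specs and
#'   the threshold.
#' @export
resolution_report <- function(model = cassi_dispersion(), feature_px = 2L,
                              usaf_horizontal = c(5, 6),
                              usaf_vertical = c(6, 1),
                              contrast_threshold = 0.4) {
  bands <- dispersion_resolution_table(model, feature_px)
  avg <- average_spectral_resolution(bands)
  fh <- usaf_frequency(usaf_horizontal[1], usaf_horizontal[2])
  fv <- usaf_frequency(usaf_vertical[1], usaf_vertical[2])
  structure(list(
    bands = bands,
    average_nm = avg$nm,
    average_exact_nm = avg$exact,
    horizontal_um = frequency_to_period(fh),
    vertical_um = frequency_to_period(fv),
    usaf_horizontal = as.integer(usaf_horizontal),
    usaf_vertical = as.integer(usaf_vertical),
    horizontal_lp_mm = fh,
    vertical_lp_mm = fv,
    contrast_threshold = contrast_threshold),
    class = "resolution_report")
}

#' @export
print.resolution_report <- function(x, ...) {
  cat("Spectral resolution by band:\n")
  print(x$bands)
  cat(sprintf("Average spectral resolution: %d nm (exact %.3f nm)\n",
              x$average_nm, x$average_exact_nm))
  cat(sprintf(
    "Spatial resolution: horizontal %.1f um (group %d element %d, %.1f lp/mm)\n",
    x$horizontal_um, x$usaf_horizontal[1], x$usaf_horizontal[2],
    x$horizontal_lp_mm))
  cat(sprintf(
    "                    vertical   %.1f um (group %d element %d, %.1f lp/mm)\n",
    x$vertical_um, x$usaf_vertical[1], x$usaf_vertical[2],
    x$vertical_lp_mm))
  cat(sprintf("Contrast threshold for resolvability: %.2f\n",
              x$contrast_threshold))
  invisible(x)
}
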