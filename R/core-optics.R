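#' Spectral datacube
#'
#' A discretized spectral scene \eqn{f(x, y; \lambda)}: a `rows x cols x L`
#' non-negative array together with the centre wavelength of each of the `L`
#' bands and the `L + 1` band edges. This is the container every simulator
#' and reconstruction routine in the package consumes and produces.
#'
#' @param values numeric array `rows x cols x L` (a matrix is treated as a
#'   single band). Band `k` is `values[, , k]`.
#' @param band_centers_nm strictly increasing vector of `L` centre
#'   wavelengths in nm.
#' @param band_edges_nm increasing vector of `L + 1` band edges in nm, each
#'   centre strictly inside its edge pair. Defaults to midpoints between
#'   centres, extended half a step at both ends.
#' @param physical if `TRUE` (the default) negative values are rejected.
#'   Internal optimization iterates set this to `FALSE`.
#'
#' @return an object of class `cassi_cube`: the array with attributes
#'   `band_centers_nm` and `band_edges_nm`.
#' @export
spectral_cube <- function(values, band_centers_nm, band_edges_nm = NULL,
                          physical = TRUE) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (length(dim(values)) != 3L)
    stop_dim("cube values must be a rows x cols x bands array")
  L <- dim(values)[3L]
  if (L < 1L) stop("cube must have at least one band")
  if (length(band_centers_nm) != L)
    stop_dim("band count mismatch: %d pages vs %d centres", L,
             length(band_centers_nm))
  if (L > 1L && any(diff(band_centers_nm) <= 0))
    stop("band_centers_nm must be strictly increasing")
  if (is.null(band_edges_nm)) {
    if (L == 1L) {
      band_edges_nm <- band_centers_nm + c(-0.5, 0.5)
    } else {
      mid <- (band_centers_nm[-1] + band_centers_nm[-L]) / 2
      band_edges_nm <- c(2 * band_centers_nm[1] - mid[1], mid,
                         2 * band_centers_nm[L] - mid[L - 1])
    }
  }
  if (length(band_edges_nm) != L + 1L)
    stop_dim("band_edges_nm must have length L + 1")
  if (any(diff(band_edges_nm) <= 0))
    stop("band_edges_nm must be increasing")
  if (any(band_centers_nm <= band_edges_nm[-(L + 1L)]) ||
      any(band_centers_nm >= band_edges_nm[-1L]))
    stop("each band centre must lie strictly inside its edges")
  if (physical && any(values < 0))
    stop("physical scenes must be non-negative")
  structure(values,
            band_centers_nm = as.numeric(band_centers_nm),
            band_edges_nm = as.numeric(band_edges_nm),
            class = "cassi_cube")
}

#' @export
print.cassi_cube <- function(x, ...) {
  d <- dim(x)
  wl <- attr(x, "band_centers_nm")
  cat(sprintf("<cassi_cube> %d x %d x %d bands, %.1f-%.1f nm, range [%g, %g]\n",
              d[1], d[2], d[3], min(wl), max(wl), min(x), max(x)))
  invisible(x)
}

#' Band centre wavelengths of a cube
#' @param cube a [spectral_cube()].
#' @return numeric vector of centre wavelengths in nm.
#' @export
band_centers <- function(cube) attr(cube, "band_centers_nm")

#' Band edge wavelengths of a cube
#' @param cube a [spectral_cube()].
#' @return numeric vector of `L + 1` edges in nm.
#' @export
band_edges <- function(cube) attr(cube, "band_edges_nm")

#' Binary coded aperture
#'
#' The transmission pattern \eqn{T(x, y)} placed at the relayed image plane.
#' Entries are 0 (opaque) or 1 (transparent); `feature_px` records the side
#' of the smallest coded feature in camera pixels (2 in the calibrated
#' system: the smallest mask feature is sampled by about 2 x 2 pixels).
#'
#' @param values 0/1 matrix over (row, col).
#' @param feature_px smallest-feature side in camera pixels.
#' @param seed generation seed, or `NA` for measured/hand-made masks.
#' @return a `cassi_mask` (the matrix with attributes).
#' @export
coded_mask <- function(values, feature_px = 2L, seed = NA_integer_) {
  values <- as.matrix(values)
  if (!all(values %in% c(0, 1)))
    stop("mask entries must all be 0 or 1")
  if (feature_px < 1L) stop("feature_px must be >= 1")
  structure(values * 1.0, feature_px = as.integer(feature_px),
            seed = seed, class = "cassi_mask")
}

#' @export
print.cassi_mask <- function(x, ...) {
  cat(sprintf("<cassi_mask> %d x %d, feature %d px, fill %.3f\n",
              nrow(x), ncol(x), attr(x, "feature_px"), mean(x)))
  invisible(x)
}

#' Random block-constant binary mask
#'
#' Generates the random binary pattern of a lithographed coded aperture:
#' each `feature_px x feature_px` block is independently transparent with
#' probability `fill`. Reproducible: the same seed gives a bit-identical
#' mask.
#'
#' @param rows,cols mask size in camera pixels; both must be divisible by
#'   `feature_px`.
#' @param feature_px smallest-feature side in pixels (default 2).
#' @param fill probability in `[0, 1]` that a feature is transparent.
#' @param seed integer RNG seed.
#' @return a [coded_mask()].
#' @export
random_mask <- function(rows, cols, feature_px = 2L, fill = 0.5, seed = 1L) {
  feature_px <- as.integer(feature_px)
  if (rows %% feature_px != 0L || cols %% feature_px != 0L)
    stop_dim("mask dimensions (%d x %d) must be divisible by feature_px = %d",
             rows, cols, feature_px)
  if (fill < 0 || fill > 1) stop("fill must be in [0, 1]")
  br <- rows %/% feature_px
  bc <- cols %/% feature_px
  blocks <- with_seed(seed, matrix(rbinom(br * bc, 1L, fill), br, bc))
  values <- blocks %x% matrix(1, feature_px, feature_px)
  coded_mask(values, feature_px = feature_px, seed = as.integer(seed))
}

#' Prism dispersion model
#'
#' The nonlinear lateral dispersion \eqn{D(\lambda)} of the prism as a
#' piecewise-linear calibration: contiguous wavelength segments, each with a
#' constant dispersion power in nm per camera pixel. The pixel shift of a
#' wavelength is obtained by integrating `1 / nm_per_pixel` from the
#' reference wavelength (which has zero shift).
#'
#' @param segments data frame (or matrix) with columns `lambda_start_nm`,
#'   `lambda_end_nm`, `nm_per_pixel`; segments must be ordered, contiguous
#'   and have positive dispersion.
#' @param reference_nm wavelength with zero shift; defaults to the start of
#'   the first segment.
#' @return a `dispersion_model` object.
#' @seealso [cassi_dispersion()] for the packaged fundus-system calibration.
#' @export
dispersion_model <- function(segments, reference_nm = NULL) {
  segments <- as.data.frame(segments)
  names(segments) <- c("lambda_start_nm", "lambda_end_nm", "nm_per_pixel")
  n <- nrow(segments)
  if (n < 1L) stop("at least one segment is required")
  if (any(segments$lambda_end_nm <= segments$lambda_start_nm))
    stop("each segment must have lambda_end > lambda_start")
  if (any(segments$nm_per_pixel <= 0))
    stop("nm_per_pixel must be positive")
  if (n > 1L &&
      any(abs(segments$lambda_start_nm[-1] - segments$lambda_end_nm[-n]) >
          1e-9))
    stop("segments must be contiguous and ordered")
  if (is.null(reference_nm)) reference_nm <- segments$lambda_start_nm[1]
  if (reference_nm < segments$lambda_start_nm[1] - 1e-9 ||
      reference_nm > segments$lambda_end_nm[n] + 1e-9)
    stop("reference_nm must lie inside the calibrated range")
  structure(list(segments = segments, reference_nm = reference_nm),
            class = "dispersion_model")
}

#' @export
print.dispersion_model <- function(x, ...) {
  cat(sprintf("<dispersion_model> %d segments, %g-%g nm, reference %g nm\n",
              nrow(x$segments), min(x$segments$lambda_start_nm),
              max(x$segments$lambda_end_nm), x$reference_nm))
  print(tibble::as_tibble(x$segments))
  invisible(x)
}

#' Packaged prism calibration for the 445-602 nm fundus CASSI system
#'
#' The measured wavelength-dependent dispersion power of the wedge prism,
#' calibrated by imaging a blank field under monochromatic illumination at
#' a series of wavelengths: four contiguous bands between 445 and 602 nm
#' with dispersion powers 1.67, 2.00, 2.50 and 3.33 nm/pixel.
#'
#' @return a [dispersion_model()] with reference wavelength 445 nm.
#' @export
cassi_dispersion <- function() {
  dispersion_model(data.frame(
    lambda_start_nm = c(445, 480, 510, 560),
    lambda_end_nm   = c(480, 510, 560, 602),
    nm_per_pixel    = c(1.67, 2.00, 2.50, 3.33)
  ), reference_nm = 445)
}

#' Lateral pixel shift of a wavelength
#'
#' Cumulative dispersion shift \eqn{D(\lambda)} in camera pixels relative to
#' the model's reference wavelength, integrating `1 / nm_per_pixel` across
#' the piecewise-linear calibration. Strictly increasing in wavelength; no
#' extrapolation outside the calibrated range.
#'
#' @param model a [dispersion_model()].
#' @param lambda_nm wavelength(s) in nm, inside the calibrated range.
#' @return pixel shift(s), zero at `reference_nm`.
#' @export
dispersion_shift <- function(model, lambda_nm) {
  seg <- model$segments
  lo <- seg$lambda_start_nm[1]
  hi <- seg$lambda_end_nm[nrow(seg)]
  if (any(lambda_nm < lo - 1e-9) || any(lambda_nm > hi + 1e-9))
    stop(sprintf("wavelength outside calibrated range [%g, %g] nm", lo, hi))
  cum_at <- function(l) {
    # pixels accumulated from the start of the table up to wavelength l
    over <- pmin(pmax(l - seg$lambda_start_nm, 0),
                 seg$lambda_end_nm - seg$lambda_start_nm)
    sum(over / seg$nm_per_pixel)
  }
  ref <- cum_at(model$reference_nm)
  vapply(lambda_nm, cum_at, numeric(1)) - ref
}

#' Wavelength at a given dispersion shift (inverse of [dispersion_shift()])
#'
#' @param model a [dispersion_model()].
#' @param shift_px pixel shift(s) relative to the reference wavelength.
#' @return wavelength(s) in nm.
#' @export
dispersion_wavelength <- function(model, shift_px) {
  seg <- model$segments
  n <- nrow(seg)
  starts <- dispersion_shift(model, seg$lambda_start_nm)
  ends <- dispersion_shift(model, seg$lambda_end_nm)
  if (any(shift_px < starts[1] - 1e-9) || any(shift_px > ends[n] + 1e-9))
    stop("shift outside calibrated range")
  vapply(shift_px, function(s) {
    j <- max(1L, findInterval(s, starts, rightmost.closed = TRUE))
    j <- min(j, n)
    seg$lambda_start_nm[j] + (s - starts[j]) * seg$nm_per_pixel[j]
  }, numeric(1))
}

#' Discretize a wavelength range into dispersion-uniform bands
#'
#' Chooses spectral bands so that consecutive band centres are separated by
#' exactly `feature_px` camera pixels of dispersion: band `k` (0-based)
#' carries the integer detector shift `d_k = k * feature_px`. This is the
#' discretization under which the smallest coded feature steps by one full
#' feature per band, so `L = ceiling(D(lambda_max) - D(lambda_min)) /
#' feature_px)` bands cover the range. Band edges are mapped back to
#' wavelength through the inverse dispersion and clipped to the range.
#'
#' @param model a [dispersion_model()].
#' @param lambda_min_nm,lambda_max_nm range to discretize, inside the model.
#' @param feature_px smallest coded feature in camera pixels (default 2).
#' @return a `band_discretization`: list with `band_centers_nm`,
#'   `band_edges_nm`, integer `shifts_px` (length `L`), `L`, `feature_px`.
#' @export
discretize_bands <- function(model, lambda_min_nm, lambda_max_nm,
                             feature_px = 2L) {
  if (lambda_min_nm >= lambda_max_nm)
    stop("lambda_min_nm must be below lambda_max_nm")
  feature_px <- as.integer(feature_px)
  if (feature_px < 1L) stop("feature_px must be >= 1")
  s0 <- dispersion_shift(model, lambda_min_nm)
  s1 <- dispersion_shift(model, lambda_max_nm)
  total <- s1 - s0
  if (total < feature_px)
    stop("wavelength range spans less than one feature step of dispersion")
  L <- as.integer(ceiling(total / feature_px))
  offsets <- (seq_len(L) - 1L) * feature_px
  centers <- dispersion_wavelength(model, s0 + offsets)
  edge_off <- pmin(pmax(c(offsets - feature_px / 2,
                          offsets[L] + feature_px / 2), 0), total)
  edges <- dispersion_wavelength(model, s0 + edge_off)
  # degenerate clipped first edge: nudge below the first centre
  if (edges[1] >= centers[1]) edges[1] <- centers[1] - 1e-6
  if (edges[L + 1] <= centers[L]) edges[L + 1] <- centers[L] + 1e-6
  structure(list(band_centers_nm = centers, band_edges_nm = edges,
                 shifts_px = as.integer(offsets), L = L,
                 feature_px = feature_px),
            class = "band_discretization")
}

#' @export
print.band_discretization <- function(x, ...) {
  cat(sprintf(
    "<band_discretization> L = %d bands, %.1f-%.1f nm, shifts 0..%d px (step %d)\n",
    x$L, x$band_centers_nm[1], x$band_centers_nm[x$L],
    max(x$shifts_px), x$feature_px))
  invisible(x)
}
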