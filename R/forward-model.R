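#' Matrix-free CASSI sensing operator
#'
#' The linear map \eqn{\Phi} from a spectral datacube to the 2D multiplexed
#' sensor image: every band is modulated by the coded mask, sheared along +x
#' by its integer dispersion shift `d_k`, and the shifted copies are summed
#' on the detector. The detector is `max(shifts)` columns wider than the
#' scene so no shifted energy is cropped. \eqn{\Phi\Phi^T} is diagonal for a
#' binary mask and distinct shifts, which the reconstructor exploits.
#'
#' @param mask a [coded_mask()] (or 0/1 matrix), same size as the scene.
#' @param shifts non-negative, non-decreasing integer per-band shifts in
#'   pixels, length `L`.
#' @param scene_shape `c(rows, cols)` of the scene; defaults to `dim(mask)`.
#' @return a `sensing_operator`.
#' @export
sensing_operator <- function(mask, shifts, scene_shape = dim(mask)) {
  if (!inherits(mask, "cassi_mask")) mask <- coded_mask(mask)
  shifts <- as.integer(shifts)
  if (length(shifts) < 1L) stop("at least one band shift is required")
  if (any(shifts < 0)) stop("shifts must be non-negative")
  if (any(diff(shifts) < 0)) stop("shifts must be non-decreasing")
  if (!all(dim(mask) == scene_shape))
    stop_dim("mask is %d x %d but scene_shape is %d x %d",
             nrow(mask), ncol(mask), scene_shape[1], scene_shape[2])
  structure(list(mask = mask, shifts = shifts,
                 scene_shape = as.integer(scene_shape),
                 detector_shape = c(as.integer(scene_shape[1]),
                                    as.integer(scene_shape[2]) + max(shifts)),
                 L = length(shifts)),
            class = "sensing_operator")
}

#' @export
print.sensing_operator <- function(x, ...) {
  cat(sprintf(
    "<sensing_operator> scene %d x %d x %d -> detector %d x %d, shifts %s px\n",
    x$scene_shape[1], x$scene_shape[2], x$L,
    x$detector_shape[1], x$detector_shape[2],
    paste(range(x$shifts), collapse = "..")))
  invisible(x)
}

#' Detector measurement
#'
#' @param values non-negative matrix on the detector grid.
#' @param noise_sigma Gaussian noise s.d. used when simulating (0 if none).
#' @param seed noise seed, or `NA`.
#' @return a `cassi_measurement` (matrix with attributes).
#' @export
measurement <- function(values, noise_sigma = 0, seed = NA_integer_) {
  structure(as.matrix(values), noise_sigma = noise_sigma, seed = seed,
            class = "cassi_measurement")
}

#' @export
print.cassi_measurement <- function(x, ...) {
  cat(sprintf("<cassi_measurement> %d x %d, range [%g, %g], sigma %g\n",
              nrow(x), ncol(x), min(x), max(x), attr(x, "noise_sigma")))
  invisible(x)
}

#' Modulate a scene by the coded aperture
#'
#' Elementwise product of every band with the binary transmission pattern:
#' the image immediately after the coded mask.
#'
#' @param cube a [spectral_cube()].
#' @param mask a [coded_mask()] with the cube's spatial shape.
#' @return the modulated [spectral_cube()].
#' @export
apply_mask <- function(cube, mask) {
  d <- dim(cube)
  if (!all(dim(mask) == d[1:2]))
    stop_dim("mask %d x %d does not match scene %d x %d",
             nrow(mask), ncol(mask), d[1], d[2])
  out <- unclass(cube) * as.vector(mask)  # mask recycles over bands
  spectral_cube(out, band_centers(cube), band_edges(cube), physical = FALSE)
}

# internal raw-array forward: mask, shear +x, accumulate
.forward_arr <- function(op, arr) {
  rows <- op$scene_shape[1]; cols <- op$scene_shape[2]
  y <- matrix(0, op$detector_shape[1], op$detector_shape[2])
  m <- unclass(op$mask)
  for (k in seq_len(op$L)) {
    d <- op$shifts[k]
    y[, (d + 1L):(d + cols)] <- y[, (d + 1L):(d + cols)] + m * arr[, , k]
  }
  y
}

# internal raw-array adjoint: un-shear, crop, mask
.adjoint_arr <- function(op, y) {
  rows <- op$scene_shape[1]; cols <- op$scene_shape[2]
  f <- array(0, c(rows, cols, op$L))
  m <- unclass(op$mask)
  for (k in seq_len(op$L)) {
    d <- op$shifts[k]
    f[, , k] <- m * y[, (d + 1L):(d + cols)]
  }
  f
}

#' Forward CASSI measurement \eqn{y = \Phi f}
#'
#' Noiseless sensor image: the sum over bands of the mask-modulated scene,
#' each band sheared along +x by its dispersion shift, accumulated on the
#' widened detector grid (zero padding outside the scene footprint).
#'
#' @param op a [sensing_operator()].
#' @param cube a [spectral_cube()] matching the operator's scene shape and
#'   band count.
#' @return a [measurement()].
#' @export
cassi_forward <- function(op, cube) {
  d <- dim(cube)
  if (!all(d[1:2] == op$scene_shape) || d[3] != op$L)
    stop_dim("cube %d x %d x %d does not match operator scene %d x %d x %d",
             d[1], d[2], d[3], op$scene_shape[1], op$scene_shape[2], op$L)
  measurement(.forward_arr(op, unclass(cube)))
}

#' Adjoint operator \eqn{\Phi^T y}
#'
#' Exact transpose of [cassi_forward()]: band `k` of the output is the mask
#' times the detector image shifted back by `d_k` and cropped to the scene.
#' Values may be negative (optimization iterates); band metadata carries
#' integer indices when none is supplied.
#'
#' @param op a [sensing_operator()].
#' @param y a [measurement()] (or matrix) on the operator's detector grid.
#' @param band_centers_nm optional wavelengths for the output cube.
#' @return a [spectral_cube()] (non-physical: negatives allowed).
#' @export
cassi_adjoint <- function(op, y, band_centers_nm = NULL) {
  if (!all(dim(y) == op$detector_shape))
    stop_dim("measurement %d x %d does not match detector %d x %d",
             nrow(y), ncol(y), op$detector_shape[1], op$detector_shape[2])
  f <- .adjoint_arr(op, unclass(y))
  if (is.null(band_centers_nm)) band_centers_nm <- seq_len(op$L)
  spectral_cube(f, band_centers_nm, physical = FALSE)
}

#' Diagonal of the Gram matrix \eqn{\Phi\Phi^T}
#'
#' For a binary mask and per-band integer shifts the Gram matrix is exactly
#' diagonal; its diagonal, reshaped to the detector grid, counts at each
#' detector pixel the number of bands whose shifted mask is transparent
#' there: \eqn{R(m, n) = \sum_k T(m, n - d_k)^2}. This map is what makes the
#' data-consistency projection solvable in one shot.
#'
#' @param op a [sensing_operator()].
#' @return non-negative matrix on the detector grid.
#' @export
gram_diagonal <- function(op) {
  cols <- op$scene_shape[2]
  R <- matrix(0, op$detector_shape[1], op$detector_shape[2])
  m2 <- unclass(op$mask)^2
  for (d in op$shifts)
    R[, (d + 1L):(d + cols)] <- R[, (d + 1L):(d + cols)] + m2
  R
}

#' Add sensor noise
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation `sigma` to a
#' measurement, reproducibly under `seed`. `sigma = 0` returns the input
#' unchanged.
#'
#' @param y a [measurement()].
#' @param sigma noise standard deviation (same units as `y`), `>= 0`.
#' @param seed integer RNG seed (optional).
#' @return a [measurement()] with `noise_sigma` and `seed` recorded.
#' @export
add_noise <- function(y, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(y)
  g <- with_seed(seed, matrix(rnorm(length(y), 0, sigma), nrow(y), ncol(y)))
  measurement(unclass(y) + g, noise_sigma = sigma,
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
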