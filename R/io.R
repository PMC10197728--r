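# --- on-disk formats ---------------------------------------------------
# cube:        multi-page 32-bit TIFF + JSON sidecar (<path>.json) holding
#              wavelengths and the affine offset/scale mapping the stored
#              [0, 1] samples back to physical values
# measurement: single-page 32-bit TIFF + JSON sidecar with shifts, scene
#              shape, band centres, mask hash, sigma, seed
# mask:        8-bit PNG or TIFF image, 0 = opaque, 255 = transparent;
#              loader binarizes at threshold 128
# dispersion:  JSON {segments: [[start, end, nm_per_pixel], ...],
#              reference_nm}

sidecar_path <- function(path) paste0(path, ".json")

# affine normalization to [0, 1] for 32-bit TIFF samples; returns the
# mapping so the reader can undo it exactly
.tiff_norm <- function(v) {
  offset <- min(v, 0)
  scale <- max(v) - offset
  if (scale <= 0) scale <- 1
  list(offset = offset, scale = scale)
}

.write_norm_tiff <- function(pages, path, norm) {
  pages <- lapply(pages, function(p) (p - norm$offset) / norm$scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
}

#' Write / read a spectral datacube
#'
#' Cubes are stored as multi-page 32-bit TIFF with a JSON sidecar
#' (`<path>.json`) carrying the band wavelengths and the affine
#' offset/scale that maps the stored `[0, 1]` samples back to physical
#' values. The round trip is exact at 32-bit quantization (relative error
#' below `2^-31` of the value range).
#'
#' @param cube a [spectral_cube()].
#' @param path output TIFF path.
#' @return `write_cube` returns `path` invisibly; `read_cube` returns the
#'   [spectral_cube()].
#' @export
write_cube <- function(cube, path) {
  v <- unclass(cube)
  norm <- .tiff_norm(v)
  pages <- lapply(seq_len(dim(v)[3]), function(k) {
    p <- v[, , k, drop = FALSE]
    dim(p) <- dim(v)[1:2]
    p
  })
  .write_norm_tiff(pages, path, norm)
  meta <- list(format = "cassi_cube", L = dim(v)[3],
               band_centers_nm = band_centers(cube),
               band_edges_nm = band_edges(cube),
               offset = norm$offset, scale = norm$scale)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing metadata sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$L)
    stop(sprintf("format error: %d TIFF pages but sidecar says L = %d",
                 length(pages), meta$L))
  off <- meta$offset %||% 0
  vals <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages))
    vals[, , k] <- pages[[k]] * meta$scale + off
  spectral_cube(vals, meta$band_centers_nm, meta$band_edges_nm,
                physical = FALSE)
}

#' Write / read a detector measurement
#'
#' Measurements are stored as single-page 32-bit TIFF plus a JSON
#' sidecar recording the affine offset/scale of the stored samples and everything needed to reconstruct: band shifts, scene
#' shape, band centre wavelengths, the MD5 of the mask file (when given),
#' noise sigma and seed.
#'
#' @param y a [measurement()].
#' @param path output TIFF path.
#' @param op the generating [sensing_operator()] (optional but recommended:
#'   stores shifts and scene shape).
#' @param mask_file path of the mask image used (hashed into the sidecar).
#' @param band_centers_nm band centres of the simulated scene.
#' @return `write_measurement` returns `path` invisibly;
#'   `read_measurement` returns a list `y`, `meta`.
#' @export
write_measurement <- function(y, path, op = NULL, mask_file = NULL,
                              band_centers_nm = NULL) {
  v <- unclass(y)
  norm <- .tiff_norm(v)
  .write_norm_tiff(list(v), path, norm)
  meta <- list(format = "cassi_measurement", offset = norm$offset,
               scale = norm$scale,
               noise_sigma = attr(y, "noise_sigma"),
               seed = attr(y, "seed"))
  if (!is.null(op)) {
    meta$shifts_px <- op$shifts
    meta$scene_shape <- op$scene_shape
  }
  if (!is.null(band_centers_nm)) meta$band_centers_nm <- band_centers_nm
  if (!is.null(mask_file))
    meta$mask_md5 <- unname(tools::md5sum(mask_file))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_measurement
#' @export
read_measurement <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing metadata sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.list(pages)) pages <- pages[[1]]
  y <- measurement(pages * meta$scale + (meta$offset %||% 0),
                   noise_sigma = meta$noise_sigma %||% 0,
                   seed = meta$seed %||% NA_integer_)
  list(y = y, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a coded mask image
#'
#' Masks are exchanged as 8-bit PNG or TIFF images (0 = opaque, 255 =
#' transparent). The loader binarizes grayscale images at threshold 128 of
#' 255, so experimentally captured mask images can be used directly.
#'
#' @param mask a [coded_mask()].
#' @param path image path, extension `.png` or `.tif`/`.tiff`.
#' @param feature_px,seed metadata attached on read.
#' @return `write_mask` returns `path` invisibly; `read_mask` a
#'   [coded_mask()].
#' @export
write_mask <- function(mask, path) {
  v <- unclass(mask)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::writePNG(v, path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(v, path, bits.per.sample = 8L, compression = "none")
  else stop("unsupported mask format: .", ext)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, feature_px = 2L, seed = NA_integer_) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
         else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else stop("unsupported mask format: .", ext)
  if (length(dim(img)) == 3L) img <- img[, , 1]  # first channel
  coded_mask((img >= 128 / 255) * 1.0, feature_px = feature_px, seed = seed)
}

#' Write / read a dispersion model as JSON
#'
#' @param model a [dispersion_model()].
#' @param path JSON path.
#' @return `write_dispersion` returns `path` invisibly; `read_dispersion`
#'   the [dispersion_model()].
#' @export
write_dispersion <- function(model, path) {
  seg <- model$segments
  jsonlite::write_json(
    list(segments = unname(lapply(seq_len(nrow(seg)), function(i)
      c(seg$lambda_start_nm[i], seg$lambda_end_nm[i],
        seg$nm_per_pixel[i]))),
      reference_nm = model$reference_nm),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dispersion
#' @export
read_dispersion <- function(path) {
  if (!file.exists(path)) stop("dispersion file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  seg <- j$segments
  if (is.list(seg)) seg <- do.call(rbind, seg)
  dispersion_model(as.data.frame(seg), reference_nm = j$reference_nm)
}

#' Read a run configuration (YAML or JSON by extension)
#'
#' @param path config path (`.yaml`/`.yml` or `.json`).
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: .", ext)
}
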