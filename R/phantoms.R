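# 5 x 7 bitmap glyphs for the letter phantom
.glyphs <- list(
  E = c("11111", "10000", "10000", "11110", "10000", "10000", "11111"),
  A = c("01110", "10001", "10001", "11111", "10001", "10001", "10001"),
  H = c("10001", "10001", "10001", "11111", "10001", "10001", "10001"),
  C = c("01110", "10001", "10000", "10000", "10000", "10001", "01110")
)

.glyph_matrix <- function(letter) {
  rows <- .glyphs[[toupper(letter)]]
  if (is.null(rows)) stop("no glyph for letter ", letter,
                          " (available: ", paste(names(.glyphs),
                                                 collapse = ", "), ")")
  do.call(rbind, lapply(rows, function(r)
    as.integer(strsplit(r, "")[[1]])))
}

# nearest-neighbour upscale of a glyph onto a target grid, centred
.render_glyph <- function(letter, rows, cols, fill_frac = 0.7) {
  g <- .glyph_matrix(letter)
  gh <- nrow(g); gw <- ncol(g)
  scale <- max(1, floor(min(rows * fill_frac / gh, cols * fill_frac / gw)))
  h <- gh * scale; w <- gw * scale
  if (h > rows || w > cols)
    stop_dim("glyph (%d x %d) does not fit the %d x %d grid", h, w, rows,
             cols)
  big <- g[rep(seq_len(gh), each = scale), rep(seq_len(gw), each = scale)]
  out <- matrix(0L, rows, cols)
  r0 <- (rows - h) %/% 2L
  c0 <- (cols - w) %/% 2L
  out[r0 + seq_len(h), c0 + seq_len(w)] <- big
  out
}

#' Rainbow-letter phantom
#'
#' Emulates a letter object illuminated through a linear variable filter
#' (LVF): the silhouette of a letter whose spectrum at each column is a
#' Gaussian passband with centre sweeping linearly from the shortest band
#' centre (left edge) to the longest (right edge), so every lateral
#' position carries a distinct colour. The per-pixel spectrum integrates to
#' `intensity` across the bands.
#'
#' @param rows,cols grid size.
#' @param band_centers_nm strictly increasing band centre wavelengths.
#' @param band_edges_nm optional band edges.
#' @param letter one of `"E"`, `"A"`, `"H"`, `"C"`.
#' @param lvf_fwhm_nm passband full width at half maximum in nm (the LVF of
#'   the emulated system is specified at 7-20 nm).
#' @param intensity per-pixel integrated irradiance inside the glyph.
#' @return a [spectral_cube()] with attributes `glyph` (0/1 matrix) and
#'   `column_centers_nm` (the swept passband centre per column).
#' @export
phantom_rainbow_letter <- function(rows, cols, band_centers_nm,
                                   band_edges_nm = NULL, letter = "E",
                                   lvf_fwhm_nm = 12, intensity = 1) {
  glyph <- .render_glyph(letter, rows, cols)
  L <- length(band_centers_nm)
  lam_min <- band_centers_nm[1]; lam_max <- band_centers_nm[L]
  col_centers <- lam_min + (lam_max - lam_min) *
    (seq_len(cols) - 1) / max(1, cols - 1)
  sigma <- lvf_fwhm_nm / (2 * sqrt(2 * log(2)))
  cube0 <- spectral_cube(array(0, c(rows, cols, L)), band_centers_nm,
                         band_edges_nm)
  edges <- band_edges(cube0)
  widths <- diff(edges)
  # columns x bands weight table, each row normalized to `intensity`
  w <- outer(col_centers, band_centers_nm,
             function(cc, bc) exp(-(bc - cc)^2 / (2 * sigma^2)))
  w <- w * rep(widths, each = cols)
  w <- w / rowSums(w) * intensity
  vals <- array(0, c(rows, cols, L))
  for (k in seq_len(L))
    vals[, , k] <- glyph * rep(w[, k], each = rows)
  out <- spectral_cube(vals, band_centers_nm, edges)
  attr(out, "glyph") <- glyph
  attr(out, "column_centers_nm") <- col_centers
  out
}

#' USAF-1951 three-bar phantom
#'
#' Renders the requested elements of a USAF resolution target at exact
#' chart geometry (three bars, bar length five times the bar width, gaps
#' equal to the width), in both vertical-bar and horizontal-bar
#' orientations, flat across all bands (broadband illumination). Bars are
#' rasterized by pixel-centre sampling of the continuous geometry.
#'
#' @param rows,cols grid size.
#' @param band_centers_nm band centre wavelengths.
#' @param um_per_pixel physical sampling of the target plane.
#' @param elements data frame with columns `group`, `element`.
#' @param orientations subset of `c("vertical", "horizontal")`.
#' @param intensity bar irradiance (background is zero).
#' @param margin_px spacing between rendered blocks.
#' @return a [spectral_cube()] with attribute `elements`: a tibble with the
#'   placement (`row0`, `col0`, 0-based), `size_px` and exact
#'   `bar_width_px` of every rendered block.
#' @export
phantom_usaf <- function(rows, cols, band_centers_nm, um_per_pixel = 4,
                         elements = data.frame(group = c(5, 6),
                                               element = c(6, 1)),
                         orientations = c("vertical", "horizontal"),
                         intensity = 1, margin_px = 3L) {
  elements <- as.data.frame(elements)
  img <- matrix(0, rows, cols)
  placed <- list()
  cur_r <- margin_px; cur_c <- margin_px; row_h <- 0
  for (i in seq_len(nrow(elements))) {
    for (ori in orientations) {
      f <- usaf_frequency(elements$group[i], elements$element[i])
      w_px <- (1000 / f) / 2 / um_per_pixel
      if (w_px < 1)
        stop(sprintf("group %d element %d bar width %.2f px < 1 px: unrenderable",
                     elements$group[i], elements$element[i], w_px))
      size <- ceiling(5 * w_px)
      if (cur_c + size + margin_px > cols) {  # wrap to next block row
        cur_r <- cur_r + row_h + margin_px
        cur_c <- margin_px
        row_h <- 0
      }
      if (cur_r + size + margin_px > rows)
        stop_dim("requested elements do not fit the %d x %d grid", rows,
                 cols)
      # pixel-centre sampling of three bars of continuous width w_px
      cc <- seq_len(size) - 0.5
      in_bar <- (cc < 5 * w_px) &
        ((cc %/% w_px) %% 2 == 0) & (cc %/% w_px <= 4)
      block <- if (ori == "vertical") {
        matrix(rep(as.numeric(in_bar), each = size), size, size)
      } else {
        matrix(rep(as.numeric(in_bar), times = size), size, size)
      }
      img[cur_r + seq_len(size), cur_c + seq_len(size)] <-
        block * intensity
      placed[[length(placed) + 1L]] <- tibble::tibble(
        group = elements$group[i], element = elements$element[i],
        orientation = ori, row0 = cur_r, col0 = cur_c,
        size_px = size, bar_width_px = w_px)
      cur_c <- cur_c + size + margin_px
      row_h <- max(row_h, size)
    }
  }
  L <- length(band_centers_nm)
  vals <- array(rep(img, L), c(rows, cols, L))
  out <- spectral_cube(vals, band_centers_nm)
  attr(out, "elements") <- do.call(rbind, placed)
  attr(out, "um_per_pixel") <- um_per_pixel
  out
}

#' Contrast of rendered USAF elements in an image
#'
#' Extracts, for every rendered block, the intensity profile across the
#' bars (averaged along the central half of the bar length) and computes
#' its Michelson contrast.
#'
#' @param img 2D image (one spectral band, or a panchromatic sum).
#' @param elements the `elements` attribute of [phantom_usaf()] (placement
#'   tibble).
#' @return tibble with `group`, `element`, `orientation`, `lp_mm`,
#'   `contrast`.
#' @export
usaf_contrast_table <- function(img, elements) {
  img <- unclass(img)
  rows <- lapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    blk <- img[e$row0 + seq_len(e$size_px), e$col0 + seq_len(e$size_px)]
    if (e$orientation == "horizontal") blk <- t(blk)
    mid <- seq(max(1, floor(e$size_px * 0.25)),
               min(e$size_px, ceiling(e$size_px * 0.75)))
    profile <- colMeans(blk[mid, , drop = FALSE])
    tibble::tibble(group = e$group, element = e$element,
                   orientation = e$orientation,
                   lp_mm = usaf_frequency(e$group, e$element),
                   contrast = michelson_contrast(profile))
  })
  do.call(rbind, rows)
}

#' Eye-vasculature phantom
#'
#' Emulates a model-eye retina: a smooth background of flat reflectance
#' overlaid with branching vessel-like curves drawn by seeded random walks
#' of decreasing width. Vessels carry a smooth absorbing spectrum dipping
#' mid-band; the background spectrum is flat. The field-averaged spectrum
#' is recorded as ground truth for spectrum-recovery tests.
#'
#' @param rows,cols grid size.
#' @param band_centers_nm band centre wavelengths.
#' @param n_vessels number of primary vessels (`>= 0`).
#' @param vessel_width starting vessel half-width scale in pixels.
#' @param vessel_depth absorption depth in `(0, 1)` at the dip wavelength.
#' @param seed RNG seed; identical seeds give identical phantoms.
#' @return a [spectral_cube()] with attributes `vessel_mask`,
#'   `vessel_spectrum`, `background_spectrum`, `mean_spectrum` (the
#'   intensity-weighted field average) and `vessel_fraction`.
#' @export
phantom_eye <- function(rows, cols, band_centers_nm, n_vessels = 6,
                        vessel_width = 2.5, vessel_depth = 0.7, seed = 1L) {
  if (n_vessels < 0) stop("n_vessels must be >= 0")
  L <- length(band_centers_nm)
  cy <- (rows + 1) / 2; cx <- (cols + 1) / 2
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  sigma_bg <- 0.6 * min(rows, cols)
  bg <- 0.6 + 0.4 * exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * sigma_bg^2))

  vessel <- matrix(FALSE, rows, cols)
  stamp <- function(r, c, rad) {
    ri <- max(1, floor(r - rad)):min(rows, ceiling(r + rad))
    ci <- max(1, floor(c - rad)):min(cols, ceiling(c + rad))
    vessel[ri, ci] <<- TRUE
  }
  walk <- function(r, c, ang, width, steps) {
    for (s in seq_len(steps)) {
      t <- s / steps
      stamp(r, c, width * (1 - 0.6 * t) / 2)
      ang <- ang + rnorm(1, 0, 0.25)
      r <- r + sin(ang); c <- c + cos(ang)
      if (r < 1 || r > rows || c < 1 || c > cols) break
    }
    c(r, c, ang)
  }
  with_seed(seed, {
    for (v in seq_len(n_vessels)) {
      side <- sample(4, 1)
      r0 <- switch(side, 1, rows, runif(1, 1, rows), runif(1, 1, rows))
      c0 <- switch(side, runif(1, 1, cols), runif(1, 1, cols), 1, cols)
      ang0 <- atan2(cy - r0, cx - c0) + rnorm(1, 0, 0.3)
      steps <- round(0.7 * max(rows, cols))
      end <- walk(r0, c0, ang0, vessel_width, steps)
      # one branch from the endpoint at a deviated angle, thinner
      walk(end[1], end[2], end[3] + sample(c(-1, 1), 1) * runif(1, 0.5, 1),
           vessel_width * 0.6, round(steps / 2))
    }
  })

  lam_mid <- mean(range(band_centers_nm))
  sigma_l <- 0.18 * max(diff(range(band_centers_nm)), 1)
  vessel_spec <- 1 - vessel_depth *
    exp(-(band_centers_nm - lam_mid)^2 / (2 * sigma_l^2))
  bg_spec <- rep(1, L)

  vals <- array(0, c(rows, cols, L))
  for (k in seq_len(L))
    vals[, , k] <- bg * ifelse(vessel, vessel_spec[k], bg_spec[k])
  npix <- rows * cols
  w_v <- sum(bg[vessel]) / npix
  w_b <- sum(bg[!vessel]) / npix
  out <- spectral_cube(vals, band_centers_nm)
  attr(out, "vessel_mask") <- vessel
  attr(out, "vessel_spectrum") <- vessel_spec
  attr(out, "background_spectrum") <- bg_spec
  attr(out, "mean_spectrum") <- w_v * vessel_spec + w_b * bg_spec
  attr(out, "vessel_fraction") <- mean(vessel)
  out
}
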