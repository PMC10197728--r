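# Shared fixtures and independent dense-matrix oracles.

test_centers <- function(L, lo = 445, hi = 602) seq(lo, hi, length.out = L)

# Dense sensing matrix built entry-by-entry from the measurement
# definition Y(r, c) = sum_k T(r, c - d_k) f_k(r, c - d_k), independent of
# the package's shift-and-sum implementation. Vectorization is column-major
# (row fastest, then column, then band) for cubes and column-major for the
# detector image.
dense_phi <- function(mask, shifts, rows = nrow(mask), cols = ncol(mask)) {
  L <- length(shifts)
  det_cols <- cols + max(shifts)
  Phi <- matrix(0, rows * det_cols, rows * cols * L)
  for (k in seq_len(L)) {
    d <- shifts[k]
    for (cp in seq_len(cols)) {
      for (rp in seq_len(rows)) {
        col_idx <- (k - 1) * rows * cols + (cp - 1) * rows + rp
        row_idx <- (cp + d - 1) * rows + rp
        Phi[row_idx, col_idx] <- mask[rp, cp]
      }
    }
  }
  Phi
}

random_instance <- function(rows, cols, L, seed, fill = 0.5, step = 2L) {
  set.seed(seed)
  mask <- coded_mask(matrix(rbinom(rows * cols, 1, fill), rows, cols),
                     feature_px = 1L)
  shifts <- (seq_len(L) - 1L) * step
  op <- sensing_operator(mask, shifts)
  cube <- spectral_cube(array(runif(rows * cols * L), c(rows, cols, L)),
                        test_centers(L))
  list(op = op, cube = cube, mask = mask, shifts = shifts,
       Phi = dense_phi(unclass(mask), shifts, rows, cols))
}

# separable box blur used by the metrology sweep (emulates the finite
# optical/coding resolution of the instrument)
box_blur <- function(img, half = 1L) {
  k <- 2 * half + 1
  pad <- function(m, n) m[c(rep(1, n), seq_len(nrow(m)), rep(nrow(m), n)), ]
  sm_rows <- function(m) {
    p <- pad(m, half)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_len(nrow(m)))
      out[i, ] <- colMeans(p[i:(i + k - 1), , drop = FALSE])
    out
  }
  t(sm_rows(t(sm_rows(img))))
}

# temp directory cleaned up when the calling test finishes
local_dir <- function(env = parent.frame()) {
  d <- tempfile("cassir")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
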