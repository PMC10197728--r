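#' Denoiser specification for the ADMM prior step
#'
#' The prior subproblem of the augmented-Lagrangian reconstruction is a
#' denoising problem; this object selects how it is solved. `"tv"` (the
#' default) applies the proximal operator of anisotropic total variation,
#' `"identity"` applies no prior, and `"external"` dispatches to a
#' user-supplied function `fn(u, weight, guidance)` honouring the same
#' contract (return an array shaped like `u`).
#'
#' @param kind one of `"tv"`, `"identity"`, `"external"`.
#' @param strength non-negative prior weight; the effective proximal weight
#'   at penalty `gamma2` is `strength / gamma2`.
#' @param max_inner_iters dual iterations of the TV proximal solver.
#' @param spectral_tv also penalize finite differences along the band axis.
#' @param guidance_enabled pass assembled [guidance_features()] to an
#'   external denoiser.
#' @param fn external denoiser callable (required for `kind = "external"`).
#' @return a `denoiser_spec`.
#' @export
denoiser <- function(kind = c("tv", "identity", "external"),
                     strength = 0.1, max_inner_iters = 20L,
                     spectral_tv = FALSE, guidance_enabled = FALSE,
                     fn = NULL) {
  kind <- match.arg(kind)
  if (strength < 0) stop("strength must be non-negative")
  if (kind == "tv" && max_inner_iters < 1L)
    stop("tv denoiser needs max_inner_iters >= 1")
  if (kind == "external" && !is.function(fn))
    stop("external denoiser requires a function `fn`")
  structure(list(kind = kind, strength = strength,
                 max_inner_iters = as.integer(max_inner_iters),
                 spectral_tv = spectral_tv,
                 guidance_enabled = guidance_enabled, fn = fn),
            class = "denoiser_spec")
}

#' Augmented-Lagrangian iterate
#'
#' Bundles the ADMM state: estimate `f`, auxiliary `v`, data-term multiplier
#' `lam1` (detector-shaped), splitting multiplier `lam2` (cube-shaped),
#' positive penalties `gamma1`, `gamma2` and the iteration index.
#'
#' @param f,v cube-shaped arrays.
#' @param lam1 detector-shaped matrix.
#' @param lam2 cube-shaped array.
#' @param gamma1,gamma2 positive penalty scalars.
#' @param iter iteration index `>= 0`.
#' @return an `al_state`.
#' @export
al_state <- function(f, v, lam1, lam2, gamma1 = 1, gamma2 = 1, iter = 0L) {
  if (gamma1 <= 0 || gamma2 <= 0) stop("penalties must be positive")
  if (!all(dim(f) == dim(v)) || !all(dim(f) == dim(lam2)))
    stop_dim("f, v and lam2 must share the cube shape")
  structure(list(f = f, v = v, lam1 = lam1, lam2 = lam2,
                 gamma1 = gamma1, gamma2 = gamma2, iter = as.integer(iter)),
            class = "al_state")
}

# solve (gamma2 I + gamma1 Phi^T Phi) f = b in one shot via the
# matrix-inversion lemma; Phi Phi^T = diag(R) makes the inner system
# elementwise: f = (b - Phi^T[ (Phi b) / (gamma2/gamma1 + R) ]) / gamma2
.al_solve <- function(op, b, gamma1, gamma2, R = gram_diagonal(op)) {
  inner <- .forward_arr(op, b) / (gamma2 / gamma1 + R)
  (b - .adjoint_arr(op, inner)) / gamma2
}

#' Closed-form initialization \eqn{f^0}
#'
#' The regularized back-projection
#' \eqn{f^0 = (\gamma_2 I + \gamma_1 \Phi^T\Phi)^{-1}\Phi^T y}, computed in
#' one shot through the diagonal Gram identity (never a dense inversion).
#'
#' @param y a [measurement()].
#' @param op a [sensing_operator()].
#' @param gamma1,gamma2 positive penalties.
#' @return cube-shaped array.
#' @export
initialize_f0 <- function(y, op, gamma1 = 1, gamma2 = 1) {
  if (gamma1 <= 0 || gamma2 <= 0) stop("penalties must be positive")
  b <- .adjoint_arr(op, unclass(y))
  .al_solve(op, b, gamma1, gamma2)
}

#' One-shot data-consistency projection
#'
#' Solves the quadratic subproblem for `f` exactly:
#' \deqn{f = (\gamma_2 I + \gamma_1\Phi^T\Phi)^{-1}
#'   (\lambda_2 + \gamma_2 v + \Phi^T(\gamma_1 y - \lambda_1))}
#' using the diagonal structure of \eqn{\Phi\Phi^T} (scalar-plus-diagonal
#' inner system solved elementwise); no iterative linear solver.
#'
#' @param state an [al_state()].
#' @param y a [measurement()].
#' @param op a [sensing_operator()].
#' @param R precomputed [gram_diagonal()] (optional).
#' @return the updated cube-shaped estimate `f`.
#' @export
projection_step <- function(state, y, op, R = gram_diagonal(op)) {
  if (state$gamma1 <= 0 || state$gamma2 <= 0)
    stop("penalties must be positive")
  rhs_det <- state$gamma1 * unclass(y) - state$lam1
  b <- state$lam2 + state$gamma2 * state$v + .adjoint_arr(op, rhs_det)
  .al_solve(op, b, state$gamma1, state$gamma2, R)
}

# forward differences with Neumann boundary (last difference zero)
.grad_list <- function(a, spectral = FALSE) {
  dm <- dim(a)
  gx <- a[, c(2:dm[2], dm[2]), , drop = FALSE] - a
  gy <- a[c(2:dm[1], dm[1]), , , drop = FALSE] - a
  out <- list(x = gx, y = gy)
  if (spectral && dm[3] > 1L)
    out$s <- a[, , c(2:dm[3], dm[3]), drop = FALSE] - a
  out
}

# negative adjoint of .grad_list
.div_list <- function(p) {
  dm <- dim(p$x)
  px <- p$x; py <- p$y
  dx <- px - px[, c(1, seq_len(dm[2] - 1)), , drop = FALSE]
  dx[, 1, ] <- px[, 1, ]
  dx[, dm[2], ] <- -px[, dm[2] - 1, ]
  dy <- py - py[c(1, seq_len(dm[1] - 1)), , , drop = FALSE]
  dy[1, , ] <- py[1, , ]
  dy[dm[1], , ] <- -py[dm[1] - 1, , ]
  out <- dx + dy
  if (!is.null(p$s)) {
    ps <- p$s
    ds <- ps - ps[, , c(1, seq_len(dm[3] - 1)), drop = FALSE]
    ds[, , 1] <- ps[, , 1]
    ds[, , dm[3]] <- -ps[, , dm[3] - 1]
    out <- out + ds
  }
  out
}

# proximal operator of w * ||grad u||_1 (anisotropic TV), projected-gradient
# ascent on the dual with componentwise clipping to [-1, 1]
.tv_prox <- function(u, w, n_iters, spectral = FALSE) {
  if (w <= 0 || n_iters < 1L) return(u)
  dm <- dim(u)
  ndirs <- 2L + as.integer(spectral && dm[3] > 1L)
  zero <- array(0, dm)
  p <- list(x = zero, y = zero)
  if (ndirs == 3L) p$s <- zero
  step <- 1 / (4 * ndirs * w)  # safe dual step for this parametrization
  for (i in seq_len(n_iters)) {
    g <- .grad_list(w * .div_list(p) - u, spectral = ndirs == 3L)
    p$x <- pmin(pmax(p$x + step * g$x, -1), 1)
    p$y <- pmin(pmax(p$y + step * g$y, -1), 1)
    if (ndirs == 3L) p$s <- pmin(pmax(p$s + step * g$s, -1), 1)
  }
  u - w * .div_list(p)
}

# anisotropic TV value (sum of absolute forward differences)
.tv_value <- function(a, spectral = FALSE) {
  g <- .grad_list(a, spectral = spectral)
  sum(vapply(g, function(z) sum(abs(z)), numeric(1)))
}

#' Prior (denoising) step
#'
#' Solves the prior subproblem on `u = f - lam2/gamma2`. For the TV kind
#' this is the anisotropic total-variation proximal estimate with weight
#' `strength / gamma2`, computed by a projected-gradient scheme on the dual
#' (`max_inner_iters` sweeps). The identity kind returns `u`; the external
#' kind dispatches to the registered callable.
#'
#' @param u cube-shaped array (finite).
#' @param spec a [denoiser()].
#' @param gamma2 current splitting penalty (sets the proximal weight).
#' @param guidance optional [guidance_features()], forwarded to external
#'   denoisers when `guidance_enabled`.
#' @return denoised array shaped like `u`.
#' @export
denoise_step <- function(u, spec, gamma2 = 1, guidance = NULL) {
  if (!all(is.finite(u))) stop("denoiser input must be finite")
  switch(spec$kind,
    identity = u,
    tv = .tv_prox(u, spec$strength / gamma2, spec$max_inner_iters,
                  spectral = isTRUE(spec$spectral_tv)),
    external = spec$fn(u, spec$strength / gamma2,
                       if (isTRUE(spec$guidance_enabled)) guidance else NULL),
    stop("unknown denoiser kind: ", spec$kind)
  )
}

#' Assemble guidance features for an external denoiser
#'
#' The physical side information a learned denoiser can condition on: a
#' constant `gamma2` map, the stack of `L` mask copies shifted to their
#' detector positions (the structure of \eqn{\Phi}), and the per-pixel Gram
#' diagonal (the detector-plane trace map of \eqn{\Phi\Phi^T}).
#'
#' @param gamma2 splitting penalty.
#' @param op a [sensing_operator()].
#' @return a `guidance_features` list with `gamma_channel`,
#'   `shift_mask_stack` (detector rows x cols x L) and `gram_trace_map`.
#' @export
guidance_features <- function(gamma2, op) {
  det <- op$detector_shape
  cols <- op$scene_shape[2]
  stack <- array(0, c(det[1], det[2], op$L))
  m <- unclass(op$mask)
  for (k in seq_len(op$L)) {
    d <- op$shifts[k]
    stack[, (d + 1L):(d + cols), k] <- m
  }
  structure(list(gamma_channel = matrix(gamma2, det[1], det[2]),
                 shift_mask_stack = stack,
                 gram_trace_map = gram_diagonal(op)),
            class = "guidance_features")
}

#' Multiplier update
#'
#' Ascent step on both Lagrange multipliers:
#' `lam1 <- lam1 - gamma1 (y - Phi f)` and
#' `lam2 <- lam2 - gamma2 (f - v)`; the iteration counter is incremented
#' and `f`, `v` are untouched.
#'
#' @param state an [al_state()] holding the current `f`, `v`.
#' @param y a [measurement()].
#' @param op a [sensing_operator()].
#' @return the updated [al_state()].
#' @export
update_multipliers <- function(state, y, op) {
  if (!all(dim(y) == op$detector_shape))
    stop_dim("measurement does not match the detector grid")
  data_res <- unclass(y) - .forward_arr(op, state$f)
  state$lam1 <- state$lam1 - state$gamma1 * data_res
  state$lam2 <- state$lam2 - state$gamma2 * (state$f - state$v)
  state$iter <- state$iter + 1L
  state
}

#' Augmented-Lagrangian ADMM reconstruction
#'
#' Recovers a spectral datacube from a single CASSI measurement by
#' alternating (i) the prior/denoising step, (ii) the one-shot
#' data-consistency projection, and (iii) the multiplier updates, for a
#' fixed number of iterations starting from the closed-form `f^0`.
#' Deterministic given its inputs.
#'
#' @param y a [measurement()].
#' @param op a [sensing_operator()].
#' @param spec a [denoiser()] (default: TV).
#' @param n_iters number of outer iterations (`>= 1`).
#' @param gamma1,gamma2 positive penalty parameters.
#' @param schedule optional geometric penalty schedule: a scalar ratio `r`
#'   (penalties at iteration `i` are `gamma * r^(i-1)`) or a vector of
#'   `n_iters` multipliers.
#' @param clamp_nonneg clamp the final estimate at zero (after the last
#'   iteration only; intermediate clamping would break the projection
#'   algebra).
#' @param band_centers_nm optional wavelengths attached to the result.
#' @return a `cassi_reconstruction`: list with `cube` (a
#'   [spectral_cube()]), `diagnostics` (tibble: `iter`, `data_residual`,
#'   `split_residual`), and the settings used. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
admm_reconstruct <- function(y, op, spec = denoiser("tv"), n_iters = 50L,
                             gamma1 = 1, gamma2 = 1, schedule = NULL,
                             clamp_nonneg = FALSE, band_centers_nm = NULL) {
  if (n_iters < 1L) stop("n_iters must be >= 1")
  mult <- if (is.null(schedule)) rep(1, n_iters)
          else if (length(schedule) == 1L) schedule^(seq_len(n_iters) - 1)
          else if (length(schedule) == n_iters) schedule
          else stop("schedule must be a scalar ratio or length n_iters")
  R <- gram_diagonal(op)
  guid <- if (isTRUE(spec$guidance_enabled)) guidance_features(gamma2, op)
          else NULL
  f <- initialize_f0(y, op, gamma1 * mult[1], gamma2 * mult[1])
  v <- f
  lam1 <- matrix(0, op$detector_shape[1], op$detector_shape[2])
  lam2 <- array(0, dim(f))
  diag_data <- numeric(n_iters)
  diag_split <- numeric(n_iters)
  for (i in seq_len(n_iters)) {
    g1 <- gamma1 * mult[i]; g2 <- gamma2 * mult[i]
    v <- denoise_step(f - lam2 / g2, spec, gamma2 = g2, guidance = guid)
    st <- al_state(f, v, lam1, lam2, g1, g2, iter = i - 1L)
    f <- projection_step(st, y, op, R)
    st$f <- f
    st <- update_multipliers(st, y, op)
    lam1 <- st$lam1; lam2 <- st$lam2
    if (!all(is.finite(f)))
      stop(sprintf("reconstruction diverged (non-finite iterate) at iteration %d", i))
    diag_data[i] <- sqrt(sum((unclass(y) - .forward_arr(op, f))^2))
    diag_split[i] <- sqrt(sum((f - v)^2))
  }
  if (clamp_nonneg) f <- pmax(f, 0)
  if (is.null(band_centers_nm)) band_centers_nm <- seq_len(op$L)
  structure(list(
    cube = spectral_cube(f, band_centers_nm, physical = FALSE),
    diagnostics = tibble::tibble(iter = seq_len(n_iters),
                                 data_residual = diag_data,
                                 split_residual = diag_split),
    settings = list(n_iters = n_iters, gamma1 = gamma1, gamma2 = gamma2,
                    schedule = schedule, denoiser = spec$kind,
                    strength = spec$strength,
                    clamp_nonneg = clamp_nonneg)),
    class = "cassi_reconstruction")
}

#' @export
print.cassi_reconstruction <- function(x, ...) {
  s <- x$settings
  n <- nrow(x$diagnostics)
  cat(sprintf(
    "<cassi_reconstruction> %s prior, %d iterations (gamma1 %g, gamma2 %g)\n",
    s$denoiser, s$n_iters, s$gamma1, s$gamma2))
  cat(sprintf("  final residuals: data %.4g, splitting %.4g\n",
              x$diagnostics$data_residual[n], x$diagnostics$split_residual[n]))
  invisible(x)
}

#' @rdname admm_reconstruct
#' @param x a `cassi_reconstruction`.
#' @param ... unused.
#' @export
tidy.cassi_reconstruction <- function(x, ...) x$diagnostics

#' @rdname admm_reconstruct
#' @export
glance.cassi_reconstruction <- function(x, ...) {
  n <- nrow(x$diagnostics)
  s <- x$settings
  tibble::tibble(n_iters = s$n_iters, denoiser = s$denoiser,
                 strength = s$strength, gamma1 = s$gamma1,
                 gamma2 = s$gamma2,
                 final_data_residual = x$diagnostics$data_residual[n],
                 final_split_residual = x$diagnostics$split_residual[n])
}

#' @rdname admm_reconstruct
#' @param object a `cassi_reconstruction`.
#' @export
autoplot.cassi_reconstruction <- function(object, ...) {
  d <- object$diagnostics
  long <- tibble::tibble(
    iter = rep(d$iter, 2),
    residual = c(d$data_residual, d$split_residual),
    which = rep(c("data ||y - Phi f||", "splitting ||f - v||"),
                each = nrow(d)))
  ggplot2::ggplot(long, ggplot2::aes(x = iter, y = residual,
                                     colour = which)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "residual (log scale)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Peak signal-to-noise ratio
#'
#' @param estimate,truth arrays of identical shape.
#' @param peak signal peak; defaults to `max(truth)`.
#' @return PSNR in dB.
#' @export
psnr <- function(estimate, truth, peak = max(truth)) {
  mse <- mean((unclass(estimate) - unclass(truth))^2)
  10 * log10(peak^2 / mse)
}
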