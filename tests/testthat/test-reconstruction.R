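dense_al_solve <- function(Phi, b_vec, y_vec, gamma1, gamma2) {
  n <- ncol(Phi)
  solve(gamma2 * diag(n) + gamma1 * t(Phi) %*% Phi, b_vec)
}

test_that("f0 initialization matches the dense solve and its limits", {
  inst <- random_instance(3, 3, 2, seed = 41)
  y0 <- measurement(matrix(0, inst$op$detector_shape[1],
                           inst$op$detector_shape[2]))
  expect_true(all(initialize_f0(y0, inst$op) == 0))

  y <- unclass(cassi_forward(inst$op, inst$cube))
  f0 <- initialize_f0(measurement(y), inst$op, gamma1 = 0.7, gamma2 = 1.3)
  b <- t(inst$Phi) %*% as.vector(y)
  ref <- dense_al_solve(inst$Phi, b, as.vector(y), 0.7, 1.3)
  expect_equal(as.vector(f0), as.vector(ref), tolerance = 1e-8)

  # gamma1 -> 0: f0 -> Phi^T y / gamma2
  f0_lim <- initialize_f0(measurement(y), inst$op, gamma1 = 1e-9,
                          gamma2 = 2)
  expect_equal(as.vector(f0_lim), as.vector(b) / 2, tolerance = 1e-6)
  expect_error(initialize_f0(measurement(y), inst$op, gamma1 = 0),
               "positive")
})

test_that("projection step is the exact one-shot solution", {
  # algebraic fixed point: v = truth, multipliers zero, consistent y
  inst <- random_instance(6, 6, 3, seed = 43)
  f_star <- unclass(inst$cube)
  y <- cassi_forward(inst$op, inst$cube)
  st <- al_state(f_star, f_star,
                 matrix(0, inst$op$detector_shape[1],
                        inst$op$detector_shape[2]),
                 array(0, dim(f_star)), gamma1 = 0.9, gamma2 = 1.7)
  out <- projection_step(st, y, inst$op)
  expect_lt(max(abs(out - f_star)) / max(abs(f_star)), 1e-10)

  # gamma1 ~ 0: data term vanishes, projection returns v + lam2/gamma2
  set.seed(44)
  v <- array(rnorm(length(f_star)), dim(f_star))
  lam2 <- array(rnorm(length(f_star)), dim(f_star))
  st2 <- al_state(f_star, v,
                  matrix(0, inst$op$detector_shape[1],
                         inst$op$detector_shape[2]),
                  lam2, gamma1 = 1e-12, gamma2 = 2)
  out2 <- projection_step(st2, y, inst$op)
  expect_equal(out2, v + lam2 / 2, tolerance = 1e-6)
})

test_that("projection matches the dense oracle on random states", {
  for (seed in 1:5) {
    inst <- random_instance(8, 8, 3, seed = 100 + seed)
    det <- inst$op$detector_shape
    set.seed(200 + seed)
    st <- al_state(array(rnorm(8 * 8 * 3), c(8, 8, 3)),
                   array(rnorm(8 * 8 * 3), c(8, 8, 3)),
                   matrix(rnorm(prod(det)), det[1]),
                   array(rnorm(8 * 8 * 3), c(8, 8, 3)),
                   gamma1 = runif(1, 0.2, 3), gamma2 = runif(1, 0.2, 3))
    y <- matrix(rnorm(prod(det)), det[1])
    out <- projection_step(st, measurement(y), inst$op)
    b <- as.vector(st$lam2) + st$gamma2 * as.vector(st$v) +
      as.vector(t(inst$Phi) %*%
                  (st$gamma1 * as.vector(y) - as.vector(st$lam1)))
    ref <- dense_al_solve(inst$Phi, b, as.vector(y), st$gamma1, st$gamma2)
    expect_equal(as.vector(out), as.vector(ref), tolerance = 1e-8)
  }
})

test_that("TV denoising step honours its proximal contract", {
  set.seed(51)
  u <- array(rep(c(0, 1), each = 24) + rnorm(96, 0, 0.15), c(6, 8, 2))

  expect_equal(denoise_step(u, denoiser("tv", strength = 0)), u)
  flat <- array(3.7, c(6, 8, 2))
  expect_equal(denoise_step(flat, denoiser("tv", strength = 0.5,
                                           max_inner_iters = 50)),
               flat, tolerance = 1e-8)

  spec <- denoiser("tv", strength = 0.3, max_inner_iters = 60)
  v <- denoise_step(u, spec, gamma2 = 1)
  tv <- function(a) cassir:::.tv_value(a)
  expect_lt(tv(v), tv(u))
  obj <- function(z) 0.5 * sum((z - u)^2) + 0.3 * tv(z)
  expect_lte(obj(v), obj(u))

  # identity and external kinds
  expect_equal(denoise_step(u, denoiser("identity")), u)
  ext <- denoiser("external", strength = 1, fn = function(z, w, g) z * 0)
  expect_true(all(denoise_step(u, ext) == 0))
  expect_error(denoise_step(u * NA, spec), "finite")
})

test_that("TV prox agrees with an independent smoothed-objective minimizer", {
  set.seed(55)
  u <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  w <- 0.3
  v <- cassir:::.tv_prox(u, w, 2000L)
  # oracle: L-BFGS on the Huber-smoothed objective, independent of the
  # dual projected-gradient scheme under test
  eps <- 1e-6
  huber <- function(t) ifelse(abs(t) > eps, abs(t) - eps / 2,
                              t^2 / (2 * eps))
  obj_s <- function(zv) {
    z <- array(zv, dim(u))
    g <- cassir:::.grad_list(z)
    0.5 * sum((z - u)^2) + w * sum(sapply(g, function(q) sum(huber(q))))
  }
  o <- optim(as.vector(u), obj_s, method = "L-BFGS-B",
             control = list(maxit = 2000, factr = 1e4))
  expect_lt(max(abs(as.vector(v) - o$par)), 0.02)
  obj <- function(z) 0.5 * sum((z - u)^2) +
    w * cassir:::.tv_value(z)
  expect_lte(obj(v), obj(array(o$par, dim(u))) + 1e-3)
})

test_that("guidance features assemble the operator side information", {
  inst <- random_instance(5, 5, 3, seed = 61)
  g <- guidance_features(2.5, inst$op)
  expect_equal(g$gram_trace_map, gram_diagonal(inst$op))
  expect_true(all(g$gamma_channel == 2.5))
  expect_equal(dim(g$shift_mask_stack),
               c(inst$op$detector_shape, inst$op$L))
  for (k in seq_len(inst$op$L)) {
    d <- inst$op$shifts[k]
    expect_equal(g$shift_mask_stack[, (d + 1):(d + 5), k],
                 unclass(inst$mask), ignore_attr = TRUE)
  }
  # invariant: gram map is the sum of squared stack entries
  expect_equal(apply(g$shift_mask_stack^2, c(1, 2), sum),
               g$gram_trace_map)
})

test_that("multiplier updates follow the ascent recursion", {
  inst <- random_instance(4, 4, 2, seed = 71)
  f <- unclass(inst$cube)
  y <- cassi_forward(inst$op, inst$cube)
  det <- inst$op$detector_shape
  st <- al_state(f, f, matrix(0, det[1], det[2]), array(0, dim(f)),
                 gamma1 = 1.5, gamma2 = 0.5)

  # zero residuals: multipliers unchanged
  st1 <- update_multipliers(st, y, inst$op)
  expect_true(all(st1$lam1 == 0) && all(st1$lam2 == 0))
  expect_equal(st1$iter, 1L)

  # nonzero data residual: lam1 = -gamma1 (y - Phi f), doubling on repeat
  f2 <- f * 0.5
  st$f <- f2
  resid <- unclass(y) - unclass(cassi_forward(inst$op,
    spectral_cube(f2, test_centers(2), physical = FALSE)))
  stA <- update_multipliers(st, y, inst$op)
  expect_equal(stA$lam1, -1.5 * resid, tolerance = 1e-12)
  stB <- update_multipliers(stA, y, inst$op)
  expect_equal(stB$lam1, -2 * 1.5 * resid, tolerance = 1e-12)
  expect_equal(stB$lam2, -2 * 0.5 * (f2 - f), tolerance = 1e-12)
})

test_that("a full ADMM iteration fixes the truth under a perfect prior", {
  inst <- random_instance(8, 8, 3, seed = 81)
  f_star <- unclass(inst$cube)
  y <- cassi_forward(inst$op, inst$cube)
  det <- inst$op$detector_shape
  st <- al_state(f_star, f_star, matrix(0, det[1], det[2]),
                 array(0, dim(f_star)), gamma1 = 1, gamma2 = 1)
  v <- denoise_step(st$f - st$lam2 / st$gamma2, denoiser("identity"))
  st$v <- v
  st$f <- projection_step(st, y, inst$op)
  st <- update_multipliers(st, y, inst$op)
  expect_lt(max(abs(st$f - f_star)), 1e-8)
  expect_lt(max(abs(st$lam1)), 1e-8)
  expect_lt(max(abs(st$lam2)), 1e-8)
})

test_that("ADMM preserves zero and reduces the data residual", {
  inst <- random_instance(8, 8, 3, seed = 91)
  y0 <- measurement(matrix(0, inst$op$detector_shape[1],
                           inst$op$detector_shape[2]))
  rec0 <- admm_reconstruct(y0, inst$op, denoiser("tv", strength = 0.1),
                           n_iters = 5)
  expect_true(all(rec0$cube == 0))

  for (seed in 1:10) {
    inst <- random_instance(16, 16, 4, seed = 300 + seed)
    y <- cassi_forward(inst$op, inst$cube)
    rec <- admm_reconstruct(y, inst$op, denoiser("tv", strength = 0.1),
                            n_iters = 15)
    d <- rec$diagnostics
    expect_lte(d$data_residual[nrow(d)], d$data_residual[1])
  }
})

test_that("doubling the data penalty does not hurt the converged residual", {
  for (seed in 1:10) {
    inst <- random_instance(12, 12, 3, seed = 400 + seed)
    y <- cassi_forward(inst$op, inst$cube)
    r1 <- admm_reconstruct(y, inst$op, denoiser("tv", strength = 0.1),
                           n_iters = 40, gamma1 = 1)
    r2 <- admm_reconstruct(y, inst$op, denoiser("tv", strength = 0.1),
                           n_iters = 40, gamma1 = 2)
    final <- function(r) r$diagnostics$data_residual[40]
    expect_lte(final(r2), final(r1) * 1.0 + 1e-12)
  }
})

test_that("reconstruction results are deterministic and tidy-able", {
  inst <- random_instance(8, 8, 2, seed = 95)
  y <- cassi_forward(inst$op, inst$cube)
  r1 <- admm_reconstruct(y, inst$op, n_iters = 5)
  r2 <- admm_reconstruct(y, inst$op, n_iters = 5)
  expect_identical(unclass(r1$cube), unclass(r2$cube))

  td <- tidy(r1)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("iter", "data_residual", "split_residual"))
  gl <- glance(r1)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_iters, 5L)
  expect_s3_class(autoplot(r1), "ggplot")
})
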