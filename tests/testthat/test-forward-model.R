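test_that("apply_mask multiplies every band by the transmission pattern", {
  cube <- spectral_cube(array(runif(48), c(4, 4, 3)), test_centers(3))
  ones <- coded_mask(matrix(1, 4, 4))
  zeros <- coded_mask(matrix(0, 4, 4))
  expect_equal(unclass(apply_mask(cube, ones)), unclass(cube),
               ignore_attr = TRUE)
  expect_true(all(apply_mask(cube, zeros) == 0))

  pin <- matrix(0, 4, 4); pin[2, 3] <- 1
  out <- apply_mask(cube, coded_mask(pin))
  expect_equal(out[2, 3, ], cube[2, 3, ])
  out[2, 3, ] <- 0
  expect_true(all(out == 0))
  expect_error(apply_mask(cube, coded_mask(matrix(1, 3, 3))), "match")
})

test_that("single-band zero-shift identity operator reproduces the band", {
  op <- sensing_operator(coded_mask(matrix(1, 5, 5)), 0L)
  cube <- spectral_cube(array(runif(25), c(5, 5, 1)), 500)
  expect_equal(unclass(cassi_forward(op, cube)), cube[, , 1],
               ignore_attr = TRUE)
})

test_that("forward is linear", {
  inst <- random_instance(6, 6, 3, seed = 11)
  c2 <- spectral_cube(array(runif(6 * 6 * 3), c(6, 6, 3)), test_centers(3))
  a <- 2.5; b <- -1.3
  comb <- spectral_cube(a * unclass(inst$cube) + b * unclass(c2),
                        test_centers(3), physical = FALSE)
  lhs <- unclass(cassi_forward(inst$op, comb))
  rhs <- a * unclass(cassi_forward(inst$op, inst$cube)) +
    b * unclass(cassi_forward(inst$op, c2))
  expect_equal(lhs, rhs, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("forward, adjoint and Gram match the dense-matrix oracle", {
  for (seed in 1:3) {
    inst <- random_instance(3, 3, 2, seed = seed)
    yv <- inst$Phi %*% as.vector(unclass(inst$cube))
    expect_equal(as.vector(unclass(cassi_forward(inst$op, inst$cube))),
                 as.vector(yv), tolerance = 1e-12)

    y <- matrix(runif(prod(inst$op$detector_shape)),
                inst$op$detector_shape[1])
    fv <- t(inst$Phi) %*% as.vector(y)
    expect_equal(as.vector(unclass(cassi_adjoint(inst$op, measurement(y)))),
                 as.vector(fv), tolerance = 1e-12)

    G <- inst$Phi %*% t(inst$Phi)
    expect_true(all(G[row(G) != col(G)] == 0))  # exactly diagonal
    expect_equal(as.vector(gram_diagonal(inst$op)), diag(G),
                 tolerance = 1e-12)
  }
})

test_that("Gram diagonal counts overlapping shifted mask features", {
  zero_op <- sensing_operator(coded_mask(matrix(0, 4, 4)), c(0L, 1L))
  expect_true(all(gram_diagonal(zero_op) == 0))

  L <- 3
  op <- sensing_operator(coded_mask(matrix(1, 4, 6)), c(0L, 1L, 2L))
  R <- gram_diagonal(op)
  # detector columns covered by every shift: max(shift)+1 .. scene cols
  expect_true(all(R[, 3:6] == L))
})

test_that("adjoint identity holds to 1e-10 relative", {
  inst <- random_instance(8, 8, 4, seed = 21)
  set.seed(22)
  for (i in 1:20) {
    f <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
    y <- matrix(rnorm(prod(inst$op$detector_shape)),
                inst$op$detector_shape[1])
    cube <- spectral_cube(f, test_centers(4), physical = FALSE)
    lhs <- sum(unclass(cassi_forward(inst$op, cube)) * y)
    rhs <- sum(f * unclass(cassi_adjoint(inst$op, measurement(y))))
    expect_lt(abs(lhs - rhs) / max(abs(lhs), 1e-12), 1e-10)
  }
})

test_that("energy accounting and the diagonal-Gram identity hold", {
  inst <- random_instance(7, 5, 3, seed = 31)
  y_f <- cassi_forward(inst$op, inst$cube)
  masked <- apply_mask(inst$cube, inst$mask)
  expect_equal(sum(y_f), sum(masked), tolerance = 1e-12)

  # forward(adjoint(y)) == R * y elementwise
  y <- matrix(runif(prod(inst$op$detector_shape)),
              inst$op$detector_shape[1])
  lhs <- unclass(cassi_forward(inst$op, cassi_adjoint(inst$op,
                                                      measurement(y))))
  expect_equal(lhs, gram_diagonal(inst$op) * y, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("sensor noise is seeded, unbiased and sized correctly", {
  y <- measurement(matrix(0, 100, 100))
  expect_identical(add_noise(y, 0, seed = 5), y)
  n1 <- add_noise(y, 1, seed = 3)
  n2 <- add_noise(y, 1, seed = 3)
  expect_identical(unclass(n1), unclass(n2))
  expect_lt(abs(mean(n1)), 3 / 100)            # 3 sd of the mean of 1e4
  expect_lt(abs(sd(as.vector(n1)) - 1), 0.05)  # s.d. within 5%
  expect_error(add_noise(y, -1), "non-negative")
})

test_that("operator construction validates shapes and shifts", {
  expect_error(sensing_operator(coded_mask(matrix(1, 4, 4)), c(2L, 0L)),
               "non-decreasing")
  expect_error(sensing_operator(coded_mask(matrix(1, 4, 4)), c(-1L, 0L)),
               "non-negative")
  op <- sensing_operator(coded_mask(matrix(1, 4, 4)), c(0L, 3L))
  expect_equal(op$detector_shape, c(4L, 7L))
  bad <- spectral_cube(array(1, c(4, 4, 3)), test_centers(3))
  expect_error(cassi_forward(op, bad), "match")
})
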