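test_that("bilinear interpolation is exact at nodes and for constants", {
  f <- random_field(n = 7, cell = 0.3, seed = 9)
  xs <- f$x_origin + (seq_len(ncol(f$values)) - 1) * f$cell_size
  ys <- f$y_origin + (seq_len(nrow(f$values)) - 1) * f$cell_size
  nodes <- expand.grid(x = xs, y = ys)
  v <- field_value(f, as.matrix(nodes))
  expect_equal(v, as.vector(t(f$values)), tolerance = 1e-14)

  cf <- const_field(5)
  pts <- cbind(runif(20, -0.99, 0.99), runif(20, -0.99, 0.99))
  expect_equal(field_value(cf, pts), rep(5, 20))
})

test_that("a unit cell with one raised corner interpolates to 1/4 at its centre", {
  f <- covariate_field(rbind(c(0, 0), c(0, 1)), 0, 0, 1)
  expect_equal(field_value(f, c(0.5, 0.5)), 0.25)
})

test_that("bilinear interpolation reproduces functions linear in each coordinate", {
  f <- planar_field(2, 3)
  set.seed(4)
  pts <- cbind(runif(50, -0.95, 0.95), runif(50, -0.95, 0.95))
  expect_equal(field_value(f, pts), 2 * pts[, 1] + 3 * pts[, 2],
               tolerance = 1e-12)
  g <- field_gradient(f, pts)
  expect_equal(g[, 1], rep(2, 50), tolerance = 1e-10)
  expect_equal(g[, 2], rep(3, 50), tolerance = 1e-10)
})

test_that("the analytic gradient matches finite differences of the interpolant", {
  f <- random_field(n = 5, cell = 0.5, seed = 17)
  set.seed(5)
  # keep points away from cell edges so both FD probes stay in one cell
  pts <- cbind(runif(20, -0.9, 0.9), runif(20, -0.9, 0.9))
  snap <- function(z) {
    frac <- (z + 1) / 0.5
    off <- frac - floor(frac)
    z + ifelse(off < 0.1, 0.1, ifelse(off > 0.9, -0.1, 0)) * 0.5
  }
  pts <- apply(pts, 2, snap)
  g <- field_gradient(f, pts)
  h <- 1e-6
  ex <- matrix(c(h, 0), nrow(pts), 2, byrow = TRUE)
  ey <- matrix(c(0, h), nrow(pts), 2, byrow = TRUE)
  fdx <- (field_value(f, pts + ex) - field_value(f, pts - ex)) / (2 * h)
  fdy <- (field_value(f, pts + ey) - field_value(f, pts - ey)) / (2 * h)
  expect_equal(g[, 1], fdx, tolerance = 1e-4)
  expect_equal(g[, 2], fdy, tolerance = 1e-4)
  expect_equal(field_gradient(const_field(3), cbind(0.1, 0.2)),
               cbind(0, 0), ignore_attr = TRUE)
})

test_that("out-of-domain evaluation raises a bounded error naming the point", {
  f <- const_field(1)
  expect_error(field_value(f, c(1.5, 0)), "1.5.*outside")
  expect_error(field_gradient(f, c(0, -2)), "outside")
  expect_error(linear_predictor(habitat_model(list(f), 1), c(2, 2)),
               "outside")
})

test_that("polynomial covariates have exact analytic values and gradients", {
  pts <- cbind(c(0.3, -1), c(-0.4, 2))
  expect_equal(cov_value(polynomial_covariate("coord_x"), pts), pts[, 1])
  expect_equal(cov_value(polynomial_covariate("coord_y"), pts), pts[, 2])
  expect_equal(cov_value(polynomial_covariate("neg_half_sq_norm"), pts),
               -0.5 * rowSums(pts^2))
  expect_equal(cov_gradient(polynomial_covariate("neg_half_sq_norm"), pts),
               -pts, ignore_attr = TRUE)
})

test_that("linear_predictor sums beta-weighted covariates without intercept", {
  m0 <- habitat_model(list(polynomial_covariate("coord_x"),
                           polynomial_covariate("coord_y")), c(0, 0))
  expect_equal(linear_predictor(m0, c(0.7, -0.3)), 0)
  m1 <- habitat_model(list(polynomial_covariate("neg_half_sq_norm")), 1)
  expect_equal(linear_predictor(m1, c(0.3, -0.4)), -0.125)
  m2 <- habitat_model(list(planar_field(2, 3),
                           polynomial_covariate("coord_x")), c(2, -1))
  expect_equal(linear_predictor(m2, c(0.1, 0.2)), 2 * 0.8 - 0.1,
               tolerance = 1e-12)
})

test_that("habitat_model validates lengths and the positivity constraint", {
  expect_error(habitat_model(list(polynomial_covariate("coord_x")),
                             c(1, 2)), "coefficients")
  expect_error(
    habitat_model(list(polynomial_covariate("neg_half_sq_norm")), -1),
    "positive")
  expect_error(ou_attraction_model(c(0, 0), -0.1), "positive")
})

test_that("utilization weights are a proper distribution, uniform when flat", {
  g <- eval_grid(-1, 1, -1, 1, 0.2)
  uw <- utilization_weights(flat_model(), g)
  expect_equal(sum(uw$weights), 1)
  expect_true(all(uw$weights >= 0))
  expect_equal(uw$weights, rep(1 / 100, 100))
})

test_that("utilization weights are invariant to constant shifts of eta", {
  g <- eval_grid(-1, 1, -1, 1, 0.25)
  m <- ou_model(0.1)
  shifted <- habitat_model(c(m$covariates, list(const_field(1))),
                           c(m$beta, 37))  # adds the constant 37 to eta
  expect_equal(utilization_weights(m, g)$weights,
               utilization_weights(shifted, g)$weights,
               tolerance = 1e-12)
})

test_that("OU utilization matches the bivariate normal stationary law", {
  lam <- 0.04
  m <- ou_model(lam)
  g <- eval_grid(-1, 1, -1, 1, 0.004)  # spacing = lambda / 10
  uw <- utilization_weights(m, g)
  # weight-implied marginal variance per coordinate
  vx <- sum(uw$weights * uw$points[, 1]^2) -
    sum(uw$weights * uw$points[, 1])^2
  vy <- sum(uw$weights * uw$points[, 2]^2) -
    sum(uw$weights * uw$points[, 2])^2
  expect_equal(vx, lam, tolerance = 0.02)
  expect_equal(vy, lam, tolerance = 0.02)
  # grid-free exact check: weight ratios equal normal-density ratios
  i <- c(10, 5000, 120000); j <- c(77, 30011, 200001)
  ratio_w <- uw$weights[i] / uw$weights[j]
  dens <- function(p) exp(-rowSums(p^2) / (2 * lam))
  ratio_d <- dens(uw$points[i, ]) / dens(uw$points[j, ])
  expect_equal(ratio_w, ratio_d, tolerance = 1e-6)
})

test_that("ou_attraction_model maps (mu, lambda) to coefficients and back", {
  ou <- ou_attraction_model(c(0, 0), 0.2^2)
  expect_equal(ou$beta, c(0, 0, 25))
  expect_equal(vapply(ou$covariates, function(cv) cv$kind, character(1)),
               c("coord_x", "coord_y", "neg_half_sq_norm"))
  ou2 <- ou_attraction_model(c(1, 2), 1)
  expect_equal(ou2$beta, c(1, 2, 1))
  rt <- ou_attraction_params(ou_attraction_model(c(-0.3, 0.7), 0.05)$beta)
  expect_equal(rt$mu, c(-0.3, 0.7))
  expect_equal(rt$lam, 0.05)
})

test_that("simulated random fields have the requested first two moments", {
  expect_equal(simulate_grf(0.1, 0, n_x = 5, n_y = 5, seed = 1)$values,
               matrix(0, 5, 5))
  # circulant path: pooled node variance over 20 seeds within 15%
  fields <- lapply(1:20, function(s)
    simulate_grf(0.1, 0.1, cell_size = 0.005, n_x = 200, n_y = 200,
                 seed = 1000 + s))
  pooled <- mean(vapply(fields, function(f) mean(f$values^2), numeric(1)))
  expect_equal(pooled, 0.1, tolerance = 0.15)
  # empirical correlation at one range unit (lag 0.1 = 20 cells) near 1/e
  lag_cor <- vapply(fields, function(f) {
    v <- f$values
    cor(as.vector(v[, 1:180]), as.vector(v[, 21:200]))
  }, numeric(1))
  expect_equal(mean(lag_cor), exp(-1), tolerance = 0.05 / exp(-1))
})

test_that("the dense-Cholesky path agrees with the covariance model too", {
  fields <- lapply(1:30, function(s)
    simulate_grf(0.5, 0.2, cell_size = 0.1, n_x = 20, n_y = 20,
                 seed = 2000 + s))
  pooled <- mean(vapply(fields, function(f) mean(f$values^2), numeric(1)))
  expect_equal(pooled, 0.2, tolerance = 0.15)
  # fields are zero-mean by construction, so use raw cross-moments
  lag1 <- mean(vapply(fields, function(f) {
    v <- f$values
    mean(v[, 1:19] * v[, 2:20])
  }, numeric(1)))
  expect_equal(lag1, 0.2 * exp(-0.1 / 0.5), tolerance = 0.1)
})

test_that("simulate_grf is bit-for-bit reproducible under a fixed seed", {
  a <- simulate_grf(0.1, 0.1, n_x = 80, n_y = 80, seed = 7)  # circulant
  b <- simulate_grf(0.1, 0.1, n_x = 80, n_y = 80, seed = 7)
  expect_identical(a$values, b$values)
  d <- simulate_grf(0.1, 0.1, n_x = 80, n_y = 80, seed = 8)
  expect_false(identical(a$values, d$values))
  s1 <- simulate_grf(0.3, 0.1, n_x = 15, n_y = 15, seed = 7)  # Cholesky
  s2 <- simulate_grf(0.3, 0.1, n_x = 15, n_y = 15, seed = 7)
  expect_identical(s1$values, s2$values)
})
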