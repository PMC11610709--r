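test_that("the Langevin drift follows (Gamma/2) * sum beta_i grad c_i", {
  expect_equal(drift(flat_model(), 1, cbind(0.2, 0.7)), cbind(0, 0),
               ignore_attr = TRUE)
  m_ou <- habitat_model(list(polynomial_covariate("coord_x"),
                             polynomial_covariate("coord_y"),
                             polynomial_covariate("neg_half_sq_norm")),
                        c(0, 0, 1))
  expect_equal(drift(m_ou, 2, c(0.3, -0.4)), cbind(-0.3, 0.4),
               ignore_attr = TRUE)
  m_pl <- habitat_model(list(planar_field(2, 3)), 2)
  expect_equal(drift(m_pl, 1e-5, c(0.12, -0.55)),
               1e-5 * cbind(2, 3), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("gradient averaging is inert where it should be", {
  m_pl <- habitat_model(list(planar_field(2, 3),
                             polynomial_covariate("coord_x")), c(2, -1))
  set.seed(11)
  pts <- cbind(runif(10, -0.5, 0.5), runif(10, -0.5, 0.5))
  b <- drift(m_pl, 1, pts)
  # zeta = 0 collapses any scheme onto the raw drift
  expect_equal(smoothed_drift(m_pl, 1, pts, zeta = 0, dt = 1, "g4"), b)
  # globally linear eta: averaging a constant gradient changes nothing
  expect_equal(smoothed_drift(m_pl, 1, pts, zeta = 0.3, dt = 1, "g4"), b,
               tolerance = 1e-12)
  # OU model: gradient linear in x, symmetric offsets cancel exactly
  m_ou <- ou_model(0.04)
  b_ou <- drift(m_ou, 1, pts)
  for (s in c("g4", "g8"))
    expect_equal(smoothed_drift(m_ou, 1, pts, zeta = 0.2, dt = 2, s), b_ou,
                 tolerance = 1e-12)
})

test_that("smoothed drift equals the hand-built weighted gradient average", {
  f <- random_field(n = 9, cell = 0.25, seed = 23)
  m <- habitat_model(list(f), 1.7)
  sch <- gradient_scheme("g4")
  p <- c(0.11, -0.27)
  zeta <- 0.05; dt <- 1.4
  manual <- Reduce(`+`, lapply(seq_along(sch$weights), function(k)
    sch$weights[k] * field_gradient(f, p + zeta * dt * sch$offsets[k, ])))
  expect_equal(smoothed_drift(m, 2, p, zeta, dt, "g4"),
               2 / 2 * 1.7 * rbind(manual), ignore_attr = TRUE)
})

test_that("gradient schemes validate symmetry and weights", {
  g4 <- gradient_scheme("g4")
  expect_equal(sum(g4$weights), 1)
  expect_equal(g4$weights[1], 0.5)
  g8 <- gradient_scheme("g8")
  expect_equal(length(g8$weights), 9)
  expect_equal(unique(g8$weights[-1]), 1 / 16)
  # all outer points of g8 are equidistant
  d <- sqrt(rowSums(g8$offsets[-1, ]^2))
  expect_equal(d, rep(sqrt(2), 8))
  expect_error(gradient_scheme(list(offsets = rbind(c(0, 0), c(1, 0)),
                                    weights = c(0.5, 0.5))),
               "negation")
  expect_error(gradient_scheme(list(offsets = rbind(c(0, 0)),
                                    weights = 2)), "sum to one")
})

test_that("zeta calibrates the scheme distance to the mean step length", {
  t1 <- trajectory("a", c(0, 1), rbind(c(0, 0), c(0.1, 0)))
  expect_equal(estimate_zeta(t1), 0.1 / sqrt(2))
  t2 <- trajectory("b", c(0, 1, 2, 3),
                   rbind(c(0, 0), c(0.05, 0), c(0.1, 0), c(0.15, 0)))
  expect_equal(estimate_zeta(t2), 0.05 / sqrt(2))
  t3 <- trajectory("c", c(0, 2, 6),
                   rbind(c(0, 0), c(0.2, 0), c(0.2, 0.4)))
  expect_equal(estimate_zeta(t3), (0.1 + 0.1) / (2 * sqrt(2)))
  expect_error(estimate_zeta(trajectory("d", 0, c(1, 1))), "steps")
})

test_that("simulation degenerates correctly and reproduces seeds", {
  tr <- simulate_langevin(flat_model(), 1e-30, c(0.2, 0.3),
                          fine_step = 0.1, duration = 2, seed = 3)
  expect_equal(length(tr$times), 21)
  expect_true(max(abs(sweep(tr$locations, 2, c(0.2, 0.3)))) < 1e-10)
  a <- simulate_langevin(ou_model(0.1), 1e-3, c(0, 0), 0.1, 5, seed = 9)
  b <- simulate_langevin(ou_model(0.1), 1e-3, c(0, 0), 0.1, 5, seed = 9)
  expect_identical(a$locations, b$locations)
})

test_that("flat-model simulation is Brownian: displacement variance = Gamma * t", {
  n <- 5000
  paths <- telsurv:::simulate_colony_paths(
    flat_model(), Gamma = 1, starts = matrix(0, n, 2),
    fine_step = 0.01, n_steps = 100, thin_every = 100, seed = 21)
  final <- paths[, , 2]
  expect_equal(mean(final[, 1]^2), 1, tolerance = 0.05)
  expect_equal(mean(final[, 2]^2), 1, tolerance = 0.05)
})

test_that("long OU simulation settles at the stationary variance lambda", {
  lam <- 0.04
  tracks <- simulate_colony(ou_model(lam), Gamma = 1e-3,
                            starts = matrix(0, 40, 2),
                            fine_step = 0.5, duration = 3000,
                            obs_interval = 10, seed = 31)
  locs <- do.call(rbind, lapply(tracks, function(tr)
    tr$locations[tr$times > 300, ]))  # discard the approach to stationarity
  expect_equal(mean(locs[, 1]^2), lam, tolerance = 0.1)
  expect_equal(mean(locs[, 2]^2), lam, tolerance = 0.1)
})

test_that("thinning counts fixes correctly and composes", {
  tr <- simulate_langevin(flat_model(), 1e-4, c(0, 0), 0.1, 500, seed = 2)
  expect_equal(length(tr$times), 5001)
  expect_identical(thin_track(tr, 0.1)$times, tr$times)
  th <- thin_track(tr, 1)
  expect_equal(length(th$times), 501)
  expect_equal(diff(th$times), rep(1, 500))
  expect_equal(thin_track(thin_track(tr, 0.5), 1)$locations,
               th$locations)
  expect_error(thin_track(tr, 0.25), "integral multiple")
  irr <- trajectory("x", c(0, 1, 3), rbind(c(0, 0), c(1, 0), c(2, 0)))
  expect_error(thin_track(irr, 2), "regular")
})

test_that("movement log-likelihood matches hand-computed normal densities", {
  step <- function(x0, x1, dt = 1)
    trajectory("s", c(0, dt), rbind(x0, x1))
  # flat model, gamma = 0: standard bivariate normal at / off its mean
  expect_equal(movement_loglik(step(c(0, 0), c(0, 0)), flat_model(), 0),
               -log(2 * pi))
  expect_equal(movement_loglik(step(c(0, 0), c(1, 0)), flat_model(), 0),
               -log(2 * pi) - 0.5)
  # OU-only, beta3 = 1, Gamma = 2, dt = 0.1: mean (0.45, 0), var 0.2
  m_ou <- habitat_model(list(polynomial_covariate("coord_x"),
                             polynomial_covariate("coord_y"),
                             polynomial_covariate("neg_half_sq_norm")),
                        c(0, 0, 1))
  expect_equal(
    movement_loglik(step(c(0.5, 0), c(0.4, 0), 0.1), m_ou, log(2)),
    -log(2 * pi * 0.2) - 0.05^2 / (2 * 0.2))
})

test_that("zeta = 0 reproduces the naive Euler likelihood exactly", {
  f <- random_field(n = 9, cell = 0.25, seed = 5)
  m <- habitat_model(list(f, polynomial_covariate("neg_half_sq_norm")),
                     c(1.5, 10))
  tr <- simulate_colony(m, 1e-3, matrix(0, 3, 2), 0.1, 20,
                        obs_interval = 1, seed = 13)
  for (s in c("g4", "g8"))
    expect_equal(movement_loglik(tr, m, -6, zeta = 0, scheme = s),
                 movement_loglik(tr, m, -6, scheme = "raw"))
})

test_that("movement likelihood ignores constant shifts of eta", {
  m <- ou_model(0.04)
  tr <- simulate_colony(m, 1e-3, matrix(0.05, 4, 2), 0.1, 20,
                        obs_interval = 1, seed = 17)
  shifted <- habitat_model(c(m$covariates, list(const_field(1))),
                           c(m$beta, -11))
  expect_equal(movement_loglik(tr, m, -6),
               movement_loglik(tr, shifted, -6))
})

test_that("single-fix tracks warn and contribute nothing", {
  ok <- trajectory("a", c(0, 1), rbind(c(0, 0), c(0.1, 0)))
  lone <- trajectory("b", 0, c(0.5, 0.5))
  expect_warning(
    ll2 <- movement_loglik(list(ok, lone), flat_model(), 0, zeta = 0),
    "single fix")
  expect_equal(ll2, movement_loglik(list(ok), flat_model(), 0, zeta = 0))
})

test_that("Brownian diffusivity MLE matches its closed form", {
  tr <- thin_track(simulate_langevin(flat_model(), 0.5, c(0, 0),
                                     0.01, 5, seed = 41), 0.1)
  ft <- fit_joint(tracks = list(tr),
                  covariates = list(polynomial_covariate("coord_x")),
                  init = list(beta = 0), fixed_beta = TRUE)
  n <- length(tr$times) - 1
  closed <- log(sum(rowSums(diff(tr$locations)^2) / diff(tr$times)) /
                  (2 * n))
  expect_equal(ft$gamma, closed, tolerance = 1e-6)
})
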