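test_that("design grids span both margins and exclude the empty design", {
  g <- design_grid()
  expect_equal(nrow(g), 11 * 11 - 1)
  expect_true(all(g$n_tracks > 0 | g$survey_side > 0))
  expect_error(design_point(0, 0), "at least one")
  small <- design_grid(c(0, 10), c(0, 0.5))
  expect_equal(nrow(small), 3)
})

test_that("run_replicate handles degenerate designs", {
  cfg <- tiny_config()
  f <- simulate_grf(cfg$landscape$range, cfg$landscape$variance,
                    -1, -1, cfg$landscape$cell_size, 101, 101, seed = 50)
  tel_only <- run_replicate(f, design_point(3, 0), seed = 1, config = cfg)
  expect_equal(tel_only$m_points, 0)
  expect_true(is.finite(tel_only$beta1_hat))
  surv_only <- run_replicate(f, design_point(0, 0.6), seed = 1,
                             config = cfg)
  expect_true(surv_only$m_points > 0)
  expect_true(is.finite(surv_only$beta1_hat))
})

test_that("experiment runs are reproducible under a fixed master seed", {
  cfg <- tiny_config()
  designs <- data.frame(n_tracks = c(3, 0), survey_side = c(0, 0.6))
  r1 <- run_experiment(environments = 0.1, n_maps = 1,
                       replicates_per_map = 2, designs = designs,
                       config = cfg, master_seed = 7)
  r2 <- run_experiment(environments = 0.1, n_maps = 1,
                       replicates_per_map = 2, designs = designs,
                       config = cfg, master_seed = 7)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 4)
})

test_that("the precision surface recovers a noiseless additive truth", {
  g <- design_grid(seq(0, 50, by = 10), seq(0, 1, by = 0.1))
  g$precision <- 0.3 * g$n_tracks + 2 * g$survey_side^2
  g$environment <- 0.1
  surf <- fit_precision_surface(g)
  expect_equal(surf$linear_coeff, 0.3, tolerance = 1e-3)
  pred <- predict(surf, g$n_tracks, g$survey_side)
  nz <- g$precision > 0
  expect_lt(max(abs(pred[nz] - g$precision[nz]) / g$precision[nz]), 0.02)
  expect_equal(predict(surf, 0, 0), 0)
})

test_that("an all-zero precision table yields the flat zero surface", {
  g <- design_grid(c(0, 10, 20), c(0, 0.5, 1))
  g$precision <- 0
  surf <- fit_precision_surface(g)
  expect_equal(surf$linear_coeff, 0, tolerance = 1e-8)
  expect_equal(predict(surf, c(0, 20), c(0.7, 0.1)), c(0, 0),
               tolerance = 1e-6)
})

test_that("surface fitting demands both margins", {
  g <- expand.grid(n_tracks = c(5, 10), survey_side = c(0.2, 0.5))
  g$precision <- 1
  expect_error(fit_precision_surface(g), "margins")
})

test_that("the fitted smooth is monotone non-decreasing in survey size", {
  g <- design_grid(seq(0, 50, by = 10), seq(0, 1, by = 0.2))
  set.seed(12)
  g$precision <- 0.3 * g$n_tracks + 4 * sqrt(g$survey_side) +
    rnorm(nrow(g), 0, 0.1)
  g$precision[g$n_tracks == 0 & g$survey_side == 0] <- 0
  surf <- fit_precision_surface(g)
  sides <- seq(0, 1, by = 0.01)
  s_vals <- predict(surf, 0, sides)
  expect_true(all(diff(s_vals) >= -1e-9))
  expect_equal(s_vals[1], 0)
})

test_that("effort curves trade tracks for survey and locate the optimum", {
  g <- design_grid(seq(0, 50, by = 10), seq(0, 1, by = 0.1))
  g$precision <- 0.3 * g$n_tracks + 2 * g$survey_side^2
  surf <- fit_precision_surface(g)
  # survey worth next to nothing per unit effort: all effort to telemetry
  ec <- effort_curve(surf, effort_scenario(50, exchange_rate = 1e-6))
  expect_equal(ec$optimum$p, 1)
  # telemetry worthless here: a flat-in-n surface puts the optimum at p = 0
  g2 <- g
  g2$precision <- 2 * g2$survey_side^2
  surf2 <- fit_precision_surface(g2)
  ec2 <- effort_curve(surf2, effort_scenario(50, exchange_rate = 0.02))
  expect_equal(ec2$optimum$p, 0)
  # requesting effort beyond the fitted range is an error, not extrapolation
  expect_error(effort_curve(surf, effort_scenario(200, 0.02)), "fitted")
  expect_error(effort_curve(surf, effort_scenario(50, 1)), "side")
})

test_that("additivity checks classify exact and broken additivity", {
  base <- expand.grid(environment = 0.1, n_tracks = c(0, 10, 20),
                      survey_side = c(0, 0.4, 0.8))
  base <- base[!(base$n_tracks == 0 & base$survey_side == 0), ]
  tel <- 0.5 * base$n_tracks
  sur <- 3 * base$survey_side
  base$precision <- ifelse(base$n_tracks > 0 & base$survey_side > 0,
                           tel + sur,
                           ifelse(base$n_tracks > 0, tel, sur))
  ac <- additivity_check(base)
  expect_equal(nrow(ac$designs), 4)  # only the mixed designs
  expect_equal(unname(ac$fraction_within), c(1, 1))
  # perturb one joint precision by 8%: inside 10% but outside 5%
  base2 <- base
  mixed <- base2$n_tracks == 10 & base2$survey_side == 0.4
  base2$precision[mixed] <- base2$precision[mixed] * 1.08
  ac2 <- additivity_check(base2)
  expect_equal(unname(ac2$fraction_within), c(3 / 4, 1))
})

test_that("the bias study returns per-scheme estimates with shared datasets", {
  cfg <- tiny_config()
  cfg$movement$n_individuals <- 4
  res <- bias_study(n_maps = 1, datasets_per_map = 2, n_tracks = 4,
                    schemes = c("raw", "g4"), config = cfg,
                    master_seed = 3)
  expect_equal(dim(res$estimates), c(2, 2))
  expect_true(all(is.finite(res$estimates)))
  expect_equal(res$bias,
               colMeans(res$estimates) - 2, ignore_attr = TRUE)
  expect_equal(dim(res$correlations), c(2, 2))
  # reproducibility
  res2 <- bias_study(n_maps = 1, datasets_per_map = 2, n_tracks = 4,
                     schemes = c("raw", "g4"), config = cfg,
                     master_seed = 3)
  expect_identical(res$estimates, res2$estimates)
})
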