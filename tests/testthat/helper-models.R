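# Shared builders for small test fixtures (all generated in code).

# constant-valued raster over [-1, 1]^2
const_field <- function(value = 0, n = 11, cell = 0.2) {
  covariate_field(matrix(value, n, n), -1, -1, cell)
}

# raster sampled from the plane a*x + b*y (bilinear reproduces it exactly)
planar_field <- function(a, b, n = 21, cell = 0.1, origin = -1) {
  xs <- origin + (seq_len(n) - 1) * cell
  covariate_field(outer(xs, xs, function(y, x) a * x + b * y),
                  origin, origin, cell)
}

# habitat model with zero selection everywhere (flat utilization)
flat_model <- function() {
  habitat_model(list(polynomial_covariate("coord_x")), 0)
}

# circular OU attraction model centred at mu
ou_model <- function(lam = 0.04, mu = c(0, 0)) {
  ou <- ou_attraction_model(mu, lam)
  habitat_model(ou$covariates, ou$beta)
}

random_field <- function(n = 5, cell = 0.25, origin = -1, seed = 42,
                         sd = 1) {
  vals <- telsurv:::with_seed(seed, matrix(rnorm(n * n, sd = sd), n, n))
  covariate_field(vals, origin, origin, cell)
}

# a small, fast experiment configuration (coarse landscape, short runs)
tiny_config <- function() {
  cfg <- default_config()
  cfg$landscape$cell_size <- 0.02
  cfg$movement$n_individuals <- 5
  cfg$movement$duration <- 30
  cfg$survey$n_individuals <- 40
  cfg
}
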