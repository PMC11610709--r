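# Spatial covariates: gridded rasters with bilinear evaluation, polynomial
# localization covariates, and the log-linear habitat model built from them.

#' Gridded spatial covariate
#'
#' A regular raster of covariate values. Node `(i, j)` of the value matrix
#' sits at `(x_origin + (j-1) * cell_size, y_origin + (i-1) * cell_size)`,
#' i.e. rows index y and columns index x, with row 1 at the southern edge.
#' Between nodes the covariate is evaluated by bilinear interpolation, so it
#' is continuous everywhere and exact at the nodes.
#'
#' @param values Numeric matrix of node values; all finite.
#' @param x_origin,y_origin Coordinates of node `(1, 1)`.
#' @param cell_size Grid spacing (same units as the coordinates), `> 0`.
#' @return An object of class `covariate_field`.
#' @seealso [field_value()], [field_gradient()], [simulate_grf()]
#' @export
covariate_field <- function(values, x_origin, y_origin, cell_size) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) >= 2, ncol(values) >= 2)
  if (!all(is.finite(values))) stop("covariate values must all be finite")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("cell_size must be a single positive number")
  structure(
    list(values = values,
         x_origin = as.numeric(x_origin), y_origin = as.numeric(y_origin),
         cell_size = as.numeric(cell_size)),
    class = "covariate_field")
}

#' @export
print.covariate_field <- function(x, ...) {
  cat(sprintf("<covariate_field> %d x %d nodes, spacing %g\n",
              nrow(x$values), ncol(x$values), x$cell_size))
  cat(sprintf("  x: [%g, %g]  y: [%g, %g]  values: [%.3g, %.3g]\n",
              x$x_origin, x$x_origin + (ncol(x$values) - 1) * x$cell_size,
              x$y_origin, x$y_origin + (nrow(x$values) - 1) * x$cell_size,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Polynomial covariate for central-attraction localization
#'
#' The Ornstein-Uhlenbeck attraction term of the habitat model is expressed
#' through three simple coordinate functions: `c(x, y) = x`, `c(x, y) = y`
#' and `c(x, y) = -(x^2 + y^2) / 2`. Their gradients are analytic:
#' `(1, 0)`, `(0, 1)` and `(-x, -y)`.
#'
#' @param kind One of `"coord_x"`, `"coord_y"`, `"neg_half_sq_norm"`.
#' @return An object of class `polynomial_covariate`.
#' @seealso [ou_attraction_model()]
#' @export
polynomial_covariate <- function(kind = c("coord_x", "coord_y",
                                          "neg_half_sq_norm")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "polynomial_covariate")
}

#' @export
print.polynomial_covariate <- function(x, ...) {
  cat(sprintf("<polynomial_covariate> %s\n", x$kind))
  invisible(x)
}

field_bounds <- function(field) {
  list(xmin = field$x_origin,
       xmax = field$x_origin + (ncol(field$values) - 1) * field$cell_size,
       ymin = field$y_origin,
       ymax = field$y_origin + (nrow(field$values) - 1) * field$cell_size)
}

as_points <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 2) stop("a point must have two coordinates")
    points <- matrix(points, 1, 2)
  }
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must be an n x 2 matrix")
  points
}

check_in_bounds <- function(points, field) {
  b <- field_bounds(field)
  bad <- points[, 1] < b$xmin | points[, 1] > b$xmax |
    points[, 2] < b$ymin | points[, 2] > b$ymax
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "point (%g, %g) lies outside the covariate grid [%g, %g] x [%g, %g]",
      points[i, 1], points[i, 2], b$xmin, b$xmax, b$ymin, b$ymax))
  }
  invisible(TRUE)
}

# Locate the interpolation cell and in-cell fractions for each point.
# Cells are half-open [node, node + cell_size) except the top/right
# boundary, which belongs to the last cell. When clamp = TRUE, points
# outside the grid are moved to the nearest in-grid point (used during
# simulation for rare excursions).
cell_index <- function(field, points, clamp = FALSE) {
  h <- field$cell_size
  nr <- nrow(field$values)
  nc <- ncol(field$values)
  fx <- (points[, 1] - field$x_origin) / h
  fy <- (points[, 2] - field$y_origin) / h
  if (clamp) {
    n_out <- sum(fx < 0 | fx > nc - 1 | fy < 0 | fy > nr - 1)
    if (n_out > 0) {
      warning(sprintf(
        "clamped %d point(s) outside the covariate grid to its boundary",
        n_out), call. = FALSE)
      fx <- pmin(pmax(fx, 0), nc - 1)
      fy <- pmin(pmax(fy, 0), nr - 1)
    }
  }
  j <- pmin(floor(fx), nc - 2)  # zero-based cell column
  i <- pmin(floor(fy), nr - 2)  # zero-based cell row
  list(i = i, j = j, u = fx - j, v = fy - i)
}

#' Evaluate a gridded covariate by bilinear interpolation
#'
#' @param field A [covariate_field()].
#' @param points A length-2 vector or an `n x 2` matrix of coordinates.
#' @param clamp Clamp out-of-grid points to the grid boundary instead of
#'   raising an error (used internally during movement simulation).
#' @return Numeric vector of interpolated values, one per point.
#' @export
field_value <- function(field, points, clamp = FALSE) {
  points <- as_points(points)
  if (!clamp) check_in_bounds(points, field)
  ix <- cell_index(field, points, clamp = clamp)
  V <- field$values
  i <- ix$i + 1L; j <- ix$j + 1L; u <- ix$u; v <- ix$v
  V[cbind(i, j)] * (1 - u) * (1 - v) + V[cbind(i, j + 1L)] * u * (1 - v) +
    V[cbind(i + 1L, j)] * (1 - u) * v + V[cbind(i + 1L, j + 1L)] * u * v
}

#' Gradient of the bilinear interpolant
#'
#' Returns the analytic gradient of the interpolated surface within the cell
#' containing each point. The components are piecewise linear and
#' discontinuous across cell edges; on an edge the containing cell follows
#' the half-open cell convention of [covariate_field()].
#'
#' @inheritParams field_value
#' @return An `n x 2` matrix of gradient vectors.
#' @export
field_gradient <- function(field, points, clamp = FALSE) {
  points <- as_points(points)
  if (!clamp) check_in_bounds(points, field)
  ix <- cell_index(field, points, clamp = clamp)
  V <- field$values
  h <- field$cell_size
  i <- ix$i + 1L; j <- ix$j + 1L; u <- ix$u; v <- ix$v
  f00 <- V[cbind(i, j)]; f01 <- V[cbind(i, j + 1L)]
  f10 <- V[cbind(i + 1L, j)]; f11 <- V[cbind(i + 1L, j + 1L)]
  cbind(((1 - v) * (f01 - f00) + v * (f11 - f10)) / h,
        ((1 - u) * (f10 - f00) + u * (f11 - f01)) / h,
        deparse.level = 0)
}

#' @rdname cov_value
#' @export
cov_value <- function(covariate, points, clamp = FALSE) {
  UseMethod("cov_value")
}

#' Evaluate any covariate (raster or polynomial) and its gradient
#'
#' Generic dispatch over the two covariate types of a habitat model.
#'
#' @param covariate A [covariate_field()] or [polynomial_covariate()].
#' @param points A length-2 vector or `n x 2` matrix.
#' @param clamp See [field_value()].
#' @return `cov_value`: numeric vector; `cov_gradient`: `n x 2` matrix.
#' @export
cov_gradient <- function(covariate, points, clamp = FALSE) {
  UseMethod("cov_gradient")
}

#' @export
cov_value.covariate_field <- function(covariate, points, clamp = FALSE) {
  field_value(covariate, points, clamp = clamp)
}

#' @export
cov_gradient.covariate_field <- function(covariate, points, clamp = FALSE) {
  field_gradient(covariate, points, clamp = clamp)
}

#' @export
cov_value.polynomial_covariate <- function(covariate, points, clamp = FALSE) {
  points <- as_points(points)
  switch(covariate$kind,
         coord_x = points[, 1],
         coord_y = points[, 2],
         neg_half_sq_norm = -0.5 * (points[, 1]^2 + points[, 2]^2))
}

#' @export
cov_gradient.polynomial_covariate <- function(covariate, points,
                                              clamp = FALSE) {
  points <- as_points(points)
  n <- nrow(points)
  switch(covariate$kind,
         coord_x = cbind(rep(1, n), rep(0, n), deparse.level = 0),
         coord_y = cbind(rep(0, n), rep(1, n), deparse.level = 0),
         neg_half_sq_norm = -points)
}

#' Log-linear habitat-selection model
#'
#' The utilization surface is `pi(x) proportional to exp(eta(x))` with linear
#' predictor `eta(x) = sum_i beta_i c_i(x)`. There is no intercept: the
#' survey intensity intercept `alpha` absorbs the normalizing constant, and
#' movement depends only on the gradient of `eta`.
#'
#' @param covariates List of [covariate_field()] / [polynomial_covariate()]
#'   objects.
#' @param beta Numeric coefficient vector, one per covariate. If a
#'   `neg_half_sq_norm` covariate is present its coefficient must be strictly
#'   positive (it equals `1 / lambda` for the attraction model, and lambda is
#'   a variance).
#' @return An object of class `habitat_model`.
#' @seealso [ou_attraction_model()], [linear_predictor()]
#' @export
habitat_model <- function(covariates, beta) {
  if (inherits(covariates, c("covariate_field", "polynomial_covariate")))
    covariates <- list(covariates)
  stopifnot(is.list(covariates), length(covariates) >= 1)
  ok <- vapply(covariates, inherits, logical(1),
               what = c("covariate_field", "polynomial_covariate"))
  if (!all(ok)) stop("covariates must be covariate_field or ",
                     "polynomial_covariate objects")
  beta <- as.numeric(beta)
  if (length(beta) != length(covariates))
    stop(sprintf("got %d coefficients for %d covariates",
                 length(beta), length(covariates)))
  if (!all(is.finite(beta))) stop("beta must be finite")
  quad <- quad_index(covariates)
  if (!is.na(quad) && beta[quad] <= 0)
    stop("the coefficient of the neg_half_sq_norm covariate must be ",
         "strictly positive (it is an inverse variance)")
  structure(list(covariates = covariates, beta = beta),
            class = "habitat_model")
}

quad_index <- function(covariates) {
  kinds <- vapply(covariates, function(cv) {
    if (inherits(cv, "polynomial_covariate")) cv$kind else "raster"
  }, character(1))
  i <- which(kinds == "neg_half_sq_norm")
  if (length(i) == 0) NA_integer_ else i[1]
}

#' @export
print.habitat_model <- function(x, ...) {
  kinds <- vapply(x$covariates, function(cv) {
    if (inherits(cv, "polynomial_covariate")) cv$kind else "raster"
  }, character(1))
  cat("<habitat_model>\n")
  for (i in seq_along(kinds))
    cat(sprintf("  beta[%d] = %10.5g  (%s)\n", i, x$beta[i], kinds[i]))
  invisible(x)
}

#' Linear predictor of the habitat model
#'
#' `eta(x) = sum_i beta_i c_i(x)`, the log of the (unnormalized)
#' utilization surface.
#'
#' @param model A [habitat_model()].
#' @param points A length-2 vector or `n x 2` matrix.
#' @param clamp See [field_value()].
#' @return Numeric vector of `eta` values.
#' @export
linear_predictor <- function(model, points, clamp = FALSE) {
  points <- as_points(points)
  eta <- numeric(nrow(points))
  for (i in seq_along(model$covariates))
    eta <- eta + model$beta[i] * cov_value(model$covariates[[i]], points,
                                           clamp = clamp)
  eta
}

#' Regular evaluation grid
#'
#' Cell-centre grid over a rectangle, used for utilization weights, survey
#' integrals and direct sampling from the utilization distribution.
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds.
#' @param cell_size Cell edge length; the rectangle is divided into
#'   `round((xmax - xmin) / cell_size)` columns (and similarly rows), so the
#'   bounds should be (near-)multiples of `cell_size`.
#' @return An object of class `eval_grid` with cell centres and area.
#' @export
eval_grid <- function(xmin, xmax, ymin, ymax, cell_size) {
  stopifnot(xmax > xmin, ymax > ymin, cell_size > 0)
  nx <- max(1L, round((xmax - xmin) / cell_size))
  ny <- max(1L, round((ymax - ymin) / cell_size))
  hx <- (xmax - xmin) / nx
  hy <- (ymax - ymin) / ny
  structure(list(xmin = xmin, ymin = ymin, nx = nx, ny = ny,
                 hx = hx, hy = hy,
                 xc = xmin + (seq_len(nx) - 0.5) * hx,
                 yc = ymin + (seq_len(ny) - 0.5) * hy),
            class = "eval_grid")
}

grid_centres <- function(grid) {
  cbind(rep(grid$xc, times = grid$ny),
        rep(grid$yc, each = grid$nx), deparse.level = 0)
}

#' Discrete utilization distribution on a grid
#'
#' Cell-centre weights proportional to `exp(eta)`, normalized to sum to one.
#' The maximum of `eta` is subtracted before exponentiation so the
#' normalization is overflow-safe; the result is invariant to adding any
#' constant to `eta`.
#'
#' @param model A [habitat_model()].
#' @param grid An [eval_grid()] inside all raster covariate domains.
#' @return List with `points` (cell centres, `n x 2`), `weights` (summing
#'   to 1) and the grid.
#' @export
utilization_weights <- function(model, grid) {
  stopifnot(inherits(grid, "eval_grid"))
  pts <- grid_centres(grid)
  eta <- linear_predictor(model, pts)
  w <- exp(eta - max(eta))
  list(points = pts, weights = w / sum(w), grid = grid)
}

#' Central-attraction (Ornstein-Uhlenbeck) localization term
#'
#' An OU process attracted to `mu` with circular stationary covariance
#' `lambda * I` has utilization density proportional to
#' `exp(mu_x x / lambda + mu_y y / lambda - (x^2 + y^2) / (2 lambda))`, i.e.
#' a log-linear selection model on the three polynomial covariates
#' `x`, `y`, `-(x^2 + y^2) / 2` with coefficients
#' `(mu_x / lambda, mu_y / lambda, 1 / lambda)`.
#'
#' @param mu Attraction centre, length-2.
#' @param lam Stationary per-coordinate variance `lambda > 0` of the home
#'   range (spatial units squared).
#' @return List with `covariates` (the three polynomial covariates) and
#'   `beta` (their coefficients), ready to splice into [habitat_model()].
#' @export
ou_attraction_model <- function(mu = c(0, 0), lam) {
  stopifnot(length(mu) == 2, is.finite(mu))
  if (!is.numeric(lam) || length(lam) != 1 || !is.finite(lam) || lam <= 0)
    stop("lam must be a single positive number")
  list(covariates = list(polynomial_covariate("coord_x"),
                         polynomial_covariate("coord_y"),
                         polynomial_covariate("neg_half_sq_norm")),
       beta = c(mu[1] / lam, mu[2] / lam, 1 / lam))
}

#' Recover OU attraction parameters from model coefficients
#'
#' Inverse of [ou_attraction_model()]: `mu = (b1 / b3, b2 / b3)`,
#' `lambda = 1 / b3`.
#'
#' @param beta Length-3 coefficient vector for the covariates
#'   (`coord_x`, `coord_y`, `neg_half_sq_norm`), with `beta[3] > 0`.
#' @return List with `mu` and `lam`.
#' @export
ou_attraction_params <- function(beta) {
  stopifnot(length(beta) == 3)
  if (beta[3] <= 0) stop("beta[3] must be positive")
  list(mu = c(beta[1], beta[2]) / beta[3], lam = 1 / beta[3])
}

#' Simulate a Gaussian random field covariate
#'
#' Stationary zero-mean Gaussian field with exponential covariance
#' `variance * exp(-d / range)`, sampled exactly at the grid nodes. Small
#' grids (at most 4096 nodes) use a dense Cholesky factorization; larger
#' grids use circulant embedding on a doubled torus with FFT, which is also
#' exact when the embedding is positive semi-definite. Embedding
#' eigenvalues more negative than a 1e-6 relative tolerance raise an error;
#' negligible negative values (FFT round-off) are clamped to zero.
#'
#' @param range Spatial range (correlation length) of the exponential
#'   covariance, `> 0`; the correlation at distance `range` is `exp(-1)`.
#' @param variance Marginal variance of the field, `>= 0`.
#' @param x_origin,y_origin,cell_size,n_x,n_y Grid layout (see
#'   [covariate_field()]); `n_x`, `n_y` are node counts.
#' @param seed Integer seed; identical seeds reproduce identical fields.
#' @return A [covariate_field()].
#' @export
simulate_grf <- function(range, variance, x_origin = -1, y_origin = -1,
                         cell_size = 0.005, n_x = 401, n_y = 401,
                         seed = NULL) {
  stopifnot(range > 0, variance >= 0, n_x >= 2, n_y >= 2)
  if (variance == 0) {
    vals <- matrix(0, n_y, n_x)
  } else if (n_x * n_y <= 4096) {
    vals <- grf_cholesky(range, variance, cell_size, n_x, n_y, seed)
  } else {
    vals <- grf_circulant(range, variance, cell_size, n_x, n_y, seed)
  }
  covariate_field(vals, x_origin, y_origin, cell_size)
}

grf_cholesky <- function(range, variance, h, n_x, n_y, seed) {
  g <- expand.grid(y = (seq_len(n_y) - 1) * h, x = (seq_len(n_x) - 1) * h)
  D <- as.matrix(stats::dist(g[, c("x", "y")]))
  C <- variance * exp(-D / range)
  L <- chol(C + diag(1e-12 * variance, nrow(C)))
  z <- with_seed(seed, stats::rnorm(n_x * n_y))
  matrix(crossprod(L, z), n_y, n_x)
}

grf_circulant <- function(range, variance, h, n_x, n_y, seed) {
  # enlarge the torus until the embedding is positive semi-definite
  # (up to FFT round-off); padding doubles at each attempt
  for (pad in c(1, 2, 4, 8)) {
    M <- stats::nextn(pad * 2 * (n_y - 1), c(2, 3, 5))
    N <- stats::nextn(pad * 2 * (n_x - 1), c(2, 3, 5))
    dy <- pmin(0:(M - 1), M - (0:(M - 1))) * h
    dx <- pmin(0:(N - 1), N - (0:(N - 1))) * h
    D <- sqrt(outer(dy^2, dx^2, "+"))
    lam <- Re(stats::fft(variance * exp(-D / range)))
    if (min(lam) >= -1e-6 * max(lam)) break
  }
  if (min(lam) < -1e-6 * max(lam))
    stop("circulant embedding is not positive semi-definite for this ",
         "covariance; enlarge the grid padding")
  lam[lam < 0] <- 0
  Z <- with_seed(seed, matrix(stats::rnorm(M * N), M, N) +
                   1i * matrix(stats::rnorm(M * N), M, N))
  Re(stats::fft(sqrt(lam / (M * N)) * Z))[seq_len(n_y), seq_len(n_x)]
}

# Run code under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards. A NULL seed uses (and advances) the
# current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
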