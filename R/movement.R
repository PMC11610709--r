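# Langevin movement model: simulation, drift (raw and locally averaged),
# and the movement log-likelihood.

#' Telemetry trajectory
#'
#' Time-stamped locations of one tracked individual.
#'
#' @param id Individual identifier (coerced to character).
#' @param times Strictly increasing numeric vector of fix times.
#' @param locations `n x 2` matrix of coordinates, one row per fix.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(id, times, locations) {
  times <- as.numeric(times)
  locations <- as_points(locations)
  if (nrow(locations) != length(times))
    stop("times and locations disagree in length")
  if (length(times) < 1) stop("a trajectory needs at least one fix")
  if (any(diff(times) <= 0))
    stop(sprintf("times of individual '%s' must be strictly increasing", id))
  if (!all(is.finite(locations))) stop("locations must be finite")
  structure(list(id = as.character(id), times = times,
                 locations = locations),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> id '%s': %d fixes, t in [%g, %g]\n",
              x$id, length(x$times), x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

as_tracks <- function(tracks) {
  if (inherits(tracks, "trajectory")) tracks <- list(tracks)
  stopifnot(is.list(tracks), length(tracks) >= 1)
  ok <- vapply(tracks, inherits, logical(1), what = "trajectory")
  if (!all(ok)) stop("tracks must be trajectory objects")
  tracks
}

#' Gradient-averaging scheme for the locally averaged drift
#'
#' The locally averaged drift replaces the covariate gradient at the step's
#' start by a weighted average of gradients at the start and at displaced
#' points. Offsets are expressed in units of `zeta * dt`; the built-in
#' schemes are:
#'
#' * `"raw"`: the origin only (no averaging; plain Euler drift),
#' * `"g4"`: origin (weight 1/2) plus the four diagonal points
#'   `(+/-1, +/-1)` (weight 1/8 each), which lie at distance
#'   `zeta * sqrt(2) * dt`,
#' * `"g8"`: origin (weight 1/2) plus those four diagonal points and four
#'   axis-aligned points at the same distance `zeta * sqrt(2) * dt`
#'   (weight 1/16 each).
#'
#' Custom schemes must have non-negative weights summing to one, and every
#' non-origin offset must be paired with its negation at equal weight.
#'
#' @param scheme `"raw"`, `"g4"`, `"g8"`, or a list with elements `offsets`
#'   (`m x 2` matrix) and `weights` (length `m`).
#' @return An object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(scheme = c("g4", "raw", "g8")) {
  if (inherits(scheme, "gradient_scheme")) return(scheme)
  if (is.character(scheme)) {
    scheme <- match.arg(scheme)
    s2 <- sqrt(2)
    def <- switch(scheme,
      raw = list(offsets = matrix(0, 1, 2), weights = 1),
      g4 = list(offsets = rbind(c(0, 0), c(1, 1), c(1, -1),
                                c(-1, 1), c(-1, -1)),
                weights = c(1 / 2, rep(1 / 8, 4))),
      g8 = list(offsets = rbind(c(0, 0), c(1, 1), c(1, -1),
                                c(-1, 1), c(-1, -1),
                                c(s2, 0), c(-s2, 0), c(0, s2), c(0, -s2)),
                weights = c(1 / 2, rep(1 / 16, 8))))
    name <- scheme
  } else {
    def <- scheme
    name <- "custom"
  }
  offsets <- as.matrix(def$offsets)
  weights <- as.numeric(def$weights)
  if (ncol(offsets) != 2 || nrow(offsets) != length(weights))
    stop("offsets must be m x 2 with one weight per offset")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("weights must be non-negative and sum to one")
  nonzero <- rowSums(offsets^2) > 0
  if (any(nonzero)) {
    o <- offsets[nonzero, , drop = FALSE]
    w <- weights[nonzero]
    for (k in seq_len(nrow(o))) {
      match_k <- which(abs(o[, 1] + o[k, 1]) < 1e-12 &
                         abs(o[, 2] + o[k, 2]) < 1e-12)
      if (length(match_k) == 0 || abs(w[match_k[1]] - w[k]) > 1e-12)
        stop("every non-origin offset needs its negation at equal weight")
    }
  }
  structure(list(name = name, offsets = offsets, weights = weights),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme> '%s', %d point(s)\n",
              x$name, length(x$weights)))
  invisible(x)
}

#' Langevin drift of the habitat model
#'
#' `b(x) = (Gamma / 2) * sum_i beta_i grad c_i(x)`: the deterministic
#' component of the Langevin diffusion whose stationary density is
#' proportional to `exp(eta)`.
#'
#' @param model A [habitat_model()].
#' @param Gamma Diffusivity `Gamma > 0` (squared spatial units per time).
#' @param points A length-2 vector or `n x 2` matrix.
#' @param clamp See [field_value()].
#' @return `n x 2` matrix of drift vectors.
#' @export
drift <- function(model, Gamma, points, clamp = FALSE) {
  stopifnot(Gamma > 0)
  points <- as_points(points)
  g <- matrix(0, nrow(points), 2)
  for (i in seq_along(model$covariates))
    g <- g + model$beta[i] * cov_gradient(model$covariates[[i]], points,
                                          clamp = clamp)
  (Gamma / 2) * g
}

#' Locally averaged (bias-corrected) drift
#'
#' Averages the covariate gradients over the scheme's displaced points
#' `x + zeta * dt * offset` before forming the drift. With the `"raw"`
#' scheme, or with `zeta = 0`, this reduces to [drift()]. Averaging changes
#' nothing for covariates whose gradient is linear in the coordinates
#' (polynomial localization terms, planar rasters), because the scheme is
#' symmetric; it matters only where the gradient varies at the scale of one
#' observation step.
#'
#' @inheritParams drift
#' @param zeta Scale parameter (spatial units per time), `>= 0`; see
#'   [estimate_zeta()].
#' @param dt Duration of the step the drift applies to.
#' @param scheme A [gradient_scheme()] or its name.
#' @return `n x 2` matrix of drift vectors.
#' @export
smoothed_drift <- function(model, Gamma, points, zeta, dt,
                           scheme = "g4", clamp = FALSE) {
  stopifnot(Gamma > 0, zeta >= 0, dt > 0)
  scheme <- gradient_scheme(scheme)
  points <- as_points(points)
  g <- matrix(0, nrow(points), 2)
  for (k in seq_along(scheme$weights)) {
    pk <- points + matrix(zeta * dt * scheme$offsets[k, ],
                          nrow(points), 2, byrow = TRUE)
    gk <- matrix(0, nrow(points), 2)
    for (i in seq_along(model$covariates))
      gk <- gk + model$beta[i] * cov_gradient(model$covariates[[i]], pk,
                                              clamp = clamp)
    g <- g + scheme$weights[k] * gk
  }
  (Gamma / 2) * g
}

#' Empirical scale for gradient averaging
#'
#' `zeta = (1 / (sqrt(2) * n_step)) * sum_j ||x_{j+1} - x_j|| / dt_j`, so
#' that the displaced points of the diagonal schemes, at distance
#' `zeta * sqrt(2) * dt`, lie on average at the distance actually moved per
#' step. Computed once from the data and held fixed during fitting.
#'
#' @param tracks A [trajectory()] or list of trajectories.
#' @return A single non-negative number.
#' @export
estimate_zeta <- function(tracks) {
  tracks <- as_tracks(tracks)
  tot <- 0
  nstep <- 0L
  for (tr in tracks) {
    n <- length(tr$times)
    if (n < 2) next
    d <- sqrt(rowSums((tr$locations[-1, , drop = FALSE] -
                         tr$locations[-n, , drop = FALSE])^2))
    tot <- tot + sum(d / diff(tr$times))
    nstep <- nstep + (n - 1L)
  }
  if (nstep == 0) stop("no movement steps available to estimate zeta")
  tot / (sqrt(2) * nstep)
}

#' Simulate one Langevin trajectory
#'
#' Euler-Maruyama simulation of `dx = b(x) dt + sqrt(Gamma) dW` using the
#' raw drift [drift()] (local averaging is an inference device, not part of
#' the model). The fine step should be small relative to the interval at
#' which the track will be observed. Points that leave the raster domain
#' have their drift evaluated at the nearest in-grid point (with a warning).
#'
#' @inheritParams drift
#' @param x0 Starting location, length-2.
#' @param fine_step Simulation time step, `> 0`.
#' @param duration Total simulated time; the track has
#'   `round(duration / fine_step) + 1` fixes.
#' @param seed Integer seed for reproducibility.
#' @param id Identifier for the resulting trajectory.
#' @return A [trajectory()] at the fine resolution; see [thin_track()].
#' @export
simulate_langevin <- function(model, Gamma, x0, fine_step, duration,
                              seed = NULL, id = "1") {
  stopifnot(fine_step > 0, duration > 0)
  states <- simulate_colony_paths(model, Gamma,
                                  matrix(x0, 1, 2), fine_step,
                                  n_steps = round(duration / fine_step),
                                  thin_every = 1L, seed = seed)
  trajectory(id, times = (seq_len(dim(states)[3]) - 1) * fine_step,
             locations = t(states[1, , ]))
}

# Vectorized Euler-Maruyama over many independent individuals.
# Returns an array [individual, coordinate, kept time] with states kept
# every `thin_every` fine steps (including the start and the final state).
simulate_colony_paths <- function(model, Gamma, starts, fine_step, n_steps,
                                  thin_every = 1L, seed = NULL) {
  starts <- as_points(starts)
  n <- nrow(starts)
  stopifnot(n_steps >= 1, thin_every >= 1, n_steps %% thin_every == 0)
  n_kept <- n_steps %/% thin_every + 1L
  with_seed(seed, {
    X <- starts
    out <- array(NA_real_, c(n, 2, n_kept))
    out[, , 1] <- X
    sd_step <- sqrt(Gamma * fine_step)
    for (s in seq_len(n_steps)) {
      b <- drift(model, Gamma, X, clamp = TRUE)
      X <- X + b * fine_step +
        matrix(stats::rnorm(2 * n, 0, sd_step), n, 2)
      if (!all(is.finite(X)))
        stop(sprintf("non-finite state at simulation step %d", s))
      if (s %% thin_every == 0) out[, , s %/% thin_every + 1L] <- X
    }
    out
  })
}

#' Simulate a colony of independently moving individuals
#'
#' Runs [simulate_langevin()] dynamics for `n` individuals at once and
#' returns their tracks already thinned to the observation interval.
#'
#' @inheritParams drift
#' @param starts `n x 2` matrix of starting locations.
#' @param fine_step Simulation time step.
#' @param duration Total simulated time.
#' @param obs_interval Observation (thinning) interval; must be an integral
#'   multiple of `fine_step`.
#' @param seed Integer seed.
#' @return List of [trajectory()] objects (ids `"1"`, `"2"`, ...).
#' @export
simulate_colony <- function(model, Gamma, starts, fine_step, duration,
                            obs_interval = fine_step, seed = NULL) {
  starts <- as_points(starts)
  thin_every <- obs_interval / fine_step
  if (abs(thin_every - round(thin_every)) > 1e-8)
    stop("obs_interval must be an integral multiple of fine_step")
  thin_every <- as.integer(round(thin_every))
  n_steps <- round(duration / fine_step)
  states <- simulate_colony_paths(model, Gamma, starts, fine_step, n_steps,
                                  thin_every = thin_every, seed = seed)
  times <- (seq_len(dim(states)[3]) - 1) * obs_interval
  lapply(seq_len(nrow(starts)), function(i)
    trajectory(as.character(i), times, t(states[i, , ])))
}

#' Thin a trajectory to a coarser, regular interval
#'
#' Retains every `interval / native`-th fix starting at the first one. The
#' requested interval must be an integral multiple of the track's (regular)
#' native spacing.
#'
#' @param track A [trajectory()] with regular spacing.
#' @param interval Target interval between retained fixes.
#' @return A [trajectory()].
#' @export
thin_track <- function(track, interval) {
  stopifnot(inherits(track, "trajectory"))
  dts <- diff(track$times)
  if (length(dts) == 0) return(track)
  native <- dts[1]
  if (any(abs(dts - native) > 1e-9 * max(native, 1)))
    stop("thin_track requires a regularly spaced track")
  k <- interval / native
  if (abs(k - round(k)) > 1e-8)
    stop(sprintf(
      "interval %g is not an integral multiple of the native spacing %g",
      interval, native))
  k <- as.integer(round(k))
  idx <- seq(1, length(track$times), by = k)
  trajectory(track$id, track$times[idx],
             track$locations[idx, , drop = FALSE])
}

# Pre-computed sufficient statistics for the movement likelihood: per-step
# displacements, durations, and scheme-averaged covariate gradients at the
# step starts. beta and gamma enter the likelihood only through these, so
# they are computed once per (data, zeta, scheme) and reused across
# optimizer iterations.
movement_suffstats <- function(tracks, covariates, zeta, scheme,
                               clamp = FALSE) {
  tracks <- as_tracks(tracks)
  scheme <- gradient_scheme(scheme)
  k <- length(covariates)
  x0 <- list(); dx <- list(); dt <- list()
  for (tr in tracks) {
    n <- length(tr$times)
    if (n < 2) {
      warning(sprintf(
        "track '%s' has a single fix and contributes nothing", tr$id),
        call. = FALSE)
      next
    }
    x0[[length(x0) + 1]] <- tr$locations[-n, , drop = FALSE]
    dx[[length(dx) + 1]] <- tr$locations[-1, , drop = FALSE] -
      tr$locations[-n, , drop = FALSE]
    dt[[length(dt) + 1]] <- diff(tr$times)
  }
  if (length(x0) == 0) stop("no usable steps in the telemetry data")
  x0 <- do.call(rbind, x0)
  dx <- do.call(rbind, dx)
  dt <- unlist(dt)
  n <- nrow(x0)
  Gx <- matrix(0, n, k)
  Gy <- matrix(0, n, k)
  for (g in seq_along(scheme$weights)) {
    pg <- x0 + (zeta * dt) * matrix(scheme$offsets[g, ], n, 2, byrow = TRUE)
    for (i in seq_len(k)) {
      gr <- cov_gradient(covariates[[i]], pg, clamp = clamp)
      Gx[, i] <- Gx[, i] + scheme$weights[g] * gr[, 1]
      Gy[, i] <- Gy[, i] + scheme$weights[g] * gr[, 2]
    }
  }
  list(x0 = x0, dx = dx, dt = dt, Gx = Gx, Gy = Gy, n = n)
}

# Movement log-likelihood and its gradient in (beta, gamma) from
# pre-computed sufficient statistics.
movement_loglik_stats <- function(ss, beta, gamma) {
  G <- exp(gamma)
  bx <- (G / 2) * drop(ss$Gx %*% beta)
  by <- (G / 2) * drop(ss$Gy %*% beta)
  s2 <- G * ss$dt
  rx <- ss$dx[, 1] - bx * ss$dt
  ry <- ss$dx[, 2] - by * ss$dt
  sum(-log(2 * pi * s2) - (rx^2 + ry^2) / (2 * s2))
}

movement_grad_stats <- function(ss, beta, gamma) {
  G <- exp(gamma)
  bx <- (G / 2) * drop(ss$Gx %*% beta)
  by <- (G / 2) * drop(ss$Gy %*% beta)
  s2 <- G * ss$dt
  rx <- ss$dx[, 1] - bx * ss$dt
  ry <- ss$dx[, 2] - by * ss$dt
  # d/d beta_i: (Gamma dt / (2 s2)) (rx Gx_i + ry Gy_i) = (rx Gx + ry Gy)/2
  gb <- drop(crossprod(ss$Gx, rx) + crossprod(ss$Gy, ry)) / 2
  gg <- sum(-1 + (rx^2 + ry^2) / (2 * s2) +
              (rx * bx + ry * by) * ss$dt / s2)
  c(gb, gamma = gg)
}

#' Movement log-likelihood of the Langevin step-selection model
#'
#' Sum over all steps of all tracks of the bivariate normal log density with
#' mean `x_j + b~(x_j) * dt_j` and covariance `exp(gamma) * dt_j * I`, where
#' `b~` is the locally averaged drift of the chosen scheme (the raw Euler
#' drift when `zeta = 0` or `scheme = "raw"`). Each track is conditioned on
#' its first fix; single-fix tracks contribute zero with a warning.
#'
#' @param tracks A [trajectory()] or list of trajectories with fixes inside
#'   the covariate domains.
#' @param model A [habitat_model()].
#' @param gamma Log diffusivity, `gamma = log(Gamma)`.
#' @param zeta Averaging scale; defaults to [estimate_zeta()] of the data.
#' @param scheme A [gradient_scheme()] or its name.
#' @return The log-likelihood (a single number).
#' @export
movement_loglik <- function(tracks, model, gamma,
                            zeta = estimate_zeta(tracks), scheme = "g4") {
  ss <- movement_suffstats(tracks, model$covariates, zeta, scheme)
  movement_loglik_stats(ss, model$beta, gamma)
}
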