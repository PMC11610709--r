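# Snapshot spatial surveys: region geometry, observation model
# (inhomogeneous Poisson process) and its log-likelihood.

#' Survey region: a union of axis-aligned rectangles
#'
#' @param rectangles A data frame (or matrix) with columns
#'   `xmin, xmax, ymin, ymax`, one row per rectangle. Rectangles must be
#'   non-degenerate and pairwise disjoint (shared edges are allowed); their
#'   union is the surveyed region A. An empty data frame gives an empty
#'   region.
#' @return An object of class `survey_region`.
#' @export
survey_region <- function(rectangles) {
  if (is.matrix(rectangles)) {
    rectangles <- as.data.frame(rectangles)
    if (ncol(rectangles) == 4)
      names(rectangles) <- c("xmin", "xmax", "ymin", "ymax")
  }
  need <- c("xmin", "xmax", "ymin", "ymax")
  if (!all(need %in% names(rectangles)))
    stop("rectangles needs columns xmin, xmax, ymin, ymax")
  rectangles <- rectangles[need]
  if (nrow(rectangles) > 0) {
    if (any(rectangles$xmax <= rectangles$xmin |
              rectangles$ymax <= rectangles$ymin))
      stop("each rectangle must have xmax > xmin and ymax > ymin")
    if (nrow(rectangles) > 1) {
      for (a in seq_len(nrow(rectangles) - 1))
        for (b in (a + 1):nrow(rectangles)) {
          ox <- min(rectangles$xmax[a], rectangles$xmax[b]) -
            max(rectangles$xmin[a], rectangles$xmin[b])
          oy <- min(rectangles$ymax[a], rectangles$ymax[b]) -
            max(rectangles$ymin[a], rectangles$ymin[b])
          if (ox > 0 && oy > 0)
            stop(sprintf("rectangles %d and %d overlap", a, b))
        }
    }
  }
  structure(list(rectangles = rectangles), class = "survey_region")
}

#' Centred square survey region
#'
#' Convenience constructor for the square of the simulation experiments.
#'
#' @param side Side length; `0` gives an empty region.
#' @param centre Centre coordinates.
#' @return A [survey_region()].
#' @export
square_region <- function(side, centre = c(0, 0)) {
  if (side < 0) stop("side must be non-negative")
  if (side == 0)
    return(survey_region(data.frame(xmin = numeric(), xmax = numeric(),
                                    ymin = numeric(), ymax = numeric())))
  survey_region(data.frame(xmin = centre[1] - side / 2,
                           xmax = centre[1] + side / 2,
                           ymin = centre[2] - side / 2,
                           ymax = centre[2] + side / 2))
}

#' @export
print.survey_region <- function(x, ...) {
  cat(sprintf("<survey_region> %d rectangle(s), area %g\n",
              nrow(x$rectangles), region_area(x)))
  invisible(x)
}

#' Total area of a survey region
#' @param region A [survey_region()].
#' @return The area of the union of its rectangles.
#' @export
region_area <- function(region) {
  r <- region$rectangles
  if (nrow(r) == 0) return(0)
  sum((r$xmax - r$xmin) * (r$ymax - r$ymin))
}

region_contains <- function(region, points) {
  points <- as_points(points)
  inside <- rep(FALSE, nrow(points))
  r <- region$rectangles
  for (k in seq_len(nrow(r)))
    inside <- inside | (points[, 1] >= r$xmin[k] & points[, 1] <= r$xmax[k] &
                          points[, 2] >= r$ymin[k] & points[, 2] <= r$ymax[k])
  inside
}

#' Snapshot survey observation
#'
#' An instantaneous census: every individual inside the region at the
#' survey time is detected (boundaries are closed), none outside.
#'
#' @param locations `n x 2` matrix of individual locations at the survey
#'   time (may have zero rows).
#' @param region A [survey_region()].
#' @return An object of class `survey_snapshot` with the region and the
#'   detected `points` (in input order).
#' @export
snapshot_survey <- function(locations, region) {
  stopifnot(inherits(region, "survey_region"))
  if (is.null(locations) || (is.matrix(locations) && nrow(locations) == 0)) {
    pts <- matrix(numeric(0), 0, 2)
  } else {
    locations <- as_points(locations)
    pts <- locations[region_contains(region, locations), , drop = FALSE]
  }
  structure(list(region = region, points = pts), class = "survey_snapshot")
}

#' Construct a snapshot from already-observed points
#'
#' @param points `m x 2` matrix of observed locations, all inside `region`.
#' @param region A [survey_region()].
#' @return A `survey_snapshot`.
#' @export
survey_snapshot <- function(points, region) {
  stopifnot(inherits(region, "survey_region"))
  if (is.null(points)) points <- matrix(numeric(0), 0, 2)
  points <- if (length(points) == 0) matrix(numeric(0), 0, 2)
            else as_points(points)
  if (nrow(points) > 0 && !all(region_contains(region, points)))
    stop("all survey points must lie inside the survey region")
  structure(list(region = region, points = points),
            class = "survey_snapshot")
}

#' @export
print.survey_snapshot <- function(x, ...) {
  cat(sprintf("<survey_snapshot> m = %d points over area %g\n",
              nrow(x$points), region_area(x$region)))
  invisible(x)
}

#' Simulate a snapshot survey of a colony directly from the utilization
#' distribution
#'
#' Draws `n_individuals` independent locations from the discrete
#' utilization distribution on `grid` (cell draw plus uniform jitter within
#' the cell) and applies [snapshot_survey()]. Because the utilization
#' distribution is the stationary law of the movement model, this is
#' equivalent to (and much faster than) simulating long movement paths and
#' censusing the final positions.
#'
#' @param model A [habitat_model()].
#' @param n_individuals Colony size (number of independent individuals).
#' @param grid An [eval_grid()] covering the population's range.
#' @param region A [survey_region()].
#' @param seed Integer seed.
#' @return A `survey_snapshot`.
#' @export
sample_colony_snapshot <- function(model, n_individuals, grid, region,
                                   seed = NULL) {
  stopifnot(n_individuals >= 0)
  locs <- sample_utilization(model, n_individuals, grid, seed = seed)
  snapshot_survey(locs, region)
}

#' Sample locations from the utilization distribution
#'
#' @inheritParams sample_colony_snapshot
#' @param n Number of locations to draw.
#' @return `n x 2` matrix.
#' @export
sample_utilization <- function(model, n, grid, seed = NULL) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  uw <- utilization_weights(model, grid)
  with_seed(seed, {
    cells <- sample.int(length(uw$weights), n, replace = TRUE,
                        prob = uw$weights)
    jitter <- cbind(stats::runif(n, -grid$hx / 2, grid$hx / 2),
                    stats::runif(n, -grid$hy / 2, grid$hy / 2))
    uw$points[cells, , drop = FALSE] + jitter
  })
}

# Pre-computed survey quadrature: for each grid cell intersected with the
# region, the exact overlap area and the covariate values at the overlap
# centroid; plus covariate values at the observed points. The survey
# log-likelihood is then a cheap function of (alpha, beta).
survey_suffstats <- function(snapshot, covariates, grid) {
  stopifnot(inherits(snapshot, "survey_snapshot"),
            inherits(grid, "eval_grid"))
  r <- snapshot$region$rectangles
  cen <- list(); area <- list()
  xl <- grid$xc - grid$hx / 2; xr <- grid$xc + grid$hx / 2
  yl <- grid$yc - grid$hy / 2; yr <- grid$yc + grid$hy / 2
  for (k in seq_len(nrow(r))) {
    wx <- pmin(xr, r$xmax[k]) - pmax(xl, r$xmin[k])
    wy <- pmin(yr, r$ymax[k]) - pmax(yl, r$ymin[k])
    jx <- which(wx > 0); jy <- which(wy > 0)
    if (length(jx) == 0 || length(jy) == 0) next
    cx <- (pmin(xr, r$xmax[k]) + pmax(xl, r$xmin[k]))[jx] / 2
    cy <- (pmin(yr, r$ymax[k]) + pmax(yl, r$ymin[k]))[jy] / 2
    cen[[length(cen) + 1]] <- cbind(rep(cx, times = length(jy)),
                                    rep(cy, each = length(jx)))
    area[[length(area) + 1]] <- as.vector(outer(wx[jx], wy[jy]))
  }
  if (length(cen) == 0) {
    Cq <- matrix(numeric(0), 0, length(covariates))
    area <- numeric(0)
  } else {
    cen <- do.call(rbind, cen)
    area <- unlist(area)
    Cq <- vapply(covariates, cov_value, numeric(nrow(cen)), points = cen)
    Cq <- matrix(Cq, nrow = nrow(cen))
  }
  m <- nrow(snapshot$points)
  Cp <- if (m > 0) {
    v <- vapply(covariates, cov_value, numeric(m), points = snapshot$points)
    matrix(v, nrow = m)
  } else matrix(numeric(0), 0, length(covariates))
  list(area = area, Cq = Cq, Cp = Cp, m = m)
}

survey_integral_stats <- function(ss, beta) {
  if (length(ss$area) == 0) return(0)
  sum(ss$area * exp(drop(ss$Cq %*% beta)))
}

survey_loglik_stats <- function(ss, alpha, beta) {
  S <- survey_integral_stats(ss, beta)
  eta_pts <- if (ss$m > 0) sum(ss$Cp %*% beta) else 0
  -exp(alpha) * S + ss$m * alpha + eta_pts
}

survey_grad_stats <- function(ss, alpha, beta) {
  if (length(ss$area) == 0) {
    S <- 0
    dS <- numeric(ncol(ss$Cq))
  } else {
    w <- ss$area * exp(drop(ss$Cq %*% beta))
    S <- sum(w)
    dS <- drop(crossprod(ss$Cq, w))
  }
  ga <- -exp(alpha) * S + ss$m
  gb <- -exp(alpha) * dS +
    if (ss$m > 0) colSums(ss$Cp) else numeric(length(dS))
  c(alpha = ga, gb)
}

#' Integral of exp(eta) over the survey region
#'
#' Midpoint quadrature on the evaluation grid, with cells partially inside
#' the region contributing their exact overlap area times `exp(eta)` at the
#' overlap centroid. This is the normalizing integral of the inhomogeneous
#' Poisson survey likelihood.
#'
#' @param model A [habitat_model()].
#' @param region A [survey_region()] inside the covariate domains.
#' @param grid An [eval_grid()] setting the quadrature resolution.
#' @return The approximate value of `integral_A exp(eta(y)) dy`.
#' @export
survey_area_integral <- function(model, region, grid) {
  snap <- survey_snapshot(NULL, region)
  ss <- survey_suffstats(snap, model$covariates, grid)
  survey_integral_stats(ss, model$beta)
}

#' Survey log-likelihood (inhomogeneous Poisson process)
#'
#' `L_s(alpha, beta) = -exp(alpha) * integral_A exp(eta) + m * alpha +
#' sum_i eta(y_i)` for `m` observed points `y_i`. The intensity of
#' detections is `exp(alpha + eta(x))`; `alpha` absorbs population size,
#' detectability and survey effort.
#'
#' @param snapshot A [survey_snapshot()].
#' @param model A [habitat_model()].
#' @param alpha Log-intensity intercept.
#' @param grid An [eval_grid()] for the area integral.
#' @return The log-likelihood (a single number).
#' @export
survey_loglik <- function(snapshot, model, alpha, grid) {
  ss <- survey_suffstats(snapshot, model$covariates, grid)
  survey_loglik_stats(ss, alpha, model$beta)
}
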