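# Simulation experiments: replicated design grids over telemetry and
# survey effort, the drift-smoothing bias study, precision-surface
# smoothing, and effort-allocation curves.

#' A study design: how much telemetry and how much survey
#'
#' @param n_tracks Number of telemetry tracks (0 for survey-only).
#' @param survey_side Side length of the centred square survey (0 for
#'   telemetry-only).
#' @return A `design_point` list. Both zero is invalid.
#' @export
design_point <- function(n_tracks, survey_side) {
  stopifnot(n_tracks >= 0, survey_side >= 0)
  if (n_tracks == 0 && survey_side == 0)
    stop("a design needs at least one data source")
  structure(list(n_tracks = as.integer(n_tracks),
                 survey_side = survey_side), class = "design_point")
}

#' Factorial design grid of the simulation study
#'
#' All combinations of track numbers and survey sides, including the
#' telemetry-only (`side = 0`) and survey-only (`n = 0`) margins, minus
#' the empty design.
#'
#' @param n_tracks Vector of track counts.
#' @param survey_sides Vector of square side lengths.
#' @return Data frame with columns `n_tracks`, `survey_side`.
#' @export
design_grid <- function(n_tracks = seq(0, 50, by = 5),
                        survey_sides = seq(0, 1, by = 0.1)) {
  g <- expand.grid(n_tracks = as.integer(n_tracks),
                   survey_side = survey_sides)
  g <- g[!(g$n_tracks == 0 & g$survey_side == 0), ]
  rownames(g) <- NULL
  g
}

# One replicate's raw material: thinned telemetry tracks from the
# informationless starts, and the survey colony's final locations.
simulate_replicate <- function(model, cfg, seed,
                               survey_mode = c("movement", "direct")) {
  survey_mode <- match.arg(survey_mode)
  mv <- cfg$movement
  l <- cfg$landscape
  seeds <- seed_stream(seed, c("tel_start", "tel_path", "surv_start",
                               "surv_path"))
  tel_starts <- with_seed(seeds[["tel_start"]],
                          matrix(stats::rnorm(2 * mv$n_individuals, 0,
                                              mv$start_sd),
                                 mv$n_individuals, 2))
  tracks <- simulate_colony(model, mv$Gamma, tel_starts, mv$fine_step,
                            mv$duration, mv$obs_interval,
                            seed = seeds[["tel_path"]])
  grid <- eval_grid(l$xmin, l$xmax, l$ymin, l$ymax, l$cell_size)
  n_surv <- cfg$survey$n_individuals
  surv_starts <- sample_utilization(model, n_surv, grid,
                                    seed = seeds[["surv_start"]])
  final <- if (survey_mode == "movement" && n_surv > 0) {
    paths <- simulate_colony_paths(model, mv$Gamma, surv_starts,
                                   mv$fine_step,
                                   n_steps = round(mv$duration /
                                                     mv$fine_step),
                                   thin_every = round(mv$duration /
                                                        mv$fine_step),
                                   seed = seeds[["surv_path"]])
    cbind(paths[, 1, 2], paths[, 2, 2], deparse.level = 0)
  } else surv_starts
  list(tracks = tracks, survey_locations = final, grid = grid)
}

# Fit every design of a grid on one replicate's data, re-using sufficient
# statistics across designs. Returns one row per design.
analyze_designs <- function(rep_data, covariates, designs, scheme = "g4",
                            bound = 50, control = list()) {
  scheme <- gradient_scheme(scheme)
  ns <- sort(unique(designs$n_tracks[designs$n_tracks > 0]))
  sides <- sort(unique(designs$survey_side[designs$survey_side > 0]))
  mss_by_n <- list()
  for (n in ns) {
    sub <- rep_data$tracks[seq_len(n)]
    zeta <- estimate_zeta(sub)
    mss_by_n[[as.character(n)]] <-
      list(ss = movement_suffstats(sub, covariates, zeta, scheme),
           zeta = zeta)
  }
  sss_by_side <- list()
  for (s in sides) {
    snap <- snapshot_survey(rep_data$survey_locations, square_region(s))
    sss_by_side[[as.character(s)]] <-
      list(ss = survey_suffstats(snap, covariates, rep_data$grid),
           points = snap$points)
  }
  out <- vector("list", nrow(designs))
  for (d in seq_len(nrow(designs))) {
    n <- designs$n_tracks[d]
    s <- designs$survey_side[d]
    mss <- if (n > 0) mss_by_n[[as.character(n)]] else NULL
    sss <- if (s > 0) sss_by_side[[as.character(s)]] else NULL
    fit <- try(fit_core(if (n > 0) mss$ss, if (s > 0) sss$ss,
                        if (s > 0) sss$points, covariates,
                        scheme_name = scheme$name,
                        zeta = if (n > 0) mss$zeta else NA_real_,
                        bound = bound, control = control),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      out[[d]] <- data.frame(n_tracks = n, survey_side = s,
                             beta1_hat = NA_real_, se_beta1 = NA_real_,
                             precision = NA_real_, loglik = NA_real_,
                             m_points = if (s > 0) sss$ss$m else 0L,
                             converged = FALSE)
      next
    }
    se1 <- if (!is.null(fit$se) && "beta1" %in% names(fit$se))
      unname(fit$se["beta1"]) else NA_real_
    out[[d]] <- data.frame(n_tracks = n, survey_side = s,
                           beta1_hat = fit$beta[1], se_beta1 = se1,
                           precision = if (is.na(se1)) NA_real_
                                       else 1 / se1^2,
                           loglik = fit$loglik,
                           m_points = fit$m_points,
                           converged = fit$converged)
  }
  do.call(rbind, out)
}

#' Run one simulation replicate of one design
#'
#' Simulates the colony on the given resource map under the configured
#' movement model (telemetry starts near the attraction centre, survey
#' starts from the utilization distribution, snapshot of final locations),
#' fits the design's data, and reports the selection-coefficient estimate
#' and its precision.
#'
#' @param field Resource map, a [covariate_field()].
#' @param design A [design_point()].
#' @param seed Integer seed for this replicate.
#' @param config Experiment configuration, see [default_config()];
#'   `config$landscape$range` should match the map's generation.
#' @param scheme Gradient-averaging scheme for fitting.
#' @return One-row data frame (estimate, precision, convergence).
#' @export
run_replicate <- function(field, design, seed, config = default_config(),
                          scheme = "g4") {
  cfg <- validate_config(config)
  stopifnot(inherits(design, "design_point"))
  model <- config_model(cfg, field = field)
  rep_data <- simulate_replicate(model, cfg, seed)
  analyze_designs(rep_data, model$covariates,
                  data.frame(n_tracks = design$n_tracks,
                             survey_side = design$survey_side),
                  scheme = scheme,
                  bound = cfg$inference$bound)
}

#' Run the replicated design-grid experiment
#'
#' For each environment (spatial range of the resource field), simulates
#' `n_maps` resource maps and `replicates_per_map` colony replicates per
#' map, and fits every design of the grid on each replicate, re-using the
#' simulated colony across designs (as the experimental design intends:
#' designs differ only in which data are analyzed).
#'
#' @param environments Spatial-range values of the resource field.
#' @param n_maps Maps per environment.
#' @param replicates_per_map Colony replicates per map.
#' @param designs Data frame from [design_grid()].
#' @param config Base configuration; its `landscape$range` is overridden
#'   per environment.
#' @param scheme Fitting scheme.
#' @param master_seed One seed reproducing the whole experiment.
#' @param verbose Print progress lines.
#' @return Tidy data frame, one row per (environment, map, replicate,
#'   design).
#' @export
run_experiment <- function(environments = c(0.1, 0.2), n_maps = 5,
                           replicates_per_map = 5,
                           designs = design_grid(),
                           config = default_config(), scheme = "g4",
                           master_seed = 1, verbose = FALSE) {
  cfg <- validate_config(config)
  out <- list()
  for (env in environments) {
    cfg$landscape$range <- env
    for (m in seq_len(n_maps)) {
      map_seed <- seed_stream(master_seed,
                              sprintf("map:%d:env:%g", m, env))
      g <- config_landscape_grid(cfg)
      field <- simulate_grf(env, cfg$landscape$variance,
                            cfg$landscape$xmin, cfg$landscape$ymin,
                            cfg$landscape$cell_size, g$n_x, g$n_y,
                            seed = map_seed)
      model <- config_model(cfg, field = field)
      for (r in seq_len(replicates_per_map)) {
        rep_seed <- seed_stream(master_seed,
                                sprintf("rep:%d:map:%d:env:%g", r, m, env))
        rep_data <- simulate_replicate(model, cfg, rep_seed)
        res <- analyze_designs(rep_data, model$covariates, designs,
                               scheme = scheme,
                               bound = cfg$inference$bound)
        res <- cbind(data.frame(environment = env, map = m,
                                replicate = r), res)
        out[[length(out) + 1]] <- res
        if (verbose)
          message(sprintf("env %g map %d replicate %d: %d designs fitted",
                          env, m, r, nrow(res)))
      }
    }
  }
  do.call(rbind, out)
}

#' Drift-smoothing bias study
#'
#' Telemetry-only experiment comparing the raw Euler drift with the
#' four-point and eight-point locally averaged drifts on identical
#' datasets: per map, `datasets_per_map` colonies of `n_tracks` tracks are
#' simulated and each dataset is fitted once per scheme. Reports the mean
#' bias of the selection-coefficient estimate per scheme and the Pearson
#' correlations between per-dataset estimates across scheme pairs.
#'
#' @param n_maps Resource maps (at `config$landscape$range`).
#' @param datasets_per_map Telemetry datasets per map.
#' @param n_tracks Tracks per dataset.
#' @param schemes Character vector of scheme names to compare.
#' @param config Base configuration.
#' @param master_seed Seed reproducing the study.
#' @param verbose Print progress lines.
#' @return List with `estimates` (dataset x scheme matrix), `bias` (named
#'   mean bias per scheme), `correlations` (scheme-pair matrix) and
#'   `true_beta1`.
#' @export
bias_study <- function(n_maps = 5, datasets_per_map = 5, n_tracks = 50,
                       schemes = c("raw", "g4", "g8"),
                       config = default_config(), master_seed = 1,
                       verbose = FALSE) {
  cfg <- validate_config(config)
  cfg$survey$n_individuals <- 0
  cfg$movement$n_individuals <- n_tracks
  est <- matrix(NA_real_, n_maps * datasets_per_map, length(schemes),
                dimnames = list(NULL, schemes))
  i <- 0
  for (m in seq_len(n_maps)) {
    map_seed <- seed_stream(master_seed, sprintf("bias-map:%d", m))
    g <- config_landscape_grid(cfg)
    field <- simulate_grf(cfg$landscape$range, cfg$landscape$variance,
                          cfg$landscape$xmin, cfg$landscape$ymin,
                          cfg$landscape$cell_size, g$n_x, g$n_y,
                          seed = map_seed)
    model <- config_model(cfg, field = field)
    for (d in seq_len(datasets_per_map)) {
      i <- i + 1
      rep_seed <- seed_stream(master_seed,
                              sprintf("bias-rep:%d:map:%d", d, m))
      rep_data <- simulate_replicate(model, cfg, rep_seed,
                                     survey_mode = "direct")
      tracks <- rep_data$tracks[seq_len(n_tracks)]
      zeta <- estimate_zeta(tracks)
      for (s in schemes) {
        mss <- movement_suffstats(tracks, model$covariates, zeta, s)
        fit <- try(fit_core(mss, NULL, NULL, model$covariates,
                            scheme_name = s, zeta = zeta,
                            bound = cfg$inference$bound), silent = TRUE)
        if (!inherits(fit, "try-error")) est[i, s] <- fit$beta[1]
      }
      if (verbose)
        message(sprintf("map %d dataset %d: %s", m, d,
                        paste(sprintf("%s=%.3f", schemes, est[i, ]),
                              collapse = " ")))
    }
  }
  list(estimates = est,
       bias = colMeans(est, na.rm = TRUE) - cfg$selection$beta1,
       correlations = stats::cor(est, use = "pairwise.complete.obs"),
       true_beta1 = cfg$selection$beta1)
}

#' Smooth precision surface over the design grid
#'
#' Summarizes mean precision as an additive model: a linear term in the
#' number of tracks plus a monotone smooth in survey side, both
#' constrained through the origin so that precision is exactly zero with
#' no data. The smooth uses an integrated-B-spline (I-spline) basis with
#' knots at the observed survey sides and non-negative coefficients
#' (monotone non-decreasing by construction); coefficients are estimated
#' by box-constrained least squares on the per-design mean precisions.
#'
#' @param results Data frame from [run_experiment()] (or compatible), with
#'   columns `n_tracks`, `survey_side`, `precision`; rows with undefined
#'   precision are dropped.
#' @param environment Optional value to filter `results$environment` by.
#' @return An object of class `precision_surface` with `linear_coeff`
#'   (precision per track) and the fitted smooth; use [predict()] or
#'   [effort_curve()] on it.
#' @export
fit_precision_surface <- function(results, environment = NULL) {
  if (!is.null(environment) && "environment" %in% names(results))
    results <- results[results$environment == environment, ]
  results <- results[is.finite(results$precision), ]
  if (nrow(results) == 0) stop("no usable precision values")
  agg <- stats::aggregate(precision ~ n_tracks + survey_side,
                          data = results, FUN = mean)
  if (!any(agg$survey_side == 0) || !any(agg$n_tracks == 0))
    stop("the design grid must include telemetry-only (side 0) and ",
         "survey-only (0 tracks) margins")
  side_max <- max(agg$survey_side)
  knots <- sort(unique(agg$survey_side[agg$survey_side > 0 &
                                         agg$survey_side < side_max]))
  basis <- ispline_basis_fn(knots, side_max)
  B <- basis(agg$survey_side)
  X <- cbind(n = agg$n_tracks, B)
  y <- agg$precision
  # box-constrained least squares, all coefficients >= 0
  obj <- function(b) sum((y - drop(X %*% b))^2)
  grb <- function(b) -2 * drop(crossprod(X, y - drop(X %*% b)))
  b0 <- rep(0.1, ncol(X))
  opt <- stats::optim(b0, obj, grb, method = "L-BFGS-B",
                      lower = rep(0, ncol(X)),
                      control = list(maxit = 1000))
  coefs <- opt$par
  structure(list(linear_coeff = coefs[1], spline_coef = coefs[-1],
                 basis = basis, knots = knots,
                 n_max = max(agg$n_tracks), side_max = side_max,
                 fitted = data.frame(agg,
                                     fitted = drop(X %*% coefs)),
                 sse = opt$value),
            class = "precision_surface")
}

# Monotone through-origin basis: running integrals of degree-2 B-splines
# on [0, xmax], each scaled to reach 1 at xmax. Returned as a closure
# evaluating the basis at arbitrary points by interpolation on a fine
# grid.
ispline_basis_fn <- function(knots, xmax, n_fine = 2001) {
  aug <- c(rep(0, 3), knots, rep(xmax, 3))
  fine <- seq(0, xmax, length.out = n_fine)
  M <- splines::splineDesign(aug, fine, ord = 3, outer.ok = TRUE)
  h <- fine[2] - fine[1]
  Imat <- apply(M, 2, function(col)
    c(0, cumsum((col[-1] + col[-length(col)]) / 2 * h)))
  top <- Imat[n_fine, ]
  keep <- top > 1e-12
  Imat <- sweep(Imat[, keep, drop = FALSE], 2, top[keep], "/")
  function(x) {
    x <- pmin(pmax(x, 0), xmax)
    idx <- pmin(floor(x / xmax * (n_fine - 1)) + 1, n_fine - 1)
    w <- x / xmax * (n_fine - 1) - (idx - 1)
    Imat[idx, , drop = FALSE] * (1 - w) + Imat[idx + 1, , drop = FALSE] * w
  }
}

#' @export
print.precision_surface <- function(x, ...) {
  cat(sprintf(paste0("<precision_surface> %.4g per track + monotone",
                     " smooth in side (max %.4g at side %g)\n"),
              x$linear_coeff, sum(x$spline_coef), x$side_max))
  invisible(x)
}

#' Predict precision at designs
#'
#' @param object A [fit_precision_surface()] result.
#' @param n_tracks,survey_side Design coordinates (vectorized).
#' @param ... Unused.
#' @return Numeric vector of predicted precisions.
#' @export
predict.precision_surface <- function(object, n_tracks, survey_side, ...) {
  drop(object$linear_coeff * n_tracks +
         object$basis(survey_side) %*% object$spline_coef)
}

#' Effort-allocation scenario
#'
#' @param total_effort Total effort in track-equivalents.
#' @param exchange_rate Survey side length bought per track-equivalent of
#'   effort.
#' @param allocations Telemetry fractions to evaluate.
#' @return An `effort_scenario` list.
#' @export
effort_scenario <- function(total_effort = 50, exchange_rate = 0.02,
                            allocations = seq(0, 1, by = 0.01)) {
  stopifnot(total_effort > 0, exchange_rate > 0,
            all(allocations >= 0 & allocations <= 1))
  structure(list(total_effort = total_effort,
                 exchange_rate = exchange_rate,
                 allocations = allocations), class = "effort_scenario")
}

#' Precision across allocations of a fixed total effort
#'
#' For telemetry fraction `p`, the design tracks `n = p * E` animals and
#' surveys a centred square of side `exchange_rate * (1 - p) * E`; the
#' fitted precision surface predicts the resulting precision. Designs
#' outside the surface's fitted range raise an error rather than
#' extrapolate.
#'
#' @param surface A [fit_precision_surface()] result.
#' @param scenario An [effort_scenario()].
#' @return List with `curve` (data frame `p`, `n_tracks`, `survey_side`,
#'   `precision`) and `optimum` (the row maximizing precision).
#' @export
effort_curve <- function(surface, scenario = effort_scenario()) {
  stopifnot(inherits(surface, "precision_surface"),
            inherits(scenario, "effort_scenario"))
  p <- scenario$allocations
  n <- p * scenario$total_effort
  side <- scenario$exchange_rate * (1 - p) * scenario$total_effort
  if (max(n) > surface$n_max + 1e-9)
    stop(sprintf("allocation needs %g tracks but the surface was fitted ",
                 max(n)), sprintf("up to %g", surface$n_max))
  if (max(side) > surface$side_max + 1e-9)
    stop(sprintf(paste0("allocation needs survey side %g but the surface",
                        " was fitted up to %g"),
                 max(side), surface$side_max))
  prec <- predict(surface, n, side)
  curve <- data.frame(p = p, n_tracks = n, survey_side = side,
                      precision = prec)
  list(curve = curve, optimum = curve[which.max(curve$precision), ])
}

#' Check additivity of telemetry and survey precision
#'
#' For every mixed design with both margins present in the results,
#' compares the mean joint precision with the sum of the corresponding
#' telemetry-only and survey-only mean precisions.
#'
#' @param results Data frame from [run_experiment()].
#' @param tolerances Relative tolerances to report fractions for.
#' @return List with `designs` (per-design table including the relative
#'   difference `rel_diff`) and `fraction_within` (named by tolerance).
#' @export
additivity_check <- function(results, tolerances = c(0.05, 0.10)) {
  if (!"environment" %in% names(results)) results$environment <- 0
  results <- results[is.finite(results$precision), ]
  agg <- stats::aggregate(precision ~ environment + n_tracks + survey_side,
                          data = results, FUN = mean)
  rows <- list()
  mixed <- agg[agg$n_tracks > 0 & agg$survey_side > 0, ]
  for (i in seq_len(nrow(mixed))) {
    e <- mixed$environment[i]
    tel <- agg[agg$environment == e & agg$n_tracks == mixed$n_tracks[i] &
                 agg$survey_side == 0, "precision"]
    sur <- agg[agg$environment == e & agg$n_tracks == 0 &
                 agg$survey_side == mixed$survey_side[i], "precision"]
    if (length(tel) != 1 || length(sur) != 1) {
      warning(sprintf(
        "design (%d tracks, side %g, env %g) lacks matched margins",
        mixed$n_tracks[i], mixed$survey_side[i], e), call. = FALSE)
      next
    }
    rows[[length(rows) + 1]] <-
      data.frame(environment = e, n_tracks = mixed$n_tracks[i],
                 survey_side = mixed$survey_side[i],
                 joint = mixed$precision[i], telemetry = tel, survey = sur,
                 rel_diff = abs(mixed$precision[i] - (tel + sur)) /
                   (tel + sur))
  }
  if (length(rows) == 0) stop("no mixed designs with matched margins")
  tab <- do.call(rbind, rows)
  frac <- vapply(tolerances, function(tol) mean(tab$rel_diff <= tol),
                 numeric(1))
  names(frac) <- paste0("within_", format(tolerances))
  list(designs = tab, fraction_within = frac)
}
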