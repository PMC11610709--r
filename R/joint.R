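# Joint likelihood over telemetry and survey data, maximum-likelihood
# fitting with L-BFGS-B, and Hessian-based standard errors.

#' Joint log-likelihood of telemetry and survey data
#'
#' `L(alpha, beta, gamma) = L_s(alpha, beta) + L_M(beta, gamma)`: the
#' survey (inhomogeneous Poisson) and movement (Langevin step) likelihoods
#' share the selection coefficients `beta`. Either data source may be
#' absent, in which case the corresponding term (and its private nuisance
#' parameter, `alpha` or `gamma`) drops out.
#'
#' @param tracks List of [trajectory()] objects, or `NULL`.
#' @param snapshot A [survey_snapshot()], or `NULL`.
#' @param model A [habitat_model()].
#' @param alpha Survey log-intensity intercept (ignored without survey).
#' @param gamma Log diffusivity (ignored without telemetry).
#' @param zeta Gradient-averaging scale; defaults to [estimate_zeta()].
#' @param scheme A [gradient_scheme()] or its name.
#' @param grid An [eval_grid()] for the survey area integral.
#' @return The joint log-likelihood.
#' @export
joint_loglik <- function(tracks = NULL, snapshot = NULL, model,
                         alpha = NULL, gamma = NULL,
                         zeta = NULL, scheme = "g4", grid = NULL) {
  has_tel <- !is.null(tracks) && length(tracks) > 0
  has_surv <- !is.null(snapshot)
  if (!has_tel && !has_surv)
    stop("at least one of telemetry and survey data is required")
  ll <- 0
  if (has_tel) {
    if (is.null(gamma)) stop("gamma is required with telemetry data")
    if (is.null(zeta)) zeta <- estimate_zeta(tracks)
    ll <- ll + movement_loglik(tracks, model, gamma, zeta, scheme)
  }
  if (has_surv) {
    if (is.null(alpha)) stop("alpha is required with survey data")
    if (is.null(grid)) stop("an eval_grid is required with survey data")
    ll <- ll + survey_loglik(snapshot, model, alpha, grid)
  }
  ll
}

#' Central-difference Hessian of a scalar function
#'
#' When an analytic gradient is supplied the Hessian is assembled from
#' central differences of the gradient (one first difference per
#' parameter), which keeps round-off amplification linear in `1/step`;
#' otherwise full second differences of the objective are used. The result
#' is symmetrized.
#'
#' @param fn Objective function of a parameter vector (for likelihood work,
#'   pass the negative log-likelihood).
#' @param at Point at which to differentiate.
#' @param gr Optional gradient function of `fn`.
#' @param step Per-parameter steps; default `pmax(rel_step * abs(at),
#'   rel_step)`.
#' @param rel_step Relative step size.
#' @return Symmetric numeric matrix.
#' @export
numerical_hessian <- function(fn, at, gr = NULL, step = NULL,
                              rel_step = 1e-3) {
  p <- length(at)
  if (is.null(step)) step <- pmax(rel_step * abs(at), rel_step)
  step <- rep_len(step, p)
  H <- matrix(NA_real_, p, p)
  if (!is.null(gr)) {
    for (i in seq_len(p)) {
      e <- numeric(p); e[i] <- step[i]
      H[i, ] <- (gr(at + e) - gr(at - e)) / (2 * step[i])
    }
  } else {
    f0 <- fn(at)
    for (i in seq_len(p)) {
      ei <- numeric(p); ei[i] <- step[i]
      H[i, i] <- (fn(at + ei) - 2 * f0 + fn(at - ei)) / step[i]^2
      if (i < p) for (j in (i + 1):p) {
        ej <- numeric(p); ej[j] <- step[j]
        H[i, j] <- H[j, i] <-
          (fn(at + ei + ej) - fn(at + ei - ej) -
             fn(at - ei + ej) + fn(at - ei - ej)) / (4 * step[i] * step[j])
      }
    }
  }
  (H + t(H)) / 2
}

# Standard errors from the negative-loglik Hessian; NULL if not positive
# definite.
hessian_se <- function(H) {
  V <- try(solve(H), silent = TRUE)
  if (inherits(V, "try-error")) return(NULL)
  d <- diag(V)
  if (any(!is.finite(d)) || any(d <= 0)) return(NULL)
  sqrt(d)
}

#' Maximum-likelihood fit of the joint model
#'
#' Maximizes [joint_loglik()] over the free parameters with the L-BFGS-B
#' quasi-Newton method under wide box bounds. The intercept `alpha` is free
#' only when survey data are present, the log diffusivity `gamma` only when
#' telemetry is present; the coefficient of a `neg_half_sq_norm`
#' localization covariate is bounded below by a small positive number. The
#' averaging scale `zeta` is computed from the data once, before
#' optimization, and held fixed. Standard errors come from the
#' central-difference Hessian of the negative log-likelihood at the
#' optimum; the reported precision of a parameter is `1 / se^2`.
#'
#' Default starting values: `alpha = log(max(m, 1) / |A|)`; raster
#' coefficients 0; OU localization coefficients from moments of all
#' observed locations (`mu` from the mean, `lambda` from the mean
#' per-coordinate variance); `gamma` from the Brownian closed form
#' `log(sum ||dx||^2 / (2 n))`.
#'
#' @inheritParams joint_loglik
#' @param covariates List of covariates defining the model (the
#'   coefficients are estimated).
#' @param init Optional named list with starting values `alpha`, `beta`,
#'   `gamma` (any subset).
#' @param fixed_beta Optional logical vector marking coefficients to hold
#'   fixed at their starting values.
#' @param bound Half-width of the box bounds on all free parameters.
#' @param quad_lower Lower bound for the localization quadratic
#'   coefficient.
#' @param control Passed to [stats::optim()] (on top of `fnscale = -1`).
#' @return An object of class `joint_fit` with elements `alpha`, `beta`,
#'   `gamma`, `loglik`, `se` (named, or `NULL`), `precision`, `hessian`
#'   (negative-loglik scale), `converged`, `n_evals`, `zeta`, `scheme`,
#'   plus the data sizes used.
#' @export
fit_joint <- function(tracks = NULL, snapshot = NULL, covariates,
                      init = NULL, scheme = "g4", grid = NULL,
                      zeta = NULL, fixed_beta = NULL,
                      bound = 50, quad_lower = 1e-8, control = list()) {
  has_tel <- !is.null(tracks) && length(tracks) > 0
  has_surv <- !is.null(snapshot)
  if (!has_tel && !has_surv)
    stop("at least one of telemetry and survey data is required")
  if (has_surv && is.null(grid))
    stop("an eval_grid is required with survey data")
  scheme <- gradient_scheme(scheme)
  k <- length(covariates)
  qi <- quad_index(covariates)

  mss <- NULL
  if (has_tel) {
    tracks <- as_tracks(tracks)
    if (is.null(zeta)) zeta <- estimate_zeta(tracks)
    mss <- movement_suffstats(tracks, covariates, zeta, scheme)
  } else zeta <- NA_real_
  sss <- if (has_surv) survey_suffstats(snapshot, covariates, grid)

  fit_core(mss, sss, if (has_surv) snapshot$points, covariates,
           init = init, scheme_name = scheme$name, zeta = zeta,
           fixed_beta = fixed_beta, bound = bound,
           quad_lower = quad_lower, control = control)
}

# Core optimizer over pre-computed sufficient statistics. mss and/or sss
# may be NULL; survey_points are the observed locations (used only for
# starting values).
fit_core <- function(mss, sss, survey_points, covariates, init = NULL,
                     scheme_name = "g4", zeta = NA_real_,
                     fixed_beta = NULL, bound = 50, quad_lower = 1e-8,
                     control = list()) {
  has_tel <- !is.null(mss)
  has_surv <- !is.null(sss)
  k <- length(covariates)
  qi <- quad_index(covariates)

  start <- default_start(mss, sss, survey_points, covariates,
                         has_tel, has_surv)
  if (!is.null(init$alpha)) start$alpha <- init$alpha
  if (!is.null(init$beta)) start$beta <- rep_len(init$beta, k)
  if (!is.null(init$gamma)) start$gamma <- init$gamma
  if (is.null(fixed_beta)) fixed_beta <- rep(FALSE, k)

  # parameter packing: [alpha?] beta_free [gamma?]
  free_b <- which(!fixed_beta)
  pack <- c(if (has_surv) "alpha", rep("beta", length(free_b)),
            if (has_tel) "gamma")
  unpack <- function(th) {
    pos <- 1L
    a <- if (has_surv) { v <- th[pos]; pos <- pos + 1L; v } else NA_real_
    b <- start$beta
    if (length(free_b)) {
      b[free_b] <- th[pos:(pos + length(free_b) - 1L)]
      pos <- pos + length(free_b)
    }
    g <- if (has_tel) th[pos] else NA_real_
    list(alpha = a, beta = b, gamma = g)
  }
  obj <- function(th) {
    p <- unpack(th)
    ll <- 0
    if (has_tel) ll <- ll + movement_loglik_stats(mss, p$beta, p$gamma)
    if (has_surv) ll <- ll + survey_loglik_stats(sss, p$alpha, p$beta)
    ll
  }
  grad <- function(th) {
    p <- unpack(th)
    ga <- 0; gb <- numeric(k); gg <- 0
    if (has_tel) {
      g <- movement_grad_stats(mss, p$beta, p$gamma)
      gb <- gb + g[seq_len(k)]; gg <- g[k + 1]
    }
    if (has_surv) {
      g <- survey_grad_stats(sss, p$alpha, p$beta)
      ga <- g[1]; gb <- gb + g[1 + seq_len(k)]
    }
    c(if (has_surv) ga, gb[free_b], if (has_tel) gg)
  }

  th0 <- c(if (has_surv) start$alpha, start$beta[free_b],
           if (has_tel) start$gamma)
  lower <- rep(-bound, length(th0))
  upper <- rep(bound, length(th0))
  if (!is.na(qi) && !fixed_beta[qi]) {
    pos <- (if (has_surv) 1L else 0L) + match(qi, free_b)
    lower[pos] <- quad_lower
    upper[pos] <- Inf
  }
  th0 <- pmin(pmax(th0, lower), upper)

  ctrl <- utils::modifyList(list(fnscale = -1, maxit = 500), control)
  opt <- stats::optim(th0, obj, grad, method = "L-BFGS-B",
                      lower = lower, upper = upper, control = ctrl)
  est <- unpack(opt$par)

  nll <- function(th) -obj(th)
  ngr <- function(th) -grad(th)
  H <- numerical_hessian(nll, opt$par, gr = ngr)
  se <- hessian_se(H)
  par_names <- pack
  par_names[par_names == "beta"] <- paste0("beta", free_b)
  dimnames(H) <- list(par_names, par_names)
  if (!is.null(se)) names(se) <- par_names

  structure(list(
    alpha = est$alpha, beta = est$beta, gamma = est$gamma,
    loglik = opt$value, hessian = H,
    se = se, precision = if (!is.null(se)) 1 / se^2,
    converged = opt$convergence == 0,
    n_evals = unname(opt$counts[1]),
    message = if (opt$convergence != 0) opt$message,
    zeta = zeta, scheme = scheme_name,
    n_steps = if (has_tel) mss$n else 0L,
    m_points = if (has_surv) sss$m else 0L,
    par_names = par_names, par = opt$par),
    class = "joint_fit")
}

default_start <- function(mss, sss, survey_points, covariates, has_tel,
                          has_surv) {
  k <- length(covariates)
  beta <- numeric(k)
  # moments of all observed locations for the OU localization start
  pts <- rbind(if (has_tel) mss$x0,
               if (has_surv && sss$m > 0) survey_points)
  kinds <- vapply(covariates, function(cv)
    if (inherits(cv, "polynomial_covariate")) cv$kind else "raster",
    character(1))
  if (!is.null(pts) && nrow(pts) >= 2) {
    mu <- colMeans(pts)
    lam <- mean(apply(pts, 2, stats::var))
    lam <- max(lam, 1e-6)
    beta[kinds == "coord_x"] <- mu[1] / lam
    beta[kinds == "coord_y"] <- mu[2] / lam
    beta[kinds == "neg_half_sq_norm"] <- 1 / lam
  } else {
    beta[kinds == "neg_half_sq_norm"] <- 1
  }
  gamma <- if (has_tel)
    log(sum(mss$dx^2) / (2 * mss$n)) else NA_real_
  alpha <- if (has_surv) {
    area <- sum(sss$area)
    log(max(sss$m, 1) / max(area, 1e-12))
  } else NA_real_
  list(alpha = alpha, beta = beta, gamma = gamma)
}

#' @export
print.joint_fit <- function(x, ...) {
  cat("<joint_fit>", if (x$converged) "converged" else "NOT converged",
      sprintf(" loglik = %.3f\n", x$loglik))
  est <- c(if (!is.na(x$alpha)) stats::setNames(x$alpha, "alpha"),
           stats::setNames(x$beta, paste0("beta", seq_along(x$beta))),
           if (!is.na(x$gamma)) stats::setNames(x$gamma, "gamma"))
  cat("  estimates:\n")
  for (nm in names(est)) {
    se_nm <- if (!is.null(x$se) && nm %in% names(x$se))
      sprintf("  (se %.4g)", x$se[nm]) else ""
    cat(sprintf("    %-7s %12.6g%s\n", nm, est[nm], se_nm))
  }
  if (is.null(x$se))
    cat("  standard errors unavailable (Hessian not positive definite)\n")
  invisible(x)
}

#' Precision of a fitted parameter
#'
#' Precision is the inverse squared standard error, `1 / se^2`, used
#' throughout the effort-allocation experiments as a proxy for effective
#' sample size.
#'
#' @param fit A [fit_joint()] result.
#' @param parameter Parameter name, e.g. `"beta1"`, `"alpha"`, `"gamma"`.
#' @return A single number, or `NA` if the standard error is unavailable.
#' @export
fit_precision <- function(fit, parameter = "beta1") {
  if (is.null(fit$se) || !(parameter %in% names(fit$se))) return(NA_real_)
  unname(1 / fit$se[parameter]^2)
}
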