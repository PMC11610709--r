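# File formats: ESRI ASCII rasters, telemetry/survey CSV, region and model
# JSON, run configuration, and seeded fixture generation.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Read / write a covariate raster as ESRI ASCII grid
#'
#' Standard `.asc` layout: `ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value` header followed by rows of node values from
#' the top (northern) row down. NODATA values inside the grid are not
#' allowed. `xllcorner`/`yllcorner` name the lower-left *node* (grid
#' registration), matching the coordinate convention of
#' [covariate_field()].
#'
#' @param path File path.
#' @return `read_asc`: a [covariate_field()].
#' @export
read_asc <- function(path) {
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing ESRI ASCII header fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  vals <- scan(path, skip = 6, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop(sprintf("expected %d values, found %d",
                 hdr$ncols * hdr$nrows, length(vals)))
  if (!is.null(hdr$nodata_value) && any(vals == hdr$nodata_value))
    stop("NODATA values are not allowed inside the covariate domain")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  covariate_field(m[rev(seq_len(hdr$nrows)), , drop = FALSE],
                  x_origin = hdr$xllcorner, y_origin = hdr$yllcorner,
                  cell_size = hdr$cellsize)
}

#' @rdname read_asc
#' @param field A [covariate_field()].
#' @export
write_asc <- function(field, path) {
  stopifnot(inherits(field, "covariate_field"))
  v <- field$values
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %s", fmt_num(field$x_origin)),
           sprintf("yllcorner %s", fmt_num(field$y_origin)),
           sprintf("cellsize %s", fmt_num(field$cell_size)),
           "NODATA_value -9999")
  body <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1,
                function(r) paste(fmt_num(r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write telemetry tracks as CSV
#'
#' Columns `individual_id, time, x, y`, one row per fix. On read, rows are
#' grouped by individual and sorted by time; duplicate or non-increasing
#' timestamps and non-numeric coordinates are rejected with the offending
#' row numbers.
#'
#' @param path File path.
#' @return `read_telemetry`: a list of [trajectory()] objects.
#' @export
read_telemetry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "time", "x", "y")
  if (!all(need %in% names(df)))
    stop("telemetry CSV needs columns individual_id, time, x, y")
  for (col in c("time", "x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0)
      stop(sprintf("non-numeric '%s' in telemetry row %d", col, bad[1] + 1))
    if (any(is.na(v)))
      stop(sprintf("missing '%s' in telemetry row %d",
                   col, which(is.na(v))[1] + 1))
    df[[col]] <- v
  }
  dup <- duplicated(df[c("individual_id", "time")])
  if (any(dup))
    stop(sprintf("duplicate (individual_id, time) at telemetry row %d",
                 which(dup)[1] + 1))
  df <- df[order(df$individual_id, df$time), ]
  lapply(split(df, df$individual_id), function(d)
    trajectory(d$individual_id[1], d$time, cbind(d$x, d$y)))
}

#' @rdname read_telemetry
#' @param tracks A list of [trajectory()] objects.
#' @export
write_telemetry <- function(tracks, path) {
  tracks <- as_tracks(tracks)
  rows <- lapply(tracks, function(tr)
    data.frame(individual_id = tr$id, time = tr$times,
               x = tr$locations[, 1], y = tr$locations[, 2]))
  df <- do.call(rbind, rows)
  df <- df[order(df$individual_id, df$time), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("individual_id,time,x,y", con)
  writeLines(paste(df$individual_id, fmt_num(df$time),
                   fmt_num(df$x), fmt_num(df$y), sep = ","), con)
  invisible(path)
}

#' Read / write survey points as CSV
#'
#' Columns `x, y`, one row per detected individual.
#'
#' @param path File path.
#' @return `read_survey_points`: an `m x 2` matrix.
#' @export
read_survey_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop("survey CSV needs columns x, y")
  if (nrow(df) == 0) return(matrix(numeric(0), 0, 2))
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  if (any(is.na(x)) || any(is.na(y)))
    stop(sprintf("non-numeric coordinate in survey row %d",
                 which(is.na(x) | is.na(y))[1] + 1))
  cbind(x, y, deparse.level = 0)
}

#' @rdname read_survey_points
#' @param points `m x 2` matrix.
#' @export
write_survey_points <- function(points, path) {
  points <- if (length(points) == 0) matrix(numeric(0), 0, 2)
            else as_points(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("x,y", con)
  if (nrow(points) > 0)
    writeLines(paste(fmt_num(points[, 1]), fmt_num(points[, 2]), sep = ","),
               con)
  invisible(path)
}

#' Read / write a survey region as JSON
#'
#' The region is a JSON array of objects with fields
#' `xmin, xmax, ymin, ymax`.
#'
#' @param path File path.
#' @return `read_region`: a [survey_region()].
#' @export
read_region <- function(path) {
  r <- jsonlite::fromJSON(path)
  if (length(r) == 0)
    return(square_region(0))
  survey_region(as.data.frame(r))
}

#' @rdname read_region
#' @param region A [survey_region()].
#' @export
write_region <- function(region, path) {
  stopifnot(inherits(region, "survey_region"))
  jsonlite::write_json(region$rectangles, path, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read / write a habitat model as JSON
#'
#' The JSON document lists, per covariate, either a raster source path
#' (written alongside as `.asc` when not already a file) or a polynomial
#' kind, plus the coefficient vector `beta`.
#'
#' @param path JSON file path.
#' @return `read_habitat_model`: a [habitat_model()].
#' @export
read_habitat_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  covs <- lapply(doc$covariates, function(cv) {
    if (identical(cv$type, "raster")) {
      src <- cv$source
      if (!file.exists(src))
        src <- file.path(dirname(path), src)
      read_asc(src)
    } else polynomial_covariate(cv$kind)
  })
  habitat_model(covs, unlist(doc$beta))
}

#' @rdname read_habitat_model
#' @param model A [habitat_model()].
#' @param raster_paths Character vector of `.asc` paths (relative to the
#'   JSON file) under which raster covariates are written, recycled in
#'   covariate order.
#' @export
write_habitat_model <- function(model, path, raster_paths = "covariate%d.asc") {
  is_raster <- vapply(model$covariates, inherits, logical(1),
                      what = "covariate_field")
  n_raster <- sum(is_raster)
  raster_paths <- rep_len(raster_paths, max(n_raster, 1))
  has_fmt <- grepl("%", raster_paths, fixed = TRUE)
  raster_paths[has_fmt] <- sprintf(raster_paths[has_fmt],
                                   seq_len(max(n_raster, 1))[has_fmt])
  ri <- 0
  covs <- lapply(seq_along(model$covariates), function(i) {
    cv <- model$covariates[[i]]
    if (inherits(cv, "covariate_field")) {
      ri <<- ri + 1
      write_asc(cv, file.path(dirname(path), raster_paths[ri]))
      list(type = "raster", source = raster_paths[ri])
    } else list(type = "polynomial", kind = cv$kind)
  })
  jsonlite::write_json(list(covariates = covs, beta = model$beta),
                       path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' @param fit A [fit_joint()] result.
#' @param path Output path.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "joint_fit"))
  doc <- list(
    estimates = list(alpha = fit$alpha, beta = fit$beta, gamma = fit$gamma),
    se = as.list(fit$se),
    precision = as.list(fit$precision),
    loglik = fit$loglik,
    converged = fit$converged,
    n_evals = fit$n_evals,
    zeta = fit$zeta, scheme = fit$scheme,
    n_steps = fit$n_steps, m_points = fit$m_points)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Load a run configuration (YAML or JSON)
#'
#' Configurations drive fixture generation and the simulation experiments.
#' Unknown top-level keys are rejected; missing keys fall back to the
#' defaults of [default_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A validated config list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  validate_config(cfg)
}

#' Default run configuration
#'
#' The default values are the generative conditions of the simulation
#' study: exponential-covariance landscapes (variance 0.1, range 0.1 or
#' 0.2) on a 401 x 401 grid spanning `[-1, 1]^2` at spacing 0.005; a
#' selection coefficient of 2 on the resource field; circular
#' central attraction at the origin with home-range variance
#' `lambda = 0.2^2`; colonies of 100 independently moving individuals with
#' diffusivity `Gamma = 1e-5`, simulated at fine step 0.1 for duration 500;
#' telemetry thinned to unit intervals from starts drawn from
#' `N(0, 0.05^2 I)`; snapshot surveys on centred squares with starts drawn
#' from the utilization distribution.
#'
#' @return A config list.
#' @export
default_config <- function() {
  list(
    landscape = list(variance = 0.1, range = 0.1, cell_size = 0.005,
                     xmin = -1, xmax = 1, ymin = -1, ymax = 1),
    selection = list(beta1 = 2.0),
    attraction = list(mu = c(0, 0), lambda = 0.04),
    movement = list(Gamma = 1e-5, fine_step = 0.1, duration = 500,
                    obs_interval = 1, n_individuals = 100,
                    start_sd = 0.05),
    survey = list(side = 0.5, n_individuals = 100),
    inference = list(scheme = "g4", bound = 50, quad_lower = 1e-8),
    seed = 1)
}

validate_config <- function(cfg) {
  base <- default_config()
  extra <- setdiff(names(cfg), names(base))
  if (length(extra) > 0)
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  for (sec in names(base)) {
    if (is.null(cfg[[sec]])) { cfg[[sec]] <- base[[sec]]; next }
    if (sec == "seed") next
    extra <- setdiff(names(cfg[[sec]]), names(base[[sec]]))
    if (length(extra) > 0)
      stop(sprintf("unknown config keys in '%s': %s", sec,
                   paste(extra, collapse = ", ")))
    cfg[[sec]] <- utils::modifyList(base[[sec]], cfg[[sec]])
  }
  with(cfg$landscape, stopifnot(variance >= 0, range > 0, cell_size > 0,
                                xmax > xmin, ymax > ymin))
  stopifnot(cfg$attraction$lambda > 0, cfg$movement$Gamma > 0,
            cfg$movement$fine_step > 0, cfg$movement$duration > 0,
            cfg$movement$n_individuals >= 0, cfg$survey$side >= 0)
  cfg
}

config_landscape_grid <- function(cfg) {
  l <- cfg$landscape
  list(n_x = round((l$xmax - l$xmin) / l$cell_size) + 1L,
       n_y = round((l$ymax - l$ymin) / l$cell_size) + 1L)
}

# Build the habitat model of a config around a given (or freshly
# simulated) resource field.
config_model <- function(cfg, field = NULL, seed = NULL) {
  l <- cfg$landscape
  g <- config_landscape_grid(cfg)
  if (is.null(field))
    field <- simulate_grf(l$range, l$variance, l$xmin, l$ymin, l$cell_size,
                          g$n_x, g$n_y, seed = seed)
  ou <- ou_attraction_model(cfg$attraction$mu, cfg$attraction$lambda)
  habitat_model(c(list(field), ou$covariates),
                c(cfg$selection$beta1, ou$beta))
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes, under `out_dir`: the resource raster (`landscape.asc`), the
#' habitat model (`model.json`), telemetry tracks (`tracks.csv`), survey
#' points (`survey.csv`), the survey region (`region.json`), the
#' generating parameters (`truth.json`) and a run record
#' (`run_record.json`). Identical seeds give byte-identical files.
#'
#' @param config A config list (see [default_config()], [read_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the named vector of written paths.
#' @export
generate_fixtures <- function(config = default_config(), out_dir) {
  cfg <- validate_config(config)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("output directory ", out_dir, " is not writable")
  unlink(probe)

  seeds <- seed_stream(cfg$seed, c("landscape", "telemetry",
                                   "telemetry_path", "survey"))
  model <- config_model(cfg, seed = seeds[["landscape"]])
  field <- model$covariates[[1]]
  l <- cfg$landscape

  mv <- cfg$movement
  tel_starts <- with_seed(seeds[["telemetry"]],
                          matrix(stats::rnorm(2 * mv$n_individuals, 0,
                                              mv$start_sd),
                                 mv$n_individuals, 2))
  tracks <- simulate_colony(model, mv$Gamma, tel_starts, mv$fine_step,
                            mv$duration, mv$obs_interval,
                            seed = seeds[["telemetry_path"]])

  grid <- eval_grid(l$xmin, l$xmax, l$ymin, l$ymax, l$cell_size)
  region <- square_region(cfg$survey$side)
  snap <- sample_colony_snapshot(model, cfg$survey$n_individuals, grid,
                                 region, seed = seeds[["survey"]])

  paths <- c(landscape = file.path(out_dir, "landscape.asc"),
             model = file.path(out_dir, "model.json"),
             tracks = file.path(out_dir, "tracks.csv"),
             survey = file.path(out_dir, "survey.csv"),
             region = file.path(out_dir, "region.json"),
             truth = file.path(out_dir, "truth.json"),
             record = file.path(out_dir, "run_record.json"))
  write_asc(field, paths[["landscape"]])
  write_habitat_model(model, paths[["model"]], "landscape.asc")
  write_telemetry(tracks, paths[["tracks"]])
  write_survey_points(snap$points, paths[["survey"]])
  write_region(region, paths[["region"]])
  jsonlite::write_json(
    list(beta1 = cfg$selection$beta1, lambda = cfg$attraction$lambda,
         mu = cfg$attraction$mu, Gamma = mv$Gamma,
         beta = model$beta, landscape = cfg$landscape,
         movement = cfg$movement, survey_side = cfg$survey$side,
         seed = cfg$seed),
    paths[["truth"]], digits = NA, auto_unbox = TRUE, pretty = TRUE)
  write_run_record(paths[["record"]], cfg, seeds)
  invisible(paths)
}

write_run_record <- function(path, cfg, seeds) {
  jsonlite::write_json(
    list(package = "telsurv",
         version = as.character(utils::packageVersion("telsurv")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config_hash = config_hash(cfg),
         seeds = as.list(seeds)),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  # small rolling hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Derive reproducible sub-seeds from a master seed
#'
#' Deterministically maps a master seed and a label (or index vector) to
#' integer seeds below `2^31`, so that independent simulation components
#' draw from decorrelated streams and every run is reproducible from one
#' master seed.
#'
#' @param master Integer master seed.
#' @param labels Character or integer vector naming the streams.
#' @return Named integer vector of seeds.
#' @export
seed_stream <- function(master, labels) {
  vapply(as.character(labels), function(lbl) {
    h <- as.numeric(master) %% 2147483647
    for (ch in utf8ToInt(lbl)) h <- (h * 31 + ch) %% 2147483647
    # two Lehmer rounds decorrelate nearby masters; products stay < 2^53
    h <- (h * 48271) %% 2147483647
    h <- (h * 48271) %% 2147483647
    as.integer(h %% 2147483629 + 1)
  }, integer(1))
}
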