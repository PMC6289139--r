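# Readers and writers: measurement TSV, parameter-structure TSV, a YAML
# problem bundle tying them to a model plugin, and JSON result files.

measurement_cols <- c("observableId", "time", "measurement", "replicateId",
                      "experimentId")

#' Read / write a measurement table
#'
#' Tab-separated with columns `observableId`, `time`, `measurement`,
#' `replicateId`, `experimentId` (the latter two optional on read,
#' defaulting to a single replicate/experiment).
#'
#' @param path file path.
#' @param measurements tibble of measurements.
#' @return `read_measurements()` returns a tibble; `write_measurements()`
#'   returns `path` invisibly.
#' @export
read_measurements <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"replicateId" %in% names(m)) m$replicateId <- "r1"
  if (!"experimentId" %in% names(m)) m$experimentId <- "e1"
  missing_cols <- setdiff(measurement_cols, names(m))
  if (length(missing_cols) > 0)
    stop("measurement table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  m[measurement_cols]
}

#' @rdname read_measurements
#' @export
write_measurements <- function(measurements, path) {
  readr::write_tsv(tibble::as_tibble(measurements)[measurement_cols], path)
  invisible(path)
}

# assignment row <-> "observable|replicate|experiment" pattern
assignment_pattern <- function(a) {
  paste(a$observableId, a$replicateId, a$experimentId, sep = "|")
}

#' Read / write a parameter-structure table
#'
#' Tab-separated with columns `parameterId`, `type`
#' (`dynamic`/`scaling`/`noise`), `groupKey`, `fixedValue` (empty if free),
#' `lowerBound`, `upperBound`, `parameterScale` (`lin`/`log10`). For scaling
#' and noise parameters the `groupKey` encodes the record-to-group map as
#' `;`-separated `observable|replicate|experiment` patterns (wildcard `*`);
#' a pattern listed under one scaling and one noise parameter defines one
#' assignment.
#'
#' @param path file path.
#' @param structure a [parameter_structure()].
#' @return `read_parameter_structure()` returns a [parameter_structure()];
#'   `write_parameter_structure()` returns `path` invisibly.
#' @export
read_parameter_structure <- function(path) {
  p <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         fixedValue = readr::col_double(),
                         lowerBound = readr::col_double(),
                         upperBound = readr::col_double(),
                         .default = readr::col_character()))
  pat_of <- function(type) {
    rows <- p[p$type == type, ]
    out <- list()
    for (i in seq_len(nrow(rows))) {
      pats <- strsplit(rows$groupKey[i], ";", fixed = TRUE)[[1]]
      for (pt in pats) out[[pt]] <- rows$parameterId[i]
    }
    out
  }
  s_map <- pat_of("scaling")
  n_map <- pat_of("noise")
  pats <- union(names(s_map), names(n_map))
  fields <- do.call(rbind, strsplit(pats, "|", fixed = TRUE))
  assignments <- tibble::tibble(
    observableId = fields[, 1], replicateId = fields[, 2],
    experimentId = fields[, 3],
    scalingId = unlist(s_map[pats], use.names = FALSE),
    noiseId = unlist(n_map[pats], use.names = FALSE))
  parameter_structure(p[setdiff(names(p), "groupKey")] |>
                        dplyr::mutate(groupKey = p$parameterId),
                      assignments)
}

#' @rdname read_parameter_structure
#' @export
write_parameter_structure <- function(structure, path) {
  stopifnot(inherits(structure, "parameter_structure"))
  p <- structure$parameters
  a <- structure$assignments
  pat <- assignment_pattern(a)
  key_for <- function(id, type) {
    if (type == "dynamic") return(id)
    col <- if (type == "scaling") a$scalingId else a$noiseId
    paste(pat[col == id], collapse = ";")
  }
  p$groupKey <- mapply(key_for, p$parameterId, p$type)
  readr::write_tsv(p, path)
  invisible(path)
}

#' Write / read a problem bundle
#'
#' A bundle is a directory holding `measurements.tsv`, `parameters.tsv` and
#' a YAML config naming the model plugin (a [builtin_model()] name), the
#' noise distribution and the observation scale of each observable.
#' `read_problem()` rebuilds the validated [build_problem()] object; models
#' other than the built-ins are passed via `plugin`.
#'
#' @param problem an `estimation_problem` whose ODE model is a built-in (or
#'   whose name matches the plugin supplied on read).
#' @param dir bundle directory (created if needed).
#' @param path path to the bundle's YAML file.
#' @param plugin optional list with elements `model` and `observation`
#'   overriding the model lookup by name.
#' @return `write_problem()` returns the YAML path invisibly;
#'   `read_problem()` returns an `estimation_problem`.
#' @export
write_problem <- function(problem, dir) {
  stopifnot(inherits(problem, "estimation_problem"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_measurements(problem$measurements[measurement_cols],
                     file.path(dir, "measurements.tsv"))
  write_parameter_structure(problem$structure, file.path(dir, "parameters.tsv"))
  cfg <- list(model = problem$ode_model$name,
              noise_distribution = problem$noise_distribution,
              observation_scale = as.list(problem$observation_model$observation_scale),
              measurements = "measurements.tsv",
              parameters = "parameters.tsv")
  yaml::write_yaml(cfg, file.path(dir, "problem.yaml"))
  invisible(file.path(dir, "problem.yaml"))
}

#' @rdname write_problem
#' @export
read_problem <- function(path, plugin = NULL) {
  cfg <- yaml::read_yaml(path)
  dir <- dirname(path)
  built <- plugin %||% tryCatch(builtin_model(cfg$model), error = function(e)
    stop("unknown model plugin '", cfg$model,
         "'; pass it via the plugin argument", call. = FALSE))
  obs <- built$observation
  if (!is.null(cfg$observation_scale))
    obs$observation_scale[names(cfg$observation_scale)] <-
      unlist(cfg$observation_scale)
  build_problem(built$model, obs,
                read_measurements(file.path(dir, cfg$measurements)),
                read_parameter_structure(file.path(dir, cfg$parameters)),
                cfg$noise_distribution)
}

result_metadata <- function(seed, config = list()) {
  list(tool = "hierode",
       version = as.character(utils::packageVersion("hierode")),
       seed = seed,
       config = config,
       config_hash = rlang::hash(config))
}

#' Write a multi-start result to JSON
#'
#' Serializes per-start records, the waterfall vector (ascending final
#' objective values), the best parameters, tool version, seed and a hash of
#' the config echo.
#'
#' @param result a `multistart_result`.
#' @param path output path.
#' @param config optional list echoed (and hashed) into the file.
#' @return `path`, invisibly.
#' @export
write_multistart_json <- function(result, path, config = list()) {
  stopifnot(inherits(result, "multistart_result"))
  starts <- tidy(result)
  payload <- c(result_metadata(result$seed, config),
               list(approach = result$approach,
                    threshold = result$threshold,
                    best_J = result$best_J,
                    converged_fraction = converged_fraction(result),
                    waterfall = sort(result$starts$J),
                    best_parameters = lapply(result$best_parameters, as.list),
                    starts = starts))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "string")
  invisible(path)
}

#' Write a comparison report to JSON
#'
#' @param report a `comparison_report`.
#' @param path output path.
#' @param config optional list echoed (and hashed) into the file.
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(report, path, config = list()) {
  stopifnot(inherits(report, "comparison_report"))
  payload <- c(result_metadata(report$seed, config),
               list(threshold = report$threshold,
                    summary = report$summary,
                    waterfalls = report$waterfalls))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "string")
  invisible(path)
}
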