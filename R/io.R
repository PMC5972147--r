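#' Read and write parameter sets as JSON
#'
#' The document carries `schema_version`, `variant` and a `parameters`
#' object. Reading validates the schema and reports the offending field
#' on failure; unknown or missing parameters for the declared variant are
#' rejected with their names.
#'
#' @param path file path.
#' @param model optional model; if given, the file's variant must match.
#' @return for `read_params`, a named parameter vector with attribute
#'   `variant`.
#' @export
read_params <- function(path, model = NULL) {
  doc <- tryCatch(jsonlite::fromJSON(path), error = function(e) {
    abort(paste0("'", path, "': not valid JSON: ", conditionMessage(e)))
  })
  for (field in c("schema_version", "variant", "parameters")) {
    if (is.null(doc[[field]])) {
      abort(paste0("'", path, "': missing field '", field, "'"))
    }
  }
  if (!doc$variant %in% c("FULL", "SMAD_GLI", "SMAD_ONLY")) {
    abort(paste0("'", path, "': field 'variant' has unknown value '",
                 doc$variant, "'"))
  }
  if (!is.null(model) && model$variant != doc$variant) {
    abort(paste0(
      "'", path, "': variant '", doc$variant,
      "' does not match the model variant '", model$variant, "'"
    ))
  }
  p <- unlist(doc$parameters)
  if (!is.numeric(p)) {
    abort(paste0("'", path, "': field 'parameters' must be numeric"))
  }
  want <- sw_param_names(doc$variant)
  miss <- setdiff(want, names(p))
  extra <- setdiff(names(p), want)
  if (length(miss) > 0) {
    abort(paste0("'", path, "': parameters missing: ",
                 paste(miss, collapse = ", ")))
  }
  if (length(extra) > 0) {
    abort(paste0("'", path, "': unknown parameters: ",
                 paste(extra, collapse = ", ")))
  }
  if (any(p <= 0)) {
    abort(paste0(
      "'", path, "': parameters must be strictly positive; offending: ",
      paste(names(p)[p <= 0], collapse = ", ")
    ))
  }
  structure(p[want], variant = doc$variant)
}

#' @rdname read_params
#' @param params named parameter vector.
#' @param variant model variant the parameters belong to.
#' @export
write_params <- function(params, path, variant = "FULL") {
  jsonlite::write_json(
    list(
      schema_version = 1L, variant = variant,
      parameters = as.list(params)
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read and write trajectories (CSV or JSON)
#'
#' CSV uses a `time_h` column followed by one column per species
#' (comma-separated, `.` decimal, header row, UTF-8). JSON wraps the
#' same table with a `schema_version` field. The format is chosen from
#' the file extension.
#'
#' @param traj trajectory tibble (from [simulate_network()]).
#' @param path output path ending in `.csv` or `.json`.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  if (grepl("[.]json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(schema_version = 1L, trajectory = df),
      path,
      auto_unbox = TRUE, digits = NA
    )
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @return for `read_trajectory`, a tibble with `time_h` first.
#' @export
read_trajectory <- function(path) {
  if (grepl("[.]json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::fromJSON(path)
    if (is.null(doc$trajectory)) {
      abort(paste0("'", path, "': missing field 'trajectory'"))
    }
    df <- as_tibble(doc$trajectory)
  } else {
    df <- as_tibble(utils::read.csv(path, fileEncoding = "UTF-8"))
  }
  if (!"time_h" %in% names(df)) {
    abort(paste0("'", path, "': missing column 'time_h'"))
  }
  df
}

#' Record of a stochastic run
#'
#' Captures everything needed to reproduce a run bit for bit: the
#' command, its configuration, the seed(s), the package version,
#' timestamps, and MD5 digests of the output files.
#'
#' @param command command or function name.
#' @param config list of configuration values.
#' @param seed seed(s) used.
#' @param outputs character vector of output file paths.
#' @param started,finished POSIXct timestamps.
#' @return a `sw_run_record` list; write it with [write_run_record()].
#' @export
run_record <- function(command, config = list(), seed = NA_integer_,
                       outputs = character(0),
                       started = Sys.time(), finished = Sys.time()) {
  digests <- if (length(outputs) > 0) {
    as.list(tools::md5sum(outputs))
  } else {
    list()
  }
  structure(
    list(
      schema_version = 1L,
      command = command,
      config = config,
      seed = seed,
      package_version = as.character(utils::packageVersion("snailwave")),
      started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
      output_digests = digests
    ),
    class = "sw_run_record"
  )
}

#' @rdname run_record
#' @param record an `sw_run_record`.
#' @param path output JSON path.
#' @export
write_run_record <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
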