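#' Load a run configuration from a YAML or JSON file
#'
#' A configuration file holds any subset of the [model_params()] fields plus
#' optional run metadata: `model` (1-4), `out` (output path),
#' `record_every`, `n_grid`, `strength_ratio`, `n_trials`, `burnin` and
#' `verbosity`.  Absent keys take the documented defaults; unknown keys are
#' rejected by name so typos cannot silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An object of class `"run_config"`: list with `params` (a validated
#'   [model_params()]) and the run metadata fields.
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format '", ext, "' (use yaml or json)",
         call. = FALSE)
  }
  if (is.null(raw)) raw <- list()
  config_from_list(raw)
}

# metadata keys accepted beside the model parameters
.config_meta_defaults <- list(model = 1L, out = NA_character_,
                              record_every = 100L, n_grid = 10000L,
                              strength_ratio = 3, n_trials = 10000L,
                              burnin = 2000L, verbosity = 1L)

# internal: validate and normalize a raw config list
config_from_list <- function(raw) {
  param_keys <- names(formals(model_params))
  meta_keys <- names(.config_meta_defaults)
  unknown <- setdiff(names(raw), c(param_keys, meta_keys))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- params_from_list(raw[intersect(names(raw), param_keys)])
  meta <- utils::modifyList(.config_meta_defaults,
                            raw[intersect(names(raw), meta_keys)])
  if (!meta$model %in% 1:4)
    stop("invalid config key 'model': must be 1, 2, 3 or 4", call. = FALSE)
  out <- c(list(params = params), meta)
  class(out) <- "run_config"
  out
}

#' Save a run configuration
#'
#' Writes a [load_config()]-compatible file; `load_config(save_config(...))`
#' round-trips losslessly.
#'
#' @param config A `"run_config"` object (or a [model_params()] alone).
#' @param path Destination ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (inherits(config, "model_params"))
    config <- config_from_list(unclass(config))
  flat <- c(unclass(config$params),
            config[setdiff(names(unclass(config)), "params")])
  flat <- flat[!vapply(flat, function(x) length(x) == 1 && is.na(x),
                       logical(1))]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(flat, path)
  } else if (ext == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported config format '", ext, "' (use yaml or json)",
         call. = FALSE)
  }
  invisible(path)
}

# required column schemas per result kind
.result_schemas <- list(
  fixation = c("trial", "outcome", "generations"),
  trajectory = c("iteration", "generation", "mean_z"),
  summary = c("model", "slope", "doubling_time", "r_squared")
)

#' Write a result table as annotated TSV
#'
#' Tab-separated, header line, `.` decimal separator, newline-terminated,
#' deterministic column order (the schema columns first).  The file starts
#' with comment lines (`#`) recording the package version, the seed and the
#' full parameter set, so every output is self-describing.
#'
#' @param table Data frame matching the column schema of `kind`.
#' @param path Destination path.
#' @param kind One of `"fixation"`, `"trajectory"`, `"summary"`.
#' @param params Optional [model_params()] recorded in the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, kind = c("fixation", "trajectory",
                                                "summary"),
                          params = NULL) {
  kind <- match.arg(kind)
  schema <- .result_schemas[[kind]]
  missing_cols <- setdiff(schema, names(table))
  if (length(missing_cols) > 0)
    stop("schema mismatch for kind '", kind, "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- names(table)[vapply(table, function(x)
    !(is.numeric(x) || is.character(x) || is.logical(x)), logical(1))]
  if (length(bad) > 0)
    stop("schema mismatch: unsupported column type in ",
         paste(bad, collapse = ", "), call. = FALSE)
  table <- table[, c(schema, setdiff(names(table), schema)), drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# enhancerun ",
                    as.character(utils::packageVersion("enhancerun")),
                    " | kind: ", kind), con)
  if (!is.null(params)) {
    writeLines(paste0("# seed: ", params$seed), con)
    flat <- unclass(params)
    writeLines(paste0("# params: ",
                      paste(sprintf("%s=%.15g", names(flat),
                                    as.numeric(unlist(flat))),
                            collapse = " ")), con)
  }
  utils::write.table(format(table, digits = 15, trim = TRUE,
                            scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, dec = ".")
  invisible(path)
}

#' Read a result TSV written by [write_results()]
#'
#' @param path Path to the TSV file.
#' @return Data frame (comment header lines are skipped).
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
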