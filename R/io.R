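#' @title Readers and writers
#' @description Structured-text configuration, trajectory CSV with a
#'   versioned header, dataset CSVs with a unit flag in the time-column
#'   header, and JSON run manifests.
#' @name io
NULL

.trajectory_schema <- "ocupk_trajectory v1"

#' Read a model configuration file
#'
#' Plain-text `key = value` format, one entry per line. Values may carry
#' unit tags (`Q_Aq = 4.2 uL/min`); section headers like `[anatomy]` and
#' `#` comments are allowed and ignored; keys are the model symbols
#' (`V_t`, `Q_UvSc`, `K_ScCh`, ...) plus `mode` and the solver settings.
#' The map is passed through [normalize_units()] and [validate_params()];
#' fatal diagnostics abort with the offending key named.
#'
#' @param path path to the configuration file, or the string
#'   `"rabbit-dexamethasone"` to load the built-in preset.
#' @return validated `ocular_params`.
#' @export
read_eye_config <- function(path) {
  if (identical(path, "rabbit-dexamethasone")) {
    return(rabbit_dexamethasone_params())
  }
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^\\[.*\\]$", lines)]  # section headers
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) {
    stop("cannot parse config line(s): ",
         paste(lines[bad], collapse = "; "), call. = FALSE)
  }
  raw <- stats::setNames(lapply(kv, `[`, 3L),
                         vapply(kv, `[`, character(1), 2L))
  params <- normalize_units(raw)
  diags <- validate_params(params)
  fatal <- diags[diags$severity == "fatal", , drop = FALSE]
  if (nrow(fatal) > 0L) {
    stop("invalid configuration (", paste(unique(fatal$key),
                                          collapse = ", "), "): ",
         paste(fatal$message, collapse = "; "), call. = FALSE)
  }
  for (msg in diags$message[diags$severity == "warning"]) {
    warning(msg, call. = FALSE)
  }
  params
}

#' Write / read a trajectory CSV
#'
#' The file starts with a versioned schema comment line, then a standard
#' CSV with `time_s`, the compartment concentrations, `C_Ep` (empty when
#' missing) and the cumulative sink columns. Numeric fields round-trip to
#' 12 significant digits.
#'
#' @param traj an `eye_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", .trajectory_schema, ", mode=",
                    attr(traj, "mode")), con)
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, sprintf("%.12g", x))
  })
  utils::write.csv(df, con, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param mode expected mode; read from the schema line when `NULL`.
#' @return for `read_trajectory`, an `eye_trajectory` data.frame (without
#'   the generating-parameter attribute).
#' @export
read_trajectory <- function(path, mode = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    stop("empty file; expected '# ", .trajectory_schema,
         "' header followed by CSV", call. = FALSE)
  }
  if (!grepl(.trajectory_schema, first, fixed = TRUE)) {
    stop("unrecognized trajectory schema; expected '# ",
         .trajectory_schema, "' on the first line", call. = FALSE)
  }
  file_mode <- sub(".*mode=", "", first)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0L || !"time_s" %in% names(df)) {
    stop("trajectory CSV has no data rows or no time_s column",
         call. = FALSE)
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop("trajectory times must be strictly increasing", call. = FALSE)
  }
  attr(df, "mode") <- if (is.null(mode)) file_mode else mode
  class(df) <- c("eye_trajectory", "data.frame")
  df
}

# parse a "time_<unit>" column name into a factor-to-seconds
.time_unit_factor <- function(colname) {
  unit <- sub("^time_", "", colname)
  factors <- c(s = 1, sec = 1, min = 60, h = 3600, hr = 3600,
               day = 86400, d = 86400)
  if (!unit %in% names(factors)) {
    stop("time column must be named time_<unit> with unit one of ",
         paste(names(factors), collapse = ", "), "; got '", colname, "'",
         call. = FALSE)
  }
  factors[[unit]]
}

#' Read a cumulative release CSV
#'
#' Two columns: a time column named `time_<unit>` (`time_s`, `time_min`,
#' `time_h`, `time_day`) and a cumulative-mass column (ng).
#'
#' @param path CSV path.
#' @return a [release_dataset].
#' @export
read_release_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected two columns", call. = FALSE)
  fac <- .time_unit_factor(names(df)[1])
  release_dataset(df[[1]] * fac, df[[2]])
}

#' Read an aqueous concentration CSV
#'
#' Two columns: `time_<unit>` and a concentration column (ng/mL).
#'
#' @param path CSV path.
#' @return an [aqueous_dataset].
#' @export
read_aqueous_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected two columns", call. = FALSE)
  fac <- .time_unit_factor(names(df)[1])
  aqueous_dataset(df[[1]] * fac, df[[2]])
}

#' Write a sensitivity table CSV
#'
#' @param sens a `sensitivity_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(sens, path) {
  utils::write.csv(as.data.frame(sens), path, row.names = FALSE)
  invisible(path)
}

#' Write an uncertainty ensemble to per-compartment CSVs plus a manifest
#'
#' One CSV per compartment with columns `time_s`, `nominal`, `min`,
#' `p2_5`, `p50`, `p97_5`, `max`, plus a JSON manifest recording seed,
#' run counts and the randomized parameter list.
#'
#' @param ens an `uncertainty_ensemble`.
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_uncertainty <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cc in names(ens$summary)) {
    df <- data.frame(time_s = ens$times, ens$summary[[cc]],
                     check.names = FALSE)
    p <- file.path(dir, paste0("uncertainty_", cc, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- file.path(dir, "uncertainty_manifest.json")
  jsonlite::write_json(
    list(seed = ens$seed, n_runs = ens$n_runs, n_failed = ens$n_failed,
         range = ens$range, parameters = ens$parameters),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, manifest))
}

#' Write a run manifest
#'
#' JSON record tying outputs to their exact inputs: config digest (md5),
#' mode, solver settings, seed, package version, start time and md5
#' checksums of every output file.
#'
#' @param path manifest output path.
#' @param params the `ocular_params` used.
#' @param outputs character vector of output file paths.
#' @param config_path optional path of the source config file.
#' @param determinism `"exact"` for deterministic runs, `"seeded"` for
#'   ensembles.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params, outputs, config_path = NULL,
                           determinism = "exact") {
  checksums <- if (length(outputs)) {
    as.list(tools::md5sum(outputs))
  } else {
    list()
  }
  manifest <- list(
    schema = "ocupk_manifest v1",
    config_digest = if (!is.null(config_path) && file.exists(config_path)) {
      unname(tools::md5sum(config_path))
    } else {
      NA
    },
    mode = params$mode,
    solver = params$solver,
    seed = params$solver$seed,
    determinism = determinism,
    version = as.character(utils::packageVersion("ocupk")),
    start_time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = checksums)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
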