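# Delimited-text I/O with schema validation and provenance headers.
# Dialect is fixed: comma separator, "." decimal, UTF-8, header row,
# '#' comment lines for provenance.

provenance_header <- function(seed = NULL, config_hash = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("gpcrsel")),
                  error = function(e) "dev")
  parts <- c(sprintf("tool=gpcrsel %s", ver))
  if (!is.null(config_hash)) parts <- c(parts, sprintf("config_hash=%s", config_hash))
  if (!is.null(seed)) parts <- c(parts, sprintf("seed=%s", seed))
  c(paste("#", paste(parts, collapse = " | ")),
    paste("# created =", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
}

#' Write a table with a provenance header
#'
#' Comma-separated, `"."` decimal, UTF-8, header row; provenance (tool
#' version, optional config hash and seed, timestamp) as leading `#` comment
#' lines. If the object carries a `ground_truth` attribute (synthetic data),
#' it is written to a sidecar `<path>.json`.
#'
#' @param x data frame.
#' @param path output file.
#' @param seed,config_hash optional provenance fields.
#' @return `path`, invisibly.
#' @export
write_gpcrsel_table <- function(x, path, seed = NULL, config_hash = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenance_header(seed, config_hash), con)
  utils::write.table(as.data.frame(x), con, sep = ",", dec = ".",
                     row.names = FALSE, quote = FALSE)
  gt <- attr(x, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(unclass(gt), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

# Read a delimited table, enforce the schema and numeric validity.
# `numeric_cols` must parse as "." decimal numbers; a malformed cell raises
# an error naming the row and column.
read_validated_table <- function(path, required, numeric_cols) {
  check_that(file.exists(path), sprintf("input file '%s' does not exist", path))
  raw <- utils::read.table(path, header = TRUE, sep = ",", comment.char = "#",
                           colClasses = "character", stringsAsFactors = FALSE,
                           encoding = "UTF-8")
  missing <- setdiff(required, names(raw))
  check_that(length(missing) == 0,
             sprintf("'%s' is missing required column(s): %s", path,
                     paste(missing, collapse = ", ")))
  for (col in intersect(numeric_cols, names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad) > 0) {
      abort_invalid(sprintf(
        "malformed numeric cell in '%s': row %d, column '%s' (value '%s'; decimal dialect is '.')",
        path, bad[1], col, raw[[col]][bad[1]]), class = "gpcrsel_data_error")
    }
    raw[[col]] <- v
  }
  raw
}

#' Read a concentration-response table
#'
#' Requires columns `log_conc` (log10 molar) and `response`; `ligand`,
#' `receptor` and `replicate` are carried along when present.
#'
#' @param path CSV file (see [write_gpcrsel_table()] for the dialect).
#' @return a `dose_response_set` data frame.
#' @export
read_dose_response <- function(path) {
  x <- read_validated_table(path, c("log_conc", "response"),
                            c("log_conc", "response", "replicate"))
  structure(x, class = c("dose_response_set", "data.frame"))
}

#' Read a binding-curve table
#'
#' Requires columns `log_conc` (log10 molar) and `signal`; `series`,
#' `replicate` and `g_tot` are carried along when present.
#'
#' @param path CSV file.
#' @return a `binding_curve_set` data frame.
#' @export
read_binding_curves <- function(path) {
  x <- read_validated_table(path, c("log_conc", "signal"),
                            c("log_conc", "signal", "replicate", "g_tot"))
  structure(x, class = c("binding_curve_set", "data.frame"))
}

#' Read a trajectory feature table
#'
#' Requires `simulation_id` and `time_ns` plus at least one feature column;
#' all non-identifier columns are parsed as numbers. Time must be strictly
#' increasing within each simulation.
#'
#' @param path CSV file.
#' @return a `feature_series` data frame.
#' @export
read_feature_series <- function(path) {
  x <- read_validated_table(path, c("simulation_id", "time_ns"), character(0))
  feat <- setdiff(names(x), "simulation_id")
  for (col in feat) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v) & !is.na(x[[col]]) & nzchar(x[[col]]))
    if (length(bad) > 0) {
      abort_invalid(sprintf(
        "malformed numeric cell in '%s': row %d, column '%s' (value '%s')",
        path, bad[1], col, x[[col]][bad[1]]), class = "gpcrsel_data_error")
    }
    x[[col]] <- v
  }
  for (sim in unique(x$simulation_id)) {
    t <- x$time_ns[x$simulation_id == sim]
    if (is.unsorted(t, strictly = TRUE)) {
      abort_invalid(sprintf(
        "time_ns must be strictly increasing within simulation '%s' in '%s'",
        sim, path), class = "gpcrsel_data_error")
    }
  }
  structure(x, class = c("feature_series", "data.frame"))
}

#' Read a multi-frame coordinate table
#'
#' Native format for [compute_features()]: columns `frame`, `atom`, `x`,
#' `y`, `z` (Angstrom).
#'
#' @param path CSV file.
#' @return a data frame.
#' @export
read_coordinate_table <- function(path) {
  read_validated_table(path, c("frame", "atom", "x", "y", "z"),
                       c("frame", "x", "y", "z"))
}
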