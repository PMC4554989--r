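# Delimited text I/O for the long-format observation schema and flat
# key-value run configurations. All files are comma-separated with a header
# row, UTF-8, '.' decimal.

#' Read a long-format observation table
#'
#' @param path CSV file with columns `individual_id`, `measure`, `time`,
#'   `value` and optionally `line`, `replicate`, `provenance`.
#' @return Data frame sorted by measure, individual and time.
#' @export
read_series_table <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "measure", "time", "value")
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    stop("file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(d$time) || !is.numeric(d$value)) {
    stop("columns 'time' and 'value' must be numeric in ", path,
         call. = FALSE)
  }
  d[order(d$measure, d$individual_id, d$time), , drop = FALSE]
}

#' Write a data frame as CSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a flat key-value run configuration
#'
#' Configurations are flat YAML mappings (`key: value` per line); nested
#' structures are rejected so a run's settings stay greppable and diffable.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg)) || any(names(cfg) == "")) {
    stop("config must be a flat key-value mapping", call. = FALSE)
  }
  if (any(vapply(cfg, function(v) is.list(v), logical(1)))) {
    stop("config must be flat (no nested mappings)", call. = FALSE)
  }
  cfg
}
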