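# Tabular trace I/O. Native exchange format is a CSV table (time_ms + value
# columns, or a dt declared in the JSON sidecar / schema) so that fixtures
# stay plain text.

SCHEMA_VERSION <- "1"

#' Read a trace from a CSV/TSV table
#'
#' The table must contain a value column and either a time column (ms) or a
#' declared sampling interval. When a time column is present, `dt` is the
#' median successive difference and the time base must be uniform to within
#' a relative jitter of 1e-6.
#'
#' @param path file path; a JSON sidecar `<path>.json`, when present,
#'   supplies metadata (signal_kind, condition, cell_id, genotype, dt).
#' @param schema named list overriding column names and metadata: entries
#'   `time` (time column name), `value` (value column name), `dt`,
#'   `signal_kind`, `condition`, `cell_id`, `genotype`.
#' @param sep field separator, inferred from the extension by default.
#' @return a [trace].
#' @export
read_trace_table <- function(path, schema = list(), sep = NULL) {
  if (!file.exists(path)) stop("read_trace_table: no such file: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  get <- function(key, default = NULL) {
    if (!is.null(schema[[key]])) schema[[key]] else
      if (!is.null(meta[[key]])) meta[[key]] else default
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  value_col <- get("value", "value")
  time_col <- get("time", "time_ms")
  if (!value_col %in% names(tab))
    stop("read_trace_table: missing value column '", value_col, "'")
  values <- tab[[value_col]]
  if (anyNA(values)) stop("read_trace_table: NaN/NA samples in '", path, "'")
  t0 <- 0
  if (time_col %in% names(tab)) {
    tt <- tab[[time_col]]
    if (anyNA(tt)) stop("read_trace_table: NaN/NA in time column")
    d <- diff(tt)
    dt <- stats::median(d)
    if (dt <= 0) stop("read_trace_table: time column not increasing")
    if (length(d) && max(abs(d - dt)) > 1e-6 * dt)
      stop("read_trace_table: non-uniform sampling (relative jitter > 1e-6)")
    t0 <- tt[1]
  } else {
    dt <- get("dt")
    if (is.null(dt))
      stop("read_trace_table: no time column and no declared dt")
    dt <- as.numeric(dt)
  }
  trace(values, dt = dt, t0 = t0,
        signal_kind = get("signal_kind", "voltage"),
        condition = get("condition", "basal"),
        cell_id = get("cell_id", "cell"),
        genotype = get("genotype", "NA"))
}

#' Write a trace to a CSV table with JSON sidecar
#'
#' Values are written at full double precision (17 significant digits) so
#' that a read-back reproduces them bit-identically.
#'
#' @param x a [trace].
#' @param path output CSV path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(x, path) {
  stopifnot(inherits(x, "trace"))
  df <- data.frame(time_ms = format(trace_times(x), digits = 17,
                                    scientific = FALSE, trim = TRUE),
                   value = format(x$values, digits = 17, trim = TRUE))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(schema_version = SCHEMA_VERSION, dt = x$dt, t0 = x$t0,
         signal_kind = x$signal_kind, condition = x$condition,
         cell_id = x$cell_id, genotype = x$genotype),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a stage result to disk
#'
#' Scalar summaries (lists of length-1 values) are written as JSON with a
#' schema-version stamp; tabular results (data frames) as CSV. Lists
#' containing data frames are split: each data frame goes to
#' `<stem>_<name>.csv` and the scalar remainder to `<stem>.json`.
#'
#' @param results a data frame, or a named list of scalars, vectors and data
#'   frames.
#' @param path output path; extension `.csv` or `.json` chosen by content.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(results, path) {
  written <- character(0)
  stem <- sub("\\.(csv|json)$", "", path)
  if (is.data.frame(results)) {
    f <- paste0(stem, ".csv")
    utils::write.csv(results, f, row.names = FALSE)
    return(invisible(f))
  }
  if (!is.list(results)) stop("write_results: unsupported result type")
  is_df <- vapply(results, is.data.frame, logical(1))
  for (nm in names(results)[is_df]) {
    f <- paste0(stem, "_", nm, ".csv")
    utils::write.csv(results[[nm]], f, row.names = FALSE)
    written <- c(written, f)
  }
  scalars <- results[!is_df]
  scalars$schema_version <- SCHEMA_VERSION
  f <- paste0(stem, ".json")
  jsonlite::write_json(scalars, f, auto_unbox = TRUE, digits = NA,
                       na = "null")
  written <- c(written, f)
  invisible(written)
}
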