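#' Read a flat key-value configuration file
#'
#' Parses files of `key = value` lines; `#` starts a comment and blank
#' lines are ignored.  Comma-separated values become vectors; entries
#' that parse as numbers are returned numeric, others as character.
#'
#' @param path file path.
#' @return Named list of values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line (no '='): ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(strsplit(substr(ln, eq + 1, nchar(ln)), ",")[[1]])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (all(!is.na(num))) num else val
  }
  out
}

#' Write a flat key-value configuration file
#'
#' Inverse of [read_config()]: one `key = v1,v2,...` line per entry.
#'
#' @param x named list of scalar or vector values.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(x, path) {
  stopifnot(is.list(x), !is.null(names(x)), all(nzchar(names(x))))
  lines <- vapply(names(x), function(k) {
    sprintf("%s = %s", k, paste(format(x[[k]], trim = TRUE,
                                       scientific = FALSE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write model constants to a configuration file
#'
#' Serializes every scalar field of a [model_constants()] object (the
#' derived node positions are omitted and rebuilt on read).
#'
#' @param constants a [model_constants()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_constants <- function(constants, path) {
  validate_constants(constants)
  keep <- setdiff(names(constants), c("dx_mm", "positions_mm"))
  write_config(constants[keep], path)
}

#' Read model constants from a configuration file
#'
#' @param path configuration file written by [write_constants()] (or any
#'   key-value file overriding a subset of the defaults).
#' @return A [model_constants()] object.
#' @export
read_constants <- function(path) {
  kv <- read_config(path)
  args <- kv[intersect(names(kv), names(formals(model_constants)))]
  do.call(model_constants, args)
}

# Canonical column order of the delimited SRT-table schema.  Millisecond
# values are integers (the model is 1-ms-resolved); optional behavioral
# columns may be absent or NA.
SRT_TABLE_COLUMNS <- c("trial", "srt_ms", "direction", "no_saccade",
                       "category", "correct", "landing_x_deg", "subject",
                       "species")

#' Write an SRT table
#'
#' Writes trial-level saccade data as comma-separated text with a header
#' row.  The schema has one row per trial: `trial`, `srt_ms` (integer ms,
#' `NA` when no saccade), `direction` (`left`/`right`/`none`),
#' `no_saccade`, plus optional behavioral columns `category`, `correct`,
#' `landing_x_deg`, `subject`, `species`.  Write-then-read is lossless.
#'
#' @param x data frame with at least `srt_ms`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_srt_table <- function(x, path) {
  stopifnot(is.data.frame(x), "srt_ms" %in% names(x))
  if (is.null(x$trial)) x$trial <- seq_len(nrow(x))
  cols <- intersect(SRT_TABLE_COLUMNS, names(x))
  extra <- setdiff(names(x), cols)
  utils::write.csv(x[, c(cols, extra), drop = FALSE], path,
                   row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read an SRT table
#'
#' @param path file written by [write_srt_table()] (or any delimited table
#'   with the same schema).
#' @return Data frame of trials.
#' @export
read_srt_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"srt_ms" %in% names(x)) stop("missing required column: srt_ms")
  if (nrow(x) > 0 && !is.numeric(x$srt_ms) && !all(is.na(x$srt_ms))) {
    stop("srt_ms must be numeric")
  }
  x
}

#' Write a run manifest
#'
#' Records the provenance of an artifact-producing run (command, seed,
#' configuration summary, package version, timestamp, output paths) as a
#' key-value sidecar file, one manifest per run.
#'
#' @param path manifest file path.
#' @param command short label of the operation.
#' @param seed RNG seed used (or `NA`).
#' @param outputs character vector of output paths.
#' @param extra optional named list of additional entries.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, seed = NA, outputs = character(),
                           extra = list()) {
  entries <- c(list(
    command = command,
    seed = seed,
    package_version = as.character(utils::packageVersion("sacfield")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = if (length(outputs)) outputs else "none"
  ), extra)
  write_config(entries, path)
}
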