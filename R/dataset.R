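#' Construct a trace set
#'
#' A `trace_set` holds a cells-by-frames matrix of fluorescence intensities
#' together with the sampling rate, one UUID per cell, and optional per-cell
#' categorical annotations (cell type, promoter, experimental group, ...).
#' All downstream analyses (spectral features, clustering, peak detection,
#' tuning) start from this container.
#'
#' @param values numeric matrix, one row per cell, one column per frame.
#' @param fs sampling rate in Hz (> 0).
#' @param cell_ids character vector of unique per-cell identifiers; fresh
#'   version-4 UUIDs are generated when omitted.
#' @param annotations named list; each element is a character vector of one
#'   categorical label per cell (tag name -> labels).
#' @return an object of class `trace_set`.
#' @examples
#' ts <- trace_set(matrix(rnorm(300), nrow = 3), fs = 10)
#' ts
#' @export
trace_set <- function(values, fs, cell_ids = NULL, annotations = list()) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("trace values must be numeric")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("sampling rate fs must be a single positive number")
  if (is.null(cell_ids)) cell_ids <- new_uuid(nrow(values))
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != nrow(values))
    stop("cell_ids must have one entry per trace row")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (!is.list(annotations)) stop("annotations must be a named list")
  for (tag in names(annotations)) {
    if (length(annotations[[tag]]) != nrow(values))
      stop(sprintf("annotation '%s' must map a value for every cell", tag))
    annotations[[tag]] <- as.character(annotations[[tag]])
  }
  rownames(values) <- cell_ids
  structure(list(values = values, fs = fs, cell_ids = cell_ids,
                 annotations = annotations),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d cells x %d frames @ %g Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$fs, ncol(x$values) / x$fs))
  if (length(x$annotations))
    cat("  annotations:", paste(names(x$annotations), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trace_set <- function(x) dim(x$values)

#' @export
summary.trace_set <- function(object, ...) {
  v <- object$values
  cat(sprintf("trace_set: %d cells, %d frames, fs = %g Hz\n",
              nrow(v), ncol(v), object$fs))
  cat(sprintf("  intensity range [%.4g, %.4g], grand mean %.4g\n",
              min(v), max(v), mean(v)))
  for (tag in names(object$annotations)) {
    tb <- table(object$annotations[[tag]])
    cat(sprintf("  %s: %s\n", tag,
                paste(sprintf("%s(%d)", names(tb), tb), collapse = " ")))
  }
  invisible(object)
}

#' Plot a trace set as stacked traces
#'
#' @param x a [trace_set()].
#' @param cells indices of cells to draw (default up to 20).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.trace_set <- function(x, cells = seq_len(min(nrow(x$values), 20L)), ...) {
  v <- x$values[cells, , drop = FALSE]
  rng <- max(apply(v, 1, function(r) diff(range(r))), .Machine$double.eps)
  off <- (seq_len(nrow(v)) - 1) * rng
  tt <- (seq_len(ncol(v)) - 1) / x$fs
  matplot(tt, t(v + off), type = "l", lty = 1, xlab = "time (s)",
          ylab = "fluorescence (offset)", ...)
  invisible(x)
}

#' Read traces from delimited text
#'
#' Expected layout: a header row; a `cell_id` column followed by one column
#' per frame (rows are cells). When the `cell_id` column is absent every
#' column is taken as a frame and fresh UUIDs are assigned.
#'
#' @param path file path to a CSV file.
#' @param fs sampling rate in Hz.
#' @param sep field separator (default ",").
#' @return a [trace_set()].
#' @export
load_traces <- function(path, fs, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(nf) == 0L) stop("format error: empty trace file: ", path)
  if (length(unique(nf)) != 1L)
    stop(sprintf("format error: ragged rows in %s (field counts %s)",
                 path, paste(unique(nf), collapse = ", ")))
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) stop("format error: no trace rows in ", path)
  ids <- NULL
  if (identical(names(df)[1], "cell_id")) {
    ids <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  m <- matrix(NA_real_, nrow(df), ncol(df))
  for (j in seq_len(ncol(df))) {
    x <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(x) & !is.na(df[[j]]) & nzchar(trimws(df[[j]])))
    if (length(bad) || anyNA(x))
      stop(sprintf("parse error: non-numeric value at row %d, column %d of %s",
                   if (length(bad)) bad[1] else which(is.na(x))[1], j, path))
    m[, j] <- x
  }
  trace_set(m, fs = fs, cell_ids = ids)
}

#' Write traces to delimited text
#'
#' Inverse of [load_traces()]; numbers are written with full double
#' precision so that a write/read round trip is lossless.
#'
#' @param x a [trace_set()].
#' @param path output file path.
#' @export
write_traces <- function(x, path) {
  stopifnot(inherits(x, "trace_set"))
  df <- data.frame(cell_id = x$cell_ids,
                   format(x$values, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  names(df) <- c("cell_id", paste0("f", seq_len(ncol(x$values)) - 1L))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a stimulus map
#'
#' Labeled frame intervals tying external events (stimuli, behaviors) to a
#' recording. Frames are 0-based and intervals half-open `[start, end)`, so
#' back-to-back trials concatenate without overlap. Intervals may repeat a
#' label (trials) but may not overlap one another.
#'
#' @param label character vector of interval labels.
#' @param start_frame,end_frame integer vectors, `0 <= start < end`.
#' @return an object of class `stimulus_map` (a data frame sorted by
#'   `start_frame`).
#' @export
stimulus_map <- function(label, start_frame, end_frame) {
  label <- as.character(label)
  start_frame <- as.integer(start_frame)
  end_frame <- as.integer(end_frame)
  n <- length(label)
  if (length(start_frame) != n || length(end_frame) != n)
    stop("label, start_frame and end_frame must have equal length")
  if (any(start_frame < 0L))
    stop("validation error: start_frame must be >= 0")
  bad <- which(start_frame >= end_frame)
  if (length(bad))
    stop(sprintf("validation error: empty or inverted interval '%s' [%d, %d)",
                 label[bad[1]], start_frame[bad[1]], end_frame[bad[1]]))
  o <- order(start_frame, end_frame)
  label <- label[o]; start_frame <- start_frame[o]; end_frame <- end_frame[o]
  if (n > 1L) {
    ov <- which(start_frame[-1] < end_frame[-n])
    if (length(ov))
      stop(sprintf(
        "validation error: overlapping intervals '%s' [%d, %d) and '%s' [%d, %d)",
        label[ov[1]], start_frame[ov[1]], end_frame[ov[1]],
        label[ov[1] + 1L], start_frame[ov[1] + 1L], end_frame[ov[1] + 1L]))
  }
  structure(data.frame(label = label, start_frame = start_frame,
                       end_frame = end_frame, stringsAsFactors = FALSE),
            class = c("stimulus_map", "data.frame"))
}

#' Read a stimulus map from delimited text
#'
#' Columns `label,start_frame,end_frame`; frames 0-based, intervals
#' half-open.
#'
#' @param path file path to a CSV file.
#' @return a [stimulus_map()].
#' @export
load_stimulus_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "start_frame", "end_frame")
  if (!all(need %in% names(df)))
    stop("format error: stimulus map needs columns label,start_frame,end_frame")
  stimulus_map(df$label, df$start_frame, df$end_frame)
}

#' Write a stimulus map to delimited text
#' @param x a [stimulus_map()].
#' @param path output file path.
#' @export
write_stimulus_map <- function(x, path) {
  stopifnot(inherits(x, "stimulus_map"))
  utils::write.csv(as.data.frame(unclass(x)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @export
print.stimulus_map <- function(x, ...) {
  cat(sprintf("<stimulus_map> %d intervals, %d labels, frames [%d, %d)\n",
              nrow(x), length(unique(x$label)),
              min(x$start_frame), max(x$end_frame)))
  print.data.frame(x, ...)
  invisible(x)
}

# ---- provenance -----------------------------------------------------------

#' Create an empty provenance log
#'
#' Analysis lineage as an append-only list of records, each tagged with a
#' fresh version-4 UUID and ISO-8601 UTC timestamp. A record names an
#' operation, its parameters, the UUIDs it consumed and the UUIDs it
#' produced; inputs must already be known to the log (raw data or outputs
#' of earlier records), which keeps the dependency graph acyclic.
#'
#' @param raw_uuids character vector of UUIDs registered as raw data roots.
#' @return an object of class `provenance_log`.
#' @export
provenance_log <- function(raw_uuids = character()) {
  structure(list(records = list(), raw = as.character(raw_uuids)),
            class = "provenance_log")
}

#' Register raw-data UUIDs with a provenance log
#' @param log a [provenance_log()].
#' @param uuids character vector of UUIDs to register as roots.
#' @export
register_raw <- function(log, uuids) {
  stopifnot(inherits(log, "provenance_log"))
  log$raw <- unique(c(log$raw, as.character(uuids)))
  log
}

prov_known <- function(log) {
  c(log$raw, unlist(lapply(log$records, `[[`, "outputs"), use.names = FALSE))
}

#' Append a provenance record
#'
#' @param log a [provenance_log()].
#' @param op operation name.
#' @param params named list of parameters (must be JSON-serializable).
#' @param inputs UUIDs consumed; each must be a raw root or an output of an
#'   earlier record.
#' @param outputs UUIDs produced; must be fresh.
#' @return the updated log.
#' @export
record_provenance <- function(log, op, params = list(),
                              inputs = character(), outputs = character()) {
  stopifnot(inherits(log, "provenance_log"))
  inputs <- as.character(inputs); outputs <- as.character(outputs)
  known <- prov_known(log)
  miss <- setdiff(inputs, known)
  if (length(miss))
    stop("lineage error: unknown input UUID(s): ", paste(miss, collapse = ", "))
  if (any(outputs %in% inputs))
    stop("lineage error: record lists one of its own outputs as an input")
  if (any(outputs %in% known))
    stop("lineage error: output UUID already produced: ",
         paste(intersect(outputs, known), collapse = ", "))
  rec <- list(record_uuid = new_uuid(1L), op = as.character(op),
              params = params, inputs = inputs, outputs = outputs,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z",
                                 tz = "UTC"))
  log$records[[length(log$records) + 1L]] <- rec
  log
}

#' Trace a UUID back to its raw-data ancestors
#'
#' Walks the dependency graph of the log from `uuid` to the registered raw
#' roots it derives from.
#'
#' @param log a [provenance_log()].
#' @param uuid the UUID to trace.
#' @return character vector of raw root UUIDs reachable from `uuid`.
#' @export
trace_lineage <- function(log, uuid) {
  stopifnot(inherits(log, "provenance_log"))
  frontier <- as.character(uuid)
  seen <- character()
  roots <- character()
  while (length(frontier)) {
    id <- frontier[1]; frontier <- frontier[-1]
    if (id %in% seen) next
    seen <- c(seen, id)
    if (id %in% log$raw) roots <- c(roots, id)
    for (rec in log$records)
      if (id %in% rec$outputs) frontier <- c(frontier, rec$inputs)
  }
  unique(roots)
}

#' Serialize / deserialize a provenance log as JSON
#'
#' The JSON round trip is lossless: `read_provenance(write_provenance(x))`
#' reproduces the log exactly.
#'
#' @param log a [provenance_log()].
#' @param path output (input) file path.
#' @return `write_provenance` returns the path; `read_provenance` the log.
#' @export
write_provenance <- function(log, path) {
  stopifnot(inherits(log, "provenance_log"))
  jsonlite::write_json(list(raw = log$raw, records = log$records), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_provenance
#' @export
read_provenance <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  log <- provenance_log(unlist(x$raw, use.names = FALSE))
  log$records <- lapply(x$records, function(r)
    list(record_uuid = r$record_uuid, op = r$op,
         params = lapply(r$params, function(p)
           if (is.list(p)) unlist(p, use.names = FALSE) else p),
         inputs = as.character(unlist(r$inputs, use.names = FALSE)),
         outputs = as.character(unlist(r$outputs, use.names = FALSE)),
         timestamp = r$timestamp))
  log
}

#' @export
print.provenance_log <- function(x, ...) {
  cat(sprintf("<provenance_log> %d raw roots, %d records\n",
              length(x$raw), length(x$records)))
  for (rec in x$records)
    cat(sprintf("  %s %s (%d in -> %d out)\n",
                substr(rec$record_uuid, 1, 8), rec$op,
                length(rec$inputs), length(rec$outputs)))
  invisible(x)
}

#' Read / write per-cell annotations as JSON
#'
#' Annotations are a named list mapping a tag name to one categorical label
#' per cell, keyed by cell UUID in the file.
#'
#' @param x a [trace_set()].
#' @param path file path.
#' @export
write_annotations <- function(x, path) {
  stopifnot(inherits(x, "trace_set"))
  out <- lapply(x$annotations, function(v) as.list(setNames(v, x$cell_ids)))
  jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(x, path) {
  stopifnot(inherits(x, "trace_set"))
  ann <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$annotations <- lapply(ann, function(v) {
    if (!all(x$cell_ids %in% names(v)))
      stop("annotation file missing labels for some cells")
    unname(unlist(v)[x$cell_ids])
  })
  x
}
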