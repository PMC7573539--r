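#' Continuous multichannel recording
#'
#' Lightweight container for a block of continuously sampled signals
#' (EEG/EOG in microvolts, or normalized cursor distance) with a sampling
#' rate, channel metadata and an event list. All event times are in seconds
#' from the start of the block.
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate, Hz.
#' @param channel_names character vector, one per row of `data`.
#' @param channel_types character vector: `"eeg"`, `"eog"` or `"cursor"`.
#' @param events data.frame with columns `label` and `time` (seconds).
#' @return object of class `recording`.
#' @export
new_recording <- function(data, fs, channel_names, channel_types,
                          events = data.frame(label = character(),
                                              time = numeric())) {
  data <- rbind(data)
  .check_positive(fs, "fs")
  if (length(channel_names) != nrow(data) ||
      length(channel_types) != nrow(data)) {
    stop("channel metadata must match the number of rows in `data`")
  }
  dur <- ncol(data) / fs
  if (nrow(events) && any(events$time < 0 | events$time > dur)) {
    stop("event times must lie within the recording duration")
  }
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 channel_types = channel_types, events = events),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels (%s) x %d samples @ %g Hz, %d events\n",
              nrow(x$data),
              paste(sprintf("%d %s", table(x$channel_types),
                            names(table(x$channel_types))), collapse = ", "),
              ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}

#' Subset a recording by channel type
#'
#' @param rec a `recording`.
#' @param types channel types to keep.
#' @return `recording` restricted to the requested channels.
#' @export
pick_channels <- function(rec, types) {
  keep <- rec$channel_types %in% types
  if (!any(keep)) stop("no channels of the requested type")
  new_recording(rec$data[keep, , drop = FALSE], rec$fs,
                rec$channel_names[keep], rec$channel_types[keep], rec$events)
}

# replace the data matrix, keeping metadata (sample count may change only
# together with fs)
.set_data <- function(rec, data, fs = rec$fs) {
  new_recording(data, fs, rec$channel_names, rec$channel_types, rec$events)
}

#' Write / read BIDS-style events tables
#'
#' Events are stored as tab-separated text with the conventional
#' `onset`, `duration`, `trial_type` columns; extra columns (detected onsets,
#' outlier flags) pass through unchanged.
#'
#' @param events data.frame with at least `onset`, `duration`, `trial_type`.
#' @param path file path, conventionally ending in `events.tsv`.
#' @return `read_events_tsv` returns the data.frame.
#' @export
write_events_tsv <- function(events, path) {
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(events))) {
    stop("events must contain columns onset, duration, trial_type")
  }
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "n/a",
                    stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# dataset container: one directory per object, TSV payload + JSON metadata.

.DATASET_SCHEMA <- "deltamotor-dataset"
.DATASET_VERSION <- 1L

.write_matrix_tsv <- function(m, path) {
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

.read_matrix_tsv <- function(path, nrow, ncol) {
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t",
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  if (!is.null(nrow) && (base::nrow(m) != nrow || base::ncol(m) != ncol)) {
    stop("dataset payload shape does not match its metadata")
  }
  m
}

#' Persist pipeline objects as plain-text dataset directories
#'
#' Serializes a `recording`, trial table, `epochs` array, source map or
#' accuracy curve to a directory holding TSV payloads plus a JSON metadata
#' file (schema-versioned), and reads it back losslessly (full double
#' precision). Recordings additionally emit a BIDS-style `events.tsv`.
#'
#' @param x object to write.
#' @param path dataset directory.
#' @return `dataset_read` returns the reconstructed object.
#' @export
dataset_write <- function(x, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(schema = .DATASET_SCHEMA, version = .DATASET_VERSION)
  if (inherits(x, "recording")) {
    meta$kind <- "recording"
    meta$fs <- x$fs
    meta$channel_names <- x$channel_names
    meta$channel_types <- x$channel_types
    meta$dim <- dim(x$data)
    .write_matrix_tsv(x$data, file.path(path, "data.tsv"))
    ev <- x$events
    write_events_tsv(
      data.frame(onset = if (nrow(ev)) ev$time else numeric(),
                 duration = rep(0, nrow(ev)),
                 trial_type = if (nrow(ev)) ev$label else character()),
      file.path(path, "events.tsv"))
  } else if (inherits(x, "epochs")) {
    meta$kind <- "epochs"
    meta$fs <- x$fs
    meta$alignment <- x$alignment
    meta$band <- x$band
    meta$time <- x$time
    meta$channel_names <- x$channel_names
    meta$dim <- dim(x$data)
    meta$rejected <- x$rejected
    flat <- matrix(x$data, nrow = dim(x$data)[1])
    .write_matrix_tsv(flat, file.path(path, "data.tsv"))
  } else if (is.data.frame(x)) {
    meta$kind <- "table"
    utils::write.table(x, file.path(path, "table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "n/a")
    meta$classes <- vapply(x, function(col) class(col)[1], character(1))
  } else if (is.list(x) && !is.null(x$values) && is.matrix(x$values)) {
    # source maps, accuracy curves: matrix payload + scalar metadata
    meta$kind <- "matrix_bundle"
    meta$dim <- dim(x$values)
    extra <- x[setdiff(names(x), "values")]
    keep <- vapply(extra, function(el) is.atomic(el) && length(el) < 10000,
                   logical(1))
    meta$extra <- extra[keep]
    .write_matrix_tsv(x$values, file.path(path, "data.tsv"))
  } else {
    stop("unsupported object kind for dataset_write")
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname dataset_write
#' @export
dataset_read <- function(path) {
  mpath <- file.path(path, "meta.json")
  if (!file.exists(mpath)) stop("not a dataset directory: missing meta.json")
  meta <- tryCatch(jsonlite::read_json(mpath, simplifyVector = TRUE),
                   error = function(e) stop("corrupted dataset metadata"))
  if (!identical(meta$schema, .DATASET_SCHEMA)) {
    stop("dataset schema mismatch: ", meta$schema)
  }
  if (!identical(as.integer(meta$version), .DATASET_VERSION)) {
    stop("dataset schema version mismatch: ", meta$version)
  }
  switch(meta$kind,
    recording = {
      d <- .read_matrix_tsv(file.path(path, "data.tsv"),
                            meta$dim[1], meta$dim[2])
      ev <- read_events_tsv(file.path(path, "events.tsv"))
      new_recording(d, meta$fs, meta$channel_names, meta$channel_types,
                    data.frame(label = as.character(ev$trial_type),
                               time = ev$onset))
    },
    epochs = {
      flat <- .read_matrix_tsv(file.path(path, "data.tsv"), meta$dim[1],
                               meta$dim[2] * meta$dim[3])
      arr <- array(flat, dim = meta$dim)
      new_epochs(arr, time = meta$time, fs = meta$fs,
                 alignment = meta$alignment, band = meta$band,
                 channel_names = meta$channel_names,
                 rejected = meta$rejected)
    },
    table = {
      tb <- utils::read.table(file.path(path, "table.tsv"), header = TRUE,
                              sep = "\t", na.strings = "n/a",
                              stringsAsFactors = FALSE)
      for (nm in names(meta$classes)) {
        cl <- meta$classes[[nm]]
        if (cl == "numeric") tb[[nm]] <- as.numeric(tb[[nm]])
        if (cl == "integer") tb[[nm]] <- as.integer(tb[[nm]])
        if (cl == "logical") tb[[nm]] <- as.logical(tb[[nm]])
        if (cl == "character") tb[[nm]] <- as.character(tb[[nm]])
      }
      tb
    },
    matrix_bundle = {
      v <- .read_matrix_tsv(file.path(path, "data.tsv"),
                            meta$dim[1], meta$dim[2])
      c(list(values = v), meta$extra)
    },
    stop("unknown dataset kind: ", meta$kind)
  )
}
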