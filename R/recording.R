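#' Epoched multichannel EEG recording
#'
#' Container for one subject-by-condition recording: a list of epochs, each a
#' channels x samples numeric matrix (microvolts), plus sampling rate and
#' channel labels. All epochs must share the same shape.
#'
#' @param epochs list of numeric matrices, each `channels x samples`.
#' @param fs sampling rate in Hz.
#' @param channels character vector of unique channel labels (one per row).
#' @param subject_id subject identifier (optional).
#' @param group group label, e.g. `"typical"` or `"dyslexic"` (optional).
#' @param condition condition label, e.g. `"baseline"` or `"task"` (optional).
#' @param band a [band_spec] if the data have already been band-filtered,
#'   otherwise `NULL` (broadband).
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(epochs, fs, channels = NULL, subject_id = NA_character_,
                          group = NA_character_, condition = NA_character_,
                          band = NULL) {
  if (!is.list(epochs) || length(epochs) == 0L)
    stop("epochs must be a non-empty list of matrices")
  epochs <- lapply(epochs, function(e) {
    e <- as.matrix(e)
    storage.mode(e) <- "double"
    e
  })
  dims <- vapply(epochs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all epochs must have identical channels x samples shape")
  n_ch <- dims[1, 1]
  if (is.null(channels)) channels <- paste0("ch", seq_len(n_ch))
  channels <- as.character(channels)
  if (length(channels) != n_ch) stop("channel label count does not match rows")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive sampling rate in Hz")
  epochs <- lapply(epochs, function(e) { rownames(e) <- channels; e })
  structure(list(epochs = epochs, fs = as.numeric(fs), channels = channels,
                 subject_id = subject_id, group = group, condition = condition,
                 band = band),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s/%s/%s: %d channels x %d epochs x %d samples @ %g Hz%s\n",
    x$subject_id, x$group, x$condition,
    n_channels(x), n_epochs(x), n_samples(x), x$fs,
    if (is.null(x$band)) "" else sprintf(" [%s band]", x$band$name)))
  invisible(x)
}

#' @rdname eeg_recording
#' @param rec an `eeg_recording`.
#' @export
n_channels <- function(rec) nrow(rec$epochs[[1]])

#' @rdname eeg_recording
#' @export
n_epochs <- function(rec) length(rec$epochs)

#' @rdname eeg_recording
#' @export
n_samples <- function(rec) ncol(rec$epochs[[1]])

#' @rdname eeg_recording
#' @export
epoch_duration <- function(rec) n_samples(rec) / rec$fs

#' Write an epoched recording to a plain-text (ASCII) epoch file
#'
#' One file per subject-by-condition. The dialect is self-describing:
#' `#`-prefixed metadata lines (`fs`, `subject`, `group`, `condition`), a
#' tab-separated header of channel labels, then epochs concatenated
#' vertically, each introduced by a `# epoch k` line, rows = samples,
#' columns = channels.
#'
#' @param rec an [eeg_recording].
#' @param path output file path.
#' @param digits significant digits written (default 10). Values round-trip
#'   through [read_ascii_epochs] exactly at this precision.
#' @return `path`, invisibly.
#' @export
write_ascii_epochs <- function(rec, path, digits = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  meta <- c(sprintf("# fs %.10g", rec$fs),
            sprintf("# subject %s", rec$subject_id),
            sprintf("# group %s", rec$group),
            sprintf("# condition %s", rec$condition))
  writeLines(meta, con)
  writeLines(paste(rec$channels, collapse = "\t"), con)
  fmt <- paste0("%.", digits, "g")
  for (k in seq_along(rec$epochs)) {
    writeLines(sprintf("# epoch %d", k), con)
    # rows = samples, columns = channels
    m <- t(rec$epochs[[k]])
    lines <- apply(m, 1L, function(row) paste(sprintf(fmt, row), collapse = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a plain-text (ASCII) epoch file
#'
#' Parses the dialect written by [write_ascii_epochs]. Metadata present in
#' the file supplies defaults; explicit arguments override them.
#'
#' @param path input file path.
#' @param fs sampling rate in Hz; required if not recorded in the file.
#' @param channel_labels optional channel labels overriding the file header.
#' @return An [eeg_recording].
#' @export
read_ascii_epochs <- function(path, fs = NULL, channel_labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- list(subject = NA_character_, group = NA_character_,
               condition = NA_character_)
  header <- NULL
  epochs <- list()
  cur <- NULL       # accumulating rows of the current epoch
  n_col <- NA_integer_

  flush_epoch <- function() {
    if (!is.null(cur) && length(cur) > 0L)
      epochs[[length(epochs) + 1L]] <<- do.call(rbind, cur)
    cur <<- NULL
  }

  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#")) {
      body <- trimws(sub("^#", "", line))
      toks <- strsplit(body, "\\s+")[[1]]
      if (length(toks) >= 1L && toks[1] == "epoch") {
        flush_epoch()
        cur <- list()
      } else if (length(toks) >= 2L && toks[1] == "fs") {
        if (is.null(fs)) fs <- as.numeric(toks[2])
      } else if (length(toks) >= 2L && toks[1] %in% names(meta)) {
        meta[[toks[1]]] <- toks[2]
      }
      next
    }
    vals <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (is.null(header)) {
      header <- vals
      n_col <- length(vals)
      next
    }
    if (length(vals) != n_col)
      stop(sprintf("ragged row at line %d: expected %d columns, found %d",
                   ln, n_col, length(vals)))
    num <- suppressWarnings(as.numeric(vals))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1]
      stop(sprintf("non-numeric value '%s' at line %d, column %d",
                   vals[bad], ln, bad))
    }
    if (is.null(cur)) cur <- list()  # tolerate files without '# epoch' markers
    cur[[length(cur) + 1L]] <- num
  }
  flush_epoch()
  if (is.null(header) || length(epochs) == 0L)
    stop("no epoch data found in ", path)
  if (is.null(fs)) stop("fs not given and not recorded in file")
  labels <- if (!is.null(channel_labels)) channel_labels else header
  eeg_recording(lapply(epochs, t), fs = fs, channels = labels,
                subject_id = meta$subject, group = meta$group,
                condition = meta$condition)
}
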