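#' Multichannel EEG record
#'
#' Container for a multichannel scalp EEG recording: an amplitude matrix
#' (one row per channel, in microvolts), the sampling rate, unique channel
#' labels (bipolar montage names such as `"FP1-F7"`), and optional seizure
#' annotations. Missing samples are stored as `NA`.
#'
#' @param data numeric matrix, channels x samples (microvolts); `NA` marks
#'   missing samples.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of unique channel names, one per
#'   row of `data`.
#' @param annotations `NULL` or a data.frame with columns `onset`, `offset`
#'   (seconds) and `label`; intervals must lie within the record.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(data, fs, channel_labels = rownames(data),
                       annotations = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("'data' must be a numeric channels x samples matrix", call. = FALSE)
  }
  stopifnot_scalar(fs, "fs")
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("CH%d", seq_len(nrow(data)))
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data)) {
    stop("one channel label per data row is required", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  dur <- ncol(data) / fs
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    need <- c("onset", "offset", "label")
    if (!all(need %in% names(annotations))) {
      stop("annotations need columns onset, offset, label", call. = FALSE)
    }
    if (nrow(annotations) &&
        (any(annotations$onset < 0) || any(annotations$offset > dur + 1e-9) ||
         any(annotations$offset < annotations$onset))) {
      stop("annotation intervals must lie within [0, record length]",
           call. = FALSE)
    }
  }
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 annotations = annotations),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  n_ann <- if (is.null(x$annotations)) 0L else nrow(x$annotations)
  cat(sprintf("  annotations: %d; missing samples: %d\n",
              n_ann, sum(is.na(x$data))))
  invisible(x)
}

#' Fixed-duration labelled EEG segment
#'
#' A fixed-length window cut from a record, labelled `"seizure"` or
#' `"nonseizure"`. These 60-second blocks are the observations the
#' classification protocol operates on.
#'
#' @param data channels x samples matrix.
#' @param fs sampling rate (Hz).
#' @param channel_labels unique channel names.
#' @param label `"seizure"` or `"nonseizure"`.
#' @param source_id provenance string.
#' @return An object of class `segment_block`.
#' @export
segment_block <- function(data, fs, channel_labels = rownames(data),
                          label = c("nonseizure", "seizure"),
                          source_id = "") {
  label <- match.arg(label)
  rec <- eeg_record(data, fs, channel_labels)
  structure(list(data = rec$data, fs = fs,
                 channel_labels = rec$channel_labels,
                 label = label, source_id = as.character(source_id)),
            class = "segment_block")
}

#' @export
print.segment_block <- function(x, ...) {
  cat(sprintf("<segment_block> %s: %d channels x %d samples @ %g Hz\n",
              x$label, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' Read an EEG record from disk
#'
#' Two on-disk layouts are supported. `"tabular"` is a comma-separated text
#' file whose first column is elapsed time in seconds followed by one column
#' per channel; dash (`-`) entries are read as missing samples (`NA`) for
#' downstream repair. `"edf"` reads a minimal European Data Format file
#' (signals and labels; EDF+ annotations are not parsed).
#'
#' @param path file to read.
#' @param format `"tabular"` or `"edf"`; default guesses from the extension.
#' @param fs sampling rate for tabular files with fewer than two time points
#'   (otherwise inferred from the time column).
#' @return An [eeg_record].
#' @export
read_eeg_record <- function(path, format = c("auto", "tabular", "edf"),
                            fs = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "tabular"
  }
  if (format == "edf") return(read_edf(path))
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "-")
  if (ncol(df) < 2L) stop("tabular record needs a time column plus channels",
                          call. = FALSE)
  labels <- names(df)[-1L]
  if (anyDuplicated(labels)) {
    stop("format error: duplicate channel label in ", path, call. = FALSE)
  }
  df[] <- lapply(df, function(col) as.numeric(as.character(col)))
  if (is.null(fs)) {
    tm <- df[[1L]]
    if (length(tm) < 2L) stop("format error: cannot infer sampling rate",
                              call. = FALSE)
    dt <- diff(tm)
    if (any(!is.finite(dt)) || any(dt <= 0)) {
      stop("format error: time column must be increasing", call. = FALSE)
    }
    fs <- 1 / stats::median(dt)
  }
  data <- t(as.matrix(df[, -1L, drop = FALSE]))
  eeg_record(data, fs = fs, channel_labels = labels)
}

#' Write an EEG record to disk
#'
#' Inverse of [read_eeg_record()]. Tabular output serialises missing samples
#' as `"-"`; EDF output quantises to 16-bit integers over the per-channel
#' physical range (missing samples are written as zeros).
#'
#' @param record an [eeg_record].
#' @param path destination file.
#' @param format `"tabular"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_eeg_record <- function(record, path, format = c("tabular", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "eeg_record"))
  if (format == "edf") {
    write_edf(record, path)
  } else {
    n <- ncol(record$data)
    tm <- (seq_len(n) - 1L) / record$fs
    cols <- c(list(format(tm, trim = TRUE)),
              lapply(seq_len(nrow(record$data)), function(i) {
                v <- format(record$data[i, ], trim = TRUE, digits = 10)
                v[is.na(record$data[i, ])] <- "-"
                v
              }))
    df <- as.data.frame(cols, optional = TRUE)
    names(df) <- c("time_s", record$channel_labels)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Read / write a seizure annotation sidecar
#'
#' A small CSV (columns `record_id`, `onset`, `offset`, `label`) mirroring
#' the per-record seizure summaries that accompany public scalp-EEG archives.
#'
#' @param path file path.
#' @return `read_annotations` returns a data.frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c("character", "numeric", "numeric",
                                       "character"))
  need <- c("record_id", "onset", "offset", "label")
  if (!identical(names(df), need)) {
    stop("annotation file must have columns record_id, onset, offset, label",
         call. = FALSE)
  }
  df
}

#' @param annotations data.frame with columns `record_id`, `onset`, `offset`,
#'   `label`.
#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  need <- c("record_id", "onset", "offset", "label")
  if (!all(need %in% names(annotations))) {
    stop("annotations need columns record_id, onset, offset, label",
         call. = FALSE)
  }
  utils::write.csv(annotations[, need], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write / read a feature table
#'
#' Serialises a [feature_matrix] as CSV: one header row of descriptor
#' strings (e.g. `"RMS CH2 0.5-30 Hz"`) plus a final `label` column, one row
#' per observation. `read_feature_table` reconstructs the matrix, parsing
#' each descriptor back into its (feature, channel, band) triple.
#'
#' @param matrix a non-empty [feature_matrix].
#' @param path file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a [feature_matrix].
#' @export
write_feature_table <- function(matrix, path) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (!nrow(matrix$values) || !ncol(matrix$values)) {
    stop("feature matrix is empty", call. = FALSE)
  }
  df <- as.data.frame(matrix$values, optional = TRUE)
  names(df) <- descriptor_names(matrix$descriptors)
  df$label <- as.character(matrix$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  # descriptor sidecar columns are recoverable from the header strings; the
  # exact descriptor table is also written alongside for lossless round trip
  utils::write.csv(matrix$descriptors, paste0(path, ".descriptors"),
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) {
    stop("feature table must contain a 'label' column", call. = FALSE)
  }
  labels <- df$label
  df$label <- NULL
  side <- paste0(path, ".descriptors")
  if (file.exists(side)) {
    desc <- utils::read.csv(side, check.names = FALSE)
  } else {
    parts <- strsplit(names(df), " ")
    desc <- data.frame(
      feature = vapply(parts, function(p)
        paste(p[seq_len(length(p) - 3L)], collapse = " "), ""),
      channel = vapply(parts, function(p) p[length(p) - 2L], ""),
      band = vapply(parts, function(p)
        paste(p[length(p) - 1L], p[length(p)]), ""),
      stringsAsFactors = FALSE)
  }
  feature_matrix(as.matrix(df), desc, labels)
}

# ---- minimal EDF codec ------------------------------------------------------
# European Data Format: 256-byte global header, 256 bytes per signal of field
# headers, then data records of 16-bit little-endian integers. One data record
# per second is written. Signals + labels only.

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(record, path) {
  data <- record$data
  data[is.na(data)] <- 0
  ns <- nrow(data)
  fs <- record$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  n_rec <- ceiling(ncol(data) / fs)
  if (n_rec * fs != ncol(data)) {  # pad the final second with zeros
    data <- cbind(data, matrix(0, ns, n_rec * fs - ncol(data)))
  }
  pmin_ <- apply(data, 1L, min)
  pmax_ <- apply(data, 1L, max)
  same <- pmax_ - pmin_ < 1e-12
  pmax_[same] <- pmin_[same] + 1
  # physical min/max live in 8-character ASCII fields; widen the range a
  # whisker, format to 6 significant digits, and use the PARSED field values
  # for quantisation so reader and writer share the exact same scale
  span <- pmax_ - pmin_
  pmin_s <- sprintf("%.6g", pmin_ - 1e-4 * span)
  pmax_s <- sprintf("%.6g", pmax_ + 1e-4 * span)
  if (any(nchar(c(pmin_s, pmax_s)) > 8L)) {
    stop("physical range not representable in an EDF header field",
         call. = FALSE)
  }
  pmin_ <- as.numeric(pmin_s)
  pmax_ <- as.numeric(pmax_s)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L), edf_pad("X", 80L), edf_pad("X", 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(256L * (1L + ns), 8L), edf_pad("", 44L),
    edf_pad(n_rec, 8L), edf_pad(1L, 8L), edf_pad(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(edf_pad(record$channel_labels, 16L), collapse = ""),
            con, eos = NULL)
  writeChar(strrep(" ", 80L * ns), con, eos = NULL)   # transducer
  writeChar(paste0(edf_pad(rep("uV", ns), 8L), collapse = ""), con, eos = NULL)
  writeChar(paste0(edf_pad(pmin_s, 8L), collapse = ""), con, eos = NULL)
  writeChar(paste0(edf_pad(pmax_s, 8L), collapse = ""), con, eos = NULL)
  writeChar(paste0(edf_pad(rep(-32768L, ns), 8L), collapse = ""),
            con, eos = NULL)
  writeChar(paste0(edf_pad(rep(32767L, ns), 8L), collapse = ""),
            con, eos = NULL)
  writeChar(strrep(" ", 80L * ns), con, eos = NULL)   # prefiltering
  writeChar(paste0(edf_pad(rep(fs, ns), 8L), collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 32L * ns), con, eos = NULL)   # reserved
  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((data[s, idx] - pmin_[s]) / scale[s]) - 32768
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  rd(8L)  # header bytes
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L) stop("format error: bad EDF header", call. = FALSE)
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16L), ""))
  rd(80L * ns); rd(8L * ns)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), ""))
  rd(80L * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), ""))
  rd(32L * ns)
  if (anyDuplicated(labels)) {
    stop("format error: duplicate channel label in EDF", call. = FALSE)
  }
  out <- lapply(seq_len(ns), function(s) numeric(n_rec * spr[s]))
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- pmin_[s] + (dig - dmin_[s]) *
        (pmax_[s] - pmin_[s]) / (dmax_[s] - dmin_[s])
      out[[s]][((r - 1L) * spr[s] + 1L):(r * spr[s])] <- phys
    }
  }
  fs <- spr[1L] / rec_dur
  if (any(spr != spr[1L])) {
    stop("format error: per-signal sampling rates differ", call. = FALSE)
  }
  eeg_record(do.call(rbind, out), fs = fs, channel_labels = labels)
}
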