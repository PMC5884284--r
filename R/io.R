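# Plain-text I/O. Records travel as TSV with one row per channel: a
# leading `channel` name column followed by the samples, with a header
# line. (EDF input is not supported by this package; convert to TSV.)

#' Read a multichannel record from TSV
#'
#' Expects a header line and one row per channel: first field the
#' channel name, remaining fields the samples. When a montage is given,
#' rows are re-ordered to the montage's canonical channel order and any
#' missing channel is an explicit error.
#'
#' @param path File path.
#' @param montage Optional `pc_montage` fixing channel order.
#' @param fs Sampling rate in Hz to attach (TSV has no header for it).
#' @return channels x samples numeric matrix with channel rownames and
#'   attribute `fs`.
#' @export
read_record <- function(path, montage = NULL, fs = 256) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ch <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- ch
  if (!is.null(montage)) {
    idx <- match(montage$channel, ch)
    if (anyNA(idx)) {
      stop("record is missing channel(s): ",
           paste(montage$channel[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    mat <- mat[idx, , drop = FALSE]
  }
  colnames(mat) <- NULL
  attr(mat, "fs") <- fs
  mat
}

#' Write a multichannel record as TSV
#'
#' @param data channels x samples matrix with channel rownames, or a
#'   `pc_record`.
#' @param path File path.
#' @export
write_record <- function(data, path) {
  if (inherits(data, "pc_record")) data <- data$data
  df <- data.frame(channel = rownames(data), data, check.names = FALSE)
  names(df) <- c("channel", seq_len(ncol(data)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cluster record as hex-label TSV, one file per band
#'
#' Each band's channels x samples grid of hexadecimal labels is written
#' as TSV (leading `channel` column), together with one JSON sidecar
#' recording the clustering threshold, sampling rate, band grid and
#' bit-order manifest.
#'
#' @param record A `pc_cluster_record`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Paths written, invisibly.
#' @export
write_cluster_record <- function(record, dir, prefix = "ceeg") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(record)
  width <- attr(record, "total_bits") %/% 4L
  ch <- attr(record, "channels") %||% as.character(seq_len(d[1]))
  grid <- attr(record, "grid")
  paths <- character(0)
  for (k in seq_len(d[3])) {
    hex <- matrix(sprintf("%0*X", width, as.integer(record[, , k])), nrow = d[1])
    lab <- if (!is.null(grid)) grid$label[k] else as.character(k)
    p <- file.path(dir, sprintf("%s_band_%s.tsv", prefix, gsub("[.]", "p", lab)))
    df <- data.frame(channel = ch, hex, check.names = FALSE)
    names(df) <- c("channel", seq_len(d[2]))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  sidecar <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(list(
    r = attr(record, "r"), fs = attr(record, "fs"),
    centers_hz = if (!is.null(grid)) grid$center_hz else NULL,
    channels = ch,
    bit_order = "montage order, first channel = most significant bit, zero-padded to whole hex digits"
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, sidecar))
}
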