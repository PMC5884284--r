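# Time-Frequency-Topography maps: windowed cluster modes of the label
# record (TFT), intertrial cluster modes across epochs (ITCM), and their
# windowed form (iTFT). All mode rules are strict-majority: a label is
# assigned only if it occurs in strictly more than rho percent of the
# constituents and is the unique most frequent label; otherwise the cell
# is unassigned (all-zero label).

.mode_code <- function(codes, rho) {
  u <- unique(codes)
  if (length(u) == 1L) {
    return(if (100 > rho) u else 0L)
  }
  tab <- tabulate(match(codes, u))
  m <- max(tab)
  if (sum(tab == m) > 1L) return(0L)          # multimodal tie
  if (m / length(codes) * 100 <= rho) return(0L)
  u[which.max(tab)]
}

#' Segment a labeled cluster record into condition epochs
#'
#' Slices the cluster-label record into epochs according to a flash
#' schedule, one stack per condition. Labels are sliced, never
#' recomputed, so identical labels mean identical clusters across
#' conditions (labeling precedes segmentation in the pipeline).
#' Overlapping epochs are permitted and share the underlying labels.
#'
#' @param record A `pc_cluster_record` from [cluster_series()].
#' @param schedule A `pc_schedule` ([speller_schedule()] /
#'   [read_schedule()]); its `epoch_window` attribute gives the window
#'   (samples, relative to the 0-based onset).
#' @return A named list of `pc_epoch_stack` arrays, one per condition:
#'   epochs x channels x samples x bands integer label codes.
#' @export
segment_epochs <- function(record, schedule) {
  win <- attr(schedule, "epoch_window")
  L <- win[2] - win[1] + 1L
  d <- dim(record)
  conditions <- unique(schedule$condition)
  out <- list()
  for (cond in conditions) {
    onsets <- schedule$onset_sample[schedule$condition == cond]
    starts <- onsets + win[1]               # onset is 0-based
    if (length(starts) && (min(starts) < 1L || max(starts) + L - 1L > d[2])) {
      stop("epoch window exceeds record bounds for condition ", cond,
           call. = FALSE)
    }
    stack <- array(NA_integer_, dim = c(length(starts), d[1], L, d[3]))
    for (e in seq_along(starts)) {
      stack[e, , , ] <- record[, starts[e]:(starts[e] + L - 1L), , drop = FALSE]
    }
    out[[cond]] <- structure(stack, class = "pc_epoch_stack",
                             channels = attr(record, "channels"),
                             grid = attr(record, "grid"),
                             fs = attr(record, "fs"),
                             r = attr(record, "r"),
                             total_bits = attr(record, "total_bits"),
                             condition = cond)
  }
  out
}

#' Windowed cluster modes of a label grid
#'
#' Tiles the sample axis into consecutive non-overlapping windows of
#' `upsilon` samples (left-aligned; a trailing partial window is
#' dropped) and assigns, per channel and window, the modal label under
#' the strict-majority rule: assigned only if its count exceeds
#' `rho` percent of `upsilon` strictly and the mode is unique.
#'
#' @param labels channels x samples integer matrix of label codes.
#' @param upsilon Window size in samples (>= 1).
#' @param rho Mode-frequency threshold in percent, `0 <= rho < 100`.
#' @return channels x windows integer matrix of label codes (0 =
#'   unassigned).
#' @export
windowed_modes <- function(labels, upsilon, rho = 50) {
  stopifnot(upsilon >= 1, rho >= 0, rho < 100)
  labels <- rbind(labels)
  N <- ncol(labels)
  if (upsilon > N) stop("window size upsilon exceeds the segment", call. = FALSE)
  n_win <- N %/% upsilon
  out <- matrix(0L, nrow(labels), n_win)
  for (w in seq_len(n_win)) {
    cols <- ((w - 1L) * upsilon + 1L):(w * upsilon)
    for (j in seq_len(nrow(labels))) {
      out[j, w] <- .mode_code(labels[j, cols], rho)
    }
  }
  rownames(out) <- rownames(labels)
  out
}

.new_tft <- function(arr, upsilon, rho, src) {
  structure(arr, upsilon = upsilon, rho = rho,
            channels = attr(src, "channels"), grid = attr(src, "grid"),
            fs = attr(src, "fs"), total_bits = attr(src, "total_bits"),
            class = "pc_tft")
}

#' Build a Time-Frequency-Topography map
#'
#' Applies [windowed_modes()] per band over a labeled record segment:
#' each (band, window) cell carries one label per channel — a scalp map
#' of cluster modes. At 256 Hz with `upsilon = 16` each window spans
#' 62.5 ms and a 1000 ms segment tiles into 16 windows.
#'
#' @param record A `pc_cluster_record` (or any channels x samples x
#'   bands label-code array).
#' @param upsilon Window size, samples.
#' @param rho Mode threshold, percent.
#' @return A `pc_tft`: channels x windows x bands integer label codes.
#' @export
build_tft <- function(record, upsilon = 16, rho = 50) {
  d <- dim(record)
  n_win <- d[2] %/% upsilon
  if (n_win < 1L) stop("segment shorter than one window", call. = FALSE)
  out <- array(0L, dim = c(d[1], n_win, d[3]),
               dimnames = list(dimnames(record)[[1]], NULL, dimnames(record)[[3]]))
  for (k in seq_len(d[3])) {
    out[, , k] <- windowed_modes(matrix(record[, , k], nrow = d[1]), upsilon, rho)
  }
  .new_tft(out, upsilon, rho, record)
}

#' Intertrial cluster modes (ITCM)
#'
#' The analogue of a grand average for label records: per channel, band
#' and within-epoch sample, the modal label across epochs under the
#' strict-majority rule. Invariant to epoch order.
#'
#' @param stack A `pc_epoch_stack` (epochs x channels x samples x bands).
#' @param rho Mode threshold, percent.
#' @return A channels x samples x bands integer array of label codes
#'   (class `pc_itcm`).
#' @export
intertrial_modes <- function(stack, rho = 50) {
  d <- dim(stack)
  if (is.null(d) || d[1] < 1L) stop("epoch stack is empty", call. = FALSE)
  out <- array(0L, dim = d[-1],
               dimnames = list(attr(stack, "channels"), NULL, NULL))
  for (k in seq_len(d[4])) {
    for (j in seq_len(d[2])) {
      sl <- matrix(stack[, j, , k], nrow = d[1])   # epochs x samples
      out[j, , k] <- apply(sl, 2, .mode_code, rho = rho)
    }
  }
  structure(out, channels = attr(stack, "channels"), grid = attr(stack, "grid"),
            fs = attr(stack, "fs"), total_bits = attr(stack, "total_bits"),
            rho = rho, class = "pc_itcm")
}

#' Build an intertrial TFT (iTFT) map
#'
#' [intertrial_modes()] across epochs first, then [windowed_modes()]
#' over the within-epoch time axis: the resulting map shows the most
#' prevalent phase-clustering patterns over the epoch (e.g. 1000 ms
#' trials windowed at upsilon = 16 samples, 62.5 ms at 256 Hz).
#'
#' @param stack A `pc_epoch_stack` for one condition.
#' @param upsilon Window size, samples.
#' @param rho Mode threshold, percent (used for both mode stages).
#' @return A `pc_tft` over the epoch time axis.
#' @export
build_itft <- function(stack, upsilon = 16, rho = 50) {
  itcm <- intertrial_modes(stack, rho = rho)
  build_tft(itcm, upsilon = upsilon, rho = rho)
}

#' @export
print.pc_tft <- function(x, ...) {
  d <- dim(x)
  cat("<pc_tft> ", d[1], " channels x ", d[2], " windows x ", d[3],
      " bands (upsilon = ", attr(x, "upsilon"), ", rho = ", attr(x, "rho"),
      "%)\n", sep = "")
  invisible(x)
}

#' Tidy a TFT/iTFT map into long format
#'
#' @param x A `pc_tft`.
#' @param ... Unused.
#' @return Tibble with columns `band`, `window`, `channel`, `label`.
#' @export
tidy.pc_tft <- function(x, ...) {
  d <- dim(x)
  width <- (attr(x, "total_bits") %||% .total_bits(d[1])) %/% 4L
  ch <- attr(x, "channels") %||% dimnames(x)[[1]] %||% as.character(seq_len(d[1]))
  grid <- attr(x, "grid")
  bands <- if (!is.null(grid)) grid$label else as.character(seq_len(d[3]))
  tibble::tibble(
    band = rep(bands, each = d[1] * d[2]),
    window = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    channel = rep(ch, times = d[2] * d[3]),
    label = sprintf("%0*X", width, as.integer(x))
  )
}
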