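# Hexadecimal cluster labels: a cluster's member set is encoded as a bit
# string in canonical montage order (first channel = most significant
# bit), padded to whole hex digits, and printed as an uppercase hex word.
# On the 8-channel speller montage {Fz, Pz, P3, P4} -> bits 10101100 ->
# "AC"; all channels -> "FF"; {PO8} -> "01"; the empty set -> "00".

label_width <- function(n_ch) as.integer(ceiling(n_ch / 4))

code_to_hex <- function(code, n_ch) {
  sprintf("%0*X", label_width(n_ch), as.integer(code))
}

hex_to_code <- function(word, n_ch) {
  width <- label_width(n_ch)
  bad <- nchar(word) != width | grepl("[^0-9A-Fa-f]", word)
  if (any(bad)) {
    stop("malformed hex label (need ", width, " hex digits): ",
         paste(unique(word[bad]), collapse = ", "), call. = FALSE)
  }
  strtoi(word, base = 16L)
}

#' Encode a channel set as a hexadecimal cluster label
#'
#' @param members Character vector of channel names (or integer indices)
#'   forming the cluster; must belong to the montage.
#' @param montage A `pc_montage`; its channel order fixes the bit order.
#' @return Uppercase hex word of `ceiling(n_ch/4)` digits.
#' @examples
#' m <- standard_montage("10-10-8ch")
#' encode_label(c("Fz", "Pz", "P3", "P4"), m) # "AC"
#' @export
encode_label <- function(members, montage) {
  n_ch <- nrow(montage)
  if (is.character(members)) {
    idx <- match(members, montage$channel)
    if (anyNA(idx)) {
      stop("unknown channel(s): ",
           paste(members[is.na(idx)], collapse = ", "), call. = FALSE)
    }
  } else {
    idx <- as.integer(members)
    if (length(idx) && (min(idx) < 1L || max(idx) > n_ch)) {
      stop("channel index out of range", call. = FALSE)
    }
  }
  total_bits <- 4L * label_width(n_ch)
  code <- if (length(idx)) sum(2^(total_bits - idx)) else 0
  code_to_hex(code, n_ch)
}

#' Decode a hexadecimal cluster label back to its channel set
#'
#' Exact inverse of [encode_label()].
#'
#' @param label Hex word of the montage's label width.
#' @param montage A `pc_montage`.
#' @return Character vector of member channel names (montage order).
#' @export
decode_label <- function(label, montage) {
  n_ch <- nrow(montage)
  code <- hex_to_code(label, n_ch)
  total_bits <- 4L * label_width(n_ch)
  idx <- which(bitwAnd(code, 2^(total_bits - seq_len(n_ch))) > 0)
  montage$channel[idx]
}

#' Map cluster labels to colors
#'
#' The colormap runs from dark blue, pinned to label `"01"` (only the
#' last channel assigned), to bright yellow, pinned to the all-channel
#' label (`"FF"` on 8 channels). Other labels are ranked by their encoded
#' integer within the set of labels seen in the run and placed linearly
#' between the endpoints; the all-zero (unassigned) label renders as
#' neutral gray. Because labeling happens before condition segmentation,
#' the same label gets the same color in every map of a run.
#'
#' @param label Character vector of hex labels to color.
#' @param universe Character vector: all labels seen in the run.
#' @return Tibble with columns `label`, `red`, `green`, `blue` (0-255)
#'   and `hex` (e.g. `"#00008B"`).
#' @export
label_color <- function(label, universe = label) {
  dark_blue <- c(0, 0, 139)
  bright_yellow <- c(255, 255, 0)
  gray <- c(128, 128, 128)
  width <- unique(nchar(c(label, universe)))
  if (length(width) != 1L) stop("labels must share one width", call. = FALSE)
  zero <- strrep("0", width)
  uni <- sort(unique(strtoi(setdiff(union(universe, label), zero), base = 16L)))
  pos <- function(code) {
    if (length(uni) <= 1L) return(ifelse(code == max(uni, 0), 1, 0))
    (match(code, uni) - 1) / (length(uni) - 1)
  }
  codes <- strtoi(label, base = 16L)
  t <- pos(codes)
  rgb_mat <- t(vapply(seq_along(label), function(i) {
    if (label[i] == zero) return(gray)
    round(dark_blue + t[i] * (bright_yellow - dark_blue))
  }, numeric(3)))
  tibble::tibble(
    label = label,
    red = rgb_mat[, 1], green = rgb_mat[, 2], blue = rgb_mat[, 3],
    hex = grDevices::rgb(rgb_mat[, 1], rgb_mat[, 2], rgb_mat[, 3],
                         maxColorValue = 255)
  )
}
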