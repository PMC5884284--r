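# Condition contrast: Levenshtein edit distance between the binary
# expansions of two conditions' cluster-mode labels, per channel, laid
# out as a Time-Frequency-Levenshtein (TFL) map.

#' Levenshtein edit distance
#'
#' Minimum total cost of transforming one string into the other with
#' unit-cost edit operations (full dynamic programming, vectorised over
#' pairs). Cluster labels are equal-length binary membership words and
#' are compared with the adapted, substitution-only operation set, under
#' which the distance is exactly the number of differing bits: comparing
#' an empty cluster-mode word `"00000000"` with the all-channel word
#' `"11111111"` gives the 8-channel maximum, 8. The general form with
#' insertions and deletions is also available (`substitution_only =
#' FALSE`); note it can undercut the bit count on shifted patterns, which
#' is why label contrast uses the substitution-only form.
#'
#' @param a,b Character vectors (recycled if one has length 1).
#' @param substitution_only If `TRUE` (default), only substitutions are
#'   allowed (equal-length strings required) — the adaptation used for
#'   cluster labels. If `FALSE`, the full insert/delete/substitute
#'   distance is computed.
#' @return Integer vector of distances.
#' @examples
#' levenshtein("10101100", "10101000") # 1
#' levenshtein("kitten", "sitting", substitution_only = FALSE) # 3
#' @export
levenshtein <- function(a, b, substitution_only = TRUE) {
  cpp_levenshtein(as.character(a), as.character(b), substitution_only)
}

.code_to_bits <- function(code, total_bits) {
  vapply(code, function(cd) {
    paste(rev(as.integer(intToBits(cd))[seq_len(total_bits)]), collapse = "")
  }, character(1))
}

#' Time-Frequency-Levenshtein contrast map for one channel
#'
#' For every (band, window) cell, the Levenshtein distance between the
#' channel's cluster-mode label under condition A and under condition B,
#' each label expanded to its binary membership string. Zero wherever
#' the two conditions agree; at most the channel count.
#'
#' @param map_a,map_b `pc_tft` maps sharing band grid, window grid and
#'   montage (e.g. the ERP and no-ERP iTFT maps of one run).
#' @param channel Channel name (or index) to contrast.
#' @return A `pc_tfl` tibble with columns `band`, `window`, `distance`,
#'   and attributes `channel` and `n_ch`.
#' @export
tfl_map <- function(map_a, map_b, channel) {
  if (!identical(dim(map_a), dim(map_b))) {
    stop("TFT maps have mismatched dimensions", call. = FALSE)
  }
  ga <- attr(map_a, "grid"); gb <- attr(map_b, "grid")
  if (!is.null(ga) && !is.null(gb) && !isTRUE(all.equal(ga$center_hz, gb$center_hz))) {
    stop("TFT maps have mismatched band grids", call. = FALSE)
  }
  ch_names <- attr(map_a, "channels") %||% dimnames(map_a)[[1]]
  j <- if (is.character(channel)) match(channel, ch_names) else as.integer(channel)
  if (is.na(j) || j < 1L || j > dim(map_a)[1]) {
    stop("unknown channel: ", channel, call. = FALSE)
  }
  total_bits <- attr(map_a, "total_bits") %||% .total_bits(dim(map_a)[1])
  d <- dim(map_a)
  grid <- attr(map_a, "grid")
  bands <- if (!is.null(grid)) grid$label else as.character(seq_len(d[3]))
  la <- .code_to_bits(as.integer(map_a[j, , ]), total_bits)
  lb <- .code_to_bits(as.integer(map_b[j, , ]), total_bits)
  out <- tibble::tibble(
    band = rep(bands, each = d[2]),
    window = rep(seq_len(d[2]), times = d[3]),
    distance = levenshtein(la, lb)
  )
  structure(out, class = c("pc_tfl", class(out)),
            channel = if (is.character(channel)) channel else ch_names[j],
            n_ch = d[1], upsilon = attr(map_a, "upsilon"),
            fs = attr(map_a, "fs"))
}

#' @export
print.pc_tfl <- function(x, ...) {
  cat("<pc_tfl> channel ", attr(x, "channel"), ", max possible distance ",
      attr(x, "n_ch"), "\n", sep = "")
  NextMethod()
}

#' @describeIn tfl_map Summary of a TFL map: cells, nonzero cells,
#'   maximum and mean distance.
#' @param x A `pc_tfl`.
#' @param ... Unused.
#' @export
glance.pc_tfl <- function(x, ...) {
  tibble::tibble(
    channel = attr(x, "channel"),
    n_cells = nrow(x),
    n_nonzero = sum(x$distance > 0),
    max_distance = max(x$distance),
    mean_distance = mean(x$distance)
  )
}
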