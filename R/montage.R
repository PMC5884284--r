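# Electrode montages on the unit sphere.
#
# Head coordinate frame: x = right, y = anterior, z = superior, scalp
# approximated by the unit sphere. Positions come from the standard
# spherical 10-20 / 10-10 angles (inclination from the vertex, azimuth
# measured from the nasion, positive towards the right ear).

.montage_angle_table <- function(layout) {
  tab <- switch(layout,
    "10-20-19ch" = data.frame(
      channel = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                  "T7", "C3", "Cz", "C4", "T8",
                  "P7", "P3", "Pz", "P4", "P8", "O1", "O2"),
      inc = c(90, 90, 90, 62, 45, 62, 90,
              90, 45, 0, 45, 90,
              90, 62, 45, 62, 90, 90, 90),
      azi = c(-18, 18, -54, -40, 0, 40, 54,
              -90, -90, 0, 90, 90,
              -126, -140, 180, 140, 126, -162, 162),
      stringsAsFactors = FALSE
    ),
    "10-10-8ch" = data.frame(
      channel = c("Fz", "Cz", "Pz", "Oz", "P3", "P4", "PO7", "PO8"),
      inc = c(45, 0, 45, 90, 62, 62, 90, 90),
      azi = c(0, 0, 180, 180, -140, 140, -144, 144),
      stringsAsFactors = FALSE
    ),
    stop("unknown montage layout: ", layout, call. = FALSE)
  )
  tab
}

#' Standard electrode montages
#'
#' Returns one of the two montages the framework uses: the 19-channel
#' 10-20 layout used for synthetic EEG, or the 8-channel 10-10 subset
#' (Fz, Cz, Pz, Oz, P3, P4, PO7, PO8) used for P300-speller recordings.
#' Channel order is canonical: it fixes the bit order of hexadecimal
#' cluster labels for the whole pipeline.
#'
#' @param layout `"10-20-19ch"` or `"10-10-8ch"`.
#' @return A `pc_montage`: a tibble with columns `channel`, `x`, `y`, `z`
#'   (unit-sphere coordinates, x = right, y = anterior, z = superior).
#' @examples
#' standard_montage("10-10-8ch")
#' @export
standard_montage <- function(layout = c("10-20-19ch", "10-10-8ch")) {
  layout <- match.arg(layout)
  tab <- .montage_angle_table(layout)
  inc <- tab$inc * pi / 180
  azi <- tab$azi * pi / 180
  out <- tibble::tibble(
    channel = tab$channel,
    x = sin(inc) * sin(azi),
    y = sin(inc) * cos(azi),
    z = cos(inc)
  )
  new_montage(out, layout = layout)
}

new_montage <- function(df, layout = "custom") {
  stopifnot(all(c("channel", "x", "y", "z") %in% names(df)))
  df <- tibble::as_tibble(df)[, c("channel", "x", "y", "z")]
  if (anyDuplicated(df$channel)) stop("montage channel names must be unique", call. = FALSE)
  nrm <- sqrt(df$x^2 + df$y^2 + df$z^2)
  if (any(nrm <= 0 | nrm > 1.05)) {
    stop("montage positions must have norm in (0, 1.05]", call. = FALSE)
  }
  structure(df, class = c("pc_montage", class(df)), layout = layout)
}

#' @export
print.pc_montage <- function(x, ...) {
  cat("<pc_montage> ", nrow(x), " channels (", attr(x, "layout"), ")\n", sep = "")
  NextMethod()
}

montage_positions <- function(montage) {
  as.matrix(montage[, c("x", "y", "z")])
}

#' Inverse-square mixing weights
#'
#' Forward-model gains from sources to electrodes under the
#' inverse-square law of distances: `w[j, i] = 1 / max(d(c_j, s_i), floor)^2`,
#' with a small distance floor so that a source coincident with an
#' electrode yields a finite weight.
#'
#' @param montage A [standard_montage()] (or any `pc_montage`).
#' @param source_positions Numeric matrix, one source per row, columns x, y, z.
#' @param floor Distance floor (unit-sphere units), must be positive.
#' @return channels x sources numeric matrix of positive finite weights.
#' @export
mixing_weights <- function(montage, source_positions, floor = 1e-3) {
  stopifnot(floor > 0)
  sp <- rbind(source_positions)
  if (is.null(dim(sp)) || nrow(sp) == 0L) stop("source_positions must be a non-empty matrix", call. = FALSE)
  if (ncol(sp) != 3L) stop("source positions need x, y, z columns", call. = FALSE)
  ep <- montage_positions(montage)
  d <- sqrt(outer(rowSums(ep^2), rep(1, nrow(sp))) +
            outer(rep(1, nrow(ep)), rowSums(sp^2)) -
            2 * ep %*% t(sp))
  d[d < floor] <- floor
  w <- 1 / d^2
  dimnames(w) <- list(montage$channel, NULL)
  w
}

#' Read or write a montage as TSV
#'
#' Plain-text interchange: four tab-separated columns
#' `channel`, `x`, `y`, `z` with a header row.
#'
#' @param path File path.
#' @return `read_montage()` returns a `pc_montage` tibble.
#' @export
read_montage <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1] <- "channel"
  new_montage(df, layout = "file")
}

#' @rdname read_montage
#' @param montage Montage to write.
#' @export
write_montage <- function(montage, path) {
  utils::write.table(as.data.frame(montage), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
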