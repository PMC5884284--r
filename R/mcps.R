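# Multivariate clustering of channels by phase synchrony: at every time
# sample and frequency band, fuzzy clusters of channels whose joint
# mean-resultant magnitude exceeds a threshold r are grown greedily and
# then reduced to a disjoint hard partition.

#' Mean resultant magnitude of a set of phase angles
#'
#' The length of the average unit vector: with `A = mean(cos theta)` and
#' `B = mean(sin theta)`, returns `sqrt(A^2 + B^2)`. Equal to 1 when all
#' angles coincide (perfect phase locking), near 0 for uniformly spread
#' angles; `1 - rbar^2` is a measure of circular variance.
#'
#' @param angles Numeric vector of angles in radians (at least one).
#' @return Scalar in `[0, 1]`.
#' @examples
#' mean_resultant(c(0, 0, pi)) # 1/3
#' @export
mean_resultant <- function(angles) {
  if (length(angles) == 0L) stop("angles must be non-empty", call. = FALSE)
  A <- mean(cos(angles))
  B <- mean(sin(angles))
  sqrt(A^2 + B^2)
}

.total_bits <- function(n_ch) 4L * as.integer(ceiling(n_ch / 4))

#' Fuzzy clusters of channels at one time sample
#'
#' Every channel seeds a cluster that is grown greedily: at each step the
#' channel whose inclusion maximises the joint [mean_resultant()] is
#' added, stopping before any addition that would drop the magnitude
#' below `r`. Duplicate member sets are merged; clusters may overlap.
#'
#' @param phases Numeric vector, one phase (radians) per channel.
#' @param r Synchrony threshold, `0 < r < 1`.
#' @return Tibble with list-column `members` (integer channel indices)
#'   and `rbar`; every row satisfies `rbar >= r`.
#' @export
create_fuzzy_clusters <- function(phases, r) {
  stopifnot(r > 0, r < 1)
  res <- cpp_fuzzy_clusters(cos(phases), sin(phases), r)
  tibble::tibble(members = lapply(res$members, as.integer),
                 rbar = res$rbar)
}

.encoded_int <- function(members, total_bits) {
  sum(2^(total_bits - members))
}

#' Reduce fuzzy clusters to a disjoint hard partition
#'
#' Candidates are ranked by mean-resultant magnitude (ties: larger
#' cardinality, then smallest encoded label integer). The top candidate
#' is accepted; its members are stripped from all survivors, whose
#' magnitudes are recomputed on the reduced sets; multi-channel survivors
#' falling below `r` are discarded. Channels never accepted into a
#' multi-channel cluster become singletons, so the result is a partition
#' of all channels in which every multi-channel cluster has `rbar >= r`.
#'
#' @param fuzzy Output of [create_fuzzy_clusters()] (tibble with
#'   `members`, `rbar`).
#' @param phases The phase vector the fuzzy clusters were built from
#'   (needed to recompute magnitudes on reduced member sets).
#' @param r Synchrony threshold.
#' @return Tibble with list-column `members` and `rbar`, rows pairwise
#'   disjoint and jointly covering all channels.
#' @export
convert_to_hard <- function(fuzzy, phases, r) {
  n_ch <- length(phases)
  total_bits <- .total_bits(n_ch)
  cand <- lapply(fuzzy$members, as.integer)
  taken <- integer(0)
  accepted <- list()
  repeat {
    pool <- list()
    seen <- character(0)
    for (m in cand) {
      red <- setdiff(m, taken)
      key <- paste(red, collapse = ",")
      if (length(red) == 0L || key %in% seen) next
      seen <- c(seen, key)
      rb <- mean_resultant(phases[red])
      if (length(red) > 1L && rb < r) next
      pool[[length(pool) + 1L]] <- list(members = red, rbar = rb)
    }
    if (length(pool) == 0L) break
    rb <- vapply(pool, `[[`, numeric(1), "rbar")
    sz <- vapply(pool, function(p) length(p$members), integer(1))
    code <- vapply(pool, function(p) .encoded_int(p$members, total_bits), numeric(1))
    best <- order(-rb, -sz, code)[1L]
    accepted[[length(accepted) + 1L]] <- pool[[best]]
    taken <- c(taken, pool[[best]]$members)
    cand <- lapply(pool, `[[`, "members")
    if (length(taken) == n_ch) break
  }
  for (j in setdiff(seq_len(n_ch), taken)) {
    accepted[[length(accepted) + 1L]] <- list(members = j, rbar = 1)
  }
  tibble::tibble(members = lapply(accepted, `[[`, "members"),
                 rbar = vapply(accepted, `[[`, numeric(1), "rbar"))
}

#' Cluster a phase tensor sample-by-sample
#'
#' Applies [create_fuzzy_clusters()] followed by [convert_to_hard()]
#' independently at every (sample, band) cell of a phase tensor
#' (implemented in compiled code), producing the cluster-label record:
#' for each band, a channels x samples grid in which each entry is the
#' encoded integer of the hard cluster containing that channel.
#'
#' @param phase A `pc_phase` array from [instantaneous_phase()], or a
#'   channels x samples x bands array of radians.
#' @param r Synchrony threshold, `0 < r < 1`.
#' @param bands Optional integer vector restricting which bands to
#'   cluster (default all).
#' @return A `pc_cluster_record`: integer array channels x samples x
#'   bands of encoded cluster labels, with attributes `r`, `channels`,
#'   `fs` and `grid` (when available from the input).
#' @export
cluster_series <- function(phase, r, bands = NULL) {
  stopifnot(r > 0, r < 1, length(dim(phase)) == 3L)
  n_ch <- dim(phase)[1]
  if (n_ch > 31) stop("encoded labels support at most 31 channels", call. = FALSE)
  total_bits <- .total_bits(n_ch)
  if (is.null(bands)) bands <- seq_len(dim(phase)[3])
  out <- array(NA_integer_, dim = c(n_ch, dim(phase)[2], length(bands)))
  for (bi in seq_along(bands)) {
    th <- phase[, , bands[bi], drop = TRUE]
    th <- matrix(th, nrow = n_ch)
    out[, , bi] <- cpp_cluster_matrix(cos(th), sin(th), r, total_bits)
  }
  grid <- attr(phase, "grid")
  if (!is.null(grid)) grid <- grid[bands, , drop = FALSE]
  dimnames(out) <- list(dimnames(phase)[[1]], NULL,
                        if (!is.null(grid)) grid$label else NULL)
  structure(out, r = r, fs = attr(phase, "fs"), grid = grid,
            channels = dimnames(phase)[[1]], total_bits = total_bits,
            class = "pc_cluster_record")
}

#' @export
print.pc_cluster_record <- function(x, ...) {
  d <- dim(x)
  cat("<pc_cluster_record> ", d[1], " channels x ", d[2], " samples x ",
      d[3], " bands, r = ", attr(x, "r"), "\n", sep = "")
  invisible(x)
}

#' @describeIn cluster_series Long-format view of a cluster record: one
#'   row per (channel, sample, band) with the hexadecimal label.
#' @param x A `pc_cluster_record`.
#' @param ... Unused.
#' @export
tidy.pc_cluster_record <- function(x, ...) {
  d <- dim(x)
  width <- attr(x, "total_bits") %/% 4L
  ch <- dimnames(x)[[1]] %||% as.character(seq_len(d[1]))
  bands <- dimnames(x)[[3]] %||% as.character(seq_len(d[3]))
  tibble::tibble(
    channel = rep(ch, times = d[2] * d[3]),
    sample = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    band = rep(bands, each = d[1] * d[2]),
    label = sprintf("%0*X", width, as.integer(x))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
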