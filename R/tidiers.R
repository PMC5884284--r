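# broom-style summaries for the remaining result types.

#' @describeIn simulate_record One-row summary of a simulated record:
#'   dimensions, sampling rate and channel-averaged SNR.
#' @param x A `pc_record`.
#' @param ... Unused.
#' @export
glance.pc_record <- function(x, ...) {
  tibble::tibble(
    n_channels = nrow(x$data),
    n_samples = ncol(x$data),
    fs = x$fs,
    n_epochs = x$n_epochs,
    epoch_length = x$epoch_length,
    snr_db = if (any(x$ground_truth$kinds == "vep")) snr_db(x) else NA_real_
  )
}

#' @describeIn cluster_series Per-band summary of a cluster record:
#'   number of distinct labels and the share of samples in which all
#'   channels form a single cluster.
#' @export
glance.pc_cluster_record <- function(x, ...) {
  n_ch <- dim(x)[1]
  all_code <- .encoded_int(seq_len(n_ch), attr(x, "total_bits"))
  tidy(x) |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(
      n_labels = dplyr::n_distinct(.data$label),
      frac_global_cluster = mean(
        .data$label == sprintf("%0*X", attr(x, "total_bits") %/% 4L, all_code)),
      .groups = "drop"
    )
}
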