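# Pipeline orchestration: phase extraction -> clustering -> labeling ->
# condition segmentation -> iTFT per condition -> TFL contrasts, with
# optional TSV artifacts. Labeling precedes segmentation so the hex
# label universes of all conditions in one run are drawn from a single
# shared universe, making labels (and colors) directly comparable.

#' Pipeline configuration
#'
#' Collects and validates every tunable of the framework.
#'
#' @param fs Sampling rate, Hz.
#' @param fmin,fmax,K Frequency grid (see [center_frequencies()]).
#' @param cycles Morlet wavelet cycles.
#' @param r Synchrony threshold, `0 < r < 1`.
#' @param rho Mode threshold, percent, `0 <= rho < 100`.
#' @param upsilon Mode window, samples.
#' @param seed Integer seed for any stochastic stage.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return A validated `pc_config` list.
#' @export
pipeline_config <- function(fs = 256, fmin = 1, fmax = 12, K = 12,
                            cycles = 4, r = 0.9, rho = 50, upsilon = 16,
                            seed = 1L, out_dir = NULL) {
  if (!(r > 0 && r < 1)) stop("config: r must be in (0, 1)", call. = FALSE)
  if (!(rho >= 0 && rho < 100)) stop("config: rho must be in [0, 100)", call. = FALSE)
  if (upsilon < 1) stop("config: upsilon must be >= 1", call. = FALSE)
  if (!(fmin > 0 && fmin < fmax && fmax <= fs / 2)) {
    stop("config: need 0 < fmin < fmax <= fs/2", call. = FALSE)
  }
  structure(list(fs = fs, fmin = fmin, fmax = fmax, K = as.integer(K),
                 cycles = cycles, r = r, rho = rho,
                 upsilon = as.integer(upsilon), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pc_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (a) Morlet decomposition and instantaneous phase,
#' (b) sample-wise phase-synchrony clustering, (c) hexadecimal labeling
#' of the cluster record, (d) segmentation into condition epochs and
#' per-condition iTFT maps, (e) per-channel TFL contrast maps between
#' the first two conditions, plus per-channel windowed TF power maps per
#' condition. Deterministic for a fixed record, schedule and config.
#'
#' @param record channels x samples matrix (montage order) or a
#'   `pc_record` from [simulate_record()].
#' @param schedule A `pc_schedule` of epoch onsets and conditions.
#' @param montage The `pc_montage` the rows follow.
#' @param config A [pipeline_config()].
#' @return A list with elements `config`, `grid`, `phase`, `power`,
#'   `ceeg` (labeled cluster record), `stacks` (per condition),
#'   `itft` (per condition `pc_tft`), `tfl` (per channel `pc_tfl`,
#'   first vs second condition), and `power_maps` (per condition:
#'   channels x windows x bands mean power). Artifacts are written under
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(record, schedule, montage, config = pipeline_config()) {
  if (inherits(record, "pc_record")) {
    stopifnot(identical(record$montage$channel, montage$channel))
  }
  grid <- center_frequencies(config$fmin, config$fmax, config$K)

  analytic <- .stage("phase extraction", analytic_decompose(
    record, grid = grid, cycles = config$cycles, fs = config$fs))
  phase <- instantaneous_phase(analytic)
  power <- tf_power(analytic)

  ceeg <- .stage("clustering", cluster_series(phase, r = config$r))

  stacks <- .stage("segmentation", segment_epochs(ceeg, schedule))
  itft <- purrr::map(stacks, build_itft, upsilon = config$upsilon, rho = config$rho)

  conditions <- names(stacks)
  tfl <- list()
  if (length(conditions) >= 2L) {
    tfl <- purrr::map(
      stats::setNames(montage$channel, montage$channel),
      ~ tfl_map(itft[[conditions[1]]], itft[[conditions[2]]], .x))
  }

  power_maps <- .stage("power maps", lapply(conditions, function(cond) {
    onsets <- schedule$onset_sample[schedule$condition == cond]
    win <- attr(schedule, "epoch_window")
    L <- win[2] - win[1] + 1L
    avg <- array(0, dim = c(dim(power)[1], L, dim(power)[3]))
    for (on in onsets) {
      avg <- avg + power[, (on + win[1]):(on + win[1] + L - 1L), , drop = FALSE]
    }
    avg <- avg / length(onsets)
    n_win <- L %/% config$upsilon
    pm <- array(0, dim = c(dim(avg)[1], n_win, dim(avg)[3]),
                dimnames = list(dimnames(power)[[1]], NULL, grid$label))
    for (w in seq_len(n_win)) {
      cols <- ((w - 1L) * config$upsilon + 1L):(w * config$upsilon)
      pm[, w, ] <- apply(avg[, cols, , drop = FALSE], c(1, 3), mean)
    }
    pm
  }))
  names(power_maps) <- conditions

  out <- list(config = config, grid = grid, phase = phase, power = power,
              ceeg = ceeg, stacks = stacks, itft = itft, tfl = tfl,
              power_maps = power_maps)
  if (!is.null(config$out_dir)) .write_artifacts(out, schedule, montage)
  invisible(out)
}

.write_artifacts <- function(out, schedule, montage) {
  dir <- out$config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cluster_record(out$ceeg, file.path(dir, "ceeg"))
  for (cond in names(out$itft)) {
    tf <- tidy(out$itft[[cond]])
    utils::write.table(as.data.frame(tf),
                       file.path(dir, sprintf("itft_%s.tsv", cond)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (ch in names(out$tfl)) {
    utils::write.table(as.data.frame(out$tfl[[ch]]),
                       file.path(dir, sprintf("tfl_%s.tsv", ch)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_schedule(schedule, file.path(dir, "schedule.tsv"))
  write_montage(montage, file.path(dir, "montage.tsv"))
  cfg <- out$config
  cfg$out_dir <- NULL
  jsonlite::write_json(
    list(config = unclass(cfg),
         package_version = as.character(utils::packageVersion("phasecluster"))),
    file.path(dir, "run_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
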