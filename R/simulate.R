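# Synthetic EEG: linear instantaneous mixing of point sources onto scalp
# electrodes with inverse-square-distance gains, a chirped Gaussian-windowed
# VEP, and harmonic / white / 1-f^alpha Gaussian noise sources that may
# stay fixed, drift linearly, or rotate.

#' Describe one simulated source
#'
#' @param kind `"vep"`, `"harmonic"`, `"white"` or `"colored"`.
#' @param amplitude Scalar gain applied to the source waveform.
#' @param frequency Oscillation frequency in Hz (harmonic only).
#' @param initial_phase Initial phase in radians (harmonic only).
#' @param alpha Spectral exponent for colored noise (power ~ 1/f^alpha).
#' @param trajectory One of [trajectory_fixed()], [trajectory_linear()],
#'   [trajectory_rotational()].
#' @return A `pc_source_spec` list.
#' @export
source_spec <- function(kind = c("vep", "harmonic", "white", "colored"),
                        amplitude = 1,
                        frequency = NULL,
                        initial_phase = 0,
                        alpha = 1,
                        trajectory = trajectory_fixed(0, 0, 0)) {
  kind <- match.arg(kind)
  if (kind == "harmonic") {
    if (is.null(frequency) || frequency <= 0) {
      stop("harmonic sources need frequency > 0", call. = FALSE)
    }
  }
  structure(
    list(kind = kind, amplitude = amplitude, frequency = frequency,
         initial_phase = initial_phase, alpha = alpha,
         trajectory = trajectory),
    class = "pc_source_spec"
  )
}

#' Source trajectories
#'
#' A trajectory maps a time vector (seconds) to 3-D positions inside the
#' unit sphere. `trajectory_linear()` drifts from `start` at `velocity`
#' (units per second); `trajectory_rotational()` circles `center` in the
#' horizontal plane at `angular_rate` (radians per second).
#'
#' @param x,y,z Fixed coordinates.
#' @return A function `f(t_seconds) -> n x 3 matrix`.
#' @export
trajectory_fixed <- function(x, y, z) {
  p <- c(x, y, z)
  .check_inside(p)
  structure(function(t) {
    matrix(p, nrow = length(t), ncol = 3, byrow = TRUE)
  }, kind = "fixed")
}

#' @rdname trajectory_fixed
#' @param start Length-3 start position.
#' @param velocity Length-3 velocity, units per second.
#' @export
trajectory_linear <- function(start, velocity) {
  stopifnot(length(start) == 3L, length(velocity) == 3L)
  structure(function(t) {
    pos <- cbind(start[1] + velocity[1] * t,
                 start[2] + velocity[2] * t,
                 start[3] + velocity[3] * t)
    .check_inside(pos)
    pos
  }, kind = "linear")
}

#' @rdname trajectory_fixed
#' @param center Length-3 circle center.
#' @param radius Circle radius.
#' @param angular_rate Radians per second.
#' @export
trajectory_rotational <- function(center, radius, angular_rate) {
  stopifnot(length(center) == 3L, radius >= 0)
  structure(function(t) {
    pos <- cbind(center[1] + radius * cos(angular_rate * t),
                 center[2] + radius * sin(angular_rate * t),
                 rep(center[3], length(t)))
    .check_inside(pos)
    pos
  }, kind = "rotational")
}

.check_inside <- function(pos) {
  pos <- rbind(pos)
  if (any(rowSums(pos^2) > 1 + 1e-9)) {
    stop("source trajectory leaves the unit sphere", call. = FALSE)
  }
  invisible(pos)
}

#' Chirped visual evoked potential waveform
#'
#' One epoch of the simulated VEP: a Gaussian envelope centred at sample
#' `mu` with variance `sigma2`, carrying a downward-chirped oscillation
#' `sin(2 pi f (n/N) gamma(n))` with `gamma(n) = (N - 0.5 n)/N`. With the
#' defaults (`f = 10` Hz, `mu = N/2`, `sigma2 = N/8`) the envelope peaks
#' mid-epoch and the instantaneous frequency at the peak is
#' `fs * f * (1 - n/N) / N` — about 1.67 Hz for a 3 s epoch at 256 Hz.
#'
#' @param N Epoch length in samples.
#' @param f Chirp parameter in Hz.
#' @param mu Envelope centre, samples.
#' @param sigma2 Envelope variance, samples^2.
#' @param fs Sampling rate, Hz (used only for the frequency annotation).
#' @return Numeric vector of length `N` with attribute `inst_freq_hz`
#'   giving the instantaneous frequency at every sample.
#' @export
vep_waveform <- function(N, f = 10, mu = 0.5 * N, sigma2 = 0.125 * N, fs = 256) {
  if (N <= 0) stop("N must be positive", call. = FALSE)
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  n <- seq_len(N)
  sigma <- sqrt(sigma2)
  envelope <- (1 / sqrt(2 * pi)) * exp(-((n - mu) / sigma)^2 / 2)
  gamma_n <- (N - 0.5 * n) / N
  v <- envelope * sin(2 * pi * f * (n / N) * gamma_n)
  # phase(n) = 2 pi f (n - n^2/(2N))/N; d(phase)/dn * fs / (2 pi)
  attr(v, "inst_freq_hz") <- fs * f * (1 - n / N) / N
  v
}

#' Generate source waveforms and their positions over time
#'
#' @param specs List of [source_spec()] objects.
#' @param N Total number of samples.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed governing all stochastic sources.
#' @param epoch_length Samples per epoch; the VEP waveform is tiled
#'   identically across epochs (constant across trials).
#' @return List with `waves` (sources x samples matrix) and `positions`
#'   (list of N x 3 matrices, one per source).
#' @export
generate_sources <- function(specs, N, fs, seed = 1L, epoch_length = N) {
  if (length(specs) == 0L) stop("specs must be non-empty", call. = FALSE)
  stopifnot(N >= 1, fs > 0, epoch_length >= 1)
  t <- (seq_len(N) - 1) / fs
  waves <- matrix(0, nrow = length(specs), ncol = N)
  positions <- vector("list", length(specs))
  set.seed(as.integer(seed))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    waves[i, ] <- sp$amplitude * switch(sp$kind,
      harmonic = sin(2 * pi * sp$frequency * t + sp$initial_phase),
      white = rnorm(N),
      colored = colored_noise(N, alpha = sp$alpha),
      vep = {
        n_ep <- ceiling(N / epoch_length)
        rep(vep_waveform(epoch_length, fs = fs), n_ep)[seq_len(N)]
      },
      stop("unsupported source kind: ", sp$kind, call. = FALSE)
    )
    positions[[i]] <- sp$trajectory(t)
  }
  list(waves = waves, positions = positions)
}

#' 1/f^alpha Gaussian noise
#'
#' White Gaussian noise shaped in the frequency domain so its power
#' spectrum falls as `1/f^alpha`, renormalised to unit variance.
#'
#' @param N Samples.
#' @param alpha Spectral exponent (default 1, pink noise).
#' @return Numeric vector of length `N`.
#' @export
colored_noise <- function(N, alpha = 1) {
  w <- rnorm(N)
  spec <- fft(w)
  freq <- c(0, seq_len(N - 1))
  freq <- pmin(freq, N - freq)  # two-sided frequency index
  gain <- ifelse(freq == 0, 0, 1 / freq^(alpha / 2))
  x <- Re(fft(spec * gain, inverse = TRUE)) / N
  x / sd(x)
}

#' Simulate a multichannel EEG record
#'
#' Applies the instantaneous linear forward model `C = W S`: every source
#' waveform is projected onto the electrodes with inverse-square-distance
#' gains, recomputed per sample for moving sources. The VEP contribution
#' is retained per source in `ground_truth` so signal-to-noise can be
#' measured afterwards.
#'
#' @param montage A `pc_montage`.
#' @param specs List of [source_spec()]s.
#' @param n_epochs Number of epochs.
#' @param epoch_seconds Epoch duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param seed Integer seed.
#' @param distance_floor Floor for electrode-source distances.
#' @return A `pc_record` list: `data` (channels x samples), `fs`,
#'   `epoch_length`, `n_epochs`, `montage`, `ground_truth` (list of
#'   per-source channels x samples contributions plus the source kinds).
#' @export
simulate_record <- function(montage, specs, n_epochs = 30, epoch_seconds = 3,
                            fs = 256, seed = 1L, distance_floor = 1e-3) {
  stopifnot(n_epochs >= 1)
  epoch_length <- round(epoch_seconds * fs)
  N <- n_epochs * epoch_length
  src <- generate_sources(specs, N, fs, seed = seed, epoch_length = epoch_length)
  n_ch <- nrow(montage)
  contributions <- vector("list", length(specs))
  data <- matrix(0, n_ch, N)
  for (i in seq_along(specs)) {
    pos <- src$positions[[i]]
    if (attr(specs[[i]]$trajectory, "kind") == "fixed") {
      w <- mixing_weights(montage, pos[1, , drop = FALSE], floor = distance_floor)
      contrib <- w %*% matrix(src$waves[i, ], nrow = 1)
    } else {
      # per-sample gains: channels x samples matrix of 1/d^2
      ep <- montage_positions(montage)
      d2 <- outer(rowSums(ep^2), rep(1, N)) +
        outer(rep(1, n_ch), rowSums(pos^2)) - 2 * ep %*% t(pos)
      d <- sqrt(pmax(d2, 0))
      d[d < distance_floor] <- distance_floor
      contrib <- (1 / d^2) * matrix(src$waves[i, ], n_ch, N, byrow = TRUE)
    }
    contributions[[i]] <- contrib
    data <- data + contrib
  }
  rownames(data) <- montage$channel
  structure(
    list(data = data, fs = fs, epoch_length = epoch_length,
         n_epochs = n_epochs, montage = montage,
         ground_truth = list(
           kinds = vapply(specs, function(s) s$kind, character(1)),
           contributions = contributions
         ),
         seed = as.integer(seed)),
    class = "pc_record"
  )
}

#' @export
print.pc_record <- function(x, ...) {
  cat("<pc_record> ", nrow(x$data), " channels x ", ncol(x$data), " samples @ ",
      x$fs, " Hz (", x$n_epochs, " epochs of ", x$epoch_length, " samples)\n",
      sep = "")
  invisible(x)
}

#' Average a record across its epochs
#'
#' Returns the channels x epoch_length grand-average signal, the input
#' to single-map analyses of the evoked response.
#'
#' @param record A `pc_record`.
#' @return channels x epoch_length numeric matrix with channel rownames.
#' @export
epoch_average <- function(record) {
  L <- record$epoch_length
  idx <- matrix(seq_len(L * record$n_epochs), nrow = L)
  avg <- matrix(0, nrow(record$data), L)
  for (e in seq_len(record$n_epochs)) {
    avg <- avg + record$data[, idx[, e], drop = FALSE]
  }
  avg <- avg / record$n_epochs
  rownames(avg) <- rownames(record$data)
  avg
}

#' Channel-averaged signal-to-noise ratio of a simulated record
#'
#' `10 log10(P_signal / P_noise)` where `P_signal` is the mean power of
#' the VEP-only mixture across channels and `P_noise` the mean power of
#' the residual (everything else). Returns `Inf` when the record has no
#' noise power. Because the evoked waveform is a short transient inside
#' each epoch, the whole-record value is much lower than the SNR inside
#' the evoked window; pass `epoch_window` (within-epoch sample range) to
#' measure the latter.
#'
#' @param record A `pc_record` from [simulate_record()].
#' @param epoch_window Optional length-2 integer vector: restrict the
#'   power measurement to these within-epoch samples (e.g. around the
#'   VEP envelope peak).
#' @return SNR in dB.
#' @export
snr_db <- function(record, epoch_window = NULL) {
  gt <- record$ground_truth
  is_vep <- gt$kinds == "vep"
  if (!any(is_vep)) stop("record has no VEP contribution in ground_truth", call. = FALSE)
  sig <- Reduce(`+`, gt$contributions[is_vep])
  noise <- record$data - sig
  if (!is.null(epoch_window)) {
    within <- seq.int(epoch_window[1], epoch_window[2])
    idx <- as.vector(outer(within, (seq_len(record$n_epochs) - 1L) *
                             record$epoch_length, `+`))
    sig <- sig[, idx, drop = FALSE]
    noise <- noise[, idx, drop = FALSE]
  }
  p_sig <- mean(sig^2)
  p_noise <- mean(noise^2)
  if (p_noise == 0) return(Inf)
  10 * log10(p_sig / p_noise)
}

#' Default source configuration for synthetic EEG experiments
#'
#' One occipitally placed VEP source plus seven noise sources covering
#' the three noise families: a strong coherent frontal-midline 1/f
#' source (the spatial signature of ocular and frontal delta activity),
#' a weaker central 1/f source, a bilateral pair of white temporal
#' sources, two fixed harmonics (8 and 12.5 Hz) and one rotating 6 Hz
#' harmonic exercising source motion. The VEP gain compensates for the
#' narrow Gaussian envelope of the evoked waveform, whose time-averaged
#' power is small; whole-record mean-power SNR of a single simulated
#' trial lands around -20 to -10 dB, the range reported for single-trial
#' ERPs, while the evoked window itself is VEP-dominated posteriorly.
#'
#' @param vep_amplitude Gain on the VEP source.
#' @return List of [source_spec()]s; the VEP source is first.
#' @export
seeg_default_sources <- function(vep_amplitude = 5) {
  list(
    source_spec("vep", amplitude = vep_amplitude,
                trajectory = trajectory_fixed(0, -0.8, 0.1)),
    source_spec("colored", amplitude = 2.0, alpha = 1,
                trajectory = trajectory_fixed(0, 0.7, 0.3)),
    source_spec("colored", amplitude = 0.8, alpha = 1,
                trajectory = trajectory_fixed(0, 0.1, 0.6)),
    source_spec("white", amplitude = 0.4,
                trajectory = trajectory_fixed(-0.65, 0, 0.3)),
    source_spec("white", amplitude = 0.4,
                trajectory = trajectory_fixed(0.65, 0, 0.3)),
    source_spec("harmonic", amplitude = 0.4, frequency = 8,
                initial_phase = 0.7,
                trajectory = trajectory_fixed(-0.4, 0.5, 0.4)),
    source_spec("harmonic", amplitude = 0.4, frequency = 12.5,
                initial_phase = 2.1,
                trajectory = trajectory_fixed(0.4, 0.5, 0.4)),
    source_spec("harmonic", amplitude = 0.3, frequency = 6,
                initial_phase = 0,
                trajectory = trajectory_rotational(c(0, 0.2, 0.4), 0.25, 0.4))
  )
}

#' P300 speller flash schedule
#'
#' Row/column paradigm on a 6 x 6 character matrix: each stimulation
#' sequence flashes the 6 rows and 6 columns once (12 flashes), exactly
#' two of which intersect the target character (condition `"ERP"`); the
#' other ten are `"noERP"`. Onsets are spaced by the interstimulus
#' interval.
#'
#' @param n_characters Characters to spell.
#' @param sequences_per_character Stimulation sequences per character.
#' @param isi_ms Interstimulus interval, milliseconds.
#' @param fs Sampling rate, Hz.
#' @param epoch_ms Epoch duration after each onset, milliseconds.
#' @param seed Integer seed for the flash-order permutation.
#' @param start_sample 0-based sample of the first onset.
#' @return A `pc_schedule` tibble with columns `onset_sample` (0-based)
#'   and `condition`, plus attributes `isi_ms`, `fs` and `epoch_window`
#'   (samples relative to onset, `(0, epoch]`).
#' @export
speller_schedule <- function(n_characters, sequences_per_character,
                             isi_ms = 125, fs = 256, epoch_ms = 1000,
                             seed = 1L, start_sample = 0L) {
  stopifnot(n_characters >= 1, sequences_per_character >= 1,
            isi_ms > 0, fs > 0, epoch_ms > 0)
  isi_samples <- round(isi_ms * fs / 1000)
  set.seed(as.integer(seed))
  conditions <- character(0)
  for (ch in seq_len(n_characters)) {
    target_row <- ((ch - 1) %% 6) + 1
    target_col <- ((ch * 2 - 1) %% 6) + 1
    for (sq in seq_len(sequences_per_character)) {
      flashes <- sample(c(paste0("R", 1:6), paste0("C", 1:6)))
      hit <- flashes %in% c(paste0("R", target_row), paste0("C", target_col))
      conditions <- c(conditions, ifelse(hit, "ERP", "noERP"))
    }
  }
  n_events <- length(conditions)
  out <- tibble::tibble(
    onset_sample = start_sample + (seq_len(n_events) - 1L) * isi_samples,
    condition = conditions
  )
  structure(out, class = c("pc_schedule", class(out)),
            isi_ms = isi_ms, fs = fs,
            epoch_window = c(1L, as.integer(round(epoch_ms * fs / 1000))))
}

#' Read or write a flash schedule as TSV
#'
#' Two tab-separated columns with a header: `onset_sample` (0-based) and
#' `condition`.
#'
#' @param path File path.
#' @param fs Sampling rate to attach, Hz.
#' @param epoch_ms Epoch duration to attach, milliseconds.
#' @export
read_schedule <- function(path, fs = 256, epoch_ms = 1000) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("onset_sample", "condition") %in% names(df)))
  if (is.unsorted(df$onset_sample, strictly = TRUE)) {
    stop("schedule onsets must be strictly increasing", call. = FALSE)
  }
  structure(tibble::as_tibble(df), class = c("pc_schedule", "tbl_df", "tbl", "data.frame"),
            fs = fs, epoch_window = c(1L, as.integer(round(epoch_ms * fs / 1000))))
}

#' @rdname read_schedule
#' @param schedule Schedule to write.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule)[, c("onset_sample", "condition")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
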