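# Time-frequency decomposition: geometric frequency grid, complex Morlet
# wavelets (rho cycles, unit-energy), FFT convolution, instantaneous phase
# via atan2, and squared-magnitude power.

#' Geometric grid of analysis center frequencies
#'
#' `K` center frequencies spaced evenly on a log axis between `fmin` and
#' `fmax`: `centers[k] = exp(log fmin + (log fmax - log fmin) * k/(K-1))`
#' for `k = 0..K-1`, so both endpoints are included and the ratio between
#' consecutive centers is constant. The defaults (1-12 Hz, 12 bands) give
#' the delta/theta/alpha grid whose centers round to 1.0, 1.3, 1.6, 2.0,
#' 2.5, 3.1, 3.9, 4.9, 6.1, 7.6, 9.6 and 12.0 Hz.
#'
#' @param fmin,fmax Band edges in Hz, `0 < fmin < fmax`.
#' @param K Number of bands, at least 2.
#' @return A `pc_freq_grid`: tibble with columns `band` (1-based index),
#'   `center_hz`, and `label` (center rounded to one decimal, display only).
#' @examples
#' center_frequencies(1, 12, 12)
#' @export
center_frequencies <- function(fmin = 1, fmax = 12, K = 12) {
  if (!(fmin > 0 && fmax > fmin)) stop("need 0 < fmin < fmax", call. = FALSE)
  if (K < 2) stop("K must be at least 2", call. = FALSE)
  k <- 0:(K - 1)
  centers <- exp(log(fmin) + (log(fmax) - log(fmin)) * k / (K - 1))
  out <- tibble::tibble(
    band = k + 1L,
    center_hz = centers,
    label = sprintf("%.1f", round(centers + 1e-12, 1))
  )
  structure(out, class = c("pc_freq_grid", class(out)),
            fmin = fmin, fmax = fmax, K = as.integer(K))
}

#' Complex Morlet wavelet
#'
#' A complex exponential at `fk` under a Gaussian envelope with standard
#' deviation `sigma = cycles / (2 pi fk)` seconds, sampled at `fs` over
#' +/- 4 sigma and normalised to unit energy. Phase estimates downstream
#' are invariant to the normalisation; power maps are comparable across
#' bands only up to it.
#'
#' @param fk Center frequency, Hz; must resolve below the Nyquist rate.
#' @param cycles Number of wavelet cycles (envelope width in periods).
#' @param fs Sampling rate, Hz.
#' @return Complex vector (odd length, centred) with attributes
#'   `sigma_s` (envelope SD in seconds) and `fk`.
#' @export
morlet <- function(fk, cycles = 4, fs = 256) {
  stopifnot(fk > 0, cycles >= 1)
  if (fk >= fs / 2) stop("fk must be below the Nyquist frequency fs/2", call. = FALSE)
  sigma_s <- cycles / (2 * pi * fk)
  half <- ceiling(4 * sigma_s * fs)
  t <- (-half:half) / fs
  w <- exp(1i * 2 * pi * fk * t) * exp(-t^2 / (2 * sigma_s^2))
  w <- w / sqrt(sum(Mod(w)^2))
  structure(w, sigma_s = sigma_s, fk = fk)
}

# centred same-length convolution via FFT; x real, h complex
.conv_same <- function(x, h) {
  n <- length(x)
  m <- length(h)
  L <- stats::nextn(n + m - 1, 2)
  X <- fft(c(x, rep(0, L - n)))
  H <- fft(c(h, rep(0, L - m)))
  full <- fft(X * H, inverse = TRUE) / L
  start <- (m - 1) %/% 2 + 1
  full[start:(start + n - 1)]
}

#' Continuous wavelet decomposition of a multichannel record
#'
#' Convolves every channel with the complex Morlet wavelet of each band
#' (zero-padded, same-length output). Samples within 4 sigma of either
#' record edge are inside the cone of influence and flagged.
#'
#' @param signals channels x samples numeric matrix (or a `pc_record`).
#' @param grid A [center_frequencies()] grid.
#' @param cycles Wavelet cycles.
#' @param fs Sampling rate, Hz.
#' @param strict_support If `TRUE` (default), a record shorter than the
#'   longest wavelet support is an error. Set `FALSE` to decompose short
#'   segments anyway (e.g. a single grand-average epoch at low
#'   frequencies); affected bands are then entirely inside the cone of
#'   influence and flagged as such.
#' @return A `pc_analytic` object: complex array channels x samples x
#'   bands with attributes `fs`, `grid`, and `coi` (samples x bands
#'   logical matrix, TRUE inside the cone of influence).
#' @export
analytic_decompose <- function(signals, grid = center_frequencies(),
                               cycles = 4, fs = NULL, strict_support = TRUE) {
  if (inherits(signals, "pc_record")) {
    if (is.null(fs)) fs <- signals$fs
    signals <- signals$data
  }
  if (is.null(fs)) stop("fs must be supplied for a bare matrix", call. = FALSE)
  signals <- rbind(signals)
  n_ch <- nrow(signals)
  N <- ncol(signals)
  K <- nrow(grid)
  banks <- lapply(grid$center_hz, morlet, cycles = cycles, fs = fs)
  longest <- max(lengths(banks))
  if (strict_support && N < longest) {
    stop("record (", N, " samples) shorter than the longest wavelet support (",
         longest, " samples)", call. = FALSE)
  }
  out <- array(0i, dim = c(n_ch, N, K),
               dimnames = list(rownames(signals), NULL, grid$label))
  coi <- matrix(FALSE, N, K)
  for (k in seq_len(K)) {
    h <- banks[[k]]
    for (j in seq_len(n_ch)) {
      out[j, , k] <- .conv_same(signals[j, ], h)
    }
    edge <- ceiling(4 * attr(h, "sigma_s") * fs)
    idx <- c(seq_len(min(edge, N)), seq.int(max(1L, N - edge + 1L), N))
    coi[unique(idx), k] <- TRUE
  }
  structure(out, fs = fs, grid = grid, coi = coi, cycles = cycles,
            class = "pc_analytic")
}

#' Instantaneous phase of an analytic decomposition
#'
#' Four-quadrant inverse tangent of each complex coefficient, in
#' `(-pi, pi]`. Exactly-zero coefficients map to phase 0 and are counted
#' in the `n_zero` attribute.
#'
#' @param analytic A `pc_analytic` array from [analytic_decompose()].
#' @return A `pc_phase` array channels x samples x bands of radians,
#'   carrying the same `fs`, `grid` and `coi` attributes.
#' @export
instantaneous_phase <- function(analytic) {
  theta <- atan2(Im(analytic), Re(analytic))
  n_zero <- sum(analytic == 0)
  structure(theta, fs = attr(analytic, "fs"), grid = attr(analytic, "grid"),
            coi = attr(analytic, "coi"), n_zero = n_zero,
            dimnames = dimnames(analytic), class = "pc_phase")
}

#' Time-frequency power of an analytic decomposition
#'
#' @param analytic A `pc_analytic` array.
#' @return A `pc_power` array channels x samples x bands of squared
#'   coefficient magnitudes.
#' @export
tf_power <- function(analytic) {
  p <- Mod(analytic)^2
  structure(p, fs = attr(analytic, "fs"), grid = attr(analytic, "grid"),
            coi = attr(analytic, "coi"), dimnames = dimnames(analytic),
            class = "pc_power")
}

#' @export
print.pc_analytic <- function(x, ...) {
  d <- dim(x)
  cat("<pc_analytic> ", d[1], " channels x ", d[2], " samples x ", d[3],
      " bands @ ", attr(x, "fs"), " Hz\n", sep = "")
  invisible(x)
}

#' @export
print.pc_phase <- function(x, ...) {
  d <- dim(x)
  cat("<pc_phase> ", d[1], " channels x ", d[2], " samples x ", d[3],
      " bands, radians in (-pi, pi]\n", sep = "")
  invisible(x)
}
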