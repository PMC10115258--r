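#' Frequency-band analysis parameters
#'
#' A band bundles the four parameters the pipeline needs per rhythm: the
#' LFP filter band, the (upward-shifted) spike-PSD band, the
#' autocorrelogram lag window, and the power-index edge frequency.
#' `band_specs()` returns the study's two bands: the 4-Hz band (LFP 3-5
#' Hz, spikes 4-6 Hz, lags 200-300 ms, edge 6 Hz) and theta (LFP 6-10
#' Hz, spikes 8-15 Hz, lags 100-200 ms, edge 15 Hz).
#'
#' @param name band label.
#' @param lfp_band LFP filter edges (Hz).
#' @param spike_band spike-PSD band (Hz).
#' @param acg_lag_window ACG feature window (ms), within +/-500 ms.
#' @param index_edge power-index edge frequency (Hz).
#' @return a `band_spec` (named list).
#' @export
band_spec <- function(name, lfp_band, spike_band, acg_lag_window, index_edge) {
  stopifnot(lfp_band[1] < lfp_band[2], spike_band[1] < spike_band[2],
            acg_lag_window[1] < acg_lag_window[2], acg_lag_window[2] <= 500)
  structure(list(name = name, lfp_band = lfp_band, spike_band = spike_band,
                 acg_lag_window = acg_lag_window, index_edge = index_edge),
            class = "band_spec")
}

#' @rdname band_spec
#' @export
band_specs <- function() {
  list(
    fourhz = band_spec("fourhz", c(3, 5), c(4, 6), c(200, 300), 6),
    theta  = band_spec("theta", c(6, 10), c(8, 15), c(100, 200), 15))
}

#' Least-squares linear-phase FIR design
#'
#' Type-I (odd-length, symmetric) FIR whose amplitude response minimises
#' the integrated squared error against a piecewise-linear desired
#' response, with transition intervals left unconstrained ("don't
#' care").  This is the classical least-squares design used by EEG
#' band-pass filtering toolchains.
#'
#' @param order filter order (even; length is `order + 1`).
#' @param bands matrix with one row per constrained band: columns
#'   `f_lo`, `f_hi` (Hz), `d_lo`, `d_hi` (desired amplitude at the
#'   edges).
#' @param fs sampling rate (Hz).
#' @return numeric vector of `order + 1` filter coefficients.
#' @export
fir_ls <- function(order, bands, fs) {
  if (order %% 2 != 0) order <- order + 1
  M <- order / 2
  # Work in omega = pi * f / nyquist, so omega in [0, pi].
  om1 <- pi * bands[, 1] / (fs / 2)
  om2 <- pi * bands[, 2] / (fs / 2)
  d1 <- bands[, 3]; d2 <- bands[, 4]

  # I(m) = sum over bands of \int cos(m w) dw
  m_all <- 0:(2 * M)
  Ivec <- vapply(m_all, function(m) {
    if (m == 0) sum(om2 - om1)
    else sum((sin(m * om2) - sin(m * om1)) / m)
  }, numeric(1))

  jj <- 0:M
  Q <- 0.5 * (matrix(Ivec[abs(outer(jj, jj, "-")) + 1], M + 1, M + 1) +
              matrix(Ivec[outer(jj, jj, "+") + 1], M + 1, M + 1))

  b <- vapply(jj, function(j) {
    tot <- 0
    for (r in seq_len(nrow(bands))) {
      a <- om1[r]; bb <- om2[r]
      if (j == 0) {
        tot <- tot + (d1[r] + d2[r]) / 2 * (bb - a)
      } else {
        sl <- if (bb > a) (d2[r] - d1[r]) / (bb - a) else 0
        tot <- tot + (d2[r] * sin(j * bb) - d1[r] * sin(j * a)) / j +
          sl * (cos(j * bb) - cos(j * a)) / j^2
      }
    }
    tot
  }, numeric(1))

  cc <- solve(Q, b)
  h <- numeric(order + 1)
  h[M + 1] <- cc[1]
  if (M > 0) {
    h[M + 1 + seq_len(M)] <- cc[-1] / 2
    h[M + 1 - seq_len(M)] <- cc[-1] / 2
  }
  h
}

# Causal FIR filtering via FFT convolution (equivalent to filter(b,1,x)).
causal_fir <- function(b, x) {
  n <- length(x); L <- length(b)
  N <- stats::nextn(n + L - 1)
  X <- stats::fft(c(x, numeric(N - n)))
  B <- stats::fft(c(b, numeric(N - L)))
  y <- Re(stats::fft(X * B, inverse = TRUE)) / N
  y[seq_len(n)]
}

# Zero-phase two-pass FIR filtering with reflection padding.
filtfilt_fir <- function(b, x) {
  n <- length(x); L <- length(b)
  p <- min(L, n - 1)
  if (p < 1) stop("filtfilt_fir: input too short")
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y1 <- causal_fir(b, xp)
  y2 <- rev(causal_fir(b, rev(y1)))
  # each causal pass delays by (L-1); two passes with a reversal cancel
  y2[(p + 1):(p + n)]
}

#' Band-pass filter an LFP trace
#'
#' Zero-phase (two-pass) least-squares FIR band-pass in the style of the
#' EEG toolbox filter, with 15% transition bands and unit pass-band.
#' The order is `6 * floor(fs / lo)` -- twice the common EEG default --
#' because a narrow pass band (2 Hz for the 3-5 Hz component) needs
#' roughly that length before the least-squares response is flat to
#' within a few percent across the band interior.  The two passes
#' square the magnitude response, so stop-band attenuation is doubled
#' while the pass band stays within a few percent of unity.
#'
#' @param lfp numeric trace.
#' @param band a [band_spec()] (its `lfp_band` is used) or numeric
#'   `c(lo, hi)` in Hz.
#' @param fs sampling rate (Hz); `hi * (1 + trans)` must be below
#'   Nyquist.
#' @param trans transition-band fraction of each edge frequency.
#' @return filtered trace, same length.
#' @export
bandpass <- function(lfp, band, fs, trans = 0.15) {
  edges <- if (inherits(band, "band_spec")) band$lfp_band else band
  lo <- edges[1]; hi <- edges[2]
  if (hi * (1 + trans) >= fs / 2)
    stop("bandpass: band too close to Nyquist")
  if (lo <= 0) stop("bandpass: lower edge must be > 0")
  ord <- 6 * floor(fs / lo)
  if (ord %% 2 != 0) ord <- ord + 1
  bands <- rbind(c(0, lo * (1 - trans), 0, 0),
                 c(lo, hi, 1, 1),
                 c(hi * (1 + trans), fs / 2, 0, 0))
  h <- fir_ls(ord, bands, fs)
  filtfilt_fir(h, lfp)
}

#' Instantaneous amplitude, phase, and frequency of a band component
#'
#' Computes the analytic signal of an (already band-limited) trace via
#' the frequency-domain Hilbert transform.  Amplitude is the modulus,
#' phase the wrapped argument, and instantaneous frequency the smoothed
#' derivative of the unwrapped phase (median filter over
#' `freq_smooth_s`), clipped to `[0, fs/2]`.
#'
#' @param filtered band-limited numeric trace.
#' @param fs sampling rate (Hz).
#' @param freq_smooth_s median-filter window for the frequency estimate
#'   (s).
#' @return an `instantaneous_metrics` list: `time` (s), `amplitude`
#'   (uV), `phase` (rad, wrapped to (-pi, pi]), `frequency` (Hz).
#' @export
analytic_metrics <- function(filtered, fs, freq_smooth_s = 0.1) {
  n <- length(filtered)
  if (n < 2 * fs) stop("analytic_metrics: need at least 2 s of signal")
  z <- analytic_signal(filtered)
  amp <- Mod(z)
  ph <- Arg(z)
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi  # unwrap increments
  freq <- c(dph, dph[n - 1]) * fs / (2 * pi)
  k <- round(freq_smooth_s * fs)
  if (k %% 2 == 0) k <- k + 1
  if (k >= 3 && k < n) freq <- as.numeric(stats::runmed(freq, k))
  freq <- pmin(pmax(freq, 0), fs / 2)
  structure(list(time = (seq_len(n) - 1) / fs, amplitude = amp,
                 phase = ph, frequency = freq, fs = fs),
            class = "instantaneous_metrics")
}

# Analytic signal via FFT (one-sided spectrum doubling).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms with a Hamming taper: the study's
#' convention is 1-s windows with 90% overlap for LFP and 5-s windows
#' with no overlap for spike trains.  Windows are zero-padded by
#' `nfft_factor` so the grid is fine enough for sub-bin peak
#' interpolation.
#'
#' @param x numeric signal (assumed approximately zero-mean unless
#'   `demean_windows`).
#' @param fs sampling rate (Hz).
#' @param window_s window length (s).
#' @param overlap fractional overlap in `[0, 1)`.
#' @param nfft_factor zero-padding factor (>= 1).
#' @param demean_windows subtract each window's mean before tapering.
#' @param fmax truncate the frequency grid at this frequency (Hz);
#'   `NULL` keeps the full one-sided grid.
#' @return a `psd_estimate`: list with `freq` (Hz), `power` (uV^2/Hz,
#'   one-sided density), `meta` (window, overlap, nfft, n_windows).
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.9, nfft_factor = 8,
                      demean_windows = FALSE, fmax = NULL) {
  nw <- round(window_s * fs)
  if (length(x) < nw)
    stop("welch_psd: signal shorter than one window (insufficient data)")
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  acc <- welch_accumulate(x, starts, nw, fs, nfft_factor, demean_windows)
  psd_finalize(acc, fs, nw, overlap, nfft_factor, fmax)
}

# Accumulate modified periodograms for windows starting at `starts`.
welch_accumulate <- function(x, starts, nw, fs, nfft_factor, demean_windows) {
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))  # Hamming
  U <- sum(w^2)
  nfft <- nw * nfft_factor
  nb <- nfft %/% 2 + 1
  tot <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + nw - 1)]
    if (demean_windows) seg <- seg - mean(seg)
    X <- stats::fft(c(seg * w, numeric(nfft - nw)))
    P <- (Mod(X[1:nb])^2) / (fs * U)
    P[2:(nb - 1)] <- 2 * P[2:(nb - 1)]
    tot <- tot + P
  }
  list(total = tot, n_windows = length(starts), nfft = nfft)
}

psd_finalize <- function(acc, fs, nw, overlap, nfft_factor, fmax) {
  nb <- length(acc$total)
  freq <- (0:(nb - 1)) * fs / acc$nfft
  power <- acc$total / acc$n_windows
  if (!is.null(fmax)) {
    sel <- freq <= fmax
    freq <- freq[sel]; power <- power[sel]
  }
  structure(list(freq = freq, power = power,
                 meta = list(window_s = nw / fs, overlap = overlap,
                             nfft = acc$nfft, nfft_factor = nfft_factor,
                             n_windows = acc$n_windows, fs = fs)),
            class = "psd_estimate")
}

#' Welch PSD restricted to kept samples
#'
#' Splits the signal at mask gaps and accumulates Welch windows only
#' within contiguous kept segments at least one window long, so spectra
#' are never computed across excluded data.
#'
#' @param x numeric signal.
#' @param keep logical keep-flag per sample (same length).
#' @inheritParams welch_psd
#' @return a `psd_estimate`, or `NULL` if no segment fits one window.
#' @export
welch_psd_masked <- function(x, keep, fs, window_s = 1, overlap = 0.9,
                             nfft_factor = 8, demean_windows = FALSE,
                             fmax = NULL) {
  nw <- round(window_s * fs)
  segs <- kept_segments(keep, min_len = nw)
  if (!nrow(segs)) return(NULL)
  step <- max(1L, round(nw * (1 - overlap)))
  tot <- NULL; n_windows <- 0; nfft <- nw * nfft_factor
  for (i in seq_len(nrow(segs))) {
    seg <- x[segs$start[i]:segs$end[i]]
    starts <- seq(1L, length(seg) - nw + 1L, by = step)
    acc <- welch_accumulate(seg, starts, nw, fs, nfft_factor, demean_windows)
    tot <- if (is.null(tot)) acc$total else tot + acc$total
    n_windows <- n_windows + acc$n_windows
  }
  psd_finalize(list(total = tot, n_windows = n_windows, nfft = nfft),
               fs, nw, overlap, nfft_factor, fmax)
}

#' Time-frequency decomposition (short-time Welch spectrogram)
#'
#' Modified periodograms on sliding windows (2-s windows, 90% overlap by
#' convention), Hamming-tapered, one-sided density per window.
#'
#' @inheritParams welch_psd
#' @param window_s window length (s).
#' @return list with `time` (window centres, s), `freq` (Hz), `power`
#'   (matrix, frequency x time).
#' @export
spectrogram_tf <- function(x, fs, window_s = 2, overlap = 0.9,
                           nfft_factor = 2, fmax = NULL) {
  nw <- round(window_s * fs)
  if (length(x) < nw) stop("spectrogram_tf: signal shorter than one window")
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  U <- sum(w^2)
  nfft <- nw * nfft_factor
  nb <- nfft %/% 2 + 1
  freq <- (0:(nb - 1)) * fs / nfft
  sel <- if (is.null(fmax)) rep(TRUE, nb) else freq <= fmax
  P <- matrix(0, sum(sel), length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nw - 1)]
    X <- stats::fft(c(seg * w, numeric(nfft - nw)))
    p <- (Mod(X[1:nb])^2) / (fs * U)
    p[2:(nb - 1)] <- 2 * p[2:(nb - 1)]
    P[, i] <- p[sel]
  }
  list(time = (starts - 1 + nw / 2) / fs, freq = freq[sel], power = P)
}

#' Band power and interpolated peak frequency
#'
#' `band_power` is the mean power density over the band; `peak_frequency`
#' is the in-band argmax refined by three-point parabolic interpolation
#' (the 1-s Welch windows give coarse native bins, so sub-bin peak
#' contrasts need both zero padding and interpolation).
#'
#' @param psd a `psd_estimate`.
#' @param band numeric `c(lo, hi)` in Hz (for a [band_spec()] pass its
#'   `lfp_band`/`spike_band`).
#' @return scalar power (uV^2/Hz) or peak frequency (Hz).
#' @export
band_power <- function(psd, band) {
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (!any(sel)) stop("band_power: band outside frequency grid")
  mean(psd$power[sel])
}

#' @rdname band_power
#' @export
peak_frequency <- function(psd, band) {
  sel <- which(psd$freq >= band[1] & psd$freq <= band[2])
  if (!length(sel)) stop("peak_frequency: band outside frequency grid")
  i <- sel[which.max(psd$power[sel])]
  df <- psd$freq[2] - psd$freq[1]
  if (i > 1 && i < length(psd$freq)) {
    ym <- psd$power[i - 1]; y0 <- psd$power[i]; yp <- psd$power[i + 1]
    den <- ym - 2 * y0 + yp
    if (den < 0) return(psd$freq[i] + df / 2 * (ym - yp) / den)
  }
  psd$freq[i]
}

#' Relative (sum-normalised) PSD
#'
#' Divides the power values by their sum over the grid, truncated at
#' `fmax` (50 Hz for LFP spectra so the denominator does not depend on
#' the estimator's upper grid limit; spike spectra keep their full
#' grid).
#'
#' @param psd a `psd_estimate`.
#' @param fmax grid truncation (Hz) before normalisation; `NULL` for
#'   none.
#' @return a `psd_estimate` whose `power` sums to 1.
#' @export
relative_psd <- function(psd, fmax = 50) {
  freq <- psd$freq; power <- psd$power
  if (!is.null(fmax)) {
    sel <- freq <= fmax
    freq <- freq[sel]; power <- power[sel]
  }
  s <- sum(power)
  if (s <= 0) stop("relative_psd: total power is zero")
  structure(list(freq = freq, power = power / s,
                 meta = c(psd$meta, list(relative = TRUE, fmax = fmax))),
            class = "psd_estimate")
}

#' Band power index of a relative PSD
#'
#' `max(relative PSD within the band) - relative PSD at the band's edge
#' frequency` (6 Hz for the 4-6 Hz spike band, 15 Hz for theta).
#' Compares rhythmic concentration across conditions with different
#' baseline power; may be <= 0 for non-rhythmic activity.
#'
#' @param rel_psd a relative `psd_estimate` (power sums to 1).
#' @param band a [band_spec()] (uses `spike_band` and `index_edge`).
#' @return scalar index (unitless).
#' @export
power_index <- function(rel_psd, band) {
  sb <- band$spike_band; edge <- band$index_edge
  if (edge > max(rel_psd$freq) || sb[1] > max(rel_psd$freq))
    stop("power_index: band or edge outside frequency grid")
  sel <- rel_psd$freq >= sb[1] & rel_psd$freq <= sb[2]
  i_edge <- which.min(abs(rel_psd$freq - edge))
  max(rel_psd$power[sel]) - rel_psd$power[i_edge]
}
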