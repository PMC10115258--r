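#' LFP autocorrelogram over kept trial samples
#'
#' Per-trial +/-0.5-s autocorrelograms of the (preprocessed) LFP in the
#' `'coeff'` convention: `r(k) = sum(x_t x_{t+k}) / sum(x_t^2)`, so the
#' zero-lag value is exactly 1.  Within a trial the ACG is computed per
#' contiguous kept segment (>= 1 s) and averaged weighted by segment
#' length, so lags never straddle excluded data; the trial traces are
#' then averaged into the group trace.
#'
#' @param lfp numeric LFP trace for the whole session.
#' @param trials trial table (`t_start`, `t_end`, `trial_id`).
#' @param fs sampling rate (Hz).
#' @param keep optional logical keep-mask per sample (default all).
#' @param max_lag_s maximum lag (s).
#' @return an `acg_result`: `lags_ms`, `average` (trace), `per_trial`
#'   (matrix trials x lags, NA rows for skipped trials), `skipped`
#'   (trial ids with < 1 s kept), `source = "lfp"`.
#' @export
lfp_acg <- function(lfp, trials, fs, keep = NULL, max_lag_s = 0.5) {
  if (is.null(keep)) keep <- rep(TRUE, length(lfp))
  nlag <- round(max_lag_s * fs)
  lags <- -nlag:nlag
  per_trial <- matrix(NA_real_, nrow(trials), 2 * nlag + 1)
  skipped <- integer(0)
  for (i in seq_len(nrow(trials))) {
    i0 <- floor(trials$t_start[i] * fs) + 1
    i1 <- min(length(lfp), ceiling(trials$t_end[i] * fs))
    segs <- kept_segments(keep[i0:i1], min_len = fs)  # >= 1 s
    if (!nrow(segs)) { skipped <- c(skipped, trials$trial_id[i]); next }
    acc <- numeric(2 * nlag + 1); wtot <- 0
    for (s in seq_len(nrow(segs))) {
      x <- lfp[(i0 + segs$start[s] - 1):(i0 + segs$end[s] - 1)]
      acc <- acc + length(x) * acg_coeff(x, nlag)
      wtot <- wtot + length(x)
    }
    per_trial[i, ] <- acc / wtot
  }
  ok <- !is.na(per_trial[, 1])
  if (!any(ok)) stop("lfp_acg: no trial had >= 1 s of kept samples")
  structure(list(lags_ms = lags / fs * 1000,
                 average = colMeans(per_trial[ok, , drop = FALSE]),
                 per_trial = per_trial, skipped = skipped, source = "lfp"),
            class = "acg_result")
}

# 'coeff' autocorrelation of a single segment via FFT, lags -nlag..nlag.
acg_coeff <- function(x, nlag) {
  n <- length(x)
  N <- stats::nextn(2 * n)
  X <- stats::fft(c(x, numeric(N - n)))
  r <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / N
  pos <- r[1:(nlag + 1)] / r[1]
  c(rev(pos[-1]), pos)
}

#' Mean interpeak interval of an autocorrelogram
#'
#' The rhythm period read off an ACG trace: local maxima at positive
#' lags are detected with a prominence criterion (a fraction of the
#' trace's range, so low-amplitude ripples from a secondary rhythm or
#' noise are ignored), lag 0 is prepended as the zeroth peak, and the
#' mean spacing of successive peaks is returned in ms.
#'
#' @param acg an `acg_result` (its `average` trace is used) or a numeric
#'   trace with a matching `lags_ms` argument.
#' @param lags_ms lag grid (ms) when `acg` is a plain vector.
#' @param min_prominence peak prominence threshold as a fraction of the
#'   trace range.
#' @param max_lag_ms restrict peaks to lags up to this value.
#' @return list with `interpeak_ms` (mean spacing) and `peak_lags_ms`.
#' @export
acg_interpeak <- function(acg, lags_ms = NULL, min_prominence = 0.2,
                          max_lag_ms = 500) {
  if (inherits(acg, "acg_result")) {
    trace <- acg$average; lags_ms <- acg$lags_ms
  } else trace <- acg
  pos <- lags_ms > 0 & lags_ms <= max_lag_ms
  v <- trace[pos]; lg <- lags_ms[pos]
  rng <- diff(range(trace))
  pk <- find_peaks(v, min_prominence = min_prominence * rng)
  if (!length(pk$index))
    return(list(interpeak_ms = NA_real_, peak_lags_ms = numeric(0)))
  peak_lags <- sort(lg[pk$index])
  list(interpeak_ms = mean(diff(c(0, peak_lags))), peak_lags_ms = peak_lags)
}

#' Local maxima with topographic prominence
#'
#' A sample is a peak if strictly greater than its neighbours; its
#' prominence is its height above the higher of the two deepest valleys
#' separating it from higher terrain (the standard topographic
#' definition).  Peaks below `min_prominence` are dropped.
#'
#' @param v numeric trace.
#' @param min_prominence prominence threshold (same units as `v`).
#' @return list `index`, `value`, `prominence`.
#' @export
find_peaks <- function(v, min_prominence = 0) {
  n <- length(v)
  if (n < 3) return(list(index = integer(0), value = numeric(0),
                         prominence = numeric(0)))
  is_pk <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  prom <- vapply(is_pk, function(i) {
    # walk left/right to the first sample higher than v[i]
    left <- if (i > 1) v[1:(i - 1)] else numeric(0)
    hl <- which(left > v[i])
    lmin <- if (length(hl)) min(left[(max(hl) + 1):(i - 1)]) else min(left)
    right <- if (i < n) v[(i + 1):n] else numeric(0)
    hr <- which(right > v[i])
    rmin <- if (length(hr)) min(right[1:(min(hr) - 1)]) else min(right)
    v[i] - max(lmin, rmin)
  }, numeric(1))
  sel <- prom >= min_prominence
  list(index = is_pk[sel], value = v[is_pk[sel]], prominence = prom[sel])
}

#' Spike-train autocorrelogram
#'
#' Histogram of spike-time differences within +/-`max_lag_ms`, on
#' `bin_ms` bins, restricted to spikes inside the supplied epochs.  The
#' zero-lag bin (trivially dominated by each spike paired with itself)
#' is removed.  Counts are divided by the number of reference spikes, a
#' spike-train dialect of the continuous `'coeff'` normalisation: each
#' value is then the expected number of spikes per bin at that lag,
#' i.e. rate * bin width for a Poisson train.
#'
#' @param spike_times sorted spike times (s).
#' @param epochs data.frame with `t_start`, `t_end` (s); spikes outside
#'   are dropped.  `NULL` keeps all spikes.
#' @param bin_ms bin width (ms).
#' @param max_lag_ms maximum lag (ms).
#' @param min_spikes minimum spikes required (an error below this).
#' @return an `acg_result`: `lags_ms` (bin centres, zero-lag removed),
#'   `average` (normalised counts), `n_spikes`, `source = "spike"`.
#' @export
spike_acg <- function(spike_times, epochs = NULL, bin_ms = 10,
                      max_lag_ms = 500, min_spikes = 100) {
  st <- spikes_in_epochs(spike_times, epochs)
  if (length(st) < min_spikes)
    stop("spike_acg: fewer than ", min_spikes, " spikes in epochs")
  max_lag <- max_lag_ms / 1000
  # pairwise differences within the lag window (two-pointer sweep)
  n <- length(st)
  hi <- findInterval(st + max_lag, st)
  diffs <- unlist(lapply(seq_len(n), function(i) {
    if (hi[i] > i) st[(i + 1):hi[i]] - st[i] else numeric(0)
  }))
  nb <- round(max_lag_ms / bin_ms)
  edges <- seq(0, max_lag, length.out = nb + 1)
  cnt <- graphics::hist(diffs[diffs > 0 & diffs <= max_lag],
                        breaks = edges, plot = FALSE)$counts
  centers <- (edges[-1] + edges[-(nb + 1)]) / 2 * 1000
  vals <- cnt / n  # per reference spike; one-sided counts mirrored
  structure(list(lags_ms = c(-rev(centers), centers),
                 average = c(rev(vals), vals),
                 n_spikes = n, source = "spike"),
            class = "acg_result")
}

spikes_in_epochs <- function(spike_times, epochs) {
  if (is.null(epochs) || !nrow(epochs)) return(spike_times)
  keep <- rep(FALSE, length(spike_times))
  for (i in seq_len(nrow(epochs)))
    keep <- keep | (spike_times >= epochs$t_start[i] &
                    spike_times < epochs$t_end[i])
  spike_times[keep]
}

#' Min-max normalise an autocorrelogram
#'
#' `NormACG = (ACG - min(ACG)) / (max(ACG) - min(ACG))`, mapping each
#' neuron's ACG to `[0, 1]` before group averaging and feature
#' extraction.
#'
#' @param acg an `acg_result` or numeric trace.
#' @return object of the same shape with the trace rescaled to `[0, 1]`.
#' @export
normalize_acg <- function(acg) {
  v <- if (inherits(acg, "acg_result")) acg$average else acg
  rng <- range(v)
  if (diff(rng) == 0)
    stop("normalize_acg: constant ACG (degenerate input)")
  out <- (v - rng[1]) / diff(rng)
  if (inherits(acg, "acg_result")) { acg$average <- out; acg } else out
}

#' Band-window peak features of a normalised ACG
#'
#' Within the band's positive-lag window (200-300 ms for the 4-Hz band,
#' 100-200 ms for theta): `peak_amplitude` is the largest local maximum
#' of the NormACG trace and `interpeak_ms` its lag (the distance from
#' lag 0 to the first band peak).  Ties break toward the smaller lag.
#' If the window contains no local maximum the value at the window's
#' maximum is returned with `boundary = TRUE`.
#'
#' @param normacg a normalised `acg_result` or numeric trace in `[0,1]`.
#' @param band a [band_spec()] (uses `acg_lag_window`).
#' @param lags_ms lag grid (ms) when `normacg` is a plain vector.
#' @return list `peak_amplitude`, `interpeak_ms`, `boundary`.
#' @export
acg_band_features <- function(normacg, band, lags_ms = NULL) {
  if (inherits(normacg, "acg_result")) {
    v <- normacg$average; lags_ms <- normacg$lags_ms
  } else v <- normacg
  w <- band$acg_lag_window
  if (w[2] > max(lags_ms)) stop("acg_band_features: window outside trace support")
  sel <- which(lags_ms >= w[1] & lags_ms <= w[2])
  if (length(sel) < 1) stop("acg_band_features: empty lag window")
  # local maxima within the window (neighbours may lie just outside it)
  is_peak <- vapply(sel, function(i) {
    left <- if (i > 1) v[i] >= v[i - 1] else TRUE
    right <- if (i < length(v)) v[i] >= v[i + 1] else TRUE
    left && right
  }, logical(1))
  if (any(is_peak)) {
    cand <- sel[is_peak]
    best <- cand[which.max(v[cand])]
    # ties toward smaller lag
    best <- min(cand[v[cand] == v[best]])
    lag <- lags_ms[best]
    if (best > 1 && best < length(v)) {
      # sub-bin lag via 3-point parabola (10-ms spike bins would otherwise
      # quantise interpeak contrasts of a few ms)
      den <- v[best - 1] - 2 * v[best] + v[best + 1]
      if (den < 0) {
        dl <- (lags_ms[best + 1] - lags_ms[best - 1]) / 2
        lag <- lag + dl / 2 * (v[best - 1] - v[best + 1]) / den
      }
    }
    list(peak_amplitude = v[best], interpeak_ms = lag, boundary = FALSE)
  } else {
    best <- sel[which.max(v[sel])]
    list(peak_amplitude = v[best], interpeak_ms = lags_ms[best],
         boundary = TRUE)
  }
}

#' Rhythmicity modulation depth of a spike ACG
#'
#' Screening statistic behind the 0.2 inclusion threshold: the ACG is
#' smoothed with a short boxcar, divided by its mean over 50-500 ms
#' lags (the asymptotic Poisson level, so the statistic is independent
#' of firing rate), and the maximum excess over that baseline within
#' 50-500 ms is returned.  A homogeneous Poisson train concentrates
#' near 0; a von Mises phase-locked train with concentration kappa has
#' expected peak depth `I0(2*kappa)/I0(kappa)^2 - 1` (~0.42 at
#' kappa = 1).
#'
#' @param acg a spike `acg_result`.
#' @param lag_range_ms lag window over which the maximum is taken (the
#'   lower edge excludes the refractory/burst shoulder).
#' @param smooth_bins boxcar width in bins.
#' @return scalar modulation depth.
#' @export
acg_mod_depth <- function(acg, lag_range_ms = c(50, 500), smooth_bins = 3) {
  v <- acg$average
  if (smooth_bins > 1)
    v <- stats::filter(v, rep(1 / smooth_bins, smooth_bins), sides = 2)
  sel <- abs(acg$lags_ms) >= lag_range_ms[1] &
    abs(acg$lags_ms) <= lag_range_ms[2] & !is.na(v)
  base <- mean(v[sel])
  if (!is.finite(base) || base <= 0) return(0)
  max(v[sel]) / base - 1
}

#' Screen neurons for rhythmic spiking and extract rhythmicity features
#'
#' Applies the study's inclusion filters per neuron: mean firing rate
#' over the epochs must exceed `rate_min` (1 Hz) and the ACG modulation
#' depth ([acg_mod_depth()]) must exceed `depth_threshold` (0.2);
#' exclusions carry a reason code (`"rate"`, `"spikes"`,
#' `"threshold"`).  Included neurons get their NormACG band features and
#' relative spike PSD with band power indices.
#'
#' @param neurons list of neuron records (`id`, `cell_type`,
#'   `spike_times`).
#' @param epochs data.frame of analysis epochs (`t_start`, `t_end`).
#' @param bands list of [band_spec()]s.
#' @param rate_min inclusion threshold on mean rate (Hz).
#' @param depth_threshold inclusion threshold on ACG modulation depth.
#' @param bin_ms spike-ACG bin width (ms).
#' @param context,condition labels copied into the output table.
#' @return list with `table` (one row per neuron x band: `neuron_id`,
#'   `cell_type`, `context`, `condition`, `rate_hz`, `included`,
#'   `reason`, `band`, `acg_peak_amp`, `interpeak_ms`, `power_index`,
#'   `mod_depth`) and `details` (per-neuron ACG/PSD objects).
#' @export
rhythmicity_screen <- function(neurons, epochs, bands = band_specs(),
                               rate_min = 1, depth_threshold = 0.2,
                               bin_ms = 10, context = NA_character_,
                               condition = NA_character_) {
  total_s <- sum(epochs$t_end - epochs$t_start)
  rows <- list(); details <- list()
  for (nr in neurons) {
    st <- spikes_in_epochs(nr$spike_times, epochs)
    rate <- length(st) / total_s
    status <- list(included = TRUE, reason = "included")
    acg <- NULL; depth <- NA_real_
    if (rate <= rate_min) {
      status <- list(included = FALSE, reason = "rate")
    } else if (length(st) < 100) {
      status <- list(included = FALSE, reason = "spikes")
    } else {
      acg <- spike_acg(nr$spike_times, epochs, bin_ms = bin_ms)
      depth <- acg_mod_depth(acg)
      if (depth <= depth_threshold)
        status <- list(included = FALSE, reason = "threshold")
    }

    feats <- list(); rel <- NULL
    if (status$included) {
      nacg <- normalize_acg(acg)
      rel <- try(spike_psd(nr$spike_times, epochs), silent = TRUE)
      if (inherits(rel, "try-error")) rel <- NULL
      for (bn in names(bands)) {
        f <- acg_band_features(nacg, bands[[bn]])
        feats[[bn]] <- list(
          amp = f$peak_amplitude, ipi = f$interpeak_ms,
          pidx = if (!is.null(rel)) power_index(rel, bands[[bn]]) else NA_real_)
      }
      details[[nr$id]] <- list(acg = acg, normacg = nacg, rel_psd = rel,
                               mod_depth = depth)
    }
    for (bn in names(bands)) {
      f <- feats[[bn]]
      rows[[length(rows) + 1]] <- data.frame(
        neuron_id = nr$id, cell_type = nr$cell_type,
        context = context, condition = condition,
        rate_hz = rate, included = status$included, reason = status$reason,
        band = bn,
        acg_peak_amp = if (is.null(f)) NA_real_ else f$amp,
        interpeak_ms = if (is.null(f)) NA_real_ else f$ipi,
        power_index = if (is.null(f)) NA_real_ else f$pidx,
        mod_depth = depth, stringsAsFactors = FALSE)
    }
  }
  list(table = if (length(rows)) do.call(rbind, rows) else
         data.frame(), details = details)
}

#' Relative power spectrum of a spike train
#'
#' The spike train is binned to counts at `bin_fs` (200 Hz: 5-ms bins,
#' resolving <= 15 Hz structure with wide margin), each 5-s Welch window
#' is mean-subtracted (removing the DC rate term), windows do not
#' overlap, and the resulting density is normalised to sum 1 over the
#' grid.
#'
#' @param spike_times sorted spike times (s).
#' @param epochs analysis epochs; windows are accumulated within each
#'   epoch separately.
#' @param window_s Welch window (s).
#' @param overlap fractional overlap.
#' @param bin_fs count-binning rate (Hz).
#' @return a relative `psd_estimate` (power sums to 1).
#' @export
spike_psd <- function(spike_times, epochs, window_s = 5, overlap = 0,
                      bin_fs = 200) {
  if (is.null(epochs) || !nrow(epochs))
    stop("spike_psd: no epochs supplied")
  usable <- epochs[epochs$t_end - epochs$t_start >= window_s, , drop = FALSE]
  if (sum(epochs$t_end - epochs$t_start) < 15 || !nrow(usable))
    stop("spike_psd: insufficient epoch duration")
  tot <- NULL; n_windows <- 0; nfft <- NULL
  for (i in seq_len(nrow(usable))) {
    n_bins <- floor((usable$t_end[i] - usable$t_start[i]) * bin_fs)
    edges <- usable$t_start[i] + (0:n_bins) / bin_fs
    cnt <- graphics::hist(spikes_in_epochs(spike_times, usable[i, ]),
                          breaks = edges, plot = FALSE)$counts
    nw <- round(window_s * bin_fs)
    if (n_bins < nw) next
    step <- max(1L, round(nw * (1 - overlap)))
    starts <- seq(1L, n_bins - nw + 1L, by = step)
    acc <- welch_accumulate(cnt, starts, nw, bin_fs, nfft_factor = 1,
                            demean_windows = TRUE)
    tot <- if (is.null(tot)) acc$total else tot + acc$total
    n_windows <- n_windows + acc$n_windows
    nfft <- acc$nfft
  }
  if (is.null(tot)) stop("spike_psd: no epoch fits one window")
  psd <- psd_finalize(list(total = tot, n_windows = n_windows, nfft = nfft),
                      bin_fs, round(window_s * bin_fs), overlap, 1, NULL)
  relative_psd(psd, fmax = NULL)
}
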