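#' Generative configuration for synthetic recording sessions
#'
#' Bundles every parameter of the synthetic-session generator: two
#' speed-coupled oscillators (a slow ~4-Hz component and theta) over 1/f
#' background noise, an Ornstein-Uhlenbeck running-speed process, von
#' Mises phase-locked inhomogeneous-Poisson spike trains, and the
#' "post" (septal inactivation) transform that abolishes theta, slightly
#' slows both rhythms, lowers running speed, and weakens spike
#' entrainment.
#'
#' Amplitude law per oscillator x: `A_x(t) = max(0, a_x0 + g_x * speed(t))`
#' (microvolts).  Frequency law: `f_x(t) = f_x + h_x * (speed(t) - s_ref)`
#' where `s_ref` is the context's configured mean speed, so `f_x` is the
#' centre frequency at typical running speed while the positive
#' frequency-speed coupling remains recoverable.  Phase advances as the
#' integral of `2*pi*f_x(t)` plus a Brownian phase-diffusion term with
#' rate `phase_diff_*` (rad^2/s) that sets how quickly each rhythm loses
#' lag coherence.
#'
#' The slow oscillator is context-gated: its amplitude is multiplied by
#' `slow_in_maze` (default 0) during maze epochs, emulating the emergence
#' of the 4-Hz rhythm only during stationary running.
#'
#' @param fs_lfp LFP sampling rate (Hz).
#' @param fs_beh behavioural (speed) sampling rate (Hz); `fs_lfp` must be
#'   an integer multiple.
#' @param n_trials_per_context number of trials per context (maze, wheel).
#' @param trial_duration trial length (s); wheel runs last ~15 s.
#' @param f_slow,f_theta oscillator centre frequencies (Hz), slow < theta.
#' @param a_slow0,a_theta0 baseline amplitudes (uV).
#' @param g_slow_speed,g_theta_speed amplitude-speed gains (uV per cm/s,
#'   signed; the slow rhythm is positively speed-coupled by default, theta
#'   decoupled).
#' @param h_slow_speed,h_theta_speed frequency-speed gains (Hz per cm/s).
#' @param speed_mean_wheel,speed_mean_maze,speed_sd,speed_tau
#'   Ornstein-Uhlenbeck speed-process parameters (cm/s, cm/s, cm/s, s).
#' @param maze_n_stops,maze_stop_duration near-zero "stop" segments
#'   inserted into maze trials (count per trial, s), exercising the
#'   10 cm/s gate.
#' @param noise_exponent 1/f spectral slope of the background noise.
#' @param noise_scale background-noise RMS (uV).
#' @param phase_diff_slow,phase_diff_theta phase-diffusion rates (rad^2/s).
#' @param slow_in_maze multiplier on the slow-oscillator amplitude during
#'   maze epochs.
#' @param n_interneurons,n_pyramidal neuron counts.
#' @param base_rate_int,base_rate_pyr mean firing rates (Hz).
#' @param kappa_slow_int,kappa_theta_int,kappa_slow_pyr,kappa_theta_pyr
#'   von Mises phase-modulation concentrations per cell type and rhythm.
#' @param burst_prob_pyr probability that a pyramidal spike initiates a
#'   complex-spike burst.  Bursting puts the global maximum of a
#'   pyramidal autocorrelogram at short lags, as in real recordings, so
#'   min-max normalised band features are anchored the same way.
#' @param burst_extra_mean mean number of extra spikes per burst
#'   (geometric).
#' @param burst_isi_ms intra-burst inter-spike interval (ms).
#' @param muscimol_theta_scale post-condition multiplier on theta
#'   amplitude (~0: theta abolished).
#' @param muscimol_speed_scale post-condition multiplier on mean running
#'   speed.
#' @param muscimol_rate_scale_int post-condition multiplier on
#'   interneuron firing rates.
#' @param muscimol_kappa_scale post-condition multiplier on all spike
#'   phase-modulation concentrations.
#' @param muscimol_freq_scale post-condition multiplier on both centre
#'   frequencies.  Peak frequencies drop slightly but measurably after
#'   inactivation while spike interpeak intervals stay within a few ms
#'   (246 vs 250 ms implies a ratio of ~0.98).
#' @param p_correct_pre,p_correct_post probability that a trial is
#'   labelled a correct choice (labels only, no cognitive model).
#' @param seed integer master seed.
#'
#' @return An object of class `synth_config` (a validated named list).
#' @export
synth_config <- function(fs_lfp = 1250, fs_beh = 50,
                         n_trials_per_context = 30, trial_duration = 15,
                         f_slow = 4.0, f_theta = 8.0,
                         a_slow0 = 10, a_theta0 = 30,
                         g_slow_speed = 1.0, g_theta_speed = 0,
                         h_slow_speed = 0.01, h_theta_speed = 0.02,
                         speed_mean_wheel = 60, speed_mean_maze = 35,
                         speed_sd = 10, speed_tau = 2,
                         maze_n_stops = 2, maze_stop_duration = 1.5,
                         noise_exponent = 1, noise_scale = 15,
                         phase_diff_slow = 0.2, phase_diff_theta = 6.0,
                         slow_in_maze = 0,
                         n_interneurons = 8, n_pyramidal = 24,
                         base_rate_int = 15, base_rate_pyr = 2.5,
                         kappa_slow_int = 1.5, kappa_theta_int = 1.0,
                         kappa_slow_pyr = 1.0, kappa_theta_pyr = 0.7,
                         burst_prob_pyr = 0.05, burst_extra_mean = 1,
                         burst_isi_ms = 5,
                         muscimol_theta_scale = 0,
                         muscimol_speed_scale = 0.85,
                         muscimol_rate_scale_int = 0.7,
                         muscimol_kappa_scale = 0.6,
                         muscimol_freq_scale = 0.984,
                         p_correct_pre = 0.94, p_correct_post = 0.60,
                         seed = 1L) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' Validate a synthetic-session configuration
#'
#' Checks the structural invariants of a [synth_config()]: non-negative
#' rates/amplitudes/durations/concentrations, slow centre frequency below
#' theta, and an LFP rate comfortably above twice the highest oscillator
#' frequency.
#'
#' @param cfg a `synth_config`.
#' @return `cfg`, invisibly, or an error.
#' @export
validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config") || is.list(cfg))
  nonneg <- c("fs_lfp", "fs_beh", "trial_duration", "a_slow0", "a_theta0",
              "speed_sd", "speed_tau", "noise_scale", "noise_exponent",
              "phase_diff_slow", "phase_diff_theta",
              "base_rate_int", "base_rate_pyr",
              "kappa_slow_int", "kappa_theta_int",
              "kappa_slow_pyr", "kappa_theta_pyr",
              "burst_prob_pyr", "burst_extra_mean", "burst_isi_ms",
              "muscimol_theta_scale", "muscimol_speed_scale",
              "muscimol_rate_scale_int", "muscimol_kappa_scale",
              "muscimol_freq_scale", "slow_in_maze",
              "maze_n_stops", "maze_stop_duration")
  for (f in nonneg) {
    v <- cfg[[f]]
    if (is.null(v) || !is.finite(v) || v < 0)
      stop("synth_config: field '", f, "' must be finite and >= 0")
  }
  if (cfg$f_slow >= cfg$f_theta)
    stop("synth_config: f_slow must be < f_theta")
  if (cfg$fs_lfp <= 2 * (cfg$f_theta + 5))
    stop("synth_config: fs_lfp must exceed 2*(f_theta + 5) Hz")
  if (cfg$trial_duration <= 0) stop("synth_config: trial_duration must be > 0")
  if (cfg$fs_lfp %% cfg$fs_beh != 0)
    stop("synth_config: fs_lfp must be an integer multiple of fs_beh")
  if (cfg$p_correct_pre < 0 || cfg$p_correct_pre > 1 ||
      cfg$p_correct_post < 0 || cfg$p_correct_post > 1)
    stop("synth_config: correct-choice probabilities must lie in [0, 1]")
  invisible(cfg)
}

#' Read / write a generator configuration as JSON
#'
#' All fields of [synth_config()] are serialised; on reading, missing
#' fields fall back to the package defaults so configs remain forward
#' compatible.
#'
#' @param cfg a `synth_config`.
#' @param path file path.
#' @return `write_synth_config` returns `path` invisibly;
#'   `read_synth_config` returns a `synth_config`.
#' @export
write_synth_config <- function(cfg, path) {
  validate_synth_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(synth_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("read_synth_config: ignoring unknown fields: ",
            paste(unknown, collapse = ", "))
  do.call(synth_config, raw[intersect(names(raw), known)])
}

# Derive a reproducible child seed from a master seed and a stream label.
# Kept below 2^31 so it is always a valid R integer.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1103 + h * 12289 + 49297) %% 2147483629)
}
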