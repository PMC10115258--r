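#' Generate pink (1/f^alpha) background noise
#'
#' Spectral-shaping generator: white Gaussian noise is filtered in the
#' frequency domain by `f^(-alpha/2)` (DC removed) and rescaled to the
#' requested RMS.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param exponent spectral slope alpha (power ~ 1/f^alpha).
#' @param scale target RMS (uV).
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, exponent = 1, scale = 1, seed = 1L) {
  if (n < 2 || scale == 0) return(numeric(n))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  x * scale / stats::sd(x)
}

#' Generate one trial of synthetic LFP with ground truth
#'
#' The LFP is the sum of a slow (~4-Hz) and a theta oscillator over 1/f
#' noise:
#' `lfp(t) = A_s(t) sin(phi_s(t)) + A_th(t) sin(phi_th(t)) + noise(t)`
#' with amplitudes `A_x(t) = max(0, a_x0 + g_x * speed(t))` and phases
#' integrating `2*pi*(f_x + h_x*(speed(t) - s_ref))` plus Brownian phase
#' diffusion.  The behavioural-rate speed trace is linearly interpolated
#' to the LFP clock.  In the post condition the theta amplitude is
#' multiplied by `muscimol_theta_scale` and both centre frequencies by
#' `muscimol_freq_scale`; during maze epochs the slow amplitude is
#' multiplied by `slow_in_maze`.
#'
#' @param speed speed trace (cm/s) at `cfg$fs_beh`.
#' @param cfg a [synth_config()].
#' @param condition `"pre"` or `"post"`.
#' @param seed integer seed.
#' @param context `"wheel"` or `"maze"` (gates the slow oscillator).
#' @return list with `lfp` (uV at `cfg$fs_lfp`) and `truth`, a list of
#'   realized per-sample `amp_slow`, `amp_theta`, `phase_slow`,
#'   `phase_theta` plus the effective centre frequencies.
#' @export
gen_lfp <- function(speed, cfg, condition = c("pre", "post"),
                    seed = cfg$seed, context = c("wheel", "maze")) {
  condition <- match.arg(condition)
  context <- match.arg(context)
  validate_synth_config(cfg)
  fs <- cfg$fs_lfp
  up <- fs / cfg$fs_beh
  n <- length(speed) * up
  if (length(speed) < 2) stop("gen_lfp: speed trace too short")

  # behavioural clock -> LFP clock (linear interpolation)
  t_beh <- (seq_along(speed) - 1) / cfg$fs_beh
  t_lfp <- (seq_len(n) - 1) / fs
  sp <- stats::approx(t_beh, speed, xout = t_lfp, rule = 2)$y
  if (length(sp) != n) stop("gen_lfp: resampled speed length mismatch")

  fscale <- if (condition == "post") cfg$muscimol_freq_scale else 1
  f_slow <- cfg$f_slow * fscale
  f_theta <- cfg$f_theta * fscale
  s_ref <- if (context == "wheel") cfg$speed_mean_wheel else cfg$speed_mean_maze
  if (condition == "post") s_ref <- s_ref * cfg$muscimol_speed_scale

  amp_slow <- pmax(0, cfg$a_slow0 + cfg$g_slow_speed * sp)
  if (context == "maze") amp_slow <- amp_slow * cfg$slow_in_maze
  amp_theta <- pmax(0, cfg$a_theta0 + cfg$g_theta_speed * sp)
  if (condition == "post") amp_theta <- amp_theta * cfg$muscimol_theta_scale

  old <- .Random.seed_guard(child_seed(seed, "lfp-phase"))
  on.exit(old(), add = TRUE)
  dt <- 1 / fs
  phi0 <- stats::runif(2, 0, 2 * pi)
  dphi_s <- 2 * pi * (f_slow + cfg$h_slow_speed * (sp - s_ref)) * dt
  dphi_t <- 2 * pi * (f_theta + cfg$h_theta_speed * (sp - s_ref)) * dt
  if (cfg$phase_diff_slow > 0)
    dphi_s <- dphi_s + stats::rnorm(n, 0, sqrt(cfg$phase_diff_slow * dt))
  if (cfg$phase_diff_theta > 0)
    dphi_t <- dphi_t + stats::rnorm(n, 0, sqrt(cfg$phase_diff_theta * dt))
  phase_slow <- phi0[1] + cumsum(dphi_s)
  phase_theta <- phi0[2] + cumsum(dphi_t)

  noise <- pink_noise(n, fs, cfg$noise_exponent, cfg$noise_scale,
                      child_seed(seed, "lfp-noise"))

  lfp <- amp_slow * sin(phase_slow) + amp_theta * sin(phase_theta) + noise
  list(lfp = lfp,
       truth = list(amp_slow = amp_slow, amp_theta = amp_theta,
                    phase_slow = phase_slow, phase_theta = phase_theta,
                    f_slow = f_slow, f_theta = f_theta))
}
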