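#' Generate a phase-locked spike train by Poisson thinning
#'
#' Spikes follow an inhomogeneous Poisson process with conditional
#' intensity
#' `lambda(t) = r0 * exp(k_s cos(phi_s(t) - mu_s)) *
#'              exp(k_th cos(phi_th(t) - mu_th)) / Z`
#' where the normaliser `Z` is the empirical time average of the
#' modulation factor, so `r0` is interpretable as the neuron's mean
#' firing rate.  Simulation is by thinning a homogeneous process at the
#' envelope rate `r0 * exp(k_s + k_th) / Z`.  In the post condition both
#' concentrations are multiplied by `muscimol_kappa_scale` and the
#' interneuron rate by `muscimol_rate_scale_int`.
#'
#' @param phases list with `phase_slow` and `phase_theta` (rad) sampled
#'   at `fs` (as returned in `gen_lfp()$truth`).
#' @param cfg a [synth_config()].
#' @param cell_type `"interneuron"` or `"pyramidal"`.
#' @param condition `"pre"` or `"post"`.
#' @param seed integer seed.
#' @param fs sampling rate of the phase series (Hz).
#' @param r0 mean firing rate (Hz); defaults to the cell type's
#'   configured base rate.
#' @param mu_slow,mu_theta preferred phases (rad).
#' @return sorted numeric vector of spike times (s).
#' @export
gen_spikes <- function(phases, cfg,
                       cell_type = c("interneuron", "pyramidal"),
                       condition = c("pre", "post"),
                       seed = cfg$seed, fs = cfg$fs_lfp,
                       r0 = NULL, mu_slow = 0, mu_theta = 0) {
  cell_type <- match.arg(cell_type)
  condition <- match.arg(condition)
  validate_synth_config(cfg)
  if (is.null(r0))
    r0 <- if (cell_type == "interneuron") cfg$base_rate_int else cfg$base_rate_pyr
  if (!is.numeric(r0) || r0 <= 0) stop("gen_spikes: r0 must be > 0")

  ks <- if (cell_type == "interneuron") cfg$kappa_slow_int else cfg$kappa_slow_pyr
  kt <- if (cell_type == "interneuron") cfg$kappa_theta_int else cfg$kappa_theta_pyr
  if (condition == "post") {
    ks <- ks * cfg$muscimol_kappa_scale
    # theta entrainment follows the theta rhythm itself: with the theta
    # amplitude scaled to ~0 there is no rhythm left to lock to
    kt <- kt * cfg$muscimol_kappa_scale * cfg$muscimol_theta_scale
    if (cell_type == "interneuron") r0 <- r0 * cfg$muscimol_rate_scale_int
  }

  n <- length(phases$phase_slow)
  if (n < 2 || length(phases$phase_theta) != n)
    stop("gen_spikes: phase series missing or mismatched")
  duration <- n / fs

  mod <- exp(ks * cos(phases$phase_slow - mu_slow) +
             kt * cos(phases$phase_theta - mu_theta))
  z <- mean(mod)                       # empirical normaliser
  lambda_max <- r0 * exp(ks + kt) / z  # envelope bound on lambda(t)

  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  n_cand <- stats::rpois(1, lambda_max * duration)
  if (n_cand == 0) return(numeric(0))
  t_cand <- sort(stats::runif(n_cand, 0, duration))
  idx <- pmin(n, floor(t_cand * fs) + 1)
  lam <- r0 * mod[idx] / z
  keep <- stats::runif(n_cand) < lam / lambda_max
  st <- t_cand[keep]

  if (cell_type == "pyramidal" && cfg$burst_prob_pyr > 0 && length(st)) {
    # complex-spike bursts: each accepted spike initiates, with fixed
    # probability, a short train of extra spikes at ~burst_isi_ms
    isi <- cfg$burst_isi_ms / 1000
    initiates <- stats::runif(length(st)) < cfg$burst_prob_pyr
    extra <- lapply(which(initiates), function(i) {
      k <- 1 + stats::rgeom(1, 1 / (1 + cfg$burst_extra_mean))
      st[i] + isi * seq_len(k) * (1 + 0.1 * stats::rnorm(k))
    })
    st <- sort(c(st, unlist(extra)))
    st <- st[st >= 0 & st <= duration]
  }
  # the RNG's 32-bit output grid can produce exact ties among hundreds of
  # thousands of candidates; spike times must be strictly increasing
  unique(st)
}
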