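#' Assemble a complete synthetic recording session
#'
#' Builds alternating wheel/maze trial epochs (wheel runs fill the
#' intertrial intervals of the alternation task, so each cycle is one
#' wheel run followed by one maze run), generates per-trial speed and
#' LFP, concatenates them, simulates every neuron's spike train from the
#' realized oscillator phases, and attaches the full ground truth.
#' Choice labels are drawn per trial pair with the condition's
#' correct-choice probability (labels only; no cognitive model).
#'
#' @param cfg a [synth_config()].
#' @param condition `"pre"` or `"post"`.
#' @param seed integer master seed (defaults to `cfg$seed`).
#' @param contexts which contexts to include (default both).
#' @return A `session_recording`: list with `lfp`, `fs_lfp`, `speed`,
#'   `fs_beh`, `neurons` (each with `id`, `cell_type`, `spike_times`),
#'   `trials` (data.frame: `trial_id`, `t_start`, `t_end`, `context`,
#'   `choice`, `condition`), `condition`, `ground_truth` (config plus
#'   realized per-sample amplitudes/phases), `schema_version`.
#' @export
gen_session <- function(cfg, condition = c("pre", "post"), seed = cfg$seed,
                        contexts = c("wheel", "maze")) {
  condition <- match.arg(condition)
  validate_synth_config(cfg)
  contexts <- match.arg(contexts, c("wheel", "maze"), several.ok = TRUE)

  n_pair <- cfg$n_trials_per_context
  p_corr <- if (condition == "pre") cfg$p_correct_pre else cfg$p_correct_post
  old <- .Random.seed_guard(child_seed(seed, "choices"))
  choice_draw <- stats::runif(n_pair) < p_corr
  old()

  order_ctx <- rep(contexts, times = n_pair)
  pair_id <- rep(seq_len(n_pair), each = length(contexts))

  speed_all <- list(); lfp_all <- list()
  amp_s <- list(); amp_t <- list(); ph_s <- list(); ph_t <- list()
  trials <- vector("list", length(order_ctx))
  t0 <- 0
  for (i in seq_along(order_ctx)) {
    ctx <- order_ctx[i]
    sd_i <- child_seed(seed, paste0("speed-", i))
    sp <- gen_speed(ctx, condition, cfg$trial_duration, cfg, seed = sd_i)
    lf <- gen_lfp(sp, cfg, condition, seed = child_seed(seed, paste0("lfp-", i)),
                  context = ctx)
    speed_all[[i]] <- sp
    lfp_all[[i]] <- lf$lfp
    amp_s[[i]] <- lf$truth$amp_slow; amp_t[[i]] <- lf$truth$amp_theta
    ph_s[[i]] <- lf$truth$phase_slow; ph_t[[i]] <- lf$truth$phase_theta
    dur <- length(sp) / cfg$fs_beh
    trials[[i]] <- data.frame(
      trial_id = i, t_start = t0, t_end = t0 + dur, context = ctx,
      choice = ifelse(choice_draw[pair_id[i]], "correct", "incorrect"),
      condition = condition, stringsAsFactors = FALSE)
    t0 <- t0 + dur
  }
  trials <- do.call(rbind, trials)

  truth_phases <- list(phase_slow = unlist(ph_s), phase_theta = unlist(ph_t))
  n_int <- round(cfg$n_interneurons); n_pyr <- round(cfg$n_pyramidal)
  neurons <- vector("list", n_int + n_pyr)
  old <- .Random.seed_guard(child_seed(seed, "mus"))
  mus <- matrix(stats::runif(2 * (n_int + n_pyr), 0, 2 * pi), ncol = 2)
  old()
  for (j in seq_len(n_int + n_pyr)) {
    ct <- if (j <= n_int) "interneuron" else "pyramidal"
    st <- gen_spikes(truth_phases, cfg, ct, condition,
                     seed = child_seed(seed, paste0("spk-", j)),
                     mu_slow = mus[j, 1], mu_theta = mus[j, 2])
    neurons[[j]] <- list(id = sprintf("%s-%02d", substr(ct, 1, 3), j),
                         cell_type = ct, spike_times = st)
  }

  session <- list(
    lfp = unlist(lfp_all), fs_lfp = cfg$fs_lfp,
    speed = unlist(speed_all), fs_beh = cfg$fs_beh,
    neurons = neurons, trials = trials, condition = condition,
    ground_truth = list(
      config = unclass(cfg), seed = seed,
      amp_slow = unlist(amp_s), amp_theta = unlist(amp_t),
      phase_slow = truth_phases$phase_slow,
      phase_theta = truth_phases$phase_theta),
    schema_version = SESSION_SCHEMA_VERSION)
  class(session) <- "session_recording"
  validate_session(session)
  session
}

#' Validate a session recording
#'
#' Checks the container invariants: LFP and speed cover the same span
#' (within one behavioural sample), trial epochs are non-overlapping and
#' within the recorded span, spike times are sorted, and labels are from
#' the allowed vocabularies.
#'
#' @param session a `session_recording`.
#' @return `session`, invisibly, or an error.
#' @export
validate_session <- function(session) {
  req <- c("lfp", "fs_lfp", "speed", "fs_beh", "trials", "condition")
  miss <- setdiff(req, names(session))
  if (length(miss))
    stop("session: missing required groups: ", paste(miss, collapse = ", "))
  dur_lfp <- length(session$lfp) / session$fs_lfp
  dur_beh <- length(session$speed) / session$fs_beh
  if (abs(dur_lfp - dur_beh) > 1 / session$fs_beh + 1e-9)
    stop("session: lfp and speed spans differ by more than one behavioural sample")
  tr <- session$trials
  if (nrow(tr)) {
    if (any(tr$t_end <= tr$t_start)) stop("session: trial with t_end <= t_start")
    o <- order(tr$t_start)
    if (any(tr$t_start[o][-1] < tr$t_end[o][-nrow(tr)] - 1e-9))
      stop("session: overlapping trial epochs")
    if (any(tr$t_end > dur_lfp + 1e-6)) stop("session: trial beyond recorded span")
    if (!all(tr$context %in% c("maze", "wheel")))
      stop("session: unknown trial context")
    if (!all(tr$choice %in% c("correct", "incorrect", "na")))
      stop("session: unknown choice label")
  }
  for (nr in session$neurons) {
    if (is.unsorted(nr$spike_times, strictly = TRUE) && length(nr$spike_times) > 1)
      stop("session: spike times of ", nr$id, " not strictly increasing")
    if (!nr$cell_type %in% c("interneuron", "pyramidal"))
      stop("session: unknown cell type for ", nr$id)
  }
  invisible(session)
}

SESSION_SCHEMA_VERSION <- "1.0"
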