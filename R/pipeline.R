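#' Preprocess a session: notch, artifact rejection, speed gating
#'
#' Runs the cleaning stages in the study's order: 55-65 Hz notch, 2-SD
#' amplitude artifact flags (dilated +/-0.25 s) on the notch-filtered
#' signal, and the 10 cm/s locomotion gate inside trial epochs.
#'
#' @param session a `session_recording`.
#' @param artifact_sd_mult artifact threshold (session SDs).
#' @param speed_threshold_cms locomotion gate (cm/s).
#' @param dilation_s artifact-flag dilation (s).
#' @param artifact_method artifact-detection dialect (see
#'   [reject_artifacts()]).
#' @return the session with added `lfp_clean` (notch-filtered trace) and
#'   `mask` (combined `epoch_mask`).
#' @export
preprocess_session <- function(session, artifact_sd_mult = 2,
                               speed_threshold_cms = 10, dilation_s = 0.25,
                               artifact_method = c("seeded", "sample")) {
  validate_session(session)
  lfp_clean <- notch_filter(session$lfp, session$fs_lfp)
  m_art <- reject_artifacts(lfp_clean, session$fs_lfp,
                            sd_mult = artifact_sd_mult,
                            dilation_s = dilation_s,
                            method = match.arg(artifact_method))
  m_run <- select_run_epochs(session$speed, session$trials,
                             session$fs_beh, session$fs_lfp,
                             threshold = speed_threshold_cms)
  n <- length(lfp_clean)
  if (m_run$n != n) {  # guard against one-sample span mismatch
    m_run$keep <- m_run$keep[seq_len(n)]
    m_run$artifact <- m_run$artifact[seq_len(n)]
    m_run$slow_speed <- m_run$slow_speed[seq_len(n)]
    m_run$n <- n
  }
  session$lfp_clean <- lfp_clean
  session$mask <- combine_masks(m_art, m_run)
  attr(session$mask, "trial_summary") <- attr(m_run, "trial_summary")
  session
}

#' Per-trial LFP spectral table
#'
#' Welch PSD (1-s windows, 90% overlap) on each trial's kept samples,
#' with band power and interpolated peak frequency per band.
#'
#' @param session a preprocessed session (see [preprocess_session()]).
#' @param bands list of [band_spec()]s.
#' @return list with `table` (trial_id, context, condition, choice,
#'   band, power, peak_freq) and `group_psd` (list of average
#'   `psd_estimate` per context over trials with any kept window).
#' @export
trial_psd_table <- function(session, bands = band_specs()) {
  stopifnot(!is.null(session$mask))
  fs <- session$fs_lfp
  rows <- list(); psds <- list(); ctxs <- character(0)
  for (i in seq_len(nrow(session$trials))) {
    tr <- session$trials[i, ]
    i0 <- floor(tr$t_start * fs) + 1
    i1 <- min(length(session$lfp_clean), ceiling(tr$t_end * fs))
    psd <- welch_psd_masked(session$lfp_clean[i0:i1],
                            session$mask$keep[i0:i1], fs, fmax = 50)
    if (is.null(psd)) next
    psds[[length(psds) + 1]] <- psd; ctxs <- c(ctxs, tr$context)
    for (bn in names(bands)) {
      rows[[length(rows) + 1]] <- data.frame(
        trial_id = tr$trial_id, context = tr$context,
        condition = tr$condition, choice = tr$choice, band = bn,
        power = band_power(psd, bands[[bn]]$lfp_band),
        peak_freq = peak_frequency(psd, bands[[bn]]$lfp_band),
        stringsAsFactors = FALSE)
    }
  }
  group <- list()
  for (ctx in unique(ctxs)) {
    sel <- which(ctxs == ctx)
    avg <- psds[[sel[1]]]
    avg$power <- Reduce(`+`, lapply(psds[sel], `[[`, "power")) / length(sel)
    group[[ctx]] <- avg
  }
  list(table = if (length(rows)) do.call(rbind, rows) else data.frame(),
       group_psd = group)
}

#' Band-limited instantaneous metrics for a whole session
#'
#' Band-passes the cleaned LFP per band and extracts Hilbert amplitude,
#' phase and frequency.
#'
#' @param session a preprocessed session.
#' @param bands list of [band_spec()]s.
#' @return named list of `instantaneous_metrics`.
#' @export
session_band_metrics <- function(session, bands = band_specs()) {
  stopifnot(!is.null(session$lfp_clean))
  out <- list()
  for (bn in names(bands)) {
    filt <- bandpass(session$lfp_clean, bands[[bn]], session$fs_lfp)
    out[[bn]] <- analytic_metrics(filt, session$fs_lfp)
  }
  out
}

#' Run the full analysis pipeline on one or two sessions
#'
#' Orchestrates preprocess -> per-trial spectra -> band metrics and
#' binned correlations -> LFP autocorrelograms -> spike-rhythmicity
#' screen -> condition contrasts.  With both a pre and a post session
#' the summary includes the septal-inactivation contrasts (theta vs
#' 4-Hz band power on speed-matched wheel trials) alongside the
#' maze/wheel and correct/incorrect contrasts.  Deterministic given its
#' inputs; every excluded trial or neuron appears in the manifest with
#' a reason code.
#'
#' @param sessions named list with elements `pre` and/or `post`
#'   (`session_recording`s).
#' @param bands list of [band_spec()]s.
#' @param bin_s correlation bin width (s).
#' @param out_dir optional directory for CSV result tables.
#' @return list with `tables` (psd, rhythmicity, correlations,
#'   contrasts), `group_psd`, `acg`, and `manifest`.
#' @export
run_pipeline <- function(sessions, bands = band_specs(), bin_s = 5,
                         out_dir = NULL) {
  stopifnot(length(sessions) >= 1, !is.null(names(sessions)),
            all(names(sessions) %in% c("pre", "post")))
  manifest <- list(stages = character(0), exclusions = list())
  psd_tab <- list(); rhyth_tab <- list(); corr_tab <- list()
  group_psd <- list(); acgs <- list(); speeds <- list(); binned_all <- list()

  for (cond in names(sessions)) {
    s <- preprocess_session(sessions[[cond]])
    manifest$stages <- c(manifest$stages, paste0("preprocess:", cond))

    pt <- trial_psd_table(s, bands)
    psd_tab[[cond]] <- pt$table
    group_psd[[cond]] <- pt$group_psd
    manifest$stages <- c(manifest$stages, paste0("spectral:", cond))

    metrics <- session_band_metrics(s, bands)
    binned <- bin_metrics(metrics, s$speed, s$trials, s$mask,
                          s$fs_lfp, s$fs_beh, bin_s = bin_s)
    binned_all[[cond]] <- binned
    for (ctx in unique(binned$context)) {
      sub <- binned[binned$context == ctx, , drop = FALSE]
      if (nrow(sub) >= 3) {
        stratum <- paste(ctx, cond, sep = ":")
        pairs <- list(
          c("fourhz_amp", "speed"), c("theta_amp", "speed"),
          c("fourhz_freq", "speed"), c("theta_freq", "speed"),
          c("fourhz_amp", "theta_amp"), c("fourhz_freq", "theta_freq"))
        for (pr in pairs) {
          r <- try(spearman_cor(sub[[pr[1]]], sub[[pr[2]]],
                                pair = paste(pr, collapse = "~"),
                                stratum = stratum), silent = TRUE)
          if (!inherits(r, "try-error"))
            corr_tab[[length(corr_tab) + 1]] <- data.frame(
              stratum = stratum, pair = r$pair, rho = r$rho, p = r$p,
              n = r$n, stringsAsFactors = FALSE)
        }
      }
    }
    manifest$stages <- c(manifest$stages, paste0("correlate:", cond))

    for (ctx in unique(s$trials$context)) {
      tr <- s$trials[s$trials$context == ctx, , drop = FALSE]
      a <- try(lfp_acg(s$lfp_clean, tr, s$fs_lfp, keep = s$mask$keep),
               silent = TRUE)
      if (!inherits(a, "try-error")) {
        acgs[[paste(ctx, cond, sep = ":")]] <- a
        if (length(a$skipped))
          manifest$exclusions[[paste0("trials:", ctx, ":", cond)]] <-
            data.frame(id = a$skipped, reason = "short-kept")
      }
      scr <- rhythmicity_screen(s$neurons, tr, bands,
                                context = ctx, condition = cond)
      rhyth_tab[[paste(ctx, cond)]] <- scr$table
      if (nrow(scr$table)) {
        exc <- unique(scr$table[!scr$table$included,
                                c("neuron_id", "reason")])
        if (nrow(exc))
          manifest$exclusions[[paste0("neurons:", ctx, ":", cond)]] <-
            data.frame(id = exc$neuron_id, reason = exc$reason)
      }
    }
    manifest$stages <- c(manifest$stages, paste0("rhythmicity:", cond))
    speeds[[cond]] <- trial_mean_speeds(s$speed, s$trials, s$fs_beh)
  }

  rbind_nonempty <- function(lst) {
    lst <- Filter(function(d) is.data.frame(d) && nrow(d) > 0, lst)
    if (length(lst)) do.call(rbind, lst) else data.frame()
  }
  psd_all <- rbind_nonempty(psd_tab)
  contrasts <- if (nrow(psd_all)) pipeline_contrasts(psd_all, speeds)
               else data.frame()
  tables <- list(
    psd = psd_all,
    rhythmicity = rbind_nonempty(rhyth_tab),
    correlations = rbind_nonempty(corr_tab),
    contrasts = contrasts,
    binned = rbind_nonempty(binned_all))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables))
      if (is.data.frame(tables[[nm]]) && nrow(tables[[nm]]))
        utils::write.csv(tables[[nm]],
                         file.path(out_dir, paste0(nm, ".csv")),
                         row.names = FALSE)
  }
  list(tables = tables, group_psd = group_psd, acg = acgs,
       manifest = manifest)
}

# Condition-contrast summary rows: maze vs wheel, pre vs post (on
# speed-matched wheel trials when both conditions are present), and
# correct vs incorrect wheel runs.
pipeline_contrasts <- function(psd_all, speeds) {
  rows <- list()
  add <- function(label, band, a, b, paired = FALSE) {
    if (length(a) >= 3 && length(b) >= 3) {
      ct <- compare_groups(a, b, paired = paired)
      rows[[length(rows) + 1]] <<- data.frame(
        contrast = label, band = band, n_a = length(a), n_b = length(b),
        mean_a = mean(a), mean_b = mean(b), p = ct$p, method = ct$method,
        stringsAsFactors = FALSE)
    }
  }
  for (bn in unique(psd_all$band)) {
    sub <- psd_all[psd_all$band == bn, , drop = FALSE]
    pre <- sub[sub$condition == "pre", , drop = FALSE]
    add("maze-vs-wheel", bn,
        pre$power[pre$context == "maze"], pre$power[pre$context == "wheel"])
    add("correct-vs-incorrect-wheel", bn,
        pre$power[pre$context == "wheel" & pre$choice == "correct"],
        pre$power[pre$context == "wheel" & pre$choice == "incorrect"])
    if (all(c("pre", "post") %in% sub$condition)) {
      sp <- do.call(rbind, speeds)
      match <- speed_matched_subsets(sp)
      wid_pre <- match$pre$trial_id; wid_post <- match$post$trial_id
      add("pre-vs-post-wheel-matched", bn,
          sub$power[sub$context == "wheel" & sub$condition == "pre" &
                    sub$trial_id %in% wid_pre],
          sub$power[sub$context == "wheel" & sub$condition == "post" &
                    sub$trial_id %in% wid_post])
    }
  }
  if (length(rows)) do.call(rbind, rows) else data.frame()
}
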