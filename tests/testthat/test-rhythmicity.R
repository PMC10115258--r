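fs <- 1250
b <- band_specs()

test_that("LFP ACG of a 4-Hz tone peaks at 250 ms with unit zero-lag", {
  t15 <- (0:(15 * fs - 1)) / fs
  tr <- data.frame(trial_id = 1, t_start = 0, t_end = 15)
  a <- lfp_acg(sin(2 * pi * 4 * t15), tr, fs)
  expect_equal(a$average[a$lags_ms == 0], 1)
  pos <- a$lags_ms > 100 & a$lags_ms < 400
  # 250 ms falls between two 0.8-ms lag bins at fs = 1250
  expect_lte(abs(a$lags_ms[pos][which.max(a$average[pos])] - 250), 0.8)
  ip <- acg_interpeak(a)
  expect_lte(abs(ip$interpeak_ms - 250), 1)
})

test_that("white-noise ACG stays within the sampling-noise bound", {
  set.seed(31)
  tr <- data.frame(trial_id = 1, t_start = 0, t_end = 15)
  a <- lfp_acg(rnorm(15 * fs), tr, fs)
  nz <- a$lags_ms != 0
  expect_lt(max(abs(a$average[nz])), 3 / sqrt(15 * fs))
})

test_that("trial ACGs are averaged and short trials are skipped", {
  t15 <- (0:(15 * fs - 1)) / fs
  x <- sin(2 * pi * 4 * t15)
  tr <- data.frame(trial_id = 1:2, t_start = c(0, 10), t_end = c(10, 15))
  keep <- rep(TRUE, length(x)); keep[(10 * fs):(15 * fs)] <- FALSE
  a <- lfp_acg(x, tr, fs, keep = keep)
  expect_equal(a$skipped, 2)
  expect_equal(sum(!is.na(a$per_trial[, 1])), 1)
})

test_that("spike ACG of a periodic train peaks at the period and its double", {
  st <- seq(0.1, 300, by = 0.25)
  a <- spike_acg(st, data.frame(t_start = 0, t_end = 300))
  pos <- a$lags_ms > 0
  big <- a$lags_ms[pos][a$average[pos] > 0.5 * max(a$average[pos])]
  expect_true(all(abs(((big + 125) %% 250) - 125) < 10))
  expect_true(any(abs(big - 250) < 10) && any(abs(big - 500) < 10))
  expect_error(spike_acg(st[1:50], NULL), "100")
})

test_that("homogeneous Poisson spike ACG is flat", {
  set.seed(32)
  st <- cumsum(stats::rexp(3000, 10))
  a <- spike_acg(st, NULL)
  expect_lt(acg_mod_depth(a), 0.2)
  v <- a$average[a$lags_ms > 0]
  se <- sqrt(mean(v) / length(st))   # Poisson count SE per bin
  expect_lt(max(v) - mean(v), 3.5 * se)
})

test_that("NormACG is an affine rescale to [0, 1]", {
  expect_equal(normalize_acg(c(2, 4, 6)), c(0, 0.5, 1))
  set.seed(33)
  x <- rnorm(101)
  expect_equal(normalize_acg(3 * x + 7), normalize_acg(x))
  nx <- normalize_acg(x)
  expect_equal(range(nx), c(0, 1))
  expect_error(normalize_acg(rep(1, 101)), "constant")
})

test_that("band features read period and amplitude off cosine ACGs", {
  lags <- seq(-500, 500, by = 1)
  acg4 <- structure(list(lags_ms = lags, average = cos(2 * pi * 4 * lags / 1000)),
                    class = "acg_result")
  f4 <- acg_band_features(normalize_acg(acg4), b$fourhz)
  expect_equal(f4$interpeak_ms, 250, tolerance = 1e-3)
  expect_equal(f4$peak_amplitude, 1)
  expect_false(f4$boundary)
  acg8 <- structure(list(lags_ms = lags, average = cos(2 * pi * 8 * lags / 1000)),
                    class = "acg_result")
  f8 <- acg_band_features(normalize_acg(acg8), b$theta)
  expect_equal(f8$interpeak_ms, 125, tolerance = 1e-3)
  ramp <- structure(list(lags_ms = lags, average = abs(lags) / 500),
                    class = "acg_result")
  fr <- acg_band_features(ramp, b$fourhz)
  expect_true(fr$boundary)
  expect_equal(fr$interpeak_ms, 300)
})

test_that("screen excludes slow and unmodulated neurons with reason codes", {
  ses <- wheel_session_300s()
  truth <- wheel_truth_300s()
  ep <- ses$trials
  neurons <- list(
    list(id = "slow", cell_type = "pyramidal",
         spike_times = seq(0.1, 299, by = 2)),                    # 0.5 Hz
    list(id = "poisson", cell_type = "interneuron",
         spike_times = gen_spikes(truth, mod_config(0), "interneuron",
                                  "pre", seed = 41)),
    list(id = "locked", cell_type = "interneuron",
         spike_times = gen_spikes(truth, mod_config(2), "interneuron",
                                  "pre", seed = 42)))
  scr <- rhythmicity_screen(neurons, ep)
  tab <- unique(scr$table[, c("neuron_id", "included", "reason")])
  expect_equal(tab$reason[tab$neuron_id == "slow"], "rate")
  expect_equal(tab$reason[tab$neuron_id == "poisson"], "threshold")
  expect_true(tab$included[tab$neuron_id == "locked"])
  expect_true(all(scr$table$rate_hz[scr$table$neuron_id == "slow"] < 1))
})

test_that("stronger phase locking never weakens the 4-Hz band peak", {
  truth <- wheel_truth_300s()
  ep <- wheel_session_300s()$trials
  amp_at <- vapply(c(0, 0.5, 1, 2), function(k) {
    amps <- vapply(1:6, function(j) {
      st <- gen_spikes(truth, mod_config(k), "interneuron", "pre",
                       seed = 500 + j)
      acg_band_features(normalize_acg(spike_acg(st, ep)),
                        b$fourhz)$peak_amplitude
    }, numeric(1))
    mean(amps)
  }, numeric(1))
  expect_true(all(diff(amp_at) > -0.05))
  expect_gt(amp_at[4], amp_at[1])
})

test_that("relative spike PSD is normalised and locates the locked rhythm", {
  truth <- wheel_truth_300s()
  ep <- wheel_session_300s()$trials
  st <- gen_spikes(truth, mod_config(2), "interneuron", "pre", seed = 43)
  rel <- spike_psd(st, ep)
  expect_equal(sum(rel$power), 1)
  sel <- rel$freq >= 1
  pkf <- rel$freq[sel][which.max(rel$power[sel])]
  expect_true(pkf >= b$fourhz$spike_band[1] && pkf <= b$fourhz$spike_band[2])
  st0 <- gen_spikes(truth, mod_config(0), "interneuron", "pre", seed = 44)
  rel0 <- spike_psd(st0, ep)
  nz <- rel0$freq >= 1
  expect_lt(max(rel0$power[nz]) / stats::median(rel0$power[nz]), 3)
  expect_error(spike_psd(st, data.frame(t_start = 0, t_end = 10)),
               "insufficient")
})

test_that("muscimol transform weakens rhythmic spiking the way the study reports", {
  cfg <- synth_config(n_trials_per_context = 20)
  pre <- gen_session(cfg, "pre", seed = 21)
  post <- gen_session(cfg, "post", seed = 22)
  s_pre <- rhythmicity_screen(
    pre$neurons, pre$trials[pre$trials$context == "wheel", ],
    context = "wheel", condition = "pre")$table
  s_post <- rhythmicity_screen(
    post$neurons, post$trials[post$trials$context == "wheel", ],
    context = "wheel", condition = "post")$table
  g <- function(tb, ct, bn, col)
    mean(tb[[col]][tb$cell_type == ct & tb$band == bn & tb$included],
         na.rm = TRUE)
  expect_lt(g(s_post, "pyramidal", "fourhz", "acg_peak_amp"),
            g(s_pre, "pyramidal", "fourhz", "acg_peak_amp"))
  expect_lt(g(s_post, "pyramidal", "fourhz", "power_index"),
            g(s_pre, "pyramidal", "fourhz", "power_index"))
  expect_lt(g(s_post, "interneuron", "fourhz", "power_index"),
            g(s_pre, "interneuron", "fourhz", "power_index"))
  expect_lt(abs(g(s_post, "interneuron", "fourhz", "interpeak_ms") -
                g(s_pre, "interneuron", "fourhz", "interpeak_ms")), 10)
  rate_pre <- mean(s_pre$rate_hz[s_pre$cell_type == "interneuron"])
  rate_post <- mean(s_post$rate_hz[s_post$cell_type == "interneuron"])
  expect_lt(rate_post, rate_pre)
})
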