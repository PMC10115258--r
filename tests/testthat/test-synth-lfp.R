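fs <- 1250

test_that("noise-free uncoupled generator is a sum of two pure sinusoids", {
  cfg <- synth_config(noise_scale = 0, g_slow_speed = 0, g_theta_speed = 0,
                      h_slow_speed = 0, h_theta_speed = 0,
                      phase_diff_slow = 0, phase_diff_theta = 0,
                      a_slow0 = 10, a_theta0 = 10, speed_sd = 0)
  sp <- gen_speed("wheel", "pre", 20, cfg, seed = 1)
  lfp <- gen_lfp(sp, cfg, "pre", seed = 1)$lfp
  psd <- welch_psd(lfp, fs, window_s = 4)
  pk <- find_peaks(psd$power, min_prominence = 0.2 * max(psd$power))
  expect_equal(sort(psd$freq[pk$index]), c(4, 8), tolerance = 0.05)
  # closed-form power: two unit-phase sinusoids of amplitude 10
  expect_equal(stats::var(lfp), 100 / 2 + 100 / 2, tolerance = 0.01)
})

test_that("muscimol transform abolishes theta but preserves the slow band", {
  # phase diffusion off: with it on, the slow rhythm has a genuine
  # spectral skirt that reaches into the theta band
  cfg <- synth_config(speed_sd = 0, phase_diff_slow = 0,
                      phase_diff_theta = 0)
  sp <- gen_speed("wheel", "pre", 60, cfg, seed = 2)
  pre <- gen_lfp(sp, cfg, "pre", seed = 2)$lfp
  post <- gen_lfp(sp, cfg, "post", seed = 2)$lfp
  noise_cfg <- synth_config(a_slow0 = 0, a_theta0 = 0, g_slow_speed = 0,
                            speed_sd = 0)
  noise_only <- gen_lfp(sp, noise_cfg, "pre", seed = 2)$lfp
  p_pre <- welch_psd(pre, fs, window_s = 2)
  p_post <- welch_psd(post, fs, window_s = 2)
  p_noise <- welch_psd(noise_only, fs, window_s = 2)
  expect_lte(band_power(p_post, c(6, 10)),
             1.05 * band_power(p_noise, c(6, 10)))
  expect_equal(band_power(p_post, c(3, 5)) / band_power(p_pre, c(3, 5)), 1,
               tolerance = 0.1)
})

test_that("realized slow amplitude is a monotone map of speed", {
  cfg <- synth_config()
  sp <- gen_speed("wheel", "pre", 30, cfg, seed = 3)
  truth <- gen_lfp(sp, cfg, "pre", seed = 3)$truth
  sp_lfp <- stats::approx((seq_along(sp) - 1) / 50, sp,
                          xout = (seq_along(truth$amp_slow) - 1) / fs,
                          rule = 2)$y
  expect_equal(stats::cor(truth$amp_slow, sp_lfp, method = "spearman"), 1)
})

test_that("phase advances at the configured centre frequency", {
  cfg <- synth_config(phase_diff_slow = 0, phase_diff_theta = 0,
                      speed_sd = 0, f_slow = 3.1)
  sp <- gen_speed("wheel", "pre", 20, cfg, seed = 4)
  truth <- gen_lfp(sp, cfg, "pre", seed = 4)$truth
  n <- length(truth$phase_slow)
  f_real <- (truth$phase_slow[n] - truth$phase_slow[1]) / (2 * pi) * fs / (n - 1)
  expect_equal(f_real, 3.1, tolerance = 1e-6)
})

test_that("LFP generation is deterministic given the seed", {
  cfg <- synth_config()
  sp <- gen_speed("wheel", "pre", 10, cfg, seed = 5)
  expect_identical(gen_lfp(sp, cfg, "pre", seed = 6)$lfp,
                   gen_lfp(sp, cfg, "pre", seed = 6)$lfp)
})

test_that("pink noise has the configured RMS and 1/f slope", {
  x <- pink_noise(2^17, fs, exponent = 1, scale = 12, seed = 8)
  expect_equal(stats::sd(x), 12, tolerance = 1e-6)
  psd <- welch_psd(x, fs, window_s = 4)
  sel <- psd$freq >= 2 & psd$freq <= 100
  fit <- stats::lm(log(psd$power[sel]) ~ log(psd$freq[sel]))
  expect_equal(unname(fit$coefficients[2]), -1, tolerance = 0.1)
})
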