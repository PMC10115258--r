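fs <- 1250
t20 <- (0:(20 * fs - 1)) / fs

test_that("notch removes 60 Hz and passes the theta range untouched", {
  x60 <- sin(2 * pi * 60 * t20)
  y60 <- notch_filter(x60, fs)
  expect_lt(sqrt(mean(y60^2)) / sqrt(mean(x60^2)), 0.05)
  x8 <- sin(2 * pi * 8 * t20)
  y8 <- notch_filter(x8, fs)
  expect_gt(stats::cor(x8, y8), 0.999)
  expect_error(notch_filter(x8, 120), "fs")
})

test_that("notch attenuates 60 Hz at least 20 dB below 40 Hz on white noise", {
  set.seed(11)
  y <- notch_filter(rnorm(40 * fs), fs)
  psd <- welch_psd(y, fs, window_s = 2)
  p60 <- band_power(psd, c(59, 61))
  p40 <- band_power(psd, c(39, 41))
  expect_gt(10 * log10(p40 / p60), 20)
})

test_that("notch is linear to numerical tolerance", {
  set.seed(12)
  x <- rnorm(5 * fs); y <- rnorm(5 * fs)
  lhs <- notch_filter(2 * x + 3 * y, fs)
  rhs <- 2 * notch_filter(x, fs) + 3 * notch_filter(y, fs)
  expect_equal(lhs, rhs, tolerance = 1e-5)
})

test_that("sample-rule artifact flags match the normal-tail fraction", {
  set.seed(13)
  m <- reject_artifacts(rnorm(1e6), fs, method = "sample")
  expect_equal(mean(m$raw_artifact), 2 * stats::pnorm(-2), tolerance = 0.001 / 0.0455)
  expect_error(reject_artifacts(rep(0, 1000), fs), "degenerate")
})

test_that("an isolated large transient is flagged and dilated; clean oscillations are not", {
  x <- 10 * sin(2 * pi * 8 * t20)
  spike_at <- 10 * fs
  x[spike_at] <- x[spike_at] + 200   # ~20 SD transient
  w <- round(0.25 * fs)
  for (meth in c("sample", "seeded")) {
    m <- reject_artifacts(x, fs, method = meth)
    expect_true(m$artifact[spike_at])
    expect_true(all(m$artifact[(spike_at - w):(spike_at + w)]))
  }
  clean <- reject_artifacts(10 * sin(2 * pi * 8 * t20) +
                              pink_noise(length(t20), fs, scale = 2, seed = 1),
                            fs, method = "seeded")
  expect_equal(sum(clean$artifact), 0)
})

test_that("speed gate keeps exactly the above-threshold samples of trials", {
  trials <- data.frame(trial_id = 1, t_start = 0, t_end = 15)
  low <- select_run_epochs(rep(5, 15 * 50), trials, 50, fs)
  expect_equal(sum(low$keep), 0)
  high <- select_run_epochs(rep(20, 15 * 50), trials, 50, fs)
  expect_equal(sum(high$keep), 15 * fs)
  step <- c(rep(0, 375), rep(20, 375))
  half <- select_run_epochs(step, trials, 50, fs)
  expect_equal(sum(half$keep), 7.5 * fs, tolerance = 25 / (7.5 * fs))
  expect_true(all(which(half$keep) > 7.5 * fs - 25))
  expect_equal(attr(half, "trial_summary")$kept_s, 7.5, tolerance = 0.03)
})

test_that("empty trial table yields an empty mask, not an error", {
  m <- select_run_epochs(rep(20, 100), data.frame(), 50, fs)
  expect_equal(sum(m$keep), 0)
})

test_that("mask composition is order-independent", {
  set.seed(14)
  x <- rnorm(10 * fs); x[2000:2010] <- 50
  trials <- data.frame(trial_id = 1, t_start = 0, t_end = 10)
  speed <- rep(c(5, 20), each = 5 * 50)
  m_art <- reject_artifacts(x, fs, method = "sample")
  m_run <- select_run_epochs(speed, trials, 50, fs)
  ab <- combine_masks(m_art, m_run)
  ba <- combine_masks(m_run, m_art)
  expect_identical(ab$keep, ba$keep)
  expect_identical(ab$artifact, m_art$artifact)   # provenance queryable
  expect_identical(ab$slow_speed, m_run$slow_speed)
})
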