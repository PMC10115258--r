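fs <- 1250
t30 <- (0:(30 * fs - 1)) / fs
core <- (3 * fs):(27 * fs)  # exclude filter/Hilbert edges

test_that("band-pass keeps the in-band tone and rejects the out-of-band tone", {
  x4 <- sin(2 * pi * 4 * t30)
  y4 <- bandpass(x4, c(3, 5), fs)
  expect_gt(stats::sd(y4[core]) / stats::sd(x4[core]), 0.95)
  x8 <- sin(2 * pi * 8 * t30)
  y8 <- bandpass(x8, c(3, 5), fs)
  expect_lt(stats::sd(y8[core]) / stats::sd(x8[core]), 0.10)
  expect_error(bandpass(x4, c(550, 640), fs), "Nyquist")
})

test_that("band-pass is zero-phase: tone peaks align within one sample", {
  x <- sin(2 * pi * 4 * t30)
  y <- bandpass(x, c(3, 5), fs)
  px <- which(diff(sign(diff(x))) < 0) + 1
  py <- which(diff(sign(diff(y))) < 0) + 1
  px <- px[px > 3 * fs & px < 27 * fs]
  py <- py[py > 3 * fs & py < 27 * fs]
  expect_equal(length(px), length(py))
  expect_lte(max(abs(px - py)), 1)
})

test_that("repeated band-pass acts like a projection within the pass band", {
  set.seed(21)
  x <- rnorm(20 * fs)
  y1 <- bandpass(x, c(3, 5), fs)
  y2 <- bandpass(y1, c(3, 5), fs)
  c0 <- (3 * fs):(17 * fs)
  expect_gt(stats::cor(y1[c0], y2[c0]), 0.98)
  expect_equal(stats::sd(y2[c0]) / stats::sd(y1[c0]), 1, tolerance = 0.06)
})

test_that("analytic metrics recover amplitude and frequency of a tone", {
  x <- 2 * sin(2 * pi * 4 * t30)
  m <- analytic_metrics(x, fs)
  keep <- (0.5 * fs):(29.5 * fs)
  expect_equal(mean(m$amplitude[keep]), 2, tolerance = 0.02)
  expect_lt(max(abs(m$frequency[keep] - 4)), 0.05)
  expect_error(analytic_metrics(x[1:100], fs), "2 s")
})

test_that("instantaneous frequency of a chirp increases monotonically", {
  ph <- 2 * pi * (3 * t30[1:(20 * fs)] + 0.05 * t30[1:(20 * fs)]^2)  # 3 -> 5 Hz
  m <- analytic_metrics(sin(ph), fs)
  f <- m$frequency[(fs):(19 * fs)]
  block <- colMeans(matrix(f[1:(18 * fs)], nrow = fs))  # 1-s means
  expect_true(all(diff(block) > 0))
})

test_that("amplitude-modulated envelope is recovered", {
  env <- 1 + 0.5 * sin(2 * pi * 0.2 * t30)
  m <- analytic_metrics(env * sin(2 * pi * 4 * t30), fs)
  keep <- (fs):(29 * fs)
  expect_gt(stats::cor(m$amplitude[keep], env[keep]), 0.98)
})

test_that("Welch PSD peaks at the tone frequency and satisfies Parseval", {
  x <- sin(2 * pi * 4 * t30[1:(10 * fs)])
  psd <- welch_psd(x, fs)
  expect_equal(psd$freq[which.max(psd$power)], 4,
               tolerance = 0.51 * (psd$freq[2] - psd$freq[1]) / 4)
  set.seed(22)
  y <- rnorm(20 * fs)
  p2 <- welch_psd(y, fs)
  expect_equal(sum(p2$power) * (p2$freq[2] - p2$freq[1]), stats::var(y),
               tolerance = 0.05)
  expect_error(welch_psd(y[1:100], fs), "window")
})

test_that("two concurrent rhythms give two local spectral maxima", {
  x <- sin(2 * pi * 4 * t30) + 0.8 * sin(2 * pi * 7.8 * t30)
  psd <- welch_psd(x, fs)
  pk <- find_peaks(psd$power, min_prominence = 0.1 * max(psd$power))
  pf <- psd$freq[pk$index]
  expect_true(any(abs(pf - 4) < 0.5))
  expect_true(any(abs(pf - 7.8) < 0.5))
})

test_that("spectrogram tracks stationary and switched rhythms", {
  sg <- spectrogram_tf(sin(2 * pi * 4 * t30), fs, fmax = 20)
  ridge <- sg$freq[apply(sg$power, 2, which.max)]
  expect_true(all(abs(ridge - 4) < 0.3))
  x <- sin(2 * pi * 8 * t30)
  x[t30 > 15] <- 0.01 * x[t30 > 15]
  sg2 <- spectrogram_tf(x, fs, fmax = 20)
  th <- sg2$freq >= 6 & sg2$freq <= 10
  before <- mean(sg2$power[th, sg2$time < 13])
  after <- mean(sg2$power[th, sg2$time > 17])
  expect_gt(before / after, 100)
})

test_that("spectrogram time-marginal matches the Welch spectrum shape", {
  set.seed(23)
  x <- sin(2 * pi * 4 * t30) + rnorm(length(t30))
  psd <- welch_psd(x, fs, nfft_factor = 2, fmax = 50)
  sg <- spectrogram_tf(x, fs, window_s = 1, nfft_factor = 2, fmax = 50)
  marg <- rowMeans(sg$power)
  cossim <- sum(marg * psd$power) /
    sqrt(sum(marg^2) * sum(psd$power^2))
  expect_gt(cossim, 0.95)
})

test_that("band power and peak frequency behave on canonical spectra", {
  flat <- structure(list(freq = 0:50, power = rep(1, 51)),
                    class = "psd_estimate")
  expect_equal(band_power(flat, c(3, 5)), 1)
  expect_equal(band_power(flat, c(6, 10)), 1)
  spikep <- structure(list(freq = 0:50, power = c(rep(0, 4), 1, rep(0, 46))),
                      class = "psd_estimate")
  expect_equal(peak_frequency(spikep, c(1, 12)), 4)
  expect_error(band_power(flat, c(100, 110)), "grid")
})

test_that("parabolic interpolation resolves a sub-bin peak on a 1-Hz grid", {
  x <- sin(2 * pi * 3.9 * t30)
  psd <- welch_psd(x, fs, window_s = 1, nfft_factor = 1)  # native 1-Hz bins
  expect_equal(psd$freq[2] - psd$freq[1], 1)
  expect_equal(peak_frequency(psd, c(1, 12)), 3.9, tolerance = 0.15 / 3.9)
})

test_that("power index follows its defining formula", {
  b <- band_specs()
  toy <- structure(list(freq = seq(0, 20, 0.5),
                        power = rep(0.04, 41)), class = "psd_estimate")
  toy$power[toy$freq == 5] <- 0.10
  expect_equal(power_index(toy, b$fourhz), 0.06)
  flat <- structure(list(freq = seq(0, 20, 0.5), power = rep(1 / 41, 41)),
                    class = "psd_estimate")
  expect_equal(power_index(flat, b$fourhz), 0)
  expect_error(power_index(structure(list(freq = 0:4, power = rep(0.2, 5)),
                                     class = "psd_estimate"), b$fourhz),
               "grid")
})

test_that("least-squares FIR response matches the design targets", {
  h <- fir_ls(2500, rbind(c(0, 2.55, 0, 0), c(3, 5, 1, 1),
                          c(5.75, fs / 2, 0, 0)), fs)
  H <- function(f) abs(sum(h * exp(-2i * pi * f * (seq_along(h) - 1) / fs)))
  expect_equal(H(4), 1, tolerance = 0.02)
  expect_lt(H(10), 0.01)   # one octave above the upper edge
  expect_lt(H(1.5), 0.05)
  expect_equal(h, rev(h))  # linear phase
})
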