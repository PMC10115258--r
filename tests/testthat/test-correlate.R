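fs <- 1250

make_metrics <- function(amp, freq) {
  structure(list(amplitude = amp, frequency = freq, fs = fs),
            class = "instantaneous_metrics")
}

test_that("binning is per trial, anchored at trial start", {
  n <- 15 * fs
  trials <- data.frame(trial_id = 1, t_start = 0, t_end = 15,
                       context = "wheel", condition = "pre")
  m <- list(fourhz = make_metrics(rep(2, n), rep(4, n)))
  out <- bin_metrics(m, rep(30, 15 * 50), trials, NULL, fs, 50, bin_s = 5)
  expect_equal(nrow(out), 3)
  expect_equal(out$bin_start, c(0, 5, 10))
  expect_equal(out$fourhz_amp, rep(2, 3))
  expect_equal(out$speed, rep(30, 3))
})

test_that("bin means equal brute-force sample means and sparse bins drop", {
  set.seed(51)
  n <- 15 * fs
  amp <- stats::runif(n)
  trials <- data.frame(trial_id = 1, t_start = 0, t_end = 15,
                       context = "wheel", condition = "pre")
  m <- list(fourhz = make_metrics(amp, rep(4, n)))
  out <- bin_metrics(m, rep(30, 750), trials, NULL, fs, 50, bin_s = 5)
  expect_equal(out$fourhz_amp[2], mean(amp[(5 * fs + 1):(10 * fs)]))
  # mask killing 30% of the first bin drops it under the 80% rule
  mask <- epoch_mask(n = n, fs = fs,
                     artifact = c(rep(TRUE, 2 * fs), rep(FALSE, n - 2 * fs)))
  out2 <- bin_metrics(m, rep(30, 750), trials, mask, fs, 50, bin_s = 5)
  expect_equal(out2$bin_start, c(5, 10))
})

test_that("Spearman correlation honours sign, ties and the null", {
  up <- spearman_cor(1:20, (1:20)^3)
  expect_equal(up$rho, 1)
  down <- spearman_cor(1:20, -(1:20))
  expect_equal(down$rho, -1)
  set.seed(52)
  x <- runif(1000); y <- runif(1000)
  expect_lt(abs(spearman_cor(x, y)$rho), 0.07)
  expect_error(spearman_cor(rep(1, 10), 1:10), "zero-variance")
  expect_error(spearman_cor(1:2, 2:3), "3")
})

test_that("small-sample p-values use the exact permutation null", {
  r <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(r$method, "exact")
  ref <- stats::cor.test(1:5, c(2, 1, 4, 3, 5), method = "spearman",
                         exact = TRUE)
  expect_equal(r$p, ref$p.value)
  big <- spearman_cor(1:30, rnorm(30))
  expect_equal(big$method, "t-approximation")
})

test_that("Spearman rho is invariant to monotone transforms", {
  set.seed(53)
  x <- rnorm(50); y <- x + rnorm(50)
  r0 <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(exp(x), y)$rho, r0)
  expect_equal(spearman_cor(x, y^3 + 5)$rho, r0)
})

test_that("speed matching retains the window and removes the speed difference", {
  all60 <- data.frame(trial_id = 1:10, condition = rep(c("pre", "post"), 5),
                      context = "wheel", mean_speed = 60)
  m <- speed_matched_subsets(all60)
  expect_equal(nrow(m$pre) + nrow(m$post), 10)
  slow <- transform(all60, mean_speed = 40)
  expect_warning(m2 <- speed_matched_subsets(slow), "empty")
  expect_equal(nrow(m2$pre), 0)
})

test_that("matched synthetic pre/post trials have indistinguishable speeds", {
  cfg <- synth_config(n_trials_per_context = 40)
  nonsig <- 0; total <- 0
  for (sd in 1:6) {
    pre <- gen_session(cfg, "pre", seed = sd, contexts = "wheel")
    post <- gen_session(cfg, "post", seed = 100 + sd, contexts = "wheel")
    sp <- rbind(trial_mean_speeds(pre$speed, pre$trials, 50),
                trial_mean_speeds(post$speed, post$trials, 50))
    m <- speed_matched_subsets(sp)
    if (nrow(m$pre) && nrow(m$post)) {
      total <- total + 1
      if (m$match_test > 0.05) nonsig <- nonsig + 1
    }
  }
  expect_gte(nonsig / total, 0.95 - 1e-9)
})

test_that("group comparison picks its branch from normality and degenerates safely", {
  ident <- compare_groups(rep(1:5, 2), rep(1:5, 2), paired = TRUE)
  expect_equal(ident$p, 1)
  set.seed(54)
  a <- rnorm(50); bso <- rnorm(50, mean = 5)
  pw <- compare_groups(a, bso)
  expect_lt(pw$p, 0.01)
  expect_match(pw$method, "t-test")
  expect_true(pw$normal)
  skewed <- rexp(80); skewed2 <- rexp(80) + 1
  nw <- compare_groups(skewed, skewed2)
  expect_match(nw$method, "Wilcoxon rank-sum")
  expect_false(nw$normal)
  expect_error(compare_groups(1:2, 1:5), "3")
})
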