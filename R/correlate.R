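#' Bin instantaneous metrics and speed into fixed windows
#'
#' Non-overlapping bins (1 or 5 s by convention) anchored at each
#' trial's start; a bin is kept only if at least `min_kept` of its LFP
#' samples pass the mask.  Per bin: mean speed and, per band, mean
#' instantaneous amplitude and frequency.
#'
#' @param metrics named list of `instantaneous_metrics` (one per band,
#'   on the LFP clock, covering the whole session).
#' @param speed behavioural-rate speed trace (cm/s).
#' @param trials trial table (`trial_id`, `t_start`, `t_end`, `context`,
#'   `condition`).
#' @param mask an `epoch_mask` on the LFP clock (`NULL` keeps all).
#' @param fs_lfp,fs_beh sampling rates (Hz).
#' @param bin_s bin width (s).
#' @param min_kept minimum kept-sample fraction per bin.
#' @return data.frame: `trial_id`, `context`, `condition`, `bin_start`,
#'   `speed`, then `<band>_amp`, `<band>_freq` columns.
#' @export
bin_metrics <- function(metrics, speed, trials, mask = NULL,
                        fs_lfp, fs_beh, bin_s = 5, min_kept = 0.8) {
  keep <- if (is.null(mask)) rep(TRUE, length(metrics[[1]]$amplitude))
          else mask$keep
  rows <- list()
  for (i in seq_len(nrow(trials))) {
    t0 <- trials$t_start[i]
    n_bins <- floor((trials$t_end[i] - t0) / bin_s)
    for (b in seq_len(n_bins)) {
      b0 <- t0 + (b - 1) * bin_s; b1 <- b0 + bin_s
      i0 <- floor(b0 * fs_lfp) + 1; i1 <- min(length(keep), floor(b1 * fs_lfp))
      if (i1 <= i0) next
      sel <- i0:i1
      kf <- mean(keep[sel])
      if (kf < min_kept) next
      ksel <- sel[keep[sel]]
      j0 <- floor(b0 * fs_beh) + 1; j1 <- min(length(speed), floor(b1 * fs_beh))
      row <- data.frame(trial_id = trials$trial_id[i],
                        context = trials$context[i],
                        condition = trials$condition[i],
                        bin_start = b0,
                        speed = mean(speed[j0:j1]),
                        stringsAsFactors = FALSE)
      for (bn in names(metrics)) {
        row[[paste0(bn, "_amp")]] <- mean(metrics[[bn]]$amplitude[ksel])
        row[[paste0(bn, "_freq")]] <- mean(metrics[[bn]]$frequency[ksel])
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  if (!length(rows))
    return(data.frame(trial_id = integer(0), context = character(0),
                      condition = character(0), bin_start = numeric(0),
                      speed = numeric(0)))
  do.call(rbind, rows)
}

#' Spearman rank correlation with the study's p-value conventions
#'
#' Mid-rank ties; p-value from the t-approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` for n > 10, and from the exact
#' permutation null (via `stats::cor.test(exact = TRUE)`) for n <= 10
#' without ties.
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @param pair label for the variable pair.
#' @param stratum label for the context x condition stratum.
#' @return a `correlation_result`: list `rho`, `p`, `n`, `pair`,
#'   `stratum`, `method`.
#' @export
spearman_cor <- function(x, y, pair = NA_character_, stratum = NA_character_) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("spearman_cor: need at least 3 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman_cor: undefined correlation for zero-variance input")
  rho <- stats::cor(rank(x), rank(y))
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !has_ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    method <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1e-12, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t-approximation"
  }
  structure(list(rho = rho, p = p, n = n, pair = pair, stratum = stratum,
                 method = method),
            class = "correlation_result")
}

#' Speed-matched wheel-trial subsets
#'
#' Retains wheel trials whose mean running speed lies in `[lo, hi]`
#' (55-63 cm/s by convention) separately for the pre and post
#' conditions, then pairs trials across conditions by nearest mean
#' speed within a caliper so the matched subsets have indistinguishable
#' speed distributions (window selection alone leaves a residual
#' difference whenever the two conditions' speed distributions enter
#' the window from opposite sides).  A rank-sum test confirming no
#' residual speed difference is reported.
#'
#' @param trial_speeds data.frame with `trial_id`, `condition`,
#'   `context`, `mean_speed`.
#' @param lo,hi matching window (cm/s).
#' @param caliper maximum speed difference within a matched pair
#'   (cm/s); `Inf` disables pairing and keeps the full window subsets.
#' @return list `pre`, `post` (matched subsets), `match_test`
#'   (`wilcox.test` p-value, NA if either subset is empty).
#' @export
speed_matched_subsets <- function(trial_speeds, lo = 55, hi = 63,
                                  caliper = 2) {
  wheel <- trial_speeds[trial_speeds$context == "wheel", , drop = FALSE]
  inwin <- wheel$mean_speed >= lo & wheel$mean_speed <= hi
  pre <- wheel[inwin & wheel$condition == "pre", , drop = FALSE]
  post <- wheel[inwin & wheel$condition == "post", , drop = FALSE]
  if (nrow(pre) && nrow(post) && is.finite(caliper)) {
    # greedy nearest-neighbour pairing, smaller side first
    swap <- nrow(pre) < nrow(post)
    a <- if (swap) pre else post     # smaller (or post) side
    b <- if (swap) post else pre
    used <- rep(FALSE, nrow(b))
    keep_a <- rep(FALSE, nrow(a))
    for (i in order(a$mean_speed)) {
      d <- abs(b$mean_speed - a$mean_speed[i])
      d[used] <- Inf
      j <- which.min(d)
      if (is.finite(d[j]) && d[j] <= caliper) {
        used[j] <- TRUE
        keep_a[i] <- TRUE
      }
    }
    a <- a[keep_a, , drop = FALSE]
    b <- b[used, , drop = FALSE]
    if (swap) { pre <- a; post <- b } else { pre <- b; post <- a }
  }
  p <- NA_real_
  if (nrow(pre) && nrow(post)) {
    p <- suppressWarnings(
      stats::wilcox.test(pre$mean_speed, post$mean_speed)$p.value)
  } else {
    warning("speed_matched_subsets: empty matched subset")
  }
  list(pre = pre, post = post, match_test = p)
}

#' Normality-gated two-sample comparison
#'
#' The study's testing convention: Shapiro-Wilk on both groups; if both
#' look normal (p > 0.05) a t-test (paired or unpaired) is used,
#' otherwise the Wilcoxon signed-rank (paired) or rank-sum (unpaired)
#' test.  Degenerate paired comparisons with all-zero differences
#' return p = 1.
#'
#' @param a,b numeric groups (paired requires equal lengths).
#' @param paired logical.
#' @return list `p`, `statistic`, `method` (which branch fired),
#'   `normal` (both Shapiro p > 0.05).
#' @export
compare_groups <- function(a, b, paired = FALSE) {
  if (length(a) < 3 || length(b) < 3)
    stop("compare_groups: need at least 3 observations per group")
  if (paired && length(a) != length(b))
    stop("compare_groups: paired groups must have equal length")
  shapiro_ok <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)
    x <- if (length(x) > 5000) x[seq(1, length(x), length.out = 5000)] else x
    stats::shapiro.test(x)$p.value > 0.05
  }
  normal <- shapiro_ok(a) && shapiro_ok(b)
  if (paired && all(a == b)) {
    return(list(p = 1, statistic = NA_real_,
                method = "degenerate (identical paired groups)",
                normal = normal))
  }
  res <- if (normal) {
    tt <- stats::t.test(a, b, paired = paired)
    list(p = tt$p.value, statistic = unname(tt$statistic),
         method = if (paired) "paired t-test" else "t-test")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired))
    list(p = wt$p.value, statistic = unname(wt$statistic),
         method = if (paired) "Wilcoxon signed-rank" else "Wilcoxon rank-sum")
  }
  c(res, list(normal = normal))
}

#' Per-trial mean running speed
#'
#' Convenience summary used by the matching and speed-contrast stages.
#'
#' @param speed behavioural-rate speed trace (cm/s).
#' @param trials trial table.
#' @param fs_beh behavioural sampling rate (Hz).
#' @return data.frame `trial_id`, `context`, `condition`, `mean_speed`.
#' @export
trial_mean_speeds <- function(speed, trials, fs_beh) {
  ms <- vapply(seq_len(nrow(trials)), function(i) {
    j0 <- floor(trials$t_start[i] * fs_beh) + 1
    j1 <- min(length(speed), floor(trials$t_end[i] * fs_beh))
    mean(speed[j0:j1])
  }, numeric(1))
  data.frame(trial_id = trials$trial_id, context = trials$context,
             condition = trials$condition, mean_speed = ms,
             stringsAsFactors = FALSE)
}
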