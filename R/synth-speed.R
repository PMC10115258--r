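#' Generate a running-speed trace
#'
#' Speed follows an Ornstein-Uhlenbeck process (exact discretisation)
#' around the context's mean speed, reflected at zero.  In the post
#' condition the mean is multiplied by `muscimol_speed_scale`.  Maze
#' trials additionally contain `maze_n_stops` near-zero "stop" segments
#' realised as smooth raised-cosine dips, so the 10 cm/s run gate is
#' exercised by realistic pauses rather than hard discontinuities.
#'
#' @param context `"maze"` or `"wheel"`.
#' @param condition `"pre"` or `"post"`.
#' @param duration trace length (s), must be positive.
#' @param cfg a [synth_config()].
#' @param seed integer seed; the trace is deterministic given
#'   `(cfg, seed)`.
#' @return numeric vector of speeds (cm/s) sampled at `cfg$fs_beh`.
#' @export
gen_speed <- function(context = c("wheel", "maze"),
                      condition = c("pre", "post"),
                      duration, cfg, seed = cfg$seed) {
  context <- match.arg(context)
  condition <- match.arg(condition)
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop("gen_speed: duration must be a positive scalar")
  validate_synth_config(cfg)

  fs <- cfg$fs_beh
  n <- max(2L, round(duration * fs))
  mu <- if (context == "wheel") cfg$speed_mean_wheel else cfg$speed_mean_maze
  if (condition == "post") mu <- mu * cfg$muscimol_speed_scale

  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  s <- numeric(n)
  if (cfg$speed_sd == 0 || cfg$speed_tau == 0) {
    s[] <- mu
  } else {
    a <- exp(-1 / (fs * cfg$speed_tau))
    innov_sd <- cfg$speed_sd * sqrt(1 - a^2)
    s[1] <- mu + cfg$speed_sd * stats::rnorm(1)
    z <- stats::rnorm(n - 1)
    for (i in 2:n) s[i] <- mu + (s[i - 1] - mu) * a + innov_sd * z[i - 1]
    s <- abs(s)  # reflection at 0
  }

  if (context == "maze" && cfg$maze_n_stops > 0 && cfg$maze_stop_duration > 0) {
    gate <- rep(1, n)
    edge <- round(0.5 * fs)                     # 0.5-s cosine edges
    core <- round(cfg$maze_stop_duration * fs)  # near-zero plateau
    width <- core + 2 * edge
    n_stops <- round(cfg$maze_n_stops)
    if (n > width + 2) {
      starts <- sort(sample.int(max(1L, n - width), n_stops))
      prof <- c((1 + cos(pi * seq_len(edge) / edge)) / 2 * 0.97 + 0.03,
                rep(0.03, core),
                (1 - cos(pi * seq_len(edge) / edge)) / 2 * 0.97 + 0.03)
      for (st in starts) {
        idx <- st:(st + width - 1)
        gate[idx] <- pmin(gate[idx], prof)
      }
    }
    s <- s * gate
  }
  s
}

# Seed scoping: set the RNG to `seed`, return a restorer for on.exit so
# callers never perturb the user's RNG stream.
.Random.seed_guard <- function(seed) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  saved <- if (had) get(".Random.seed", envir = env) else NULL
  set.seed(as.integer(seed %% 2147483629))
  function() {
    if (had) assign(".Random.seed", saved, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }
}
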