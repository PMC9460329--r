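#' Synthetic band-signal configuration
#'
#' Parameters of the generator emulating a chest-band recording: a large
#' respiratory oscillation with small superimposed cardiac pulses, white
#' noise, cycle-to-cycle rate variability and random pulse dropouts
#' emulating the sensor's cardiac miss rate. Amplitude defaults (3120 mV
#' respiratory peak-to-peak, 84 mV pulse peak-to-peak, a 37x ratio) match
#' the bench recordings the event-processing chain was designed around.
#'
#' @param duration_s Recording length in seconds (> 0).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param rr_mean,rr_sd Respiratory rate mean and cycle-to-cycle SD
#'   (breaths/min); `rr_mean` must be below 60.
#' @param hr_mean,hr_sd Heart rate mean and beat-to-beat SD (beats/min);
#'   `hr_mean` must be below 180.
#' @param resp_pp_mv,pulse_pp_mv Respiratory / pulse peak-to-peak
#'   amplitudes in mV.
#' @param noise_sd_mv Additive white-noise SD in mV.
#' @param pulse_dropout_prob Probability that a beat leaves no pulse on
#'   the waveform (it stays in the ground truth, flagged).
#' @param baseline_mv Constant offset in mV.
#' @param seed Integer RNG seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(duration_s = 600,
                             sample_rate_hz = 200,
                             rr_mean = 17.41, rr_sd = 0.5,
                             hr_mean = 85, hr_sd = 1.5,
                             resp_pp_mv = 3120, pulse_pp_mv = 84,
                             noise_sd_mv = 1,
                             pulse_dropout_prob = 0.3,
                             baseline_mv = 0,
                             seed = 1L) {
  vals <- c(duration_s, sample_rate_hz, rr_mean, rr_sd, hr_mean, hr_sd,
            resp_pp_mv, pulse_pp_mv, noise_sd_mv, pulse_dropout_prob,
            baseline_mv, seed)
  if (!all(is.finite(vals))) stop("synthetic_config: non-finite parameter")
  if (duration_s <= 0) stop("synthetic_config: 'duration_s' must be > 0")
  if (sample_rate_hz <= 0) stop("synthetic_config: 'sample_rate_hz' must be > 0")
  if (pulse_dropout_prob < 0 || pulse_dropout_prob > 1) {
    stop("synthetic_config: 'pulse_dropout_prob' must be in [0, 1]")
  }
  if (resp_pp_mv < 0 || pulse_pp_mv < 0 || noise_sd_mv < 0) {
    stop("synthetic_config: amplitudes must be >= 0")
  }
  if (rr_mean >= 60) stop("synthetic_config: 'rr_mean' must be below 60")
  if (hr_mean >= 180) stop("synthetic_config: 'hr_mean' must be below 180")
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 rr_mean = rr_mean, rr_sd = rr_sd,
                 hr_mean = hr_mean, hr_sd = hr_sd,
                 resp_pp_mv = resp_pp_mv, pulse_pp_mv = pulse_pp_mv,
                 noise_sd_mv = noise_sd_mv,
                 pulse_dropout_prob = pulse_dropout_prob,
                 baseline_mv = baseline_mv, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Respiratory cycle shape g(phi) on [0, 1), crest (1) -> crest (1).
# Three segments: an eased near-linear expiration, a slow exhalation tail
# into the trough, and a brisk raised-cosine inspiration. Between crest
# and trough the signal falls monotonically and is never flat, which is
# what the delayed comparator keys on; throughout the fall and tail the
# local drop over the comparator delay stays below the pulse amplitude,
# so a superimposed pulse briefly reverses the trend and splits the
# breath event -- the phenomenon the merge step repairs. The inspiration
# is kept brief so that beats hidden by its steep rise (which no
# comparator setting can see under the ~37x amplitude ratio) stay rare
# and the configured dropout probability dominates the miss process.
resp_shape <- function(phi,
                       frac_fall = 0.70, frac_tail = 0.25,
                       tail_from = 0.12, ease = 0.10) {
  g <- numeric(length(phi))
  # main expiration: trapezoidal-speed eased-linear drop to tail_from
  in_fall <- phi < frac_fall
  u <- phi[in_fall] / frac_fall
  vmax <- 1 / (1 - ease)
  w <- ifelse(u < ease, vmax * u^2 / (2 * ease),
        ifelse(u <= 1 - ease, vmax * (u - ease / 2),
               1 - vmax * (1 - u)^2 / (2 * ease)))
  g[in_fall] <- 1 - (1 - tail_from) * w
  # slow exhalation tail: linear decline to the trough
  in_tail <- !in_fall & phi < frac_fall + frac_tail
  u <- (phi[in_tail] - frac_fall) / frac_tail
  g[in_tail] <- tail_from * (1 - u)
  # inspiration: raised-cosine rise back to the crest
  f2 <- frac_fall + frac_tail
  in_rise <- phi >= f2
  u <- (phi[in_rise] - f2) / (1 - f2)
  g[in_rise] <- 0.5 * (1 - cos(pi * u))
  g
}

# Cardiac pulse template: inverted Ricker (Mexican-hat) wavelet,
# normalized to unit peak-to-peak -- a negative-going notch ~150 ms wide
# with gentle positive side lobes. Both the drop into the notch and the
# recovery out of it are sharp (~50 ms), so on slowly varying signal the
# drop registers as a short comparator run, and on a falling respiratory
# flank the recovery briefly reverses the trend and splits the breath
# event.
pulse_template <- function(t, sigma = 0.03) {
  u <- t / sigma
  -(1 - u^2) * exp(-u^2 / 2) / (1 + 2 * exp(-1.5))
}

#' Generate a synthetic band signal with ground truth
#'
#' Builds `baseline + respiratory oscillation + cardiac pulses + noise`.
#' Breath crest times and beat times are drawn with Gaussian
#' cycle-to-cycle / beat-to-beat variability; every beat is recorded in
#' the ground truth, but beats flagged as dropped (with probability
#' `pulse_dropout_prob`) leave no pulse on the waveform, emulating the
#' band's cardiac miss rate. Output is bit-reproducible for a fixed
#' configuration and seed.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `series` (a [sample_series()]) and `truth` (a list
#'   of class `ground_truth` with `breath_peak_times`, `beat_times` and
#'   `dropped_beat_flags`).
#' @export
#' @examples
#' out <- generate_band_signal(synthetic_config(duration_s = 30, seed = 7))
#' length(out$truth$breath_peak_times)
generate_band_signal <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(cfg$seed)
  N <- cfg$sample_rate_hz
  tt <- seq(0, cfg$duration_s, by = 1 / N)

  # breath crest times: cycle durations from the rate distribution,
  # clamped so consecutive crests are always > 1 s apart
  n_breaths <- ceiling(cfg$duration_s * cfg$rr_mean / 60) + 3L
  rr <- stats::rnorm(n_breaths, cfg$rr_mean, cfg$rr_sd)
  rr <- pmin(pmax(rr, 1), 57)
  crests <- cumsum(c(0, 60 / rr))
  while (crests[length(crests)] < cfg$duration_s + 60 / cfg$rr_mean) {
    extra <- pmin(pmax(stats::rnorm(1, cfg$rr_mean, cfg$rr_sd), 1), 57)
    crests <- c(crests, crests[length(crests)] + 60 / extra)
  }

  # respiratory component
  k <- findInterval(tt, crests)
  k[k < 1] <- 1L
  dk <- diff(crests)[k]
  phi <- (tt - crests[k]) / dk
  phi <- pmin(pmax(phi, 0), 1 - 1e-12)
  resp <- cfg$baseline_mv + cfg$resp_pp_mv * resp_shape(phi)

  # beat times: beat-to-beat intervals from the rate distribution,
  # clamped to the 180 bpm physiological ceiling
  n_beats <- ceiling(cfg$duration_s * cfg$hr_mean / 60) + 3L
  hr <- stats::rnorm(n_beats, cfg$hr_mean, cfg$hr_sd)
  hr <- pmin(pmax(hr, 20), 179)
  beats <- cumsum(c(0.4, 60 / hr))
  while (beats[length(beats)] < cfg$duration_s) {
    extra <- pmin(pmax(stats::rnorm(1, cfg$hr_mean, cfg$hr_sd), 20), 179)
    beats <- c(beats, beats[length(beats)] + 60 / extra)
  }
  beats <- beats[beats <= cfg$duration_s]
  dropped <- stats::runif(length(beats)) < cfg$pulse_dropout_prob

  # cardiac pulses for the beats that reach the waveform
  y <- resp
  half_w <- 0.09
  sigma <- 0.03
  if (cfg$pulse_pp_mv > 0) {
    for (tb in beats[!dropped]) {
      i0 <- max(1L, ceiling((tb - half_w) * N) + 1L)
      i1 <- min(length(tt), floor((tb + half_w) * N) + 1L)
      if (i1 >= i0) {
        y[i0:i1] <- y[i0:i1] +
          cfg$pulse_pp_mv * pulse_template(tt[i0:i1] - tb, sigma)
      }
    }
  }
  if (cfg$noise_sd_mv > 0) {
    y <- y + stats::rnorm(length(y), 0, cfg$noise_sd_mv)
  }

  truth <- structure(
    list(breath_peak_times = crests[crests <= cfg$duration_s],
         beat_times = beats,
         dropped_beat_flags = dropped),
    class = "ground_truth")
  list(series = sample_series(y, N), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d breaths, %d beats (%d dropped from waveform)\n",
              length(x$breath_peak_times), length(x$beat_times),
              sum(x$dropped_beat_flags)))
  invisible(x)
}

#' Write ground truth as CSV peak lists
#'
#' @param truth A `ground_truth` object from [generate_band_signal()].
#' @param breaths_path,beats_path Output CSV paths.
#' @return Invisibly, a list of the paths written.
#' @export
write_ground_truth <- function(truth, breaths_path, beats_path) {
  stopifnot(inherits(truth, "ground_truth"))
  utils::write.csv(data.frame(time_s = truth$breath_peak_times),
                   breaths_path, row.names = FALSE)
  utils::write.csv(data.frame(time_s = truth$beat_times,
                              dropped = truth$dropped_beat_flags),
                   beats_path, row.names = FALSE)
  invisible(list(breaths = breaths_path, beats = beats_path))
}
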