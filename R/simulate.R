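# Synthetic oddball-EEG study generator.
#
# The signal model is deliberately simple and makes no claim of physiological
# realism: pink-noise background plus stimulus-locked damped alpha-band
# bursts whose amplitude and cross-channel phase coherence shrink with
# impairment. Coherent bursts with a fixed phase progression across the
# montage trace large clean loops in channel space, which is exactly the
# "cyclic" structure the topological features downstream are designed to
# measure; impairment shrinks and de-phases the loops.

# 1/f ("pink") background noise via spectral shaping of white noise.
pink_noise <- function(n, sd_uv) {
  if (n == 0) return(numeric(0))
  w <- rnorm(n)
  spec <- fft(w)
  k <- c(1, pmin(seq_len(n - 1), n - seq_len(n - 1)))  # symmetric freq index
  spec <- spec / sqrt(k)
  x <- Re(fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x) * sd_uv
}

# Amplitude (microvolts) and timing constants of the burst model.
.burst <- list(
  amp_uv = 22,        # peak alpha-burst amplitude of a fully healthy subject
  floor = 0.08,       # residual burst fraction at severity 1, effect size 1
  freq_hz = 10,       # alpha centre frequency
  freq_sd_hz = 0.6,   # per-event frequency jitter
  tau_s = 0.45,       # exponential decay time of the burst envelope
  dur_s = 1.6,        # burst support after stimulus onset
  target_gain = 1.25, # attention bump for cue/target displays
  noise_sd_uv = 6     # pink-noise background SD per channel
)

#' Sample a MoCA score consistent with group and severity
#'
#' The Montreal Cognitive Assessment score (0-30, lower = more impaired) is
#' drawn as a noisy, monotonically decreasing function of the latent severity
#' and clipped to the generator's group convention: healthy cognitive aging
#' scores at or above the standard cutoff of 26, MCI strictly below it.
#'
#' @param group `"healthy"` or `"mci"`.
#' @param severity Number in `[0, 1]`; 0 is fully healthy.
#' @return Integer MoCA score in `[0, 30]`.
#' @examples
#' set.seed(1)
#' sample_moca("mci", severity = 0.9)
#' @export
sample_moca <- function(group, severity) {
  stopifnot(group %in% c("healthy", "mci"),
            is.finite(severity), severity >= 0, severity <= 1)
  if (group == "healthy") {
    raw <- 30 - 5 * severity + rnorm(1, sd = 0.8)
    as.integer(min(30, max(26, round(raw))))
  } else {
    raw <- 25.4 - 11 * severity + rnorm(1, sd = 1.4)
    as.integer(min(25, max(0, round(raw))))
  }
}

# Event schedule for one subject: each session is one cue display followed by
# a randomly ordered stream of the image identities in which the cued image
# appears once as the target. Half the image identities are reminiscent
# (childhood-themed), half contemporary.
make_events <- function(config) {
  fs <- config$sampling_rate_hz
  isi <- round(config$isi_s * fs)
  gap <- round(config$inter_session_gap_s * fs)
  n_img <- config$n_images_per_session
  n_rem <- ceiling(n_img / 2)
  rows <- vector("list", config$n_sessions)
  cursor <- gap  # lead-in before the first session
  for (s in seq_len(config$n_sessions)) {
    target_img <- if (n_img > 0) sample.int(n_img, 1) else NA_integer_
    stream <- if (n_img > 0) sample.int(n_img) else integer(0)
    ids <- c(target_img, stream)
    roles <- c("cue",
               ifelse(stream == target_img, "target", "ignored"))
    onsets <- cursor + (seq_along(ids) - 1L) * isi
    rows[[s]] <- data.frame(
      onset_sample = onsets,
      session_index = s,
      role = roles,
      category = ifelse(ids <= n_rem, "reminiscent", "contemporary"),
      image_id = ids,
      stringsAsFactors = FALSE)
    cursor <- cursor + length(ids) * isi + gap
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev)) ev <- data.frame(onset_sample = integer(0),
                                    session_index = integer(0),
                                    role = character(0),
                                    category = character(0),
                                    image_id = integer(0))
  attr(ev, "n_samples") <- cursor + round(2 * fs)  # tail so last epoch fits
  ev
}

#' Generate one synthetic EEG recording
#'
#' Produces a continuous multichannel recording for one participant:
#' pink-noise background plus a damped alpha-band burst locked to each
#' stimulus onset. Burst amplitude and the coherence of the fixed
#' cross-channel phase progression scale with
#' `1 - severity * effect_size`, so healthy subjects' post-stimulus epochs
#' trace larger, cleaner loops in channel space than impaired subjects'.
#'
#' Artifacts are not added here; see [inject_artifacts()].
#'
#' @param profile A row-like list with at least `subject_id` and `severity`
#'   (e.g. one row of the participants table of [generate_study()]).
#' @param config A [study_config()].
#' @return An `eeg_recording`: list with `subject_id`, `channel_names`,
#'   `sampling_rate_hz`, `data` (channels x samples matrix, microvolts) and
#'   `events` (one row per stimulus display).
#' @export
generate_recording <- function(profile, config) {
  validate_study_config(config)
  stopifnot(!is.null(profile$subject_id), is.finite(profile$severity))
  fs <- config$sampling_rate_hz
  nch <- config$n_channels
  events <- make_events(config)
  n_samples <- attr(events, "n_samples")

  gain <- 1 - profile$severity * config$effect_size  # coherence/amplitude dial
  amp <- .burst$amp_uv * (.burst$floor + (1 - .burst$floor) * gain)

  data <- matrix(0, nrow = nch, ncol = n_samples)
  for (ch in seq_len(nch))
    data[ch, ] <- pink_noise(n_samples, .burst$noise_sd_uv)

  if (nrow(events) > 0) {
    burst_len <- round(.burst$dur_s * fs)
    t <- (seq_len(burst_len) - 1) / fs
    env <- exp(-t / .burst$tau_s)
    phase0 <- 2 * pi * (seq_len(nch) - 1) / nch  # fixed loop in channel space
    for (e in seq_len(nrow(events))) {
      f <- rnorm(1, .burst$freq_hz, .burst$freq_sd_hz)
      role_gain <- if (events$role[e] %in% c("cue", "target"))
        .burst$target_gain else 1
      jitter <- rnorm(nch, sd = pi * (1 - gain))  # de-phase when impaired
      idx <- events$onset_sample[e] + seq_len(burst_len)
      idx <- idx[idx <= n_samples]
      for (ch in seq_len(nch)) {
        wave <- amp * role_gain * env[seq_along(idx)] *
          sin(2 * pi * f * t[seq_along(idx)] + phase0[ch] + jitter[ch])
        data[ch, idx] <- data[ch, idx] + wave
      }
    }
  }
  rownames(data) <- config$channel_names
  structure(list(subject_id = profile$subject_id,
                 channel_names = config$channel_names,
                 sampling_rate_hz = fs,
                 data = data,
                 events = events),
            class = "eeg_recording")
}

#' Inject eye-blink-like transients into a recording
#'
#' Adds smooth low-frequency (< 5 Hz) positive deflections at random onsets,
#' strongest over the frontal midline and fading toward posterior sites,
#' mimicking ocular artifacts. The input recording is not modified.
#'
#' @param recording An `eeg_recording`.
#' @param rate_per_min Expected transients per minute (Poisson).
#' @param peak_amplitude_uv Peak amplitude on the frontal channel.
#' @param seed Integer seed for onset placement.
#' @return A new `eeg_recording` with artifacts added.
#' @export
inject_artifacts <- function(recording, rate_per_min, peak_amplitude_uv = 200,
                             seed = 1L) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (rate_per_min < 0) stop("`rate_per_min` must be nonnegative")
  if (peak_amplitude_uv < 0) stop("`peak_amplitude_uv` must be nonnegative")
  out <- recording
  if (rate_per_min == 0) return(out)
  fs <- recording$sampling_rate_hz
  n <- ncol(recording$data)
  nch <- nrow(recording$data)
  minutes <- n / fs / 60
  # anterior-to-posterior falloff of ocular artifacts over the montage
  topo <- c(1, 0.6, 0.6, 0.6, 0.3, 0.2, 0.15, 0.2)
  topo <- if (nch <= 8) topo[seq_len(nch)] else c(topo, rep(0.1, nch - 8))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  k <- rpois(1, rate_per_min * minutes)
  if (k == 0) return(out)
  onsets <- sort(runif(k, 0, n / fs))
  width_s <- 0.15  # Gaussian SD: ~1.1 Hz half-power bandwidth, well below 5 Hz
  half <- round(3 * width_s * fs)
  for (o in onsets) {
    centre <- round(o * fs)
    idx <- max(1, centre - half):min(n, centre + half)
    bump <- peak_amplitude_uv *
      exp(-((idx - centre) / fs)^2 / (2 * width_s^2))
    out$data[, idx] <- out$data[, idx] + outer(topo, bump)
  }
  out
}

#' Generate a complete synthetic study
#'
#' Draws a cohort of participants (group labels, latent severity, age, MoCA
#' score), then a full recording with event markers for each, with eye-blink
#' artifacts injected at the configured rate. The entire study is a pure
#' function of the configuration, including `master_seed`.
#'
#' @param config A [study_config()].
#' @return An object of class `eeg_study`: list with `config`,
#'   `participants` (data frame: subject_id, group, severity, moca,
#'   age_years) and `recordings` (named list of `eeg_recording`).
#' @examples
#' study <- generate_study(study_config(n_subjects = 2, n_mci = 1,
#'                                      n_sessions = 1, master_seed = 3))
#' study$participants
#' @export
generate_study <- function(config) {
  validate_study_config(config)
  n <- config$n_subjects
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  set.seed(config$master_seed)
  groups <- c(rep("mci", config$n_mci), rep("healthy", n - config$n_mci))
  participants <- vector("list", n)
  recordings <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$master_seed, i, stream = 1L))
    group <- groups[i]
    severity <- if (group == "healthy") runif(1, 0, 0.25) else runif(1, 0.35, 1)
    profile <- list(
      subject_id = sprintf("sub-%02d", i),
      group = group,
      severity = severity,
      moca = sample_moca(group, severity),
      age_years = min(90, max(60, rnorm(1, config$age_mean_years,
                                        config$age_sd_years))))
    set.seed(derive_seed(config$master_seed, i, stream = 2L))
    rec <- generate_recording(profile, config)
    if (config$artifact_rate_per_min > 0)
      rec <- inject_artifacts(rec, config$artifact_rate_per_min,
                              config$artifact_peak_uv,
                              seed = derive_seed(config$master_seed, i,
                                                 stream = 3L))
    participants[[i]] <- as.data.frame(profile, stringsAsFactors = FALSE)
    recordings[[i]] <- rec
  }
  participants <- if (n > 0) do.call(rbind, participants) else
    data.frame(subject_id = character(0), group = character(0),
               severity = numeric(0), moca = integer(0),
               age_years = numeric(0))
  names(recordings) <- participants$subject_id
  structure(list(config = config, participants = participants,
                 recordings = recordings),
            class = "eeg_study")
}

#' @export
print.eeg_study <- function(x, ...) {
  cat(sprintf("Synthetic EEG study: %d subjects (%d MCI, %d healthy)\n",
              nrow(x$participants), sum(x$participants$group == "mci"),
              sum(x$participants$group == "healthy")))
  invisible(x)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording %s: %d ch x %d samples @ %g Hz, %d events\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$sampling_rate_hz,
              nrow(x$events)))
  invisible(x)
}
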