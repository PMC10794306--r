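#' Study configuration for the synthetic oddball-EEG generator
#'
#' Bundles every knob of the simulated study. The defaults reproduce the
#' design this pipeline targets: an 8-channel dry-electrode montage sampled
#' at 250 Hz, eight oddball sessions per participant, each consisting of one
#' cue display followed by a stream of eight interior-image displays in which
#' the cued image reappears once as the target, i.e.
#' `n_sessions * (n_images_per_session + 1) = 72` stimulus displays per
#' participant.
#'
#' @param n_subjects Number of participants.
#' @param n_mci Number of participants in the MCI group (the rest are
#'   labelled healthy cognitive aging). Must lie in `[0, n_subjects]`.
#' @param n_channels Number of EEG channels.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param n_sessions Oddball sessions per participant.
#' @param n_images_per_session Stream displays per session (half reminiscent,
#'   half contemporary image identities).
#' @param age_mean_years,age_sd_years Normal age distribution of the cohort
#'   (clipped to 60-90 years; cosmetic metadata).
#' @param effect_size Number in `[0, 1]` controlling cohort separation:
#'   post-stimulus oscillatory burst amplitude and cross-channel phase
#'   coherence scale with `1 - severity * effect_size`. At 0 the two groups
#'   are statistically exchangeable; at 1 the separation is strong.
#' @param artifact_rate_per_min Expected number of eye-blink-like transients
#'   injected per minute of recording.
#' @param artifact_peak_uv Peak amplitude of injected transients
#'   (microvolts, on the frontal channel).
#' @param isi_s Inter-stimulus interval within a session, seconds.
#' @param inter_session_gap_s Pause between sessions, seconds.
#' @param cue_as_target How cue epochs are labelled downstream: `"target"`
#'   counts them with TGT (default, giving 16 TGT / 56 IGN per participant
#'   under the default design), `"drop"` excludes them.
#' @param channel_names Electrode labels (defaults to the 8-channel montage
#'   Fz, C3, Cz, C4, Pz, PO7, Oz, PO8).
#' @param master_seed Integer seed; the whole study is a pure function of
#'   the configuration including this seed.
#' @return An object of class `study_config` (a validated list).
#' @examples
#' cfg <- study_config(n_subjects = 4, n_mci = 2, master_seed = 7)
#' cfg$n_sessions * (cfg$n_images_per_session + 1) # 72 displays
#' @export
study_config <- function(n_subjects = 23,
                         n_mci = 16,
                         n_channels = 8,
                         sampling_rate_hz = 250,
                         n_sessions = 8,
                         n_images_per_session = 8,
                         age_mean_years = 70.70,
                         age_sd_years = 5.32,
                         effect_size = 1,
                         artifact_rate_per_min = 5,
                         artifact_peak_uv = 200,
                         isi_s = 2.5,
                         inter_session_gap_s = 2,
                         cue_as_target = c("target", "drop"),
                         channel_names = NULL,
                         master_seed = 1L) {
  cue_as_target <- match.arg(cue_as_target)
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_mci = as.integer(n_mci),
              n_channels = as.integer(n_channels),
              sampling_rate_hz = as.numeric(sampling_rate_hz),
              n_sessions = as.integer(n_sessions),
              n_images_per_session = as.integer(n_images_per_session),
              age_mean_years = age_mean_years,
              age_sd_years = age_sd_years,
              effect_size = effect_size,
              artifact_rate_per_min = artifact_rate_per_min,
              artifact_peak_uv = artifact_peak_uv,
              isi_s = isi_s,
              inter_session_gap_s = inter_session_gap_s,
              cue_as_target = cue_as_target,
              channel_names = channel_names,
              master_seed = as.integer(master_seed))
  if (is.null(cfg$channel_names)) {
    base <- c("Fz", "C3", "Cz", "C4", "Pz", "PO7", "Oz", "PO8")
    cfg$channel_names <- if (cfg$n_channels <= 8) base[seq_len(cfg$n_channels)]
                         else c(base, paste0("EEG", seq_len(cfg$n_channels - 8)))
  }
  validate_study_config(cfg)
  class(cfg) <- "study_config"
  cfg
}

validate_study_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 0)
    stop("`n_subjects` must be a nonnegative integer", call. = FALSE)
  if (is.na(cfg$n_mci) || cfg$n_mci < 0 || cfg$n_mci > cfg$n_subjects)
    stop("`n_mci` must lie in [0, n_subjects]", call. = FALSE)
  if (cfg$n_channels < 1) stop("`n_channels` must be positive", call. = FALSE)
  if (cfg$sampling_rate_hz <= 0)
    stop("`sampling_rate_hz` must be positive", call. = FALSE)
  if (cfg$n_sessions < 0 || cfg$n_images_per_session < 0)
    stop("session counts must be nonnegative", call. = FALSE)
  if (cfg$effect_size < 0 || cfg$effect_size > 1)
    stop("`effect_size` must lie in [0, 1]", call. = FALSE)
  if (cfg$artifact_rate_per_min < 0)
    stop("`artifact_rate_per_min` must be nonnegative", call. = FALSE)
  if (cfg$artifact_peak_uv < 0)
    stop("`artifact_peak_uv` must be nonnegative", call. = FALSE)
  if (cfg$isi_s <= 0) stop("`isi_s` must be positive", call. = FALSE)
  if (length(cfg$channel_names) != cfg$n_channels ||
      anyDuplicated(cfg$channel_names))
    stop("`channel_names` must be unique and match `n_channels`",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic oddball-EEG study config: %d subjects ",
                     "(%d MCI), %d ch @ %g Hz, %d sessions x %d images, ",
                     "effect size %.2f, seed %d\n"),
              x$n_subjects, x$n_mci, x$n_channels, x$sampling_rate_hz,
              x$n_sessions, x$n_images_per_session, x$effect_size,
              x$master_seed))
  invisible(x)
}

# Stable per-entity seed derivation so each subject / stage is independently
# reproducible from the master seed. Kept strictly below 2^31 - 1.
derive_seed <- function(master_seed, index, stream = 0L) {
  (as.numeric(master_seed) * 48271 + as.numeric(index) * 104729 +
     as.numeric(stream) * 7919) %% 2147483647
}
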