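#' Zero-phase band-pass filter a recording
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (zero group delay) to every channel. The default 1-40 Hz band removes
#' baseline drift and high-frequency noise while keeping the oscillatory
#' content the downstream topological features rely on.
#'
#' @param recording An `eeg_recording`.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < sampling_rate / 2`.
#' @return A new `eeg_recording` with filtered data.
#' @export
eeg_bandpass <- function(recording, low_hz = 1, high_hz = 40) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate_hz
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("invalid band: need 0 < low_hz < high_hz < sampling_rate / 2")
  bf <- signal::butter(4, c(low_hz, high_hz) / (fs / 2), type = "pass")
  out <- recording
  for (ch in seq_len(nrow(out$data)))
    out$data[ch, ] <- signal::filtfilt(bf, out$data[ch, ])
  out
}

#' Segment a recording into stimulus-locked epochs
#'
#' Cuts one epoch per event over the half-open window
#' `[onset, onset + epoch_length_s)`, i.e. exactly
#' `round(epoch_length_s * sampling_rate)` samples (500 at the default
#' 2 s x 250 Hz). Events whose window would overrun the end of the recording
#' are dropped and counted in the `dropped` attribute. Cue displays are
#' labelled with the target condition by default (`cue_as = "target"`),
#' since the cue is the display the participant is instructed to memorize;
#' pass `"drop"` to exclude them.
#'
#' @param recording An `eeg_recording` with an event table.
#' @param epoch_length_s Epoch duration in seconds.
#' @param cue_as `"target"` or `"drop"`.
#' @return An `epoch_set`: list with `subject_id`, `sampling_rate_hz`,
#'   `epoch_length_s`, `epochs` (list of channels x samples matrices),
#'   `condition` (factor, `TGT`/`IGN`) and `session` (integer vector);
#'   attribute `dropped` holds the number of discarded events.
#' @export
segment_epochs <- function(recording, epoch_length_s = 2,
                           cue_as = c("target", "drop")) {
  stopifnot(inherits(recording, "eeg_recording"))
  cue_as <- match.arg(cue_as)
  fs <- recording$sampling_rate_hz
  len <- round(epoch_length_s * fs)
  ev <- recording$events
  n <- ncol(recording$data)

  keep <- rep(TRUE, nrow(ev))
  if (cue_as == "drop") keep <- keep & ev$role != "cue"
  usable <- keep & (ev$onset_sample + len <= n)
  dropped <- sum(keep & !usable)
  if (dropped > 0)
    message(sprintf("segment_epochs: dropped %d event(s) overrunning the recording end", dropped))
  ev <- ev[usable, , drop = FALSE]

  epochs <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    idx <- ev$onset_sample[i] + seq_len(len)  # [onset, onset + len)
    epochs[[i]] <- recording$data[, idx, drop = FALSE]
  }
  condition <- ifelse(ev$role == "ignored", "IGN", "TGT")
  structure(list(subject_id = recording$subject_id,
                 sampling_rate_hz = fs,
                 epoch_length_s = epoch_length_s,
                 epochs = epochs,
                 condition = factor(condition, levels = c("TGT", "IGN")),
                 session = ev$session_index),
            class = "epoch_set", dropped = dropped)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set %s: %d epochs (%s) of %g s @ %g Hz\n",
              x$subject_id, length(x$epochs),
              paste(sprintf("%s=%d", levels(x$condition),
                            tabulate(x$condition, 2)), collapse = ", "),
              x$epoch_length_s, x$sampling_rate_hz))
  invisible(x)
}

#' Preprocess one recording: filter, epoch, EMD-clean
#'
#' The fixed pipeline order is band-pass filter, then stimulus-locked
#' epoching, then per-channel empirical-mode-decomposition cleaning of each
#' epoch at the amplitude threshold (see [emd_clean()]).
#'
#' @param recording An `eeg_recording`.
#' @param low_hz,high_hz Band-pass edges (Hz).
#' @param epoch_length_s Epoch duration (seconds).
#' @param threshold_uv Amplitude threshold for IMF rejection (microvolts).
#' @param emd If `FALSE`, skip the EMD cleaning stage (useful for
#'   artifact-free simulations where it is a no-op by construction).
#' @param cue_as Cue-epoch handling, see [segment_epochs()].
#' @return A cleaned `epoch_set`.
#' @export
preprocess_recording <- function(recording, low_hz = 1, high_hz = 40,
                                 epoch_length_s = 2, threshold_uv = 100,
                                 emd = TRUE, cue_as = c("target", "drop")) {
  cue_as <- match.arg(cue_as)
  rec <- eeg_bandpass(recording, low_hz, high_hz)
  es <- segment_epochs(rec, epoch_length_s, cue_as = cue_as)
  if (emd)
    es$epochs <- lapply(es$epochs, emd_clean, threshold_uv = threshold_uv)
  es
}
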