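# helpers to build bare recordings around known signals
make_recording <- function(data, fs = 250, events = NULL) {
  if (is.null(events))
    events <- data.frame(onset_sample = integer(0), session_index = integer(0),
                         role = character(0), category = character(0),
                         image_id = integer(0))
  structure(list(subject_id = "test",
                 channel_names = paste0("ch", seq_len(nrow(data))),
                 sampling_rate_hz = fs, data = data, events = events),
            class = "eeg_recording")
}

test_that("band-pass keeps the passband and kills drift", {
  fs <- 250; t <- seq(0, 20, by = 1 / fs)

  zero <- make_recording(matrix(0, 2, length(t)), fs)
  expect_equal(eeg_bandpass(zero)$data, zero$data)

  tone <- make_recording(matrix(10 * sin(2 * pi * 10 * t), 1), fs)
  out <- eeg_bandpass(tone)$data[1, ]
  mid <- seq(fs, length(t) - fs)  # ignore edge transients
  rms_ratio <- sqrt(mean(out[mid]^2)) / sqrt(mean(tone$data[1, mid]^2))
  expect_lt(abs(rms_ratio - 1), 0.12)

  drift <- make_recording(matrix(100 * sin(2 * pi * 0.1 * t), 1), fs)
  expect_lt(max(abs(eeg_bandpass(drift)$data[1, mid])), 10)

  expect_error(eeg_bandpass(tone, 40, 1), "invalid band")
  expect_error(eeg_bandpass(tone, 1, 200), "invalid band")
})

test_that("epoching yields 72 half-open 500-sample windows per subject", {
  cfg <- study_config(n_subjects = 1, n_mci = 0, artifact_rate_per_min = 0,
                      master_seed = 4)
  rec <- generate_study(cfg)$recordings[[1]]
  es <- segment_epochs(rec)
  expect_length(es$epochs, 72)
  expect_true(all(vapply(es$epochs, function(e) all(dim(e) == c(8, 500)),
                         logical(1))))
  # default cue mapping: cue + target count as TGT
  expect_equal(as.integer(table(es$condition)), c(16L, 56L))
  es_drop <- segment_epochs(rec, cue_as = "drop")
  expect_equal(as.integer(table(es_drop$condition)), c(8L, 56L))

  # epochs are contiguous slices of the recording, no fabricated samples
  i <- 10
  on <- rec$events$onset_sample[i]
  expect_identical(es$epochs[[i]], rec$data[, on + 1:500])

  # truncation mid-final-epoch drops exactly that epoch, with a log message
  short <- rec
  last_on <- rec$events$onset_sample[72]
  short$data <- rec$data[, 1:(last_on + 499), drop = FALSE]
  expect_message(es71 <- segment_epochs(short), "dropped 1")
  expect_length(es71$epochs, 71)
  expect_equal(attr(es71, "dropped"), 1)

  none <- rec; none$events <- rec$events[0, ]
  expect_length(segment_epochs(none)$epochs, 0)
})

test_that("preprocessing order and EMD-clean idempotence hold", {
  cfg <- study_config(n_subjects = 1, n_mci = 1, n_sessions = 1,
                      sampling_rate_hz = 100, artifact_rate_per_min = 0,
                      master_seed = 6)
  rec <- generate_study(cfg)$recordings[[1]]
  es <- preprocess_recording(rec, emd = TRUE)
  expect_s3_class(es, "epoch_set")
  expect_length(es$epochs, 9)
  # artifact-free epochs survive cleaning nearly unchanged, and a second
  # cleaning pass is a near no-op
  ep <- es$epochs[[3]]
  ep2 <- emd_clean(ep, 100)
  expect_lt(max(abs(ep2 - ep)) / max(abs(ep)), 1e-3)
})
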