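test_that("study generation respects cohort sizes and is deterministic", {
  cfg <- study_config(n_subjects = 23, n_mci = 16, n_sessions = 1,
                      sampling_rate_hz = 100, artifact_rate_per_min = 0,
                      master_seed = 1)
  study <- generate_study(cfg)
  expect_equal(nrow(study$participants), 23)
  expect_length(study$recordings, 23)
  expect_equal(sum(study$participants$group == "mci"), 16)

  cfg2 <- study_config(n_subjects = 2, n_mci = 1, n_sessions = 1,
                       sampling_rate_hz = 100, master_seed = 7)
  a <- generate_study(cfg2); b <- generate_study(cfg2)
  expect_identical(a$participants, b$participants)
  expect_identical(a$recordings[[1]]$data, b$recordings[[1]]$data)
  expect_identical(a$recordings[[2]]$events, b$recordings[[2]]$events)

  empty <- generate_study(study_config(n_subjects = 0, n_mci = 0))
  expect_equal(nrow(empty$participants), 0)
  expect_length(empty$recordings, 0)

  expect_error(study_config(n_subjects = 3, n_mci = 5), "n_mci")
  expect_error(study_config(n_subjects = 2, n_mci = 1, isi_s = -1), "isi")
})

test_that("event grammar: one cue and one in-stream target per session", {
  cfg <- study_config(n_subjects = 1, n_mci = 0, master_seed = 3,
                      artifact_rate_per_min = 0)
  rec <- generate_study(cfg)$recordings[[1]]
  ev <- rec$events
  expect_equal(nrow(ev), 8 * 9)  # 72 displays under the default design
  expect_true(all(diff(ev$onset_sample) > 0))
  expect_true(all(ev$onset_sample + 2 * rec$sampling_rate_hz <=
                    ncol(rec$data)))
  per <- split(ev, ev$session_index)
  for (s in per) {
    expect_equal(sum(s$role == "cue"), 1)
    expect_equal(sum(s$role == "target"), 1)
    expect_equal(sum(s$role == "ignored"), 7)
    stream <- s[s$role != "cue", ]
    expect_setequal(stream$image_id, 1:8)
    expect_equal(sum(stream$category == "reminiscent"), 4)
    expect_equal(sum(stream$category == "contemporary"), 4)
    expect_equal(s$image_id[s$role == "cue"], s$image_id[s$role == "target"])
  }
  expect_equal(as.integer(table(ev$role)[c("cue", "target", "ignored")]),
               c(8L, 8L, 56L))
})

test_that("MoCA scores respect the group cutoff and decrease with severity", {
  set.seed(5)
  h <- replicate(200, sample_moca("healthy", 0))
  expect_true(all(h >= 26 & h <= 30))
  m <- replicate(200, sample_moca("mci", 1))
  expect_true(all(m < 26 & m >= 0))
  sev <- runif(1000, 0.35, 1)
  moca <- vapply(sev, function(s) sample_moca("mci", s), integer(1))
  expect_lt(cor(sev, moca, method = "spearman"), 0)
})

test_that("post-stimulus alpha band power separates severity extremes", {
  cfg <- study_config(n_subjects = 2, n_mci = 1, n_sessions = 4,
                      effect_size = 1, artifact_rate_per_min = 0,
                      master_seed = 11)
  healthy <- generate_recording(list(subject_id = "h", severity = 0), cfg)
  impaired <- generate_recording(list(subject_id = "m", severity = 1), cfg)
  power_of <- function(rec) {
    es <- segment_epochs(rec)
    vapply(es$epochs,
           function(ep) bandpower_oracle(ep["Cz", ], cfg$sampling_rate_hz,
                                         8, 12),
           numeric(1))
  }
  ph <- power_of(healthy); pm <- power_of(impaired)
  expect_gte(length(ph) + length(pm), 50)
  expect_gt(mean(ph), mean(pm))
})

test_that("artifact injection adds frontal-dominant transients reproducibly", {
  cfg <- study_config(n_subjects = 1, n_mci = 0, n_sessions = 2,
                      artifact_rate_per_min = 0, master_seed = 2)
  rec <- generate_study(cfg)$recordings[[1]]

  expect_identical(inject_artifacts(rec, 0, 200, seed = 1)$data, rec$data)

  dirty <- inject_artifacts(rec, rate_per_min = 10, peak_amplitude_uv = 200,
                            seed = 1)
  expect_gt(max(abs(dirty$data["Fz", ])), 150)
  expect_identical(rec$data["Fz", 1:10], rec$data["Fz", 1:10])  # input intact
  # frontal dominance of the added component
  added <- dirty$data - rec$data
  expect_gt(max(abs(added["Fz", ])), max(abs(added["Oz", ])))

  dirty2 <- inject_artifacts(rec, 10, 200, seed = 2)
  expect_false(identical(dirty$data, dirty2$data))
  expect_error(inject_artifacts(rec, 10, -5), "nonnegative")
})
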