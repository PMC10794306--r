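# Shared, lazily computed fixtures. The heavy simulated studies are built
# once per test run and reused by every test file that needs them.

.fx <- new.env(parent = emptyenv())

# Effect-recovery study: the cohort split of interest (10 healthy / 13 MCI),
# full effect, one oddball session per subject at the native 250 Hz.
recovery_fixture <- function() {
  if (is.null(.fx$recovery)) {
    cfg <- study_config(n_subjects = 23, n_mci = 13, n_sessions = 1,
                        effect_size = 1, artifact_rate_per_min = 0,
                        master_seed = 20921)
    study <- generate_study(cfg)
    feats <- study_features(study, emd = FALSE)
    .fx$recovery <- list(study = study, features = feats)
  }
  .fx$recovery
}

# Tiny end-to-end study for pipeline / IO tests.
tiny_study_fixture <- function() {
  if (is.null(.fx$tiny)) {
    cfg <- study_config(n_subjects = 4, n_mci = 2, n_sessions = 1,
                        sampling_rate_hz = 100, effect_size = 1,
                        artifact_rate_per_min = 0, master_seed = 42)
    .fx$tiny <- generate_study(cfg)
  }
  .fx$tiny
}

# Engine-vs-oracle comparison over 200 random small clouds; computed once.
oracle_comparison_fixture <- function() {
  if (is.null(.fx$oracle)) {
    set.seed(42)
    mismatches <- 0L
    worst <- 0
    for (r in 1:200) {
      n <- sample(5:12, 1); d <- sample(2:8, 1)
      pts <- matrix(rnorm(n * d), n, d)
      a <- canon_diagram(rips_diagram(pts))
      b <- rips_oracle(pts)
      same_shape <- nrow(a) == nrow(b) &&
        all(a$dimension == b$dimension) &&
        identical(is.finite(a$death), is.finite(b$death))
      if (!same_shape) { mismatches <- mismatches + 1L; next }
      dev <- max(abs(a$birth - b$birth),
                 abs((a$death - b$death)[is.finite(a$death)]), 0)
      worst <- max(worst, dev)
      if (dev >= 1e-9) mismatches <- mismatches + 1L
    }
    .fx$oracle <- list(mismatches = mismatches, worst = worst)
  }
  .fx$oracle
}

# Synthetic feature table with optional group shift, for ML-layer tests that
# do not need real persistence values.
make_feature_table <- function(n_subjects, epochs_per_subject, n_mci,
                               effect = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    group <- if (i <= n_mci) "mci" else "healthy"
    shift <- if (group == "healthy") effect else 0
    n <- epochs_per_subject
    rows[[i]] <- data.frame(
      subject_id = sprintf("s%02d", i),
      group = group,
      moca = if (group == "healthy") 27L + (i %% 4) else 14L + (i %% 9),
      condition = rep(c("TGT", "IGN"), length.out = n),
      session = 1L,
      total_cycles = rnorm(n, 200 + 20 * shift, 15),
      max_cycles = rnorm(n, 60, 8),
      max_persistence = rnorm(n, 8 + 3 * shift, 1.5),
      npe = pmin(1, pmax(0, rnorm(n, 0.88, 0.03))),
      max_persistence_ratio = rnorm(n, 2.2 + 0.3 * shift, 0.3),
      median_persistence_ratio = rnorm(n, 1.08, 0.02),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
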