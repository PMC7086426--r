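# Shared fixtures, built once per test session and cached. The CNN-scale
# cohorts use a reduced acquisition (16 channels, 32 Hz, 16 s) so that
# subject-level bootstrap runs stay tractable; the class-effect settings are
# the study conditions (15+15 subjects, alpha attenuation / theta gain).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# training regime for the reduced-scale CNN runs
cnn_test_config <- function(seed = 1) {
  train_config(learning_rate = 0.02, momentum = 0.9, l2_regularization = 5e-4,
               mini_batch_size = 64, epochs = 25, seed = seed)
}

cnn_test_pipeline <- function(seed = 1) {
  cnn_pipeline(config = cnn_test_config(seed), discard_seconds = 2,
               max_segments = 14)
}

# 15 + 15 cohorts at the reduced CNN scale
null_cohort <- function() {
  fixture("null_cohort", function() {
    generate_cohort(cohort_spec(n_per_class = 15, n_channels = 16, fs = 32,
                                duration_s = 16, seed = 101))
  })
}

effect_cohort <- function() {
  fixture("effect_cohort", function() {
    generate_cohort(cohort_spec(n_per_class = 15, n_channels = 16, fs = 32,
                                duration_s = 16, alpha_attenuation = 0.4,
                                theta_gain = 1.5, seed = 102))
  })
}

# faster-sampled cohort for the feature-engineered baselines (their filter
# chains need the mains/100 Hz region to exist)
baseline_cohort <- function() {
  fixture("baseline_cohort", function() {
    generate_cohort(cohort_spec(n_per_class = 15, n_channels = 16, fs = 250,
                                duration_s = 12, alpha_attenuation = 0.4,
                                theta_gain = 1.5, seed = 103))
  })
}

# tiny cohort for unit tests that only need valid recordings
tiny_cohort <- function() {
  fixture("tiny_cohort", function() {
    generate_cohort(cohort_spec(n_per_class = 4, n_channels = 8, fs = 64,
                                duration_s = 6, alpha_attenuation = 0.4,
                                theta_gain = 1.5, seed = 104))
  })
}

# the 20-iteration null bootstrap of the CNN, shared between the calibration
# and effect-recovery checks
null_cnn_bootstrap <- function() {
  fixture("null_cnn_bootstrap", function() {
    run_bootstrap_cv(null_cohort()$recordings, cnn_test_pipeline(),
                     n_iterations = 20, base_seed = 7)
  })
}

# plain segments with arbitrary content for trainer unit tests
toy_segments <- function(n = 8, h = 11, w = 16, seed = 1,
                         labels = rep(c("healthy", "tbi"), length.out = n)) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    structure(list(matrix = matrix(stats::rnorm(h * w), h, w),
                   subject_id = sprintf("s%02d", i), index = 1L,
                   class_label = labels[i]),
              class = "eeg_segment")
  })
}
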