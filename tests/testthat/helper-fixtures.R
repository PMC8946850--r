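# Shared, lazily computed fixtures. The heavy cohort runs are reused by
# several tests (discrimination regime, resolution dependence, parameter
# recovery), so they are computed once per suite run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# One fully processed default subject.
fixture_subject <- function(seed = 1) {
  fixture(paste0("subject_", seed), function() {
    process_subject(generate_subject(subject_config(
      sprintf("S%02d", seed), seed = seed)))
  })
}

# Default synthetic cohort: 18 subjects, beta_effect = 1.5, seeds 1-18,
# Neurometric measure over the full decimation grid.
fixture_study <- function() {
  fixture("study", function() {
    run_study(n_subjects = 18, seed = 1, beta_effect = 1.5,
              measures = "neurometric")
  })
}

# Null cohort: 20 subjects with no stress effect in either modality,
# all four measures.
fixture_null_study <- function() {
  fixture("null_study", function() {
    run_study(n_subjects = 20, seed = 1, beta_effect = 0,
              measures = c("neurometric", "scl", "rf_intra", "rf_cross"),
              rf_budget = 6,
              config_args = list(scl_stress_shift = 0))
  })
}

# Small labeled feature set with a controllable class imbalance, drawn from
# two bivariate normal clouds.
make_lfs <- function(n0, n1, shift = 1, seed = 42, sd = 1) {
  set.seed(seed)
  x <- rbind(matrix(abs(stats::rnorm(n0 * 2, 5, sd)), n0, 2),
             matrix(abs(stats::rnorm(n1 * 2, 5 + shift, sd)), n1, 2))
  colnames(x) <- c("P3", "P4")
  structure(list(features = x,
                 labels = c(rep(0L, n0), rep(1L, n1)),
                 groups = rep(1L, n0 + n1),
                 synthetic = rep(FALSE, n0 + n1),
                 subject_id = "toy"),
            class = "labeled_feature_set")
}

# Plain performance record for formula tests.
make_record <- function(right_add = 10, max_add = 10,
                        rts = rep(0, 4),
                        bar2fill = 0, rt_vis = 0, time2fill = 5,
                        right_phone = 10, max_phone = 10, level = 1) {
  structure(list(num_right_additions = right_add,
                 max_num_additions = max_add,
                 auditory_reaction_times = rts,
                 visual_events = data.frame(bar2fill = bar2fill,
                                            reaction_time = rt_vis,
                                            time2fill = time2fill),
                 num_right_entries = right_phone,
                 max_num_entries = max_phone,
                 level = level),
            class = "performance_record")
}

# Sinusoidal EEG block on all 8 channels.
tone_block <- function(freq, seconds = 10, amp = 1, fs = 250, noise_sd = 0) {
  t <- seq_len(seconds * fs) / fs
  x <- amp * sin(2 * pi * freq * t)
  m <- matrix(rep(x, each = 8), nrow = 8,
              dimnames = list(EEG_CHANNELS, NULL))
  if (noise_sd > 0) m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), 8)
  eeg_block(m)
}
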