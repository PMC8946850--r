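test_that("band-pass filter preserves the passband and kills stopband tones", {
  tone10 <- bandpass_filter(tone_block(10))
  # compare RMS in the central region (away from filter edge transients)
  mid <- 500:2000
  ratio10 <- stats::sd(tone10$samples[1, mid]) / (1 / sqrt(2))
  expect_lt(abs(ratio10 - 1), 0.05)

  # oracle: squared magnitude response of the designed filter at 50 Hz
  # (zero-phase application squares the single-pass response)
  bf <- signal::butter(5, c(2, 30) / 125, type = "pass")
  z <- exp(-1i * 2 * pi * 50 / 250)
  h50 <- Mod(sum(bf$b * z^(seq_along(bf$b) - 1)) /
             sum(bf$a * z^(seq_along(bf$a) - 1)))^2
  tone50 <- bandpass_filter(tone_block(50))
  ratio50 <- stats::sd(tone50$samples[1, mid]) / (1 / sqrt(2))
  expect_lt(ratio50, 0.1)                       # >= 90% amplitude reduction
  expect_equal(ratio50, h50, tolerance = 0.2)

  z <- eeg_block(matrix(0, 8, 2500))
  expect_equal(bandpass_filter(z)$samples, matrix(0, 8, 2500),
               ignore_attr = TRUE)

  expect_error(bandpass_filter(tone_block(10), hi = 130), "Nyquist")
})

test_that("blink correction only touches detected intervals and shrinks the artifact", {
  clean <- tone_block(10, seconds = 10, amp = 3, noise_sd = 2)
  out <- remove_blinks(clean)
  expect_equal(out$samples, clean$samples)

  # inject template blinks: frontal x1, parietal x0.2
  fs <- 250
  x <- clean$samples
  tmpl <- 120 * sin(pi * seq(0, 1, length.out = 100))^2
  gain <- ifelse(EEG_CHANNELS %in% c("Pz", "P3", "P4"), 0.2, 1)
  at <- c(2, 5, 8) * fs
  for (i0 in at) x[, i0:(i0 + 99)] <- x[, i0:(i0 + 99)] + outer(gain, tmpl)
  blk <- eeg_block(x)
  corr <- remove_blinks(blk)
  iv <- attr(corr, "blink_intervals")
  expect_gte(nrow(iv), 3)

  cov_in <- function(m) {
    vals <- vapply(at, function(i0) {
      w <- i0:(i0 + 99)
      stats::cov(colMeans(m[1:5, w]), colMeans(m[6:8, w]))
    }, numeric(1))
    mean(abs(vals))
  }
  expect_lt(cov_in(corr$samples), 0.5 * cov_in(blk$samples))

  # sub-threshold blink: nothing detected, identity
  x2 <- clean$samples
  x2[, 500:599] <- x2[, 500:599] + outer(gain, 0.1 * tmpl)
  small <- eeg_block(x2)
  expect_equal(remove_blinks(small)$samples, small$samples)
})

test_that("epoching truncates partial seconds and rejects short blocks", {
  mk <- function(sec) eeg_block(matrix(rnorm(8 * round(sec * 250)), 8))
  expect_equal(dim(epoch_signal(mk(60))$epochs)[3], 60)
  expect_equal(dim(epoch_signal(mk(60.9))$epochs)[3], 60)
  expect_error(epoch_signal(mk(0.5)), "shorter")
})

test_that("artifact rejection flags strictly above-threshold epochs only", {
  x <- matrix(0, 8, 750)
  x[1, 100] <- 80          # boundary: kept
  x[3, 400] <- -85         # flagged
  ep <- reject_artifacts(epoch_signal(eeg_block(x)))
  expect_equal(ep$artifact_flags, c(FALSE, TRUE, FALSE))
  expect_equal(unname(ep$epochs[3, 150, 2]), -85)   # samples untouched

  z <- reject_artifacts(epoch_signal(eeg_block(matrix(0, 8, 2500))))
  expect_false(any(z$artifact_flags))
})

test_that("IAF estimation recovers the alpha peak and falls back on flat spectra", {
  for (seed in c(1, 4, 9)) {
    cfg <- subject_config(seed = seed, iaf_true = 10.5)
    rest <- generate_subject(cfg)[[1]]$eeg
    est <- estimate_iaf(bandpass_filter(rest))
    expect_false(est$fallback_used)
    expect_lte(abs(est$iaf - 10.5), 0.5)
  }

  set.seed(1)
  wn <- eeg_block(matrix(rnorm(8 * 250 * 60), 8))
  est <- estimate_iaf(wn)
  expect_true(est$fallback_used)
  expect_equal(est$iaf, 10)

  tone <- tone_block(11, seconds = 60, amp = 5, noise_sd = 0.5)
  est11 <- estimate_iaf(tone)
  expect_false(est11$fallback_used)
  expect_lte(abs(est11$iaf - 11), 0.5)

  no_par <- eeg_block(matrix(rnorm(5 * 250 * 60), 5),
                      channel_names = c("AFz", "AF3", "AF4", "AF7", "AF8"))
  expect_error(estimate_iaf(no_par), "parietal")
  expect_error(estimate_iaf(eeg_block(matrix(rnorm(8 * 250 * 10), 8))), "30 s")
})

test_that("the high-beta band is anchored 11-16 Hz above the alpha peak", {
  b <- beta_high_band(10)
  expect_equal(c(b$lo, b$hi), c(21, 26))
  expect_equal(unlist(beta_high_band(9.5)[c("lo", "hi")]),
               c(lo = 20.5, hi = 25.5))
  expect_equal(unlist(beta_high_band(11)[c("lo", "hi")]), c(lo = 22, hi = 27))
})

test_that("band power concentrates in the right bins and ignores DC offsets", {
  ep23 <- epoch_signal(tone_block(23, seconds = 5))
  bp <- band_power(ep23, band_definition("beta_high", 21, 26))
  tot <- band_power(ep23, band_definition("broad", 1, 40))
  expect_true(all(bp$values >= 0.95 * tot$values))
  # time-domain variance oracle: unit sinusoid has power 1/2
  expect_lt(max(abs(bp$values - 0.5)), 0.05)

  ep10 <- epoch_signal(tone_block(10, seconds = 5))
  bp10 <- band_power(ep10, band_definition("beta_high", 21, 26))
  tot10 <- band_power(ep10, band_definition("broad", 1, 40))
  expect_true(all(bp10$values <= 0.05 * tot10$values))

  z <- band_power(epoch_signal(eeg_block(matrix(0, 8, 500))),
                  band_definition("beta_high", 21, 26))
  expect_true(all(z$values == 0))

  # shift invariance within the analysis band
  set.seed(2)
  x <- matrix(rnorm(8 * 500), 8)
  b1 <- band_power(epoch_signal(eeg_block(x)), band_definition("b", 2, 30))
  b2 <- band_power(epoch_signal(eeg_block(x + 50)), band_definition("b", 2, 30))
  expect_lt(max(abs(b2$values - b1$values) / b1$values), 0.01)

  expect_error(band_power(ep23, band_definition("b", 2, 30), channels = character(0)))
})

test_that("the Neurometric is the P3/P4 mean and orders stress conditions", {
  fs <- structure(list(
    values = cbind(AFz = c(9, 9), P3 = c(2, 5), P4 = c(4, 5)),
    channel_names = c("AFz", "P3", "P4"),
    band = band_definition("beta_high", 21, 26),
    epoch_times = c(0, 1), condition = c("low", "high")),
    class = "feature_series")
  nm <- neurometric(fs)
  expect_equal(nm$value, c(3, 5))
  expect_equal(nm$label, c(0L, 1L))

  # invariant to non-parietal channel ordering
  fs2 <- fs
  fs2$values <- fs$values[, c("P4", "AFz", "P3")]
  fs2$channel_names <- c("P4", "AFz", "P3")
  expect_equal(neurometric(fs2)$value, nm$value)

  fs3 <- fs; fs3$values <- fs$values[, c("AFz", "P3"), drop = FALSE]
  fs3$channel_names <- c("AFz", "P3")
  expect_error(neurometric(fs3), "P3 and P4")

  # generator contract: mean Neurometric larger under high stress
  diffs <- vapply(c(1, 6, 12), function(seed) {
    proc <- fixture_subject(seed)
    e <- proc$epochs[grepl("^multitask", proc$epochs$task), ]
    mean(e$neurometric[e$condition == "high"]) -
      mean(e$neurometric[e$condition == "low"])
  }, numeric(1))
  expect_true(all(diffs > 0))
})
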