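#' Band-pass filter an EEG block
#'
#' Fifth-order Butterworth band-pass, zero-phase by default (forward-backward
#' application); set `causal = TRUE` for a single causal pass as in a
#' real-time setting.
#'
#' @param block an `eeg_block`.
#' @param lo,hi band edges in Hz (defaults 2 and 30).
#' @param order filter order (default 5).
#' @param causal logical; if `TRUE` apply the filter once, causally.
#' @return filtered `eeg_block` of identical shape.
#' @export
bandpass_filter <- function(block, lo = 2, hi = 30, order = 5, causal = FALSE) {
  stopifnot(inherits(block, "eeg_block"))
  fs <- block$sampling_rate
  if (hi >= fs / 2) stop("upper edge must be below the Nyquist frequency")
  if (lo <= 0 || lo >= hi) stop("band edges must satisfy 0 < lo < hi")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  x <- block$samples
  out <- t(apply(x, 1, function(ch) {
    if (causal) as.numeric(signal::filter(bf, ch - mean(ch)))
    else filtfilt_safe(bf, ch)
  }))
  dimnames(out) <- dimnames(x)
  res <- eeg_block(out, fs, block$channel_names, block$start_time)
  attr(res, "truth") <- attr(block, "truth")
  res
}

#' Detect and correct blink artifacts
#'
#' Simplified blink stage: blinks are detected on the smoothed mean of the
#' frontal channels by an amplitude threshold; inside each detected interval
#' the frontal-derived blink component is regressed out of every channel.
#' The signal outside detected intervals is returned unchanged.
#'
#' @param block an `eeg_block` containing frontal channels.
#' @param threshold detection threshold in microvolts on the smoothed
#'   frontal mean (default 40).
#' @param pad_seconds padding added around each detected interval.
#' @return corrected `eeg_block`; attribute `"blink_intervals"` holds the
#'   detected (start, end) sample indices.
#' @export
remove_blinks <- function(block, threshold = 40, pad_seconds = 0.15) {
  stopifnot(inherits(block, "eeg_block"))
  fr <- intersect(FRONTAL_CHANNELS, block$channel_names)
  if (length(fr) == 0) stop("no frontal channels present")
  fs <- block$sampling_rate
  x <- block$samples
  f <- colMeans(x[fr, , drop = FALSE])
  k <- max(3L, round(0.1 * fs))
  fsm <- as.numeric(stats::filter(f, rep(1 / k, k), sides = 2))
  fsm[is.na(fsm)] <- 0

  mask <- abs(fsm) > threshold
  if (!any(mask)) {
    attr(block, "blink_intervals") <- cbind(start = integer(0), end = integer(0))
    return(block)
  }
  pad <- round(pad_seconds * fs)
  idx <- which(mask)
  ext <- unique(unlist(lapply(idx, function(i)
    max(1L, i - pad):min(ncol(x), i + pad))))
  mask2 <- logical(ncol(x)); mask2[ext] <- TRUE
  runs <- mask_runs(mask2)

  out <- x
  for (r in seq_len(nrow(runs))) {
    sel <- runs[r, 1]:runs[r, 2]
    b <- fsm[sel]
    vb <- stats::var(b)
    if (!is.finite(vb) || vb <= 0) next
    for (ch in seq_len(nrow(out))) {
      beta <- stats::cov(out[ch, sel], b) / vb
      out[ch, sel] <- out[ch, sel] - beta * b
    }
  }
  res <- eeg_block(out, fs, block$channel_names, block$start_time)
  attr(res, "truth") <- attr(block, "truth")
  attr(res, "blink_intervals") <- runs
  res
}

#' Segment an EEG block into fixed-length epochs
#'
#' Consecutive, non-overlapping epochs; a trailing partial epoch is
#' discarded.
#'
#' @param block an `eeg_block`.
#' @param length epoch length in seconds (default 1).
#' @param condition optional condition label attached to every epoch.
#' @return an object of class `epoch_set`: a list with the epoch array
#'   (channels x samples x epochs), epoch start times, artifact flags
#'   (all `FALSE` initially) and per-epoch condition labels.
#' @export
epoch_signal <- function(block, length = 1, condition = NA_character_) {
  stopifnot(inherits(block, "eeg_block"))
  fs <- block$sampling_rate
  npe <- round(fs * length)
  n <- ncol(block$samples)
  if (n < npe) stop("block shorter than one epoch")
  n_ep <- floor(n / npe)
  arr <- array(block$samples[, seq_len(n_ep * npe), drop = FALSE],
               dim = c(nrow(block$samples), npe, n_ep),
               dimnames = list(block$channel_names, NULL, NULL))
  structure(list(epochs = arr,
                 epoch_times = block$start_time + (seq_len(n_ep) - 1) * length,
                 artifact_flags = rep(FALSE, n_ep),
                 source_condition = rep(condition, n_ep),
                 sampling_rate = fs),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d ch, %d flagged\n",
              dim(x$epochs)[3], dim(x$epochs)[1], sum(x$artifact_flags)))
  invisible(x)
}

#' Flag epochs exceeding an amplitude threshold
#'
#' An epoch is marked artifactual when the absolute amplitude on any channel
#' strictly exceeds `threshold`; samples are never altered, and flagged
#' epochs are excluded from all downstream feature computation.
#'
#' @param epochs an `epoch_set`.
#' @param threshold amplitude ceiling in microvolts (default 80).
#' @return the `epoch_set` with updated `artifact_flags`.
#' @export
reject_artifacts <- function(epochs, threshold = 80) {
  stopifnot(inherits(epochs, "epoch_set"))
  mx <- apply(abs(epochs$epochs), 3, max)
  epochs$artifact_flags <- mx > threshold
  epochs
}

#' Estimate the Individual Alpha Frequency from eyes-closed rest EEG
#'
#' Welch-averaged spectrum (2 s Hann segments, 50% overlap) of the mean
#' parietal signal; the IAF is the most prominent local spectral maximum in
#' the 7-13 Hz search band. If no peak has prominence above
#' `prominence_factor` times the median band density, the estimate falls
#' back to 10 Hz with `fallback_used = TRUE`.
#'
#' @param rest an `eeg_block` of at least 30 s containing Pz, P3, P4.
#' @param search_band numeric length-2, the search interval in Hz.
#' @param prominence_factor prominence floor as a fraction of the median
#'   spectral density inside the search band.
#' @return object of class `iaf_estimate` with fields `iaf`, `search_band`,
#'   `fallback_used`, `peak_prominence`.
#' @export
estimate_iaf <- function(rest, search_band = c(7, 13), prominence_factor = 0.5) {
  stopifnot(inherits(rest, "eeg_block"))
  par <- intersect(PARIETAL_CHANNELS, rest$channel_names)
  if (length(par) < length(PARIETAL_CHANNELS))
    stop("parietal channels Pz, P3, P4 are required")
  fs <- rest$sampling_rate
  if (ncol(rest$samples) < 30 * fs) stop("rest block must last at least 30 s")
  x <- colMeans(rest$samples[par, , drop = FALSE])
  sp <- welch_psd(x, fs, seg_seconds = 2, overlap = 0.5)
  inb <- sp$freq >= search_band[1] & sp$freq <= search_band[2]
  f <- sp$freq[inb]; p <- sp$power[inb]
  floor_p <- prominence_factor * stats::median(p)

  best <- NULL
  m <- length(p)
  for (i in seq_len(m)) {
    left <- if (i > 1) p[i - 1] else -Inf
    right <- if (i < m) p[i + 1] else -Inf
    if (p[i] > left && p[i] > right) {
      lmin <- if (i > 1) min(p[1:(i - 1)]) else p[i]
      rmin <- if (i < m) min(p[(i + 1):m]) else p[i]
      prom <- p[i] - max(lmin, rmin)
      if (prom >= floor_p && (is.null(best) || prom > best$prom))
        best <- list(f = f[i], prom = prom)
    }
  }
  if (is.null(best)) {
    est <- list(iaf = 10, search_band = search_band, fallback_used = TRUE,
                peak_prominence = 0)
  } else {
    est <- list(iaf = best$f, search_band = search_band, fallback_used = FALSE,
                peak_prominence = best$prom)
  }
  structure(est, class = "iaf_estimate")
}

#' @export
print.iaf_estimate <- function(x, ...) {
  cat(sprintf("<iaf_estimate> %.2f Hz%s\n", x$iaf,
              if (x$fallback_used) " (fallback)" else ""))
  invisible(x)
}

#' Subject-specific high-beta band
#'
#' Anchors the high-beta band to the individual alpha peak:
#' `(IAF + 11)` to `(IAF + 16)` Hz, i.e. 21-26 Hz for a 10 Hz alpha.
#'
#' @param iaf an `iaf_estimate` or a plain frequency in Hz.
#' @return object of class `band_definition` with fields `name`, `lo`, `hi`.
#' @export
#' @examples
#' beta_high_band(10)   # 21-26 Hz
beta_high_band <- function(iaf) {
  f <- if (inherits(iaf, "iaf_estimate")) iaf$iaf else iaf
  band_definition("beta_high", f + 11, f + 16)
}

#' @rdname beta_high_band
#' @param name band label.
#' @param lo,hi band edges in Hz.
#' @export
band_definition <- function(name, lo, hi) {
  if (!(lo > 0 && lo < hi && hi <= 40))
    stop("band edges must satisfy 0 < lo < hi <= 40")
  structure(list(name = name, lo = lo, hi = hi), class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band %s> %.1f-%.1f Hz\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' Per-epoch, per-channel band power
#'
#' Hann-windowed periodogram of each unflagged 1 s epoch (1 Hz bin width at
#' 250 Hz); power is summed over the frequency bins whose centers fall in
#' the closed interval `[lo, hi]`.
#'
#' @param epochs an `epoch_set` (flagged epochs are excluded).
#' @param band a `band_definition`.
#' @param channels channel names to include (default: all).
#' @return object of class `feature_series`: a list with the epochs x
#'   channels power matrix `values` (in uV^2), `channel_names`, `band`,
#'   `epoch_times` and `condition` for the retained epochs.
#' @export
band_power <- function(epochs, band, channels = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(band, "band_definition"))
  chs <- channels %||% dimnames(epochs$epochs)[[1]]
  if (length(chs) == 0) stop("empty channel list")
  if (!all(chs %in% dimnames(epochs$epochs)[[1]]))
    stop("requested channels not present")
  keep <- which(!epochs$artifact_flags)
  npe <- dim(epochs$epochs)[2]
  fs <- epochs$sampling_rate

  vals <- matrix(0, length(keep), length(chs),
                 dimnames = list(NULL, chs))
  if (length(keep) > 0) {
    # one FFT call per channel over all retained epochs
    for (j in seq_along(chs)) {
      m <- matrix(epochs$epochs[chs[j], , keep], nrow = npe)
      pg <- periodogram_cols(m, fs)
      inb <- pg$freq >= band$lo - 1e-9 & pg$freq <= band$hi + 1e-9
      vals[, j] <- colSums(pg$power[inb, , drop = FALSE])
    }
  }
  structure(list(values = vals, channel_names = chs, band = band,
                 epoch_times = epochs$epoch_times[keep],
                 condition = epochs$source_condition[keep]),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series %s> %d epochs x %d ch\n", x$band$name,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' The stress Neurometric: parietal high-beta band power
#'
#' One scalar per retained epoch: the arithmetic mean of the P3 and P4
#' high-beta band-power values. This is the calibration-free stress index;
#' larger values indicate higher stress.
#'
#' @param features a `feature_series` containing P3 and P4.
#' @return a [score_series()] with measure `"neurometric"`.
#' @export
neurometric <- function(features) {
  stopifnot(inherits(features, "feature_series"))
  if (!all(c("P3", "P4") %in% features$channel_names))
    stop("feature series must contain P3 and P4")
  v <- rowMeans(features$values[, c("P3", "P4"), drop = FALSE])
  score_series(values = v, epoch_times = features$epoch_times,
               labels = condition_to_label(features$condition),
               blocks = rep(1L, length(v)), measure = "neurometric")
}

condition_to_label <- function(cond) {
  ifelse(cond == "high", 1L, ifelse(cond == "low", 0L, NA_integer_))
}
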