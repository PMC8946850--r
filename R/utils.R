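# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a bounded child seed from a base seed and a stream index.
# Kept below 2^31 so set.seed() always accepts it.
child_seed <- function(seed, idx) {
  (abs(as.integer(seed)) %% 100000L) * 10000L + as.integer(idx)
}

# Periodic Hann window: its DFT has support only on bins 0 and +/-1, so a
# constant offset cannot leak past the first frequency bin.
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
}

# Zero-phase filtering with reflection padding and mean removal, avoiding
# the edge transients of plain filtfilt on signals with a large offset.
# keep_mean re-adds the mean (low-pass use); band-pass callers drop it.
filtfilt_safe <- function(filt, x, keep_mean = FALSE) {
  n <- length(x)
  mu <- mean(x)
  xc <- x - mu
  np <- min(n - 1, 500L)
  padded <- c(2 * xc[1] - xc[(np + 1):2], xc, 2 * xc[n] - xc[(n - 1):(n - np)])
  y <- as.numeric(signal::filtfilt(filt, padded))[(np + 1):(np + n)]
  if (keep_mean) y + mu else y
}

# One-sided periodogram of the columns of `x` (samples x series), Hann
# windowed, in power-density-like units so that the sum over bins of a
# zero-mean series approximates its variance.
periodogram_cols <- function(x, fs, window = TRUE) {
  n <- nrow(x)
  w <- if (window) hann_window(n) else rep(1, n)
  xw <- x * w
  X <- stats::mvfft(xw)
  nh <- floor(n / 2)
  p <- (Mod(X[seq_len(nh + 1), , drop = FALSE])^2) / (n * sum(w^2))
  # one-sided: double all bins except DC (and Nyquist when n is even)
  dbl <- rep(2, nh + 1)
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[nh + 1] <- 1
  p <- p * dbl
  list(freq = seq(0, nh) * fs / n, power = p)
}

# Welch averaged spectrum of a single series.
welch_psd <- function(x, fs, seg_seconds = 2, overlap = 0.5) {
  ns <- round(seg_seconds * fs)
  if (length(x) < ns) stop("signal shorter than one Welch segment")
  step <- max(1L, round(ns * (1 - overlap)))
  starts <- seq(1L, length(x) - ns + 1L, by = step)
  segs <- vapply(starts, function(s) x[s:(s + ns - 1L)], numeric(ns))
  segs <- sweep(segs, 2, colMeans(segs))     # de-mean each segment
  pg <- periodogram_cols(segs, fs)
  list(freq = pg$freq, power = rowMeans(pg$power))
}

# 1/f ("pink") noise via spectral shaping, unit-sd, length n.
pink_noise <- function(n) {
  X <- stats::fft(stats::rnorm(n))
  k <- c(1, pmin(seq_len(n - 1), n - seq_len(n - 1)))  # symmetric bin index
  sc <- 1 / sqrt(k)
  sc[1] <- 0                                           # no DC
  x <- Re(stats::fft(X * sc, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Trailing moving average with expanding warm-up (never looks back more
# than `w` samples, never across the start of the vector).
trailing_mean <- function(x, w) {
  n <- length(x)
  if (w <= 1 || n == 0) return(x)
  cs <- c(0, cumsum(x))
  idx <- seq_len(n)
  lo <- pmax(idx - w, 0L)
  (cs[idx + 1L] - cs[lo + 1L]) / (idx - lo)
}

# Convert a logical mask into a two-column matrix of run (start, end) indices.
mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
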