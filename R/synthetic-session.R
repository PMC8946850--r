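#' EEG channel montage used throughout the package
#'
#' Frontal sites (AFz, AF3, AF4, AF7, AF8) carry the blink activity; the
#' parietal sites (Pz, P3, P4) carry the alpha rhythm at rest and the
#' stress-sensitive high-beta activity.
#' @export
EEG_CHANNELS <- c("AFz", "AF3", "AF4", "AF7", "AF8", "Pz", "P3", "P4")

FRONTAL_CHANNELS  <- c("AFz", "AF3", "AF4", "AF7", "AF8")
PARIETAL_CHANNELS <- c("Pz", "P3", "P4")

EEG_FS <- 250
EDA_FS <- 64

#' Configuration of one synthetic subject
#'
#' Bundles everything the generator needs to produce a complete, fully
#' reproducible recording day for one subject: an eyes-closed rest block,
#' two repetitions of the seven-level multitasking battery, and driving
#' runs (2 scenarios x low/high stress x 2 repetitions).
#'
#' @param subject_id character label.
#' @param seed integer; fixes every random draw for this subject.
#' @param iaf_true true individual alpha frequency in Hz. Default `NULL`
#'   draws it uniformly in 9-11 Hz (deterministically from `seed`).
#' @param beta_effect standardized difference (in within-condition SDs) of
#'   parietal high-beta log band power between high- and low-stress blocks.
#' @param scl_baseline tonic skin conductance level in microsiemens.
#' @param scl_stress_shift tonic increase in microsiemens under high stress.
#' @param blink_rate blink events per minute (frontal-dominant transients).
#' @param spike_rate EEG amplitude artifacts per minute exceeding 80 uV.
#' @param eda_spike_rate fast motion spikes per minute on the EDA trace.
#' @param collision_rate_low,collision_rate_high expected collisions per
#'   driving run in the low/high stress condition.
#' @param n_multitask_reps repetitions of the 7-level battery (>= 2 so the
#'   intra-subject protocol has train/test splits).
#' @param n_driving_reps driving repetitions per scenario and condition.
#' @param run_seconds duration of each task block in seconds.
#' @return an object of class `subject_config`.
#' @export
subject_config <- function(subject_id = "S01",
                           seed = 1L,
                           iaf_true = NULL,
                           beta_effect = 1.5,
                           scl_baseline = 5,
                           scl_stress_shift = 1,
                           blink_rate = 8,
                           spike_rate = 2,
                           eda_spike_rate = 1,
                           collision_rate_low = 1,
                           collision_rate_high = 4,
                           n_multitask_reps = 2L,
                           n_driving_reps = 2L,
                           run_seconds = 60) {
  if (is.null(iaf_true)) {
    iaf_true <- with_seed(child_seed(seed, 9999L), stats::runif(1, 9, 11))
  }
  cfg <- structure(list(
    subject_id = as.character(subject_id),
    seed = as.integer(seed),
    iaf_true = iaf_true,
    beta_effect = beta_effect,
    scl_baseline = scl_baseline,
    scl_stress_shift = scl_stress_shift,
    blink_rate = blink_rate,
    spike_rate = spike_rate,
    eda_spike_rate = eda_spike_rate,
    collision_rate_low = collision_rate_low,
    collision_rate_high = collision_rate_high,
    n_multitask_reps = as.integer(n_multitask_reps),
    n_driving_reps = as.integer(n_driving_reps),
    run_seconds = run_seconds
  ), class = "subject_config")
  validate_subject_config(cfg)
  cfg
}

validate_subject_config <- function(cfg) {
  stopifnot(inherits(cfg, "subject_config"))
  if (cfg$iaf_true < 7 || cfg$iaf_true > 13)
    stop("iaf_true must lie in [7, 13] Hz")
  if (cfg$beta_effect < 0) stop("beta_effect must be >= 0")
  rates <- c(cfg$blink_rate, cfg$spike_rate, cfg$eda_spike_rate,
             cfg$collision_rate_low, cfg$collision_rate_high)
  if (any(rates < 0)) stop("all event rates must be >= 0")
  if (cfg$run_seconds <= 0) stop("run_seconds must be positive")
  if (cfg$n_multitask_reps < 1 || cfg$n_driving_reps < 1)
    stop("repetition counts must be positive")
  invisible(cfg)
}

#' @export
print.subject_config <- function(x, ...) {
  cat(sprintf("<subject_config %s> seed=%d iaf=%.2f Hz beta_effect=%.2f\n",
              x$subject_id, x$seed, x$iaf_true, x$beta_effect))
  invisible(x)
}

#' EEG block container
#'
#' @param samples channels x time matrix in microvolts.
#' @param sampling_rate sampling frequency in Hz.
#' @param channel_names channel labels matching the rows of `samples`.
#' @param start_time block start time in seconds.
#' @return an object of class `eeg_block`.
#' @export
eeg_block <- function(samples, sampling_rate = EEG_FS,
                      channel_names = EEG_CHANNELS, start_time = 0) {
  stopifnot(is.matrix(samples), nrow(samples) == length(channel_names))
  if (any(!is.finite(samples))) stop("EEG samples must be finite")
  rownames(samples) <- channel_names
  structure(list(channel_names = channel_names,
                 sampling_rate = sampling_rate,
                 samples = samples,
                 start_time = start_time),
            class = "eeg_block")
}

#' @export
print.eeg_block <- function(x, ...) {
  cat(sprintf("<eeg_block> %d ch x %.1f s @ %g Hz\n",
              nrow(x$samples), ncol(x$samples) / x$sampling_rate,
              x$sampling_rate))
  invisible(x)
}

#' EDA trace container
#'
#' @param samples conductance series in microsiemens.
#' @param sampling_rate sampling frequency in Hz (64 for raw, 8 thereafter).
#' @param stage processing stage: `"raw"`, `"preprocessed"`, `"tonic"` or
#'   `"phasic"`.
#' @return an object of class `eda_trace`.
#' @export
eda_trace <- function(samples, sampling_rate, stage = "raw") {
  stage <- match.arg(stage, c("raw", "preprocessed", "tonic", "phasic"))
  if (stage == "raw" && sampling_rate != EDA_FS)
    stop("raw EDA must be sampled at 64 Hz")
  if (stage != "raw" && sampling_rate != 8)
    stop("processed EDA must be sampled at 8 Hz")
  structure(list(sampling_rate = sampling_rate,
                 samples = as.numeric(samples),
                 stage = stage),
            class = "eda_trace")
}

#' @export
print.eda_trace <- function(x, ...) {
  cat(sprintf("<eda_trace %s> %.1f s @ %g Hz\n", x$stage,
              length(x$samples) / x$sampling_rate, x$sampling_rate))
  invisible(x)
}

recording_session <- function(subject_id, task, condition, eeg, eda,
                              behavior = NULL, repetition_id = 1L,
                              scenario = NA_character_, level = NA_integer_) {
  structure(list(subject_id = subject_id, task = task, condition = condition,
                 eeg = eeg, eda = eda, behavior = behavior,
                 repetition_id = as.integer(repetition_id),
                 scenario = scenario, level = level),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session %s> task=%s cond=%s rep=%d\n",
              x$subject_id, x$task, x$condition, x$repetition_id))
  invisible(x)
}

# Stress drive in [0, 1] for a multitask level: levels 1-2 are the
# low-stress conditions, 6-7 the high-stress ones, 3-5 ramp in between.
level_stress <- function(level) c(0, 0, 0.25, 0.5, 0.75, 1, 1)[level]

level_condition <- function(level) {
  if (level <= 2) "low" else if (level >= 6) "high" else "middle"
}

# ---------------------------------------------------------------------------
# EEG synthesis

# Amplitude model (uV): pink broadband background, a parietal-dominant alpha
# rhythm at the subject's true IAF (strong at rest, attenuated during tasks),
# and a narrowband high-beta component centred at iaf_true + 13.5 Hz on
# P3/P4 whose per-epoch log-amplitude carries the stress effect. Since band
# power ~ amplitude^2 and the background contribution in the high-beta band
# is kept small, a log-amplitude shift of beta_effect * sigma_a / 2 per unit
# of stress drive realizes a standardized log-power difference close to
# beta_effect between the high and low conditions.
synth_eeg_block <- function(duration, cfg, stress, is_rest, seed) {
  with_seed(seed, {
    fs <- EEG_FS
    n <- round(duration * fs)
    t <- seq_len(n) / fs
    nch <- length(EEG_CHANNELS)
    x <- matrix(0, nch, n, dimnames = list(EEG_CHANNELS, NULL))

    noise_sd <- 7
    for (i in seq_len(nch)) x[i, ] <- noise_sd * pink_noise(n)

    # alpha rhythm with slow phase jitter and a positive amplitude envelope
    alpha_amp <- if (is_rest) 6 else 2
    phase <- cumsum(stats::rnorm(n, 0, 0.03))
    env <- 1 + 0.3 * sin(2 * pi * 0.05 * t + stats::runif(1, 0, 2 * pi))
    a <- alpha_amp * env * sin(2 * pi * cfg$iaf_true * t + phase)
    gain_a <- ifelse(EEG_CHANNELS %in% PARIETAL_CHANNELS, 1, 0.25)
    x <- x + outer(gain_a, a)

    # stress-sensitive narrowband high-beta on P3/P4, amplitude per 1 s epoch
    if (!is_rest) {
      f_beta <- cfg$iaf_true + 13.5
      sigma_a <- 0.4
      n_ep <- floor(duration)
      log_amp <- log(10) +
        cfg$beta_effect * sigma_a * (stress - 0.5) +
        sigma_a * stats::rnorm(n_ep)
      amp <- rep(exp(log_amp), each = fs)[seq_len(n)]
      bphase <- cumsum(stats::rnorm(n, 0, 0.02))
      b <- amp * sin(2 * pi * f_beta * t + bphase)
      for (ch in c("P3", "P4")) x[ch, ] <- x[ch, ] + b
    }

    # blinks: 400 ms positive deflection, frontal-dominant
    blink_times <- numeric(0)
    n_blink <- stats::rpois(1, cfg$blink_rate * duration / 60)
    if (n_blink > 0) {
      blink_times <- sort(stats::runif(n_blink, 0.5, duration - 0.5))
      tmpl <- sin(pi * seq(0, 1, length.out = round(0.4 * fs)))^2
      gain_b <- ifelse(EEG_CHANNELS %in% FRONTAL_CHANNELS, 1, 0.2)
      for (bt in blink_times) {
        i0 <- round(bt * fs)
        idx <- i0:(i0 + length(tmpl) - 1L)
        idx <- idx[idx >= 1 & idx <= n]
        amp_b <- stats::rnorm(1, 110, 15)
        x[, idx] <- x[, idx] + outer(gain_b, amp_b * tmpl[seq_along(idx)])
      }
    }

    # high-amplitude transients (> 80 uV) on single channels
    spike_times <- numeric(0)
    n_spk <- stats::rpois(1, cfg$spike_rate * duration / 60)
    if (n_spk > 0) {
      spike_times <- sort(stats::runif(n_spk, 0.1, duration - 0.1))
      tmpl <- c(seq(0, 1, length.out = 5), seq(1, -0.6, length.out = 5),
                seq(-0.6, 0, length.out = 4))
      for (st in spike_times) {
        ch <- sample.int(nch, 1)
        i0 <- round(st * fs)
        idx <- i0:(i0 + length(tmpl) - 1L)
        idx <- idx[idx >= 1 & idx <= n]
        x[ch, idx] <- x[ch, idx] + stats::runif(1, 100, 150) * tmpl[seq_along(idx)]
      }
    }

    blk <- eeg_block(x)
    attr(blk, "truth") <- list(iaf = cfg$iaf_true, stress = stress,
                               blink_times = blink_times,
                               spike_times = spike_times)
    blk
  })
}

# ---------------------------------------------------------------------------
# EDA synthesis

# Bateman-shaped skin conductance response kernel (rise 0.75 s, decay 2 s),
# peak-normalized.
bateman_kernel <- function(fs, tau_rise = 0.75, tau_decay = 2, support = 10) {
  t <- seq(0, support, by = 1 / fs)
  h <- exp(-t / tau_decay) - exp(-t / tau_rise)
  h / max(h)
}

synth_eda_trace <- function(duration, cfg, stress, seed) {
  with_seed(seed, {
    fs <- EDA_FS
    n <- round(duration * fs)
    t <- seq_len(n) / fs

    drift <- cumsum(stats::rnorm(n, 0, 0.015))
    drift <- stats::filter(drift, rep(1 / fs, fs), sides = 2)
    drift[is.na(drift)] <- 0
    tonic <- cfg$scl_baseline + cfg$scl_stress_shift * stress + as.numeric(drift)

    # phasic responses: more frequent under stress
    h <- bateman_kernel(fs)
    phasic <- numeric(n)
    n_ev <- stats::rpois(1, (2 + 4 * stress) * duration / 60)
    ev_times <- if (n_ev > 0) sort(stats::runif(n_ev, 0.5, duration - 3)) else numeric(0)
    ev_amps <- if (n_ev > 0) stats::runif(n_ev, 0.1, 0.5) else numeric(0)
    for (j in seq_along(ev_times)) {
      i0 <- round(ev_times[j] * fs)
      idx <- i0:min(i0 + length(h) - 1L, n)
      phasic[idx] <- phasic[idx] + ev_amps[j] * h[seq_along(idx)]
    }

    # fast motion spikes (square transients surviving the 8 Hz decimation)
    n_spk <- stats::rpois(1, cfg$eda_spike_rate * duration / 60)
    spikes <- numeric(n)
    spk_times <- if (n_spk > 0) sort(stats::runif(n_spk, 1, duration - 1)) else numeric(0)
    for (st in spk_times) {
      i0 <- round(st * fs)
      idx <- i0:min(i0 + round(0.25 * fs), n)
      spikes[idx] <- spikes[idx] + sample(c(-2, 2), 1)
    }

    x <- pmax(tonic + phasic + spikes + stats::rnorm(n, 0, 0.02), 0.05)
    tr <- eda_trace(x, fs, "raw")
    attr(tr, "truth") <- list(tonic = tonic, event_times = ev_times,
                              event_amps = ev_amps, spike_times = spk_times,
                              stress = stress)
    tr
  })
}

# ---------------------------------------------------------------------------
# Behavior synthesis

attempts_for <- function(level, cfg, repetition, what = c("add", "phone")) {
  what <- match.arg(what)
  off <- if (what == "add") 300L else 400L
  with_seed(child_seed(cfg$seed, off + 10L * repetition + level),
            8L + stats::rpois(1, 3))
}

#' Generate behavioral responses for one multitask level
#'
#' Draws counts and reaction times for the four subtasks (mental arithmetic,
#' auditory monitoring, visual monitoring, phone number entry) such that the
#' expected overall performance index decreases with the difficulty level.
#'
#' @param level multitask difficulty level, 1..7.
#' @param config a [subject_config()].
#' @param repetition repetition index of the battery.
#' @return an object of class `performance_record`.
#' @export
generate_behavior <- function(level, config, repetition = 1L) {
  if (!is.numeric(level) || length(level) != 1 || level < 1 || level > 7 ||
      level != round(level))
    stop("level must be an integer in 1..7")
  validate_subject_config(config)
  level <- as.integer(level)

  max_add <- max(vapply(1:7, attempts_for, 1L, cfg = config,
                        repetition = repetition, what = "add"))
  max_phone <- max(vapply(1:7, attempts_for, 1L, cfg = config,
                          repetition = repetition, what = "phone"))
  n_add <- attempts_for(level, config, repetition, "add")
  n_phone <- attempts_for(level, config, repetition, "phone")

  with_seed(child_seed(config$seed, 500L + 10L * repetition + level), {
    p_add <- max(0.3, 0.95 - 0.08 * (level - 1))
    right_add <- stats::rbinom(1, n_add, p_add)

    n_aud <- 12L
    wrong <- stats::runif(n_aud) < (0.05 + 0.07 * (level - 1))
    rt_aud <- pmin(pmax(stats::rnorm(n_aud, 0.8 + 0.25 * (level - 1), 0.3),
                        0.1), 4.9)
    rt_aud[wrong] <- 5            # wrong answers are scored as RT = 5 s

    n_vis <- 10L
    time2fill <- max(1.5, 8 - 0.8 * level)
    early <- stats::runif(n_vis) < 0.2
    bar2fill <- ifelse(early, stats::runif(n_vis, 0, 5 + 3 * level), 0)
    rt_vis <- ifelse(early, 0,
                     pmin(pmax(stats::rnorm(n_vis, 0.2 + 0.15 * level, 0.15), 0),
                          time2fill))
    visual <- data.frame(bar2fill = bar2fill, reaction_time = rt_vis,
                         time2fill = time2fill)

    p_phone <- max(0.4, 0.97 - 0.06 * (level - 1))
    right_phone <- stats::rbinom(1, n_phone, p_phone)

    structure(list(num_right_additions = right_add,
                   max_num_additions = max_add,
                   auditory_reaction_times = rt_aud,
                   visual_events = visual,
                   num_right_entries = right_phone,
                   max_num_entries = max_phone,
                   level = level),
              class = "performance_record")
  })
}

#' Generate a synthetic driving simulator event log
#'
#' Collision events arrive as a Poisson process whose rate is strictly
#' larger in the high-stress condition; non-collision checkpoint events are
#' interleaved so that log parsing has to filter by event type.
#'
#' @param condition `"low"` or `"high"`.
#' @param config a [subject_config()].
#' @param run_id identifier of the driving run.
#' @return an object of class `collision_log`: a data frame with columns
#'   `time`, `event_type`, `object`.
#' @export
generate_collisions <- function(condition, config, run_id = 1L) {
  condition <- match.arg(condition, c("low", "high"))
  validate_subject_config(config)
  rate <- if (condition == "high") config$collision_rate_high else config$collision_rate_low
  with_seed(child_seed(config$seed, 700L + 10L * run_id +
                         (condition == "high")), {
    dur <- config$run_seconds
    n <- stats::rpois(1, rate)
    times <- sort(stats::runif(n, 0, dur))
    objs <- if (n > 0)
      sample(c("car", "barrier", "curb", "pedestrian"), n, replace = TRUE)
    else character(0)
    ev <- data.frame(time = times, event_type = rep("collision", n),
                     object = objs, stringsAsFactors = FALSE)
    cp <- data.frame(time = seq(10, dur, by = 20), event_type = "checkpoint",
                     object = "waypoint", stringsAsFactors = FALSE)
    log <- rbind(ev, cp)
    log <- log[order(log$time), , drop = FALSE]
    rownames(log) <- NULL
    structure(log, class = c("collision_log", "data.frame"),
              run_id = run_id, condition = condition)
  })
}

#' Generate synthetic NASA-TLX subscale scores
#'
#' Six subscales on 0-100; demand/effort/frustration scales shift upward and
#' the performance scale downward under high stress.
#'
#' @param condition `"low"` or `"high"`.
#' @param config a [subject_config()].
#' @param repetition repetition index.
#' @return named numeric vector of the six subscale scores.
#' @export
generate_nasa_tlx <- function(condition, config, repetition = 1L) {
  condition <- match.arg(condition, c("low", "high"))
  validate_subject_config(config)
  with_seed(child_seed(config$seed, 800L + 10L * repetition +
                         (condition == "high")), {
    up <- if (condition == "high") 25 else 0
    base <- c(mental_demand = 35, physical_demand = 20, temporal_demand = 35,
              performance = 70, effort = 40, frustration = 25)
    shift <- c(up, up, up, -up, up, up)
    pmin(pmax(base + shift + stats::rnorm(6, 0, 8), 0), 100)
  })
}

# ---------------------------------------------------------------------------

#' Generate all recording sessions of one synthetic subject
#'
#' Produces one eyes-closed rest session (>= 60 s), `n_multitask_reps`
#' repetitions of the seven 60 s multitasking levels, and driving runs
#' (2 scenarios x low/high condition x `n_driving_reps` repetitions), each
#' with co-registered EEG (250 Hz, 8 channels), EDA (64 Hz) and behavior.
#' Output is byte-identical for identical configurations.
#'
#' @param config a [subject_config()].
#' @return list of `recording_session` objects.
#' @export
#' @examples
#' cfg <- subject_config("S01", seed = 7)
#' sessions <- generate_subject(cfg)
#' length(sessions)
generate_subject <- function(config) {
  validate_subject_config(config)
  cfg <- config
  sessions <- list()
  idx <- 0L
  nxt <- function() { idx <<- idx + 1L; idx }

  rest <- recording_session(
    cfg$subject_id, "rest", "rest",
    eeg = synth_eeg_block(60, cfg, stress = 0, is_rest = TRUE,
                          seed = child_seed(cfg$seed, nxt())),
    eda = synth_eda_trace(60, cfg, stress = 0,
                          seed = child_seed(cfg$seed, nxt())))
  sessions[[length(sessions) + 1L]] <- rest

  for (rep_i in seq_len(cfg$n_multitask_reps)) {
    for (level in 1:7) {
      st <- level_stress(level)
      sessions[[length(sessions) + 1L]] <- recording_session(
        cfg$subject_id, paste0("multitask_level_", level),
        level_condition(level),
        eeg = synth_eeg_block(cfg$run_seconds, cfg, st, FALSE,
                              seed = child_seed(cfg$seed, nxt())),
        eda = synth_eda_trace(cfg$run_seconds, cfg, st,
                              seed = child_seed(cfg$seed, nxt())),
        behavior = generate_behavior(level, cfg, rep_i),
        repetition_id = rep_i, level = level)
    }
  }

  run_id <- 0L
  for (rep_i in seq_len(cfg$n_driving_reps)) {
    for (scenario in c("circuit", "city")) {
      for (cond in c("low", "high")) {
        run_id <- run_id + 1L
        st <- if (cond == "high") 1 else 0
        sessions[[length(sessions) + 1L]] <- recording_session(
          cfg$subject_id, "driving_run", cond,
          eeg = synth_eeg_block(cfg$run_seconds, cfg, st, FALSE,
                                seed = child_seed(cfg$seed, nxt())),
          eda = synth_eda_trace(cfg$run_seconds, cfg, st,
                                seed = child_seed(cfg$seed, nxt())),
          behavior = generate_collisions(cond, cfg, run_id),
          repetition_id = rep_i, scenario = scenario)
      }
    }
  }
  sessions
}
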