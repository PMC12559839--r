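#' Generate 1/f ("pink") background noise
#'
#' Spectral synthesis: Gaussian white noise is shaped in the frequency domain
#' so that power falls off as 1/f^exponent. The DC component is removed, so
#' the series is zero-mean. With `exponent = 0` this is white noise.
#'
#' @param n_samples number of samples (>= 2).
#' @param exponent spectral slope alpha in `[0, 2]`.
#' @param sampling_rate sampling rate in Hz (sets the frequency axis only).
#' @param seed integer seed; the global RNG state is left untouched.
#' @param sd target standard deviation of the output series.
#' @return numeric vector of length `n_samples`, zero mean, SD `sd`.
#' @export
pink_noise <- function(n_samples, exponent, sampling_rate = 2000, seed = 1L,
                       sd = 1) {
  if (length(n_samples) != 1 || n_samples < 2) {
    stop("n_samples must be a single value >= 2", call. = FALSE)
  }
  stopifnot(exponent >= 0, exponent <= 2)
  n <- stats::nextn(as.integer(n_samples), c(2, 3)) # fast FFT length
  white <- withr::with_seed(as.integer(seed), stats::rnorm(n))
  x_f <- stats::fft(white)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * sampling_rate / n # two-sided frequency magnitude
  shape <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(stats::fft(x_f * shape, inverse = TRUE)) / n
  x <- x[seq_len(as.integer(n_samples))]
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * (sd / s)
  x
}

#' Inject an event-locked band-limited power modulation
#'
#' Adds (or removes) band-limited signal in a time window around each event
#' onset so that band power inside the window changes by `delta_db` decibels
#' relative to the unmodified series, leaving power outside the band and
#' window untouched. The added component is the series' own band-passed
#' content (sharp zero-phase FIR) scaled by `10^(delta_db/20) - 1` under a
#' raised-cosine on/off envelope (50 ms ramps by default); negative
#' `delta_db` therefore attenuates the band (desynchronization) rather than
#' adding independent noise, which could only increase power.
#'
#' @param series numeric voltage series.
#' @param sampling_rate sampling rate in Hz.
#' @param band `c(low, high)` Hz, within 1-50.
#' @param window_ms `c(start, end)` in ms relative to each onset.
#' @param delta_db target change in band power, dB.
#' @param onsets_s event onset times in seconds.
#' @param ramp_s raised-cosine ramp duration, seconds.
#' @return modified series, same length.
#' @export
inject_modulation <- function(series, sampling_rate, band, window_ms,
                              delta_db, onsets_s, ramp_s = 0.05) {
  stopifnot(band[1] >= 1, band[2] <= 50, band[1] < band[2])
  if (delta_db == 0 || length(onsets_s) == 0) return(series)
  bp <- fir_bandpass(series, sampling_rate, band[1], band[2])
  env <- modulation_envelope(length(series), sampling_rate, window_ms,
                             onsets_s, ramp_s)
  gain <- 10^(delta_db / 20) - 1
  series + gain * bp * env
}

modulation_envelope <- function(n, sampling_rate, window_ms, onsets_s,
                                ramp_s = 0.05) {
  starts <- onsets_s + window_ms[1] / 1000
  ends <- onsets_s + window_ms[2] / 1000
  if (any(starts < 0) || any(ends * sampling_rate > n)) {
    stop("modulation window extends beyond recording bounds", call. = FALSE)
  }
  env <- numeric(n)
  ramp_n <- max(1L, round(ramp_s * sampling_rate))
  up <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
  for (i in seq_along(onsets_s)) {
    i0 <- max(1L, round(starts[i] * sampling_rate) + 1L)
    i1 <- min(n, round(ends[i] * sampling_rate))
    len <- i1 - i0 + 1L
    if (len < 2L * ramp_n) next
    e <- rep(1, len)
    e[seq_len(ramp_n)] <- up
    e[len - ramp_n + seq_len(ramp_n)] <- rev(up)
    env[i0:i1] <- pmax(env[i0:i1], e)
  }
  env
}

new_recording_session <- function(data, labels, participant_id, hemisphere,
                                  sampling_rate_hz, lead_model) {
  stopifnot(is.matrix(data), ncol(data) == length(labels),
            !anyDuplicated(labels), hemisphere %in% c("left", "right"))
  structure(list(
    participant_id = participant_id,
    hemisphere = hemisphere,
    sampling_rate_hz = sampling_rate_hz,
    lead_model = lead_model,
    labels = labels,
    data = data
  ), class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf(
    "<recording_session> %s / %s: %d channels (%s), %.1f s at %g Hz\n",
    x$participant_id, x$hemisphere, ncol(x$data),
    paste(x$labels, collapse = ","), nrow(x$data) / x$sampling_rate_hz,
    x$sampling_rate_hz))
  invisible(x)
}

# trial schedule: tasks interleaved in blocks of 10 (as in the protocol),
# onset_{i+1} = offset_i + ITI
build_schedule <- function(config, lead_in_s = 4) {
  tasks <- config$tasks
  block <- 10L
  seq_tasks <- character(0)
  remaining <- stats::setNames(rep(config$trials_per_task, 3), tasks)
  while (any(remaining > 0)) {
    for (task in tasks) {
      k <- min(block, remaining[[task]])
      if (k > 0) {
        seq_tasks <- c(seq_tasks, rep(task, k))
        remaining[[task]] <- remaining[[task]] - k
      }
    }
  }
  n_trials <- length(seq_tasks)
  durations <- vapply(seq_tasks, function(task) {
    d <- config$trial_duration_s[[task]]
    rtruncnorm(1, d[["mean"]], d[["sd"]],
               lower = max(0.2, d[["mean"]] - 3 * d[["sd"]]),
               upper = d[["mean"]] + 3 * d[["sd"]])
  }, numeric(1))
  itis <- rtruncnorm(n_trials, config$iti_s$mean, config$iti_s$sd,
                     config$iti_s$min, config$iti_s$max)
  onsets <- numeric(n_trials)
  onsets[1] <- lead_in_s
  if (n_trials > 1) {
    for (i in 2:n_trials) {
      onsets[i] <- onsets[i - 1] + durations[i - 1] + itis[i - 1]
    }
  }
  data.frame(trial_id = seq_len(n_trials), task = seq_tasks,
             onset_s = onsets, offset_s = onsets + durations,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate one synthetic recording session
#'
#' One participant-hemisphere: a continuous multi-channel voltage recording
#' (4 contacts, or 8 for the segmented lead), per-trial annotations, and the
#' ground truth actually injected. Channels carry independent 1/f backgrounds;
#' injected modulations use identical gains and timing on every channel, so
#' segment averaging preserves the effect.
#'
#' @param config a [synth_config()].
#' @param participant_id identifier string.
#' @param hemisphere `"left"` or `"right"`.
#' @param seed integer seed for this session.
#' @param participant_offset_db participant-level dB offset added to every
#'   injected effect (drawn by [generate_cohort()]).
#' @return list with elements `session` (recording_session), `annotations`
#'   (data.frame: trial_id, task, onset_s, offset_s) and `ground_truth`
#'   (injected onsets and the per task x band x window dB actually applied).
#' @export
generate_session <- function(config, participant_id, hemisphere,
                             seed = config$seed, participant_offset_db = 0) {
  stopifnot(inherits(config, "synth_config"))
  ann <- withr::with_seed(derive_seed(seed, 1L), build_schedule(config))
  rate <- config$sampling_rate_hz
  total_s <- max(ann$offset_s) + 4 # tail for the +1000 ms epoch edge
  n <- ceiling(total_s * rate)

  labels <- if (config$lead_model == "four_contact") contact_labels else
    segmented_labels
  prefix <- if (hemisphere == "left") "L" else "R"
  labels <- paste0(prefix, labels)

  effects <- rbind(
    data.frame(band_name = "theta", low = config$theta_band[1],
               high = config$theta_band[2],
               win_lo = config$theta_window_ms[1],
               win_hi = config$theta_window_ms[2],
               task = config$tasks,
               delta_db = unname(config$theta_effect_db),
               stringsAsFactors = FALSE),
    data.frame(band_name = "beta", low = config$beta_band[1],
               high = config$beta_band[2],
               win_lo = config$beta_window_ms[1],
               win_hi = config$beta_window_ms[2],
               task = config$tasks,
               delta_db = unname(config$beta_effect_db),
               stringsAsFactors = FALSE)
  )
  effects$applied_db <- ifelse(effects$delta_db == 0, 0,
                               effects$delta_db + participant_offset_db)

  data <- matrix(0, n, length(labels))
  band_key <- paste(effects$low, effects$high)
  for (ch in seq_along(labels)) {
    x <- pink_noise(n, config$pink_exponent, rate,
                    seed = derive_seed(seed, 100L + ch),
                    sd = config$background_sd)
    # one band extraction per band; task windows within a band are disjoint
    for (bk in unique(band_key)) {
      sub <- effects[band_key == bk & effects$applied_db != 0, , drop = FALSE]
      if (nrow(sub) == 0) next
      bp <- fir_bandpass(x, rate, sub$low[1], sub$high[1])
      add <- numeric(n)
      for (j in seq_len(nrow(sub))) {
        onsets <- ann$onset_s[ann$task == sub$task[j]]
        env <- modulation_envelope(n, rate,
                                   c(sub$win_lo[j], sub$win_hi[j]), onsets)
        add <- add + (10^(sub$applied_db[j] / 20) - 1) * bp * env
      }
      x <- x + add
    }
    data[, ch] <- x
  }

  session <- new_recording_session(data, labels, participant_id, hemisphere,
                                   rate, config$lead_model)
  ground_truth <- list(
    participant_id = participant_id, hemisphere = hemisphere,
    onsets_s = ann$onset_s, tasks = ann$task,
    effects = effects[, c("band_name", "low", "high", "win_lo", "win_hi",
                          "task", "delta_db", "applied_db")],
    participant_offset_db = participant_offset_db
  )
  list(session = session, annotations = ann, ground_truth = ground_truth)
}

#' Generate a full synthetic cohort
#'
#' `n_participants` x 2 hemispheres sessions with per-participant seeds and
#' participant-level dB offsets derived deterministically from `config$seed`.
#'
#' @param config a [synth_config()].
#' @return object of class `synth_cohort`: list of per-session results (see
#'   [generate_session()]) plus the config; session names are
#'   `"<participant>_<hemisphere>"`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  offsets <- withr::with_seed(
    derive_seed(config$seed, 9L),
    stats::rnorm(config$n_participants, 0, config$participant_sd_db))
  sessions <- list()
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("P%02d", p)
    for (h in c("left", "right")) {
      s <- generate_session(
        config, pid, h,
        seed = derive_seed(config$seed, 10L * p + (h == "right")),
        participant_offset_db = offsets[p])
      sessions[[paste0(pid, "_", h)]] <- s
    }
  }
  structure(list(sessions = sessions, config = config,
                 participant_offsets_db = offsets),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d sessions (%d participants x 2 hemispheres)\n",
              length(x$sessions), x$config$n_participants))
  invisible(x)
}

#' Simulate a balanced band-power table directly
#'
#' Draws mean dB band power for every participant x hemisphere x contact x
#' task cell from task effect + participant offset + Gaussian noise. Used for
#' calibration and recovery studies of the mixed-effects stage at scale
#' without synthesising and decomposing voltage data.
#'
#' @param n_participants participants (2 hemispheres x 4 contacts each).
#' @param task_effect_db named numeric (vowel, ddk, sentence) cell means, dB.
#' @param participant_sd_db SD of the participant random offset.
#' @param noise_sd_db residual SD per cell.
#' @param band,window labels stamped on the rows.
#' @param seed integer seed.
#' @return a `band_power_table` data.frame (see [summarize_bandpower()]).
#' @export
simulate_bandpower_table <- function(n_participants = 13,
                                     task_effect_db = c(vowel = 1, ddk = 2.5,
                                                        sentence = 3),
                                     participant_sd_db = 0.5,
                                     noise_sd_db = 0.5,
                                     band = "theta", window = "during",
                                     seed = 1L) {
  grid <- expand.grid(
    participant = sprintf("P%02d", seq_len(n_participants)),
    hemisphere = c("left", "right"),
    contact = contact_labels,
    task = names(task_effect_db),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  withr::with_seed(as.integer(seed), {
    offs <- stats::setNames(stats::rnorm(n_participants, 0, participant_sd_db),
                            sprintf("P%02d", seq_len(n_participants)))
    grid$mean_power <- task_effect_db[grid$task] + offs[grid$participant] +
      stats::rnorm(nrow(grid), 0, noise_sd_db)
  })
  grid$band <- band
  grid$window <- window
  grid <- grid[, c("participant", "hemisphere", "contact", "task", "band",
                   "window", "mean_power")]
  class(grid) <- c("band_power_table", "data.frame")
  grid
}
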