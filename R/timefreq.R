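#' Build a complex Morlet wavelet bank
#'
#' Frequencies are logarithmically spaced over `[f_min, f_max]` (endpoints
#' included); the cycle count grows linearly in log-frequency from
#' `cycle_min` at `f_min` to `cycle_max` at `f_max`, trading temporal for
#' spectral resolution as frequency rises. Each kernel is a Gaussian-windowed
#' complex exponential spanning +/- 3.5 temporal SDs, normalized to unit
#' energy; decibel baseline normalization later cancels any per-frequency
#' gain, so thresholded maps do not depend on this normalization choice.
#'
#' @param f_min,f_max frequency range, Hz (`f_max` below Nyquist).
#' @param n_freqs number of frequencies (>= 2).
#' @param cycle_min,cycle_max cycle counts at `f_min` and `f_max`.
#' @param rate sampling rate of the epochs, Hz.
#' @return a `wavelet_bank`: frequencies, cycles, kernels (complex vectors),
#'   half-lengths, rate.
#' @export
build_wavelet_bank <- function(f_min = 1, f_max = 50, n_freqs = 50,
                               cycle_min = 3, cycle_max = 10, rate = 500) {
  if (!(f_min < f_max && f_max < rate / 2)) {
    stop("need f_min < f_max < Nyquist", call. = FALSE)
  }
  stopifnot(n_freqs >= 2, cycle_min >= 1, cycle_max >= cycle_min)
  freqs <- exp(seq(log(f_min), log(f_max), length.out = n_freqs))
  cycles <- cycle_min + (cycle_max - cycle_min) *
    (log(freqs) - log(f_min)) / (log(f_max) - log(f_min))
  kernels <- vector("list", n_freqs)
  halves <- integer(n_freqs)
  for (i in seq_len(n_freqs)) {
    sd_t <- cycles[i] / (2 * pi * freqs[i])
    half <- ceiling(3.5 * sd_t * rate)
    t <- (-half:half) / rate
    w <- exp(2i * pi * freqs[i] * t) * exp(-t^2 / (2 * sd_t^2))
    w <- w / sqrt(sum(Mod(w)^2))
    kernels[[i]] <- w
    halves[i] <- half
  }
  structure(list(freqs = freqs, cycles = cycles, kernels = kernels,
                 half_lengths = halves, rate = rate),
            class = "wavelet_bank")
}

#' @export
print.wavelet_bank <- function(x, ...) {
  cat(sprintf(
    "<wavelet_bank> %d log-spaced frequencies %.3g-%.3g Hz, %g-%g cycles, %g Hz\n",
    length(x$freqs), min(x$freqs), max(x$freqs), min(x$cycles),
    max(x$cycles), x$rate))
  invisible(x)
}

#' Per-trial wavelet power via spectral multiplication
#'
#' Convolves every trial and channel with every wavelet kernel by FFT
#' (multiply the trial spectrum with each kernel spectrum, inverse FFT,
#' squared magnitude), zero-padded so circular wrap-around cannot reach the
#' retained "same"-aligned samples; this equals direct time-domain
#' convolution to numerical precision. When the epochs carry guard context
#' (see [epoch_session()]), the convolution runs on the extended series and
#' is cropped back to the fixed grid, so epoch edges see real data instead
#' of zero padding. Samples within half a kernel length of the true data
#' edge are flagged (`$edge`), not dropped; with the default guard no sample
#' on the grid is flagged.
#'
#' @param epochs an `epoch_set`.
#' @param bank a `wavelet_bank` with matching sampling rate.
#' @param channels channel indices or labels to decompose (default: all).
#' @return a `trial_power_tensor`: linear power array
#'   `freq x time x trial x channel`, frequency and time axes, task labels,
#'   edge-flag matrix (`freq x time`), `scale = "linear"`.
#' @export
wavelet_power <- function(epochs, bank, channels = NULL) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(bank, "wavelet_bank"))
  if (!isTRUE(all.equal(epochs$sampling_rate_hz, bank$rate))) {
    stop("epochs and wavelet bank sampling rates differ", call. = FALSE)
  }
  if (is.null(channels)) channels <- seq_along(epochs$labels)
  if (is.character(channels)) channels <- match(channels, epochs$labels)
  stopifnot(!anyNA(channels))

  n_t <- dim(epochs$data)[3]
  n_trials <- dim(epochs$data)[1]
  n_f <- length(bank$freqs)
  use_guard <- !is.null(epochs$guard)
  g_pre <- if (use_guard) epochs$guard_n[["pre"]] else 0L
  g_post <- if (use_guard) epochs$guard_n[["post"]] else 0L
  n_ext <- n_t + g_pre + g_post
  src <- if (use_guard) epochs$guard else epochs$data

  max_len <- max(2L * bank$half_lengths + 1L)
  nfft <- stats::nextn(n_ext + max_len - 1L, c(2, 3))

  kern_f <- matrix(0i, nfft, n_f)
  for (i in seq_len(n_f)) {
    k <- bank$kernels[[i]]
    kern_f[, i] <- stats::fft(c(k, complex(real = rep(0, nfft - length(k)))))
  }

  power <- array(NA_real_, c(n_f, n_t, n_trials, length(channels)))
  pad <- matrix(0, nfft, n_trials)
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    pad[seq_len(n_ext), ] <- t(src[, ch, , drop = FALSE][, 1, ])
    trial_f <- stats::mvfft(pad)
    for (i in seq_len(n_f)) {
      conv <- stats::mvfft(trial_f * kern_f[, i], inverse = TRUE) / nfft
      off <- bank$half_lengths[i] + g_pre
      seg <- conv[(off + 1L):(off + n_t), , drop = FALSE]
      power[i, , , ci] <- Mod(seg)^2
    }
  }

  # flag samples whose kernel support reaches beyond the available data
  edge <- matrix(FALSE, n_f, n_t)
  for (i in seq_len(n_f)) {
    h <- bank$half_lengths[i]
    j <- seq_len(n_t)
    edge[i, ] <- (g_pre + j - 1L) < h | (g_post + n_t - j) < h
  }

  structure(list(
    power = power,
    freqs = bank$freqs,
    time_ms = epochs$time_ms,
    tasks = epochs$tasks,
    labels = epochs$labels[channels],
    participant_id = epochs$participant_id,
    hemisphere = epochs$hemisphere,
    edge = edge,
    scale = "linear"
  ), class = "trial_power_tensor")
}

#' @export
print.trial_power_tensor <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf(
    "<trial_power_tensor> [%s] %d freqs x %d samples x %d trials x %d channels\n",
    x$scale, d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Decibel-normalize single-trial power
#'
#' `dB(f, t, trial) = 10 log10(power_t / power_baseline)`, with
#' `power_baseline` the mean linear power over `baseline_window_ms` for that
#' trial and frequency (whole-epoch baseline, -2000..+1000 ms, by default).
#' The log transform also brings single-trial power (heavily right-skewed)
#' closer to normality for the mixed-effects stage. With
#' `per_trial = FALSE` the baseline is instead pooled across trials.
#'
#' @param tensor a linear-scale `trial_power_tensor`.
#' @param baseline_window_ms baseline window, ms (closed interval).
#' @param per_trial logical; per-trial (default) or across-trial baseline.
#' @return the tensor with `scale = "db"`.
#' @export
db_normalize <- function(tensor, baseline_window_ms = c(-2000, 1000),
                         per_trial = TRUE) {
  stopifnot(inherits(tensor, "trial_power_tensor"))
  if (tensor$scale != "linear") {
    stop("tensor is already dB-normalized", call. = FALSE)
  }
  bidx <- idx_closed(tensor$time_ms, baseline_window_ms)
  if (length(bidx) == 0) stop("baseline window outside epoch", call. = FALSE)
  d <- dim(tensor$power)
  base <- apply(tensor$power[, bidx, , , drop = FALSE], c(1, 3, 4), mean)
  if (!per_trial) {
    pooled <- apply(base, c(1, 3), mean) # freq x channel, pooled over trials
    for (tr in seq_len(d[3])) base[, tr, ] <- pooled
  }
  if (any(base <= 0)) {
    bad <- which(base <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-positive baseline power at frequency %.3g Hz, trial %d, channel %s",
      tensor$freqs[bad[1]], bad[2], tensor$labels[bad[3]]), call. = FALSE)
  }
  denom <- array(NA_real_, d)
  for (tt in seq_len(d[2])) denom[, tt, , ] <- base
  tensor$power <- 10 * log10(tensor$power / denom)
  tensor$scale <- "db"
  tensor$baseline_window_ms <- baseline_window_ms
  tensor
}

new_tf_map <- function(power, freqs, time_ms, level, condition = NA_character_,
                       participant_id = NA_character_,
                       hemisphere = NA_character_, label = NA_character_) {
  structure(list(power = power, freqs = freqs, time_ms = time_ms,
                 level = level, condition = condition,
                 participant_id = participant_id, hemisphere = hemisphere,
                 label = label),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> [%s%s] %d freqs x %d samples\n", x$level,
              if (is.na(x$condition)) "" else paste0(", ", x$condition),
              nrow(x$power), ncol(x$power)))
  invisible(x)
}

#' Average power into time-frequency maps
#'
#' `level = "trials"` averages a dB tensor across trials (optionally a trial
#' subset, e.g. one task) into one participant-level map per requested
#' channel. `level = "participants"` averages a list of participant maps into
#' a grand-average map with equal weight per participant regardless of trial
#' count.
#'
#' @param x a dB `trial_power_tensor`, or a list of `tf_map`s.
#' @param level `"trials"` or `"participants"`.
#' @param trials optional trial index subset (for `"trials"`).
#' @param channel channel label or index (for `"trials"`; default first).
#' @param condition condition label to stamp on the map.
#' @return a `tf_map`.
#' @export
average_maps <- function(x, level = c("trials", "participants"),
                         trials = NULL, channel = 1L,
                         condition = NA_character_) {
  level <- match.arg(level)
  if (level == "trials") {
    stopifnot(inherits(x, "trial_power_tensor"))
    if (is.character(channel)) channel <- match(channel, x$labels)
    if (is.null(trials)) trials <- seq_len(dim(x$power)[3])
    if (length(trials) < 1) stop("no trials to average", call. = FALSE)
    m <- apply(x$power[, , trials, channel, drop = FALSE], c(1, 2), mean)
    new_tf_map(m, x$freqs, x$time_ms, "participant", condition,
               x$participant_id, x$hemisphere, x$labels[channel])
  } else {
    stopifnot(is.list(x), length(x) >= 1,
              all(vapply(x, inherits, logical(1), "tf_map")))
    m <- Reduce(`+`, lapply(x, `[[`, "power")) / length(x)
    new_tf_map(m, x[[1]]$freqs, x[[1]]$time_ms, "grand", condition)
  }
}
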