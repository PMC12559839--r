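#' Resample a recording session
#'
#' Anti-alias filtered downsampling to `target_rate` (default 500 Hz, the
#' rate all downstream stages assume). Integer decimation uses a zero-phase
#' low-pass (Chebyshev type I via [signal::decimate()]); non-integer but
#' rational ratios fall back to polyphase resampling.
#'
#' @param session a `recording_session`.
#' @param target_rate target rate in Hz; must not exceed the source rate.
#' @return the resampled session.
#' @export
resample_session <- function(session, target_rate = 500) {
  stopifnot(inherits(session, "recording_session"))
  src <- session$sampling_rate_hz
  if (target_rate > src) {
    stop("upsampling is not supported (target_rate > sampling_rate_hz)",
         call. = FALSE)
  }
  if (target_rate == src) return(session)
  if (src %% target_rate == 0) {
    q <- src %/% target_rate
    out <- apply(session$data, 2, function(x) signal::decimate(x, q))
  } else {
    frac <- .ratio(target_rate / src)
    out <- apply(session$data, 2,
                 function(x) signal::resample(x, frac[1], frac[2]))
  }
  session$data <- out
  session$sampling_rate_hz <- target_rate
  session
}

# small-denominator rational approximation of a ratio in (0, 1)
.ratio <- function(r, max_den = 1000) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("target rate is not rationally related to the source rate",
       call. = FALSE)
}

#' Remove line noise with a zero-phase notch bank
#'
#' One biquad notch (zeros on the unit circle) per targeted harmonic, applied
#' forward-backward so perievent latencies are not shifted. Harmonics at or
#' above Nyquist are skipped.
#'
#' @param session a `recording_session`.
#' @param line_hz mains frequency (60 by default; set 50 where applicable).
#' @param harmonics number of multiples of `line_hz` to notch (2 = 60 and
#'   120 Hz).
#' @param bw notch bandwidth in Hz.
#' @return the denoised session.
#' @export
remove_line_noise <- function(session, line_hz = 60, harmonics = 2, bw = 2) {
  stopifnot(inherits(session, "recording_session"))
  nyq <- session$sampling_rate_hz / 2
  if (line_hz >= nyq) stop("line_hz must be below Nyquist", call. = FALSE)
  targets <- line_hz * seq_len(harmonics)
  targets <- targets[targets < nyq]
  for (f0 in targets) {
    session$data <- apply(session$data, 2, zp_notch,
                          rate = session$sampling_rate_hz, f0 = f0, bw = bw)
  }
  session
}

#' Average segmented-lead contacts to four depths
#'
#' Segmented leads split the middle two contact rows into three radial
#' segments (2A, 2B, 2C and 3A, 3B, 3C). LFP analysis works at contact-depth
#' resolution, so segments at the same depth are averaged samplewise into a
#' single contact; contacts 1 and 4 pass through. A four-channel session is
#' returned unchanged with a message.
#'
#' @param session a `recording_session`.
#' @return a four-channel session with labels 1-4.
#' @export
average_segments <- function(session) {
  stopifnot(inherits(session, "recording_session"))
  if (session$lead_model == "four_contact" || ncol(session$data) == 4) {
    message("session already has 4 contacts; nothing to average")
    return(session)
  }
  prefix <- substr(session$labels[1], 1, 1)
  need <- paste0(prefix, segmented_labels)
  if (!setequal(session$labels, need)) {
    stop("malformed segmented lead: expected labels ",
         paste(need, collapse = ","), call. = FALSE)
  }
  pick <- function(lbls) {
    m <- session$data[, match(paste0(prefix, lbls), session$labels),
                      drop = FALSE]
    rowMeans(m)
  }
  data <- cbind(pick("1"), pick(c("2A", "2B", "2C")),
                pick(c("3A", "3B", "3C")), pick("4"))
  session$data <- data
  session$labels <- paste0(prefix, contact_labels)
  session$lead_model <- "four_contact"
  session
}

#' Common average rereference within a hemisphere
#'
#' Subtracts the samplewise mean of the four contacts from each contact,
#' cancelling noise common to the electrode shaft. Output channels sum to
#' zero at every sample.
#'
#' @param session a four-channel `recording_session`.
#' @return the rereferenced session.
#' @export
common_average_reference <- function(session) {
  stopifnot(inherits(session, "recording_session"))
  if (ncol(session$data) != 4) {
    stop("common average reference requires exactly 4 contacts ",
         "(average segments first)", call. = FALSE)
  }
  session$data <- session$data - rowMeans(session$data)
  session
}

#' Band-pass filter a session
#'
#' Zero-phase Butterworth cascade (2nd-order high-pass, 4th-order low-pass,
#' each applied forward-backward), 1-50 Hz by default: the band the
#' oscillatory analysis covers. DC and drift are removed by the high-pass.
#'
#' @param session a `recording_session`.
#' @param low,high band edges in Hz, `0 < low < high < Nyquist`.
#' @return the filtered session.
#' @export
bandpass_session <- function(session, low = 1, high = 50) {
  stopifnot(inherits(session, "recording_session"))
  session$data <- apply(session$data, 2, zp_bandpass,
                        rate = session$sampling_rate_hz, low = low,
                        high = high)
  session
}

#' Extract onset-locked epochs
#'
#' Cuts one fixed-length epoch per annotation row on the grid
#' `window_ms[1]..window_ms[2]` (inclusive endpoints; at 500 Hz and the
#' default -2000..+1000 ms window, 1,501 samples with t = 0 at the sample
#' nearest each onset). Epochs are extracted independently, so overlapping
#' trials share samples. Onsets too close to the recording edge are dropped
#' and reported.
#'
#' In addition to the fixed grid, `guard_ms` of real recording context can be
#' carried on each side of every epoch (`$guard`); the wavelet stage uses it
#' so that convolution near the epoch edges sees actual data instead of zero
#' padding, removing edge attenuation from the analysis window. The guard is
#' trimmed (with a message) when the recording does not extend far enough
#' around the kept trials.
#'
#' @param session a four-channel `recording_session`.
#' @param annotations data.frame with `trial_id`, `task`, `onset_s`,
#'   `offset_s`.
#' @param window_ms epoch window in ms relative to onset.
#' @param guard_ms context carried on each side of the epoch for later
#'   convolution (0 disables).
#' @return an `epoch_set`: trial x channel x time array plus task labels,
#'   time axis, contact labels and a rejection report (`$rejected`).
#' @export
epoch_session <- function(session, annotations,
                          window_ms = c(-2000, 1000), guard_ms = 0) {
  stopifnot(inherits(session, "recording_session"),
            all(c("trial_id", "task", "onset_s") %in% names(annotations)))
  rate <- session$sampling_rate_hz
  time_ms <- time_axis_ms(window_ms, rate)
  n_t <- length(time_ms)
  offs <- round(window_ms * rate / 1000)
  n <- nrow(session$data)

  onset_idx <- round(annotations$onset_s * rate) + 1L
  lo <- onset_idx + offs[1]
  hi <- onset_idx + offs[2]
  ok <- lo >= 1 & hi <= n
  rejected <- annotations[!ok, , drop = FALSE]
  if (nrow(rejected) > 0) {
    warning(sprintf("%d trial(s) dropped: epoch window exceeds recording",
                    nrow(rejected)), call. = FALSE)
  }
  keep <- which(ok)
  guard_n <- round(guard_ms * rate / 1000)
  g_pre <- g_post <- 0L
  if (guard_n > 0 && length(keep)) {
    g_pre <- min(guard_n, min(lo[keep]) - 1L)
    g_post <- min(guard_n, n - max(hi[keep]))
    if (g_pre < guard_n || g_post < guard_n) {
      message(sprintf("guard trimmed to %d/%d ms (recording bounds)",
                      round(1000 * g_pre / rate),
                      round(1000 * g_post / rate)))
    }
  }
  data <- array(NA_real_, c(length(keep), ncol(session$data), n_t))
  guard <- if (g_pre + g_post > 0) {
    array(NA_real_, c(length(keep), ncol(session$data),
                      n_t + g_pre + g_post))
  } else NULL
  for (i in seq_along(keep)) {
    idx <- lo[keep[i]]:hi[keep[i]]
    data[i, , ] <- t(session$data[idx, , drop = FALSE])
    if (!is.null(guard)) {
      gidx <- (lo[keep[i]] - g_pre):(hi[keep[i]] + g_post)
      guard[i, , ] <- t(session$data[gidx, , drop = FALSE])
    }
  }
  structure(list(
    data = data,
    time_ms = time_ms,
    tasks = annotations$task[keep],
    trial_id = annotations$trial_id[keep],
    participant_id = session$participant_id,
    hemisphere = session$hemisphere,
    labels = session$labels,
    sampling_rate_hz = rate,
    guard = guard,
    guard_n = c(pre = g_pre, post = g_post),
    rejected = rejected
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %s / %s: %d trials x %d channels x %d samples (%g..%g ms)\n",
    x$participant_id, x$hemisphere, dim(x$data)[1], dim(x$data)[2],
    dim(x$data)[3], min(x$time_ms), max(x$time_ms)))
  if (nrow(x$rejected)) cat(sprintf("  %d trial(s) rejected\n",
                                    nrow(x$rejected)))
  invisible(x)
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: resample -> line-noise notch -> segment averaging ->
#' common average reference -> band-pass -> epoch.
#'
#' @param session a `recording_session`.
#' @param annotations trial annotations (see [epoch_session()]).
#' @param target_rate resampling target, Hz.
#' @param line_hz mains frequency for the notch bank; `NULL` skips the stage.
#' @param band band-pass edges, Hz.
#' @param window_ms epoch window, ms.
#' @param guard_ms per-epoch context for edge-free convolution; the default
#'   covers the longest default wavelet kernel (3 cycles at 1 Hz).
#' @return an `epoch_set`.
#' @export
preprocess_session <- function(session, annotations, target_rate = 500,
                               line_hz = 60, band = c(1, 50),
                               window_ms = c(-2000, 1000), guard_ms = 1700) {
  s <- resample_session(session, target_rate)
  if (!is.null(line_hz)) s <- remove_line_noise(s, line_hz)
  if (ncol(s$data) == 8) s <- average_segments(s)
  s <- common_average_reference(s)
  s <- bandpass_session(s, band[1], band[2])
  epoch_session(s, annotations, window_ms, guard_ms)
}
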