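# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a base seed and a stage/index counter
#'
#' Stages of the pipeline and per-participant generators draw their own seeds
#' from one top-level seed through this counter scheme, so any stage can be
#' re-run in isolation and still reproduce the full-pipeline result.
#' Result is always a valid 32-bit integer seed.
#'
#' @param base integer base seed.
#' @param index non-negative integer counter.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(base, index) {
  stopifnot(is.numeric(base), length(base) == 1, is.numeric(index))
  as.integer((abs(as.double(base)) * 48271 + as.double(index) * 1000003) %%
               2147483629)
}

# zero-phase Butterworth band-pass as a high-pass / low-pass cascade.
# A direct 4th-order band-pass with a 1 Hz corner at fs = 500 is numerically
# fragile; the cascade keeps each section well conditioned. Corners are
# placed just outside the requested band so that, after forward-backward
# filtering, the band edges themselves lose less than 1 dB while one octave
# outside the band is still attenuated by more than 20 dB.
zp_bandpass <- function(x, rate, low, high, order_hp = 4L, order_lp = 6L) {
  if (!(low > 0 && low < high && high < rate / 2)) {
    stop("invalid band: need 0 < low < high < Nyquist", call. = FALSE)
  }
  fc_hp <- 0.75 * low
  fc_lp <- min(1.10 * high, 0.95 * rate / 2)
  hp <- signal::butter(order_hp, fc_hp / (rate / 2), type = "high")
  lp <- signal::butter(order_lp, fc_lp / (rate / 2), type = "low")
  y <- signal::filtfilt(hp, x)
  signal::filtfilt(lp, y)
}

# sharp zero-phase FIR band-pass (Hamming-windowed linear-phase design,
# applied by FFT convolution with the group delay removed). Used where a
# narrow analysis band must be isolated with near-flat passband and steep
# transitions (modulation injection and band-variance measurement); the IIR
# cascade above is kept for broad-band conditioning where its gentle skirts
# do not matter.
fir_bandpass <- function(x, rate, low, high, transition = NULL) {
  stopifnot(low > 0, low < high, high < rate / 2)
  if (is.null(transition)) transition <- max(1, low / 4)
  ord <- ceiling(3.3 * rate / transition)
  ord <- ord + ord %% 2 # even order -> odd symmetric taps
  b <- signal::fir1(ord, c(low, high) / (rate / 2), type = "pass")
  n <- length(x)
  nfft <- stats::nextn(n + ord, c(2, 3))
  xf <- stats::fft(c(x, rep(0, nfft - n)))
  bf <- stats::fft(c(b, rep(0, nfft - length(b))))
  y <- Re(stats::fft(xf * bf, inverse = TRUE)) / nfft
  y[(ord / 2 + 1):(ord / 2 + n)]
}

# zero-phase biquad notch (zeros on the unit circle at the target frequency)
zp_notch <- function(x, rate, f0, bw = 2) {
  w0 <- 2 * pi * f0 / rate
  r <- 1 - pi * bw / rate
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  b <- b * sum(a) / sum(b) # unit gain at DC
  signal::filtfilt(signal::Arma(b = b, a = a), x)
}

# truncated-normal sampler (rejection; bounds assumed reachable)
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

# time axis helpers ---------------------------------------------------------

time_axis_ms <- function(window_ms, rate) {
  step <- 1000 / rate
  seq(window_ms[1], window_ms[2], by = step)
}

# indices of a half-open-left, closed-right interval (surrogate baseline)
idx_open_left <- function(time_ms, win) {
  which(time_ms > win[1] & time_ms <= win[2])
}

# indices of a closed interval
idx_closed <- function(time_ms, win) {
  which(time_ms >= win[1] & time_ms <= win[2])
}
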