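# fixtures built in code; no data files

std_time_ms <- seq(-2000, 1000, by = 2)

# epoch_set wrapped around a trials x time matrix (single channel)
mk_epochs <- function(mat, tasks = rep("vowel", nrow(mat)), rate = 500,
                      time_ms = std_time_ms, labels = "L1") {
  stopifnot(ncol(mat) == length(time_ms))
  structure(list(
    data = array(mat, c(nrow(mat), 1, ncol(mat))),
    time_ms = time_ms, tasks = tasks, trial_id = seq_len(nrow(mat)),
    participant_id = "P01", hemisphere = "left", labels = labels,
    sampling_rate_hz = rate, guard = NULL, guard_n = c(pre = 0L, post = 0L),
    rejected = data.frame()), class = "epoch_set")
}

# recording_session from a samples x channels matrix
mk_session <- function(data, rate = 500, labels = paste0("L", 1:ncol(data)),
                       lead_model = "four_contact", hemisphere = "left") {
  structure(list(participant_id = "P01", hemisphere = hemisphere,
                 sampling_rate_hz = rate, lead_model = lead_model,
                 labels = labels, data = data),
            class = "recording_session")
}

# trial_power_tensor from a freq x time x trial array (single channel)
mk_tensor <- function(arr, freqs, time_ms = std_time_ms, scale = "db",
                      tasks = rep("vowel", dim(arr)[3])) {
  structure(list(
    power = array(arr, c(dim(arr), 1)), freqs = freqs, time_ms = time_ms,
    tasks = tasks, labels = "L1", participant_id = "P01",
    hemisphere = "left", edge = matrix(FALSE, dim(arr)[1], dim(arr)[2]),
    scale = scale), class = "trial_power_tensor")
}

# Welch-averaged periodogram slope over a frequency range (log-log LS fit);
# independent oracle for the 1/f generator
welch_slope <- function(x, rate, f_range = c(1, 50), seg = 4096) {
  nseg <- floor(length(x) / seg)
  psd <- 0
  win <- 0.5 * (1 - cos(2 * pi * (0:(seg - 1)) / seg))
  for (i in seq_len(nseg)) {
    s <- x[((i - 1) * seg + 1):(i * seg)] * win
    psd <- psd + Mod(stats::fft(s))^2
  }
  psd <- psd[2:(seg / 2)] / nseg
  f <- (1:(seg / 2 - 1)) * rate / seg
  sel <- f >= f_range[1] & f <= f_range[2]
  unname(stats::coef(stats::lm(log(psd[sel]) ~ log(f[sel])))[2])
}

# band variance via a high-order zero-phase FIR (measurement oracle,
# independent of the package's injection path parameters)
band_var <- function(x, rate, low, high, idx = seq_along(x)) {
  ord <- 2 * ceiling(3.3 * rate / max(1, low / 4) / 2)
  b <- signal::fir1(ord, c(low, high) / (rate / 2), type = "pass")
  nfft <- stats::nextn(length(x) + ord, c(2, 3))
  y <- Re(stats::fft(stats::fft(c(x, rep(0, nfft - length(x)))) *
                       stats::fft(c(b, rep(0, nfft - ord - 1))),
                     inverse = TRUE)) / nfft
  stats::var(y[(ord / 2 + 1):(ord / 2 + length(x))][idx])
}

# brute-force complex 'same'-aligned convolution (oracle for wavelet_power)
direct_conv_same <- function(x, k, half) {
  n <- length(x)
  lk <- length(k)
  out <- complex(real = numeric(n), imaginary = numeric(n))
  for (i in seq_len(n)) {
    j <- i + half
    mm <- max(1L, j - lk + 1L):min(n, j)
    out[i] <- sum(x[mm] * k[j - mm + 1L])
  }
  out
}

# amplitude of a sinusoid at f in x, by least squares (sine-fit oracle)
sine_amp <- function(x, rate, f) {
  t <- (seq_along(x) - 1) / rate
  fit <- stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}
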