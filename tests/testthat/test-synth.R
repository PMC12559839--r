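test_that("pink noise has the requested spectral slope and is reproducible", {
  x0 <- pink_noise(1e5, 0, 2000, seed = 3)
  expect_lt(abs(welch_slope(x0, 2000) - 0), 0.1)

  x1 <- pink_noise(1e5, 1, 2000, seed = 7)
  expect_lt(abs(welch_slope(x1, 2000) - (-1)), 0.15)
  expect_equal(mean(x1), 0, tolerance = 1e-12)
  expect_equal(sd(x1), 1, tolerance = 1e-9)

  expect_identical(pink_noise(1000, 1, 2000, seed = 5),
                   pink_noise(1000, 1, 2000, seed = 5))
  expect_false(identical(pink_noise(1000, 1, 2000, seed = 5),
                         pink_noise(1000, 1, 2000, seed = 6)))
  expect_error(pink_noise(1, 1), "n_samples")
})

test_that("inject_modulation changes band power by the requested dB and
           leaves the rest of the signal alone", {
  rate <- 2000
  y <- pink_noise(rate * 60, 1, rate, seed = 11)
  ons <- seq(5, 55, by = 3)
  win <- unlist(lapply(ons, function(o)
    (round(o * rate) + 160):(round((o + 1) * rate) - 160)))

  expect_identical(inject_modulation(y, rate, c(4, 8), c(0, 1000), 0, ons), y)

  y2 <- inject_modulation(y, rate, c(4, 8), c(0, 1000), 6, ons)
  ratio <- band_var(y2, rate, 4, 8, win) / band_var(y, rate, 4, 8, win)
  expect_gt(ratio, 4 * 0.7) # 6 dB = 4x power, within +/-30%
  expect_lt(ratio, 4 * 1.3)

  pre <- unlist(lapply(ons, function(o)
    (round((o - 0.5) * rate) + 160):(round(o * rate) - 160)))
  y3 <- inject_modulation(y, rate, c(13, 30), c(-500, 0), -6, ons)
  ratio3 <- band_var(y3, rate, 13, 30, pre) / band_var(y, rate, 13, 30, pre)
  expect_gt(ratio3, 0.25 * 0.7)
  expect_lt(ratio3, 0.25 * 1.3)

  # other band and out-of-window power unchanged (within 0.5 dB)
  other <- 10 * log10(band_var(y2, rate, 13, 30, win) /
                        band_var(y, rate, 13, 30, win))
  expect_lt(abs(other), 0.5)
  out_idx <- unlist(lapply(ons, function(o)
    (round((o + 1.7) * rate)):(round((o + 2.5) * rate))))
  outw <- 10 * log10(band_var(y2, rate, 4, 8, out_idx) /
                       band_var(y, rate, 4, 8, out_idx))
  expect_lt(abs(outw), 0.5)

  expect_error(inject_modulation(y, rate, c(4, 8), c(-6000, 0), 3, ons[1]),
               "bounds")
})

test_that("generate_session produces the configured trial structure", {
  cfg <- synth_config(n_participants = 1, trials_per_task = 30, seed = 2)
  gs <- generate_session(cfg, "P01", "left", seed = 9)
  ann <- gs$annotations

  expect_equal(nrow(ann), 90)
  expect_equal(as.vector(table(ann$task)[c("vowel", "ddk", "sentence")]),
               rep(30L, 3))
  expect_true(all(diff(ann$onset_s) > 0))
  expect_true(all(ann$offset_s > ann$onset_s))
  for (task in cfg$tasks) {
    d <- cfg$trial_duration_s[[task]]
    dur <- ann$offset_s[ann$task == task] - ann$onset_s[ann$task == task]
    expect_true(all(abs(dur - d[["mean"]]) <= 3 * d[["sd"]] + 1e-9))
  }
  itis <- ann$onset_s[-1] - ann$offset_s[-nrow(ann)]
  expect_true(all(itis >= cfg$iti_s$min - 1e-9 &
                    itis <= cfg$iti_s$max + 1e-9))
  expect_equal(gs$session$labels, paste0("L", 1:4))

  cfg8 <- synth_config(n_participants = 1, trials_per_task = 30,
                       lead_model = "eight_contact_segmented", seed = 2)
  gs8 <- generate_session(cfg8, "P01", "right", seed = 9)
  expect_equal(gs8$session$labels,
               paste0("R", c("1", "2A", "2B", "2C", "3A", "3B", "3C", "4")))
})

test_that("generate_cohort yields 2 sessions per participant,
           deterministically", {
  cfg <- suppressMessages(
    synth_config(n_participants = 2, trials_per_task = 5, seed = 31))
  co1 <- suppressMessages(generate_cohort(cfg))
  expect_length(co1$sessions, 4)
  co2 <- suppressMessages(generate_cohort(cfg))
  expect_identical(co1$sessions[[1]]$session$data,
                   co2$sessions[[1]]$session$data)
  expect_identical(co1$sessions[[4]]$annotations, co2$sessions[[4]]$annotations)

  cfg1 <- suppressMessages(
    synth_config(n_participants = 1, trials_per_task = 5, seed = 31))
  expect_length(suppressMessages(generate_cohort(cfg1))$sessions, 2)
})

test_that("effect-free recordings are stationary in band variance", {
  cfg <- synth_config(n_participants = 1, trials_per_task = 30,
                      theta_effect_db = c(vowel = 0, ddk = 0, sentence = 0),
                      beta_effect_db = c(vowel = 0, ddk = 0, sentence = 0),
                      seed = 17)
  gs <- generate_session(cfg, "P01", "left", seed = 17)
  x <- gs$session$data[, 1]
  rate <- cfg$sampling_rate_hz
  for (band in list(c(1, 8), c(13, 30))) {
    ord <- 2 * ceiling(3.3 * rate / max(1, band[1] / 4) / 2)
    b <- signal::fir1(ord, band / (rate / 2), type = "pass")
    nfft <- stats::nextn(length(x) + ord, c(2, 3))
    y <- Re(stats::fft(stats::fft(c(x, rep(0, nfft - length(x)))) *
                         stats::fft(c(b, rep(0, nfft - ord - 1))),
                       inverse = TRUE)) / nfft
    y <- y[(ord / 2 + 1):(ord / 2 + length(x))]
    # variance in 100 contiguous 1 s windows; permutation test that a random
    # half does not differ from the other half beyond sampling error
    v <- vapply(0:99, function(k)
      var(y[(k * rate + 1):((k + 1) * rate)]), numeric(1))
    obs <- abs(mean(v[1:50]) - mean(v[51:100]))
    perm <- withr::with_seed(1, replicate(500, {
      s <- sample(100, 50)
      abs(mean(v[s]) - mean(v[-s]))
    }))
    expect_gt(mean(perm >= obs), 0.01)
  }
})

test_that("synth_config validates its inputs", {
  expect_error(synth_config(sampling_rate_hz = 50), "sampling_rate")
  expect_error(synth_config(pink_exponent = 3))
  expect_error(synth_config(iti_s = list(mean = 1, sd = 0.1, min = 0,
                                         max = 2)))
  expect_message(synth_config(trials_per_task = 10), "30-50")
})
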