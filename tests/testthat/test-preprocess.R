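test_that("resampling preserves counts, amplitudes and band content", {
  rate <- 2000
  t <- (0:(10 * rate - 1)) / rate
  s <- mk_session(cbind(sin(2 * pi * 10 * t)), rate = rate, labels = "L1")
  r <- resample_session(s, 500)
  expect_equal(nrow(r$data), 5000)
  expect_equal(r$sampling_rate_hz, 500)
  expect_lt(abs(sine_amp(r$data[101:4900, 1], 500, 10) - 1), 0.01)

  expect_identical(resample_session(s, rate), s)
  expect_error(resample_session(s, 4000), "upsampling")

  # broadband 1-50 Hz variance preserved within 10% through resample+bandpass
  x <- pink_noise(rate * 60, 1, rate, seed = 4)
  sb <- mk_session(cbind(x), rate = rate, labels = "L1")
  out <- bandpass_session(resample_session(sb, 500), 1, 50)
  v_in <- band_var(x, rate, 1, 50)
  v_out <- band_var(out$data[, 1], 500, 1, 50)
  expect_lt(abs(v_out / v_in - 1), 0.10)
})

test_that("line-noise notch attenuates the line and spares the band", {
  rate <- 500
  n <- rate * 30
  t <- (0:(n - 1)) / rate
  bg <- pink_noise(n, 1, rate, seed = 8)
  line <- sqrt(10) * sd(bg) * sin(2 * pi * 60 * t)
  s <- mk_session(cbind(bg + line), rate = rate, labels = "L1")
  den <- remove_line_noise(s, 60, harmonics = 2)
  att <- sine_amp(s$data[, 1], rate, 60) / sine_amp(den$data[, 1], rate, 60)
  expect_gt(20 * log10(att), 20)

  # line-free input passes nearly unchanged across 1-50 Hz
  clean <- mk_session(cbind(bg), rate = rate, labels = "L1")
  den2 <- remove_line_noise(clean, 60, harmonics = 2)
  drift <- 10 * log10(band_var(den2$data[, 1], rate, 1, 50) /
                        band_var(bg, rate, 1, 50))
  expect_lt(abs(drift), 0.5)

  # 50 Hz option honoured
  line50 <- sqrt(10) * sd(bg) * sin(2 * pi * 50 * t)
  s50 <- mk_session(cbind(bg + line50), rate = rate, labels = "L1")
  den50 <- remove_line_noise(s50, 50, harmonics = 1)
  att50 <- sine_amp(s50$data[, 1], rate, 50) /
    sine_amp(den50$data[, 1], rate, 50)
  expect_gt(20 * log10(att50), 20)
})

test_that("segment averaging collapses the segmented lead to four depths", {
  n <- 1000
  base <- matrix(rnorm(8 * n), n, 8)
  labs <- paste0("L", c("1", "2A", "2B", "2C", "3A", "3B", "3C", "4"))
  s <- mk_session(base, labels = labs, lead_model = "eight_contact_segmented")

  avg <- average_segments(s)
  expect_equal(avg$labels, paste0("L", 1:4))
  expect_equal(avg$data[, 2], rowMeans(base[, 2:4]))
  expect_equal(avg$data[, 3], rowMeans(base[, 5:7]))
  expect_equal(avg$data[, 1], base[, 1])
  expect_equal(avg$data[, 4], base[, 8])

  # identical segments pass through; symmetric segments cancel
  s2 <- s
  s2$data[, 2:4] <- s2$data[, c(2, 2, 2)]
  expect_equal(average_segments(s2)$data[, 2], s2$data[, 2])
  s3 <- s
  s3$data[, 2] <- 1; s3$data[, 3] <- 0; s3$data[, 4] <- -1
  expect_equal(average_segments(s3)$data[, 2], rep(0, n))

  s4 <- mk_session(base[, 1:4], labels = paste0("L", 1:4))
  expect_message(average_segments(s4), "nothing to average")

  s5 <- s
  s5$labels[2] <- "L2X"
  expect_error(average_segments(s5), "malformed")
})

test_that("common average referencing removes shared signal exactly", {
  n <- 2000
  base <- matrix(rnorm(4 * n), n, 4)
  s <- mk_session(base)
  car <- common_average_reference(s)
  expect_lt(max(abs(rowSums(car$data))), 1e-9 * sd(base))

  common <- sin(2 * pi * 7 * (0:(n - 1)) / 500)
  s2 <- mk_session(base + common)
  expect_equal(common_average_reference(s2)$data, car$data)

  # idempotence and degenerate input
  expect_equal(common_average_reference(car)$data, car$data)
  s3 <- mk_session(matrix(rnorm(n), ncol = 1), labels = "L1")
  expect_error(common_average_reference(s3), "4 contacts")
  same <- mk_session(matrix(rep(rnorm(n), 4), n, 4))
  expect_equal(max(abs(common_average_reference(same)$data)), 0)
})

test_that("band-pass keeps the passband and rejects DC and high frequency", {
  rate <- 500
  n <- rate * 20
  t <- (0:(n - 1)) / rate
  core <- 3000:7000
  s25 <- mk_session(cbind(sin(2 * pi * 25 * t)), rate = rate, labels = "L1")
  out <- bandpass_session(s25, 1, 50)
  expect_lt(abs(20 * log10(sine_amp(out$data[core, 1], rate, 25))), 1)

  s100 <- mk_session(cbind(sin(2 * pi * 100 * t)), rate = rate, labels = "L1")
  out100 <- bandpass_session(s100, 1, 50)
  expect_lt(20 * log10(sine_amp(out100$data[core, 1], rate, 100)), -20)

  sdc <- mk_session(cbind(rep(2, n) + 0.1 * sin(2 * pi * 10 * t)),
                    rate = rate, labels = "L1")
  outdc <- bandpass_session(sdc, 1, 50)
  expect_lt(abs(mean(outdc$data[core, 1])), 0.02) # >= 20 dB down on DC = 2

  expect_error(bandpass_session(s25, 50, 1), "invalid band")
})

test_that("epoching cuts the fixed grid, drops edge trials and permits
           overlap", {
  rate <- 500
  n <- rate * 200
  s <- mk_session(matrix(rnorm(4 * n), n, 4))
  onsets <- seq(5, 185, by = 2)[1:90]
  ann <- data.frame(trial_id = 1:90, task = rep(c("vowel", "ddk", "sentence"),
                                                30),
                    onset_s = onsets, offset_s = onsets + 1)
  ep <- epoch_session(s, ann)
  expect_equal(dim(ep$data), c(90, 4, 1501))
  expect_equal(ep$time_ms, seq(-2000, 1000, by = 2))
  expect_equal(nrow(ep$rejected), 0)
  # t = 0 sample equals the recording sample nearest the onset
  expect_equal(ep$data[1, 1, which(ep$time_ms == 0)],
               s$data[round(onsets[1] * rate) + 1, 1])

  # onset too close to the start is dropped and reported
  ann_bad <- rbind(data.frame(trial_id = 0, task = "vowel", onset_s = 0.5,
                              offset_s = 1.2), ann)
  expect_warning(ep2 <- epoch_session(s, ann_bad), "dropped")
  expect_equal(nrow(ep2$rejected), 1)
  expect_equal(dim(ep2$data)[1], 90)

  # overlapping epochs duplicate shared samples
  ann_ov <- data.frame(trial_id = 1:2, task = c("vowel", "ddk"),
                       onset_s = c(10, 11), offset_s = c(10.9, 11.9))
  ep3 <- epoch_session(s, ann_ov)
  # trial 1's 0..1000 ms and trial 2's -1000..0 ms are the same recording span
  sh1 <- ep3$data[1, 1, ep3$time_ms >= 0]
  sh2 <- ep3$data[2, 1, ep3$time_ms >= -1000 & ep3$time_ms <= 0]
  expect_equal(sh1, sh2)
})

test_that("epoch guard context carries real samples and trims at bounds", {
  rate <- 500
  n <- rate * 30
  s <- mk_session(matrix(rnorm(4 * n), n, 4))
  ann <- data.frame(trial_id = 1:2, task = c("vowel", "ddk"),
                    onset_s = c(10, 14), offset_s = c(11, 15))
  ep <- epoch_session(s, ann, guard_ms = 1000)
  expect_equal(unname(ep$guard_n), c(500L, 500L))
  expect_equal(dim(ep$guard)[3], 1501 + 1000)
  expect_equal(ep$guard[1, 1, 501:2001], ep$data[1, 1, ])
  expect_equal(ep$guard[1, 2, 1],
               s$data[round(10 * rate) + 1 - 1000 - 500, 2])

  ann_edge <- data.frame(trial_id = 1, task = "vowel", onset_s = 2.2,
                         offset_s = 3)
  expect_message(ep2 <- epoch_session(s, ann_edge, guard_ms = 1000),
                 "guard trimmed")
  expect_lt(ep2$guard_n[["pre"]], 500L)
})
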