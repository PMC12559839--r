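suppress_res_warn <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("too coarse", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

test_that("surrogate null has the right shape, degenerate and CLT
           behaviour", {
  freqs <- c(4, 20)
  const <- mk_tensor(array(3.25, c(2, 1501, 8)), freqs)
  nl <- suppress_res_warn(build_null(const, n_shuffles = 250, seed = 1))
  expect_equal(dim(nl$draws), c(250, 2))
  expect_true(all(nl$draws == 3.25))

  # i.i.d. N(0,1) pixels, 40 trials: surrogate SD ~ 1/sqrt(40) within 20%
  arr <- withr::with_seed(5, array(rnorm(2 * 1501 * 40), c(2, 1501, 40)))
  tns <- mk_tensor(arr, freqs)
  nl2 <- build_null(tns, n_shuffles = 2241, seed = 2)
  for (f in 1:2) {
    expect_lt(abs(sd(nl2$draws[, f]) / (1 / sqrt(40)) - 1), 0.2)
  }

  expect_identical(build_null(tns, n_shuffles = 2241, seed = 9)$draws,
                   build_null(tns, n_shuffles = 2241, seed = 9)$draws)
  expect_warning(build_null(tns, n_shuffles = 500, seed = 1), "too coarse")
  expect_error(build_null(tns, n_shuffles = 100), "at least 200")
  expect_error(build_null(tns, baseline_window_ms = c(-9000, -8000)),
               "outside epoch")
})

test_that("pixel p-values follow the add-one two-tailed counting formula", {
  freqs <- c(4, 20)
  nl <- structure(list(
    draws = cbind(seq_len(2241) / 100, seq_len(2241) / 100),
    freqs = freqs, baseline_window_ms = c(-1000, -500),
    n_shuffles = 2241L, seed = 1L, n_participants = 1L),
    class = "surrogate_null")
  obs <- structure(list(power = matrix(c(-5, -5, 11.205, 11.205), 2, 2),
                        freqs = freqs, time_ms = c(0, 2), level = "grand",
                        condition = NA_character_), class = "tf_map")
  p <- pixel_p(obs, nl)
  expect_equal(p[1, 1], 2 / 2242) # below every draw
  expect_equal(p[1, 2], 1)        # at the median, capped
  expect_true(all(p > 0 & p <= 1))

  # exact tie counting: observed equal to k draws counts them on both sides
  nl2 <- nl
  nl2$draws <- matrix(rep(c(1, 2, 2, 3), 2241 / 4 * 2)[1:(2241 * 2)],
                      2241, 2)
  obs2 <- obs
  obs2$power <- matrix(2, 2, 2)
  p2 <- pixel_p(obs2, nl2)
  expect_true(all(p2 > 0.5))
})

test_that("thresholding respects alpha, the evaluation window and
           boundaries", {
  freqs <- c(4, 20)
  arr <- withr::with_seed(6, array(rnorm(2 * 1501 * 20), c(2, 1501, 20)))
  tns <- mk_tensor(arr, freqs)
  obs <- average_maps(tns, "trials")
  nl <- build_null(tns, n_shuffles = 2241, seed = 3)
  th <- threshold_map(obs, nl, alpha = 0.001)
  out_win <- obs$time_ms < -500 | obs$time_ms > 1000
  expect_false(any(th$mask[, out_win]))
  expect_true(all(th$masked_power[!th$mask] == 0))

  th_all <- threshold_map(obs, nl, alpha = 1)
  expect_true(all(th_all$mask[, !out_win]))
})

test_that("contrasts are antisymmetric, null for identical input, and detect
           injected differences", {
  freqs <- c(4, 20)
  arr <- withr::with_seed(7, array(rnorm(2 * 1501 * 30), c(2, 1501, 30)))
  tns <- mk_tensor(arr, freqs)

  same <- contrast_maps(list(P1 = tns), list(P1 = tns), n_shuffles = 2241,
                        seed = 4)
  expect_equal(max(abs(same$map$power)), 0)
  expect_false(any(same$mask))

  # A carries a +3 dB offset after t = 0 in the first frequency row
  arr_b <- withr::with_seed(8, array(rnorm(2 * 1501 * 30), c(2, 1501, 30)))
  arr_a <- arr_b
  arr_a[1, std_time_ms >= 0, ] <- arr_a[1, std_time_ms >= 0, ] + 3
  ta <- mk_tensor(arr_a, freqs)
  tb <- mk_tensor(arr_b, freqs)
  ab <- contrast_maps(list(P1 = ta), list(P1 = tb), n_shuffles = 2241,
                      seed = 5)
  ba <- contrast_maps(list(P1 = tb), list(P1 = ta), n_shuffles = 2241,
                      seed = 5)
  expect_equal(ab$map$power, -ba$map$power)
  post <- std_time_ms >= 100 & std_time_ms <= 1000
  expect_gt(mean(ab$mask[1, post]), 0.9)
  expect_lt(mean(ab$mask[2, post]), 0.05)
  expect_true(all(ab$map$power[1, post] > 0))

  expect_error(contrast_maps(list(P1 = ta, P2 = tb), list(P1 = tb)),
               "participant sets differ")
})

test_that("significant-pixel counts grow with injected effect size", {
  # same background seed, three effect levels, one session each
  counts <- integer(3)
  levels_db <- c(0, 3, 6)
  bank <- build_wavelet_bank(n_freqs = 25)
  for (i in seq_along(levels_db)) {
    cfg <- synth_config(
      n_participants = 1, trials_per_task = 30,
      theta_effect_db = c(vowel = 0, ddk = 0, sentence = levels_db[i]),
      beta_effect_db = c(vowel = 0, ddk = 0, sentence = 0),
      participant_sd_db = 0, seed = 77)
    gs <- generate_session(cfg, "P01", "left", seed = 77)
    ep <- preprocess_session(gs$session, gs$annotations, line_hz = NULL)
    dbt <- db_normalize(wavelet_power(ep, bank, channels = 1))
    obs <- average_maps(dbt, "trials",
                        trials = which(dbt$tasks == "sentence"))
    tns_s <- dbt
    keep <- which(dbt$tasks == "sentence")
    tns_s$power <- tns_s$power[, , keep, , drop = FALSE]
    tns_s$tasks <- tns_s$tasks[keep]
    nl <- build_null(tns_s, n_shuffles = 2241, seed = 11)
    th <- threshold_map(obs, nl)
    fidx <- bank$freqs >= 1 & bank$freqs <= 8
    tidx <- obs$time_ms >= 0 & obs$time_ms <= 1000
    counts[i] <- sum(th$mask[fidx, tidx] & obs$power[fidx, tidx] > 0)
  }
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[3], counts[1])
})
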