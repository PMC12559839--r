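#' Build a shuffled-baseline surrogate null distribution
#'
#' For each of `n_shuffles` iterations and each frequency, blocks of
#' `block_len` chronologically consecutive trials are resampled with
#' replacement (moving-block bootstrap) and one baseline latency is drawn
#' uniformly from the baseline window (open-left, closed-right; default
#' (-1000, -500] ms) per block; each resampled trial contributes its dB
#' value at its block's latency, and the values are averaged to give one
#' surrogate statistic. The per-frequency empirical distribution mirrors how
#' the observed statistic (the trial-averaged map) is formed.
#'
#' Two departures from a plain per-trial time shuffle matter for
#' calibration. First, trials must be resampled, not held fixed: wavelet
#' smoothing at low frequencies exceeds the 500 ms baseline, so time draws
#' within a fixed trial set barely vary and the null's spread collapses far
#' below the true variability of a map pixel. Second, the resampling must
#' respect the dependence of neighbouring trials: with realistic inter-trial
#' intervals, 3 s epochs overlap, and power values of adjacent trials at the
#' same perievent latency are correlated at low frequencies; blocks with a
#' shared latency carry that covariance into the null, where independent
#' per-trial draws would understate it. `resample_trials = FALSE` reproduces
#' the plain time-shuffle scheme; `block_len = 1` gives an independent
#' per-trial bootstrap.
#'
#' For a group-level null, pass a list of per-participant tensors: each
#' participant contributes its own surrogate draws (derived seeds), and each
#' group draw averages a with-replacement resample of participants
#' (hierarchical bootstrap), mirroring the grand-average observed statistic
#' under resampling of its independent units. Without participant
#' resampling the null would carry no between-participant variance and the
#' grand-average test becomes anti-conservative wherever slow power
#' fluctuations shift whole participants between the baseline and
#' evaluation windows.
#'
#' @param x a dB `trial_power_tensor`, or a list of them (one per
#'   participant).
#' @param baseline_window_ms baseline window, ms; samples strictly after the
#'   left edge up to and including the right edge are eligible.
#' @param n_shuffles number of surrogate draws (default 2,241). Below 2,000
#'   the smallest attainable two-tailed p exceeds typical map thresholds
#'   (alpha = 0.001), so a warning fires; below 200 it is an error.
#' @param seed integer seed.
#' @param channel channel label or index of the tensor(s) to use.
#' @param resample_trials resample trials with replacement in each draw
#'   (recommended; see above).
#' @param block_len trials per resampled block (1 = independent trials).
#' @param resample_participants resample participants with replacement in
#'   each group draw (recommended; ignored for a single tensor).
#' @return a `surrogate_null`: `draws` (`n_shuffles x n_freq` matrix),
#'   frequency axis, window, seed.
#' @export
build_null <- function(x, baseline_window_ms = c(-1000, -500),
                       n_shuffles = 2241, seed = 1L, channel = 1L,
                       resample_trials = TRUE, block_len = 5L,
                       resample_participants = TRUE) {
  if (n_shuffles < 200) {
    stop("n_shuffles must be at least 200", call. = FALSE)
  }
  if (n_shuffles < 2000) {
    warning(sprintf(
      "n_shuffles = %d: smallest two-tailed p = %.2g; too coarse for alpha = 0.001",
      n_shuffles, 2 / (n_shuffles + 1)), call. = FALSE)
  }
  if (inherits(x, "trial_power_tensor")) x <- list(x)
  stopifnot(all(vapply(x, inherits, logical(1), "trial_power_tensor")))
  if (any(vapply(x, `[[`, character(1), "scale") != "db")) {
    stop("surrogate null expects dB-normalized tensors", call. = FALSE)
  }
  freqs <- x[[1]]$freqs
  per_part <- lapply(seq_along(x), function(p)
    one_null(x[[p]], baseline_window_ms, n_shuffles,
             derive_seed(seed, p), channel, resample_trials, block_len))
  draws <- pool_null(per_part, n_shuffles, derive_seed(seed, 0L),
                     resample_participants)
  structure(list(draws = draws, freqs = freqs,
                 baseline_window_ms = baseline_window_ms,
                 n_shuffles = as.integer(n_shuffles), seed = as.integer(seed),
                 n_participants = length(x)),
            class = "surrogate_null")
}

# average per-participant draw matrices into group draws, resampling
# participants with replacement per shuffle when requested
pool_null <- function(per_part, n_shuffles, seed, resample_participants) {
  n_p <- length(per_part)
  if (n_p == 1) return(per_part[[1]])
  if (!resample_participants) {
    return(Reduce(`+`, per_part) / n_p)
  }
  acc <- matrix(0, n_shuffles, ncol(per_part[[1]]))
  w <- withr::with_seed(as.integer(seed), {
    picks <- sample.int(n_p, n_p * n_shuffles, replace = TRUE)
    vapply(seq_len(n_p), function(p)
      colSums(matrix(picks == p, n_p, n_shuffles)), numeric(n_shuffles))
  })
  for (p in seq_len(n_p)) {
    acc <- acc + per_part[[p]] * (w[, p] / n_p)
  }
  acc
}

one_null <- function(tensor, baseline_window_ms, n_shuffles, seed, channel,
                     resample_trials = TRUE, block_len = 5L) {
  if (is.character(channel)) channel <- match(channel, tensor$labels)
  bidx <- idx_open_left(tensor$time_ms, baseline_window_ms)
  if (length(bidx) == 0) {
    stop("baseline window outside epoch", call. = FALSE)
  }
  n_trials <- dim(tensor$power)[3]
  if (n_trials < 2) stop("need at least 2 trials", call. = FALSE)
  n_f <- length(tensor$freqs)
  n_b <- length(bidx)
  b_len <- max(1L, min(as.integer(block_len), n_trials))
  n_blocks <- ceiling(n_trials / b_len)
  draws <- matrix(NA_real_, n_shuffles, n_f)
  withr::with_seed(as.integer(seed), {
    for (f in seq_len(n_f)) {
      b <- matrix(tensor$power[f, bidx, , channel], nrow = n_b)
      if (!resample_trials) {
        pick <- sample.int(n_b, n_trials * n_shuffles, replace = TRUE)
        vals <- b[cbind(pick, rep(seq_len(n_trials), times = n_shuffles))]
        draws[, f] <- colMeans(matrix(vals, n_trials, n_shuffles))
      } else {
        starts <- sample.int(n_trials - b_len + 1L, n_blocks * n_shuffles,
                             replace = TRUE)
        tau <- sample.int(n_b, n_blocks * n_shuffles, replace = TRUE)
        acc <- numeric(n_blocks * n_shuffles)
        for (o in 0:(b_len - 1L)) {
          acc <- acc + b[cbind(tau, starts + o)]
        }
        draws[, f] <- colSums(matrix(acc, n_blocks, n_shuffles)) /
          (n_blocks * b_len)
      }
    }
  })
  draws
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf(
    "<surrogate_null> %d draws x %d freqs, baseline (%g, %g] ms, %d participant(s)\n",
    x$n_shuffles, length(x$freqs), x$baseline_window_ms[1],
    x$baseline_window_ms[2], x$n_participants))
  invisible(x)
}

#' Pixel-wise two-tailed surrogate p-values
#'
#' For each pixel, the p-value is the add-one permutation estimate
#' `p = 2 * min((1 + #\{draws >= obs\}) / (n + 1),
#' (1 + #\{draws <= obs\}) / (n + 1))`, capped at 1, so p is never zero and
#' the smallest attainable value at n draws is `2 / (n + 1)`.
#'
#' @param observed a `tf_map`.
#' @param null a `surrogate_null` on the same frequency axis.
#' @return matrix of p-values, `freq x time`, values in (0, 1].
#' @export
pixel_p <- function(observed, null) {
  stopifnot(inherits(observed, "tf_map"), inherits(null, "surrogate_null"))
  if (!isTRUE(all.equal(observed$freqs, null$freqs))) {
    stop("frequency axes differ between map and null", call. = FALSE)
  }
  n <- null$n_shuffles
  p <- matrix(NA_real_, nrow(observed$power), ncol(observed$power))
  for (f in seq_len(nrow(p))) {
    s <- sort(null$draws[, f])
    obs <- observed$power[f, ]
    n_leq <- findInterval(obs, s)
    n_lt <- findInterval(obs, s, left.open = TRUE)
    n_geq <- n - n_lt
    p[f, ] <- pmin(1, 2 * pmin((1 + n_geq) / (n + 1), (1 + n_leq) / (n + 1)))
  }
  p
}

#' Threshold a map against its surrogate null
#'
#' Pixels with two-tailed surrogate p below `alpha` (default 0.001,
#' uncorrected) are marked significant; evaluation is restricted to
#' `eval_window_ms` (default -500..+1000 ms) and pixels outside it are never
#' marked. `alpha >= 1` disables thresholding (every evaluated pixel marked).
#'
#' @param observed a `tf_map`.
#' @param null a `surrogate_null`.
#' @param alpha significance level (exclusive bound on p).
#' @param eval_window_ms window over which statistics are evaluated, ms.
#' @return a `thresholded_tf_map`: the map, p-value matrix, logical mask,
#'   `masked_power` (non-significant pixels set to 0 dB), alpha, window.
#' @export
threshold_map <- function(observed, null, alpha = 0.001,
                          eval_window_ms = c(-500, 1000)) {
  p <- pixel_p(observed, null)
  in_win <- observed$time_ms >= eval_window_ms[1] &
    observed$time_ms <= eval_window_ms[2]
  mask <- if (alpha >= 1) p <= 1 else p < alpha
  mask <- sweep(mask, 2, in_win, `&`)
  masked <- observed$power
  masked[!mask] <- 0
  structure(list(map = observed, p = p, mask = mask, masked_power = masked,
                 alpha = alpha, eval_window_ms = eval_window_ms),
            class = "thresholded_tf_map")
}

#' @export
print.thresholded_tf_map <- function(x, ...) {
  in_win <- x$map$time_ms >= x$eval_window_ms[1] &
    x$map$time_ms <= x$eval_window_ms[2]
  n_eval <- sum(in_win) * nrow(x$p)
  cat(sprintf(
    "<thresholded_tf_map> alpha = %g: %d / %d evaluated pixels significant\n",
    x$alpha, sum(x$mask), n_eval))
  invisible(x)
}

#' Between-condition surrogate contrast
#'
#' The observed statistic is the participant-averaged difference of
#' unthresholded per-participant maps (condition A minus condition B). The
#' null is built by the same shuffle scheme on each participant's two
#' tensors: per shuffle, a baseline draw from A minus an independent baseline
#' draw from B, averaged across participants. The difference map is then
#' thresholded two-tailed as in [threshold_map()].
#'
#' @param tensors_a,tensors_b named lists of dB `trial_power_tensor`s, one
#'   per participant, with identical name sets. For single-tensor input
#'   (one participant) pass length-1 lists.
#' @param tasks_a,tasks_b optional task label selecting the trials used from
#'   each tensor (tensors may hold all tasks of a session).
#' @param n_shuffles,seed,alpha,channel,baseline_window_ms,eval_window_ms as
#'   in [build_null()] and [threshold_map()].
#' @return a `thresholded_tf_map` of the A - B difference; the unthresholded
#'   difference map is in `$map`.
#' @export
contrast_maps <- function(tensors_a, tensors_b, tasks_a = NULL,
                          tasks_b = NULL, n_shuffles = 2241, seed = 1L,
                          alpha = 0.001, channel = 1L,
                          baseline_window_ms = c(-1000, -500),
                          eval_window_ms = c(-500, 1000)) {
  if (n_shuffles < 200) stop("n_shuffles must be at least 200", call. = FALSE)
  if (n_shuffles < 2000) {
    warning(sprintf(
      "n_shuffles = %d: smallest two-tailed p = %.2g; too coarse for alpha = 0.001",
      n_shuffles, 2 / (n_shuffles + 1)), call. = FALSE)
  }
  if (inherits(tensors_a, "trial_power_tensor")) tensors_a <- list(tensors_a)
  if (inherits(tensors_b, "trial_power_tensor")) tensors_b <- list(tensors_b)
  if (length(tensors_a) != length(tensors_b)) {
    stop("participant sets differ between conditions", call. = FALSE)
  }
  if (!is.null(names(tensors_a)) && !is.null(names(tensors_b)) &&
      !setequal(names(tensors_a), names(tensors_b))) {
    stop("participant sets differ between conditions", call. = FALSE)
  }
  if (!is.null(names(tensors_b)) && !is.null(names(tensors_a))) {
    tensors_b <- tensors_b[names(tensors_a)]
  }
  sel <- function(tensor, task) {
    if (is.null(task)) seq_len(dim(tensor$power)[3]) else
      which(tensor$tasks == task)
  }
  maps_a <- lapply(tensors_a, function(tns)
    average_maps(tns, "trials", trials = sel(tns, tasks_a), channel = channel))
  maps_b <- lapply(tensors_b, function(tns)
    average_maps(tns, "trials", trials = sel(tns, tasks_b), channel = channel))
  diff_maps <- Map(function(a, b) {
    a$power <- a$power - b$power
    a
  }, maps_a, maps_b)
  observed <- average_maps(unname(diff_maps), "participants",
                           condition = "difference")

  # per-participant difference draws (A and B drawn independently within
  # each participant), then pooled with participant resampling so the group
  # null mirrors the participant-averaged observed difference
  ta <- restrict_trials(tensors_a, tasks_a)
  tb <- restrict_trials(tensors_b, tasks_b)
  per_part <- lapply(seq_along(ta), function(p)
    one_null(ta[[p]], baseline_window_ms, n_shuffles,
             derive_seed(seed, 2L * p), channel) -
      one_null(tb[[p]], baseline_window_ms, n_shuffles,
               derive_seed(seed, 2L * p + 1L), channel))
  null <- structure(list(
    draws = pool_null(per_part, n_shuffles, derive_seed(seed, 0L), TRUE),
    freqs = observed$freqs, baseline_window_ms = baseline_window_ms,
    n_shuffles = as.integer(n_shuffles), seed = as.integer(seed),
    n_participants = length(ta)), class = "surrogate_null")
  threshold_map(observed, null, alpha, eval_window_ms)
}

restrict_trials <- function(tensors, task) {
  if (is.null(task)) return(tensors)
  lapply(tensors, function(tns) {
    keep <- which(tns$tasks == task)
    tns$power <- tns$power[, , keep, , drop = FALSE]
    tns$tasks <- tns$tasks[keep]
    tns
  })
}
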