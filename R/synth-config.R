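#' Configuration for the synthetic LFP cohort generator
#'
#' Defines the study conditions the simulator emulates: an awake intraoperative
#' speech protocol with three tasks of graded motor complexity (sustained
#' vowel, diadochokinesis "DDK", sentence repetition), bilateral four-contact
#' (or eight-contact segmented) DBS leads, a 1/f voltage background, and
#' event-locked band-limited power modulations whose size is graded by task.
#'
#' Defaults mirror the recording protocol the package targets: raw sampling at
#' 2,000 Hz, 30 trials per task (protocols collect 30-50), inter-trial
#' intervals with mean 1.5 s, SD 0.6 s, truncated to 0.8-3.1 s, and median-like
#' trial durations of 0.96 / 1.27 / 1.60 s for vowel / DDK / sentence.
#' Injected effect sizes are free parameters of the simulator (field data do
#' not pin them down in dB); the defaults grade delta/theta (1-8 Hz) increases
#' during speech as +1 / +2.5 / +3 dB and prespeech beta (13-30 Hz) decreases
#' as -0.5 / -1 / -2 dB for vowel / DDK / sentence.
#'
#' @param n_participants number of participants (each contributes two
#'   hemispheres).
#' @param trials_per_task trials collected per task per session.
#' @param sampling_rate_hz raw acquisition rate in Hz.
#' @param lead_model `"four_contact"` or `"eight_contact_segmented"` (middle
#'   two rows split into three radial segments, labels 1, 2A-2C, 3A-3C, 4).
#' @param pink_exponent spectral slope alpha of the background
#'   (power ~ 1/f^alpha), in `[0, 2]`.
#' @param theta_effect_db named numeric (vowel, ddk, sentence): dB change in
#'   1-8 Hz power during 0..+1000 ms after speech onset.
#' @param beta_effect_db named numeric: dB change in 13-30 Hz power during
#'   -500..0 ms before onset (negative = desynchronization).
#' @param trial_duration_s named list of `c(mean, sd)` seconds per task.
#' @param iti_s list with `mean`, `sd`, `min`, `max` seconds for inter-trial
#'   intervals (truncated normal).
#' @param participant_sd_db SD of the participant-level dB offset added to
#'   every injected effect (gives the mixed model's random intercept something
#'   to estimate).
#' @param background_sd standard deviation of the background voltage series
#'   (arbitrary units).
#' @param seed integer seed; all per-participant and per-channel seeds are
#'   derived from it.
#' @return an object of class `synth_config`.
#' @seealso [generate_session()], [generate_cohort()]
#' @export
synth_config <- function(n_participants = 13,
                         trials_per_task = 30,
                         sampling_rate_hz = 2000,
                         lead_model = c("four_contact",
                                        "eight_contact_segmented"),
                         pink_exponent = 1,
                         theta_effect_db = c(vowel = 1, ddk = 2.5,
                                             sentence = 3),
                         beta_effect_db = c(vowel = -0.5, ddk = -1,
                                            sentence = -2),
                         trial_duration_s = list(
                           vowel = c(mean = 0.96, sd = 0.15),
                           ddk = c(mean = 1.27, sd = 0.15),
                           sentence = c(mean = 1.60, sd = 0.15)),
                         iti_s = list(mean = 1.5, sd = 0.6,
                                      min = 0.8, max = 3.1),
                         participant_sd_db = 0.5,
                         background_sd = 10,
                         seed = 1L) {
  lead_model <- match.arg(lead_model)
  tasks <- c("vowel", "ddk", "sentence")
  stopifnot(
    n_participants >= 1,
    trials_per_task >= 2,
    sampling_rate_hz >= 100, # >= 2 x 50 Hz analysis band
    pink_exponent >= 0, pink_exponent <= 2,
    all(tasks %in% names(theta_effect_db)),
    all(tasks %in% names(beta_effect_db)),
    all(tasks %in% names(trial_duration_s)),
    all(c("mean", "sd", "min", "max") %in% names(iti_s)),
    iti_s$min > 0, iti_s$sd >= 0, iti_s$max >= iti_s$min,
    all(vapply(trial_duration_s, function(d) d[["sd"]] >= 0, logical(1))),
    participant_sd_db >= 0, background_sd > 0
  )
  if (trials_per_task < 30 || trials_per_task > 50) {
    message("trials_per_task outside the typical 30-50 protocol range")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    trials_per_task = as.integer(trials_per_task),
    sampling_rate_hz = sampling_rate_hz,
    lead_model = lead_model,
    pink_exponent = pink_exponent,
    theta_effect_db = theta_effect_db[tasks],
    beta_effect_db = beta_effect_db[tasks],
    theta_band = c(1, 8), theta_window_ms = c(0, 1000),
    beta_band = c(13, 30), beta_window_ms = c(-500, 0),
    trial_duration_s = trial_duration_s[tasks],
    iti_s = iti_s,
    participant_sd_db = participant_sd_db,
    background_sd = background_sd,
    seed = as.integer(seed),
    tasks = tasks
  ), class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n",
      sprintf("  %d participants x 2 hemispheres, %d trials/task, %s lead\n",
              x$n_participants, x$trials_per_task, x$lead_model),
      sprintf("  raw rate %g Hz, 1/f^%.2g background\n",
              x$sampling_rate_hz, x$pink_exponent),
      sprintf("  theta (1-8 Hz, 0..1000 ms) dB: %s\n",
              paste(sprintf("%s %+g", names(x$theta_effect_db),
                            x$theta_effect_db), collapse = ", ")),
      sprintf("  beta (13-30 Hz, -500..0 ms) dB: %s\n",
              paste(sprintf("%s %+g", names(x$beta_effect_db),
                            x$beta_effect_db), collapse = ", ")),
      sprintf("  seed %d\n", x$seed), sep = "")
  invisible(x)
}

segmented_labels <- c("1", "2A", "2B", "2C", "3A", "3B", "3C", "4")
contact_labels <- c("1", "2", "3", "4")
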