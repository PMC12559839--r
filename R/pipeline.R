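PIPELINE_KEYS <- c(
  "n_participants", "trials_per_task", "sampling_rate_hz", "lead_model",
  "pink_exponent", "theta_effect_db", "beta_effect_db", "trial_duration_s",
  "iti_s", "participant_sd_db", "background_sd", "seed",
  "target_rate", "line_hz", "band", "epoch_window_ms",
  "n_freqs", "n_shuffles", "alpha", "stats_channel", "contrasts",
  "out_dir")

#' Build a validated pipeline configuration
#'
#' One object drives the full run: the synthetic-cohort parameters (see
#' [synth_config()]) plus the analysis-stage parameters. Unknown keys are
#' rejected. The configuration round-trips losslessly through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param ... any of: the [synth_config()] arguments; `target_rate` (500),
#'   `line_hz` (NULL: the synthetic background carries no mains noise),
#'   `band` (c(1, 50)), `epoch_window_ms` (c(-2000, 1000)), `n_freqs` (50),
#'   `n_shuffles` (2241), `alpha` (0.001), `stats_channel` (1, the contact
#'   used for the surrogate maps), `contrasts` (list of c(A, B) task pairs),
#'   `out_dir` (NULL keeps results in memory only).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  args <- list(...)
  unknown <- setdiff(names(args), PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(
    target_rate = 500, line_hz = NULL, band = c(1, 50),
    epoch_window_ms = c(-2000, 1000), n_freqs = 50, n_shuffles = 2241,
    alpha = 0.001, stats_channel = 1L,
    contrasts = list(c("sentence", "vowel"), c("ddk", "vowel"),
                     c("sentence", "ddk")),
    out_dir = NULL)
  analysis <- defaults
  override <- args[names(args) %in% names(defaults)]
  analysis[names(override)] <- override
  synth_args <- args[setdiff(names(args), names(defaults))]
  cfg <- c(list(synth = do.call(synth_config, synth_args)), analysis)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  flat <- unclass(config)
  synth <- flat$synth
  flat$synth <- NULL
  keep <- c("n_participants", "trials_per_task", "sampling_rate_hz",
            "lead_model", "pink_exponent", "theta_effect_db",
            "beta_effect_db", "trial_duration_s", "iti_s",
            "participant_sd_db", "background_sd", "seed")
  flat <- c(lapply(synth[keep], function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else
      if (is.list(v)) lapply(v, as.list) else v), flat)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` (for writing).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in c("theta_effect_db", "beta_effect_db")) {
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  }
  for (k in c("trial_duration_s", "iti_s")) {
    if (!is.null(raw[[k]])) {
      raw[[k]] <- if (k == "iti_s") as.list(unlist(raw[[k]])) else
        lapply(raw[[k]], unlist)
    }
  }
  if (!is.null(raw$iti_s)) raw$iti_s <- lapply(raw$iti_s, as.numeric)
  if (!is.null(raw$contrasts)) {
    raw$contrasts <- lapply(raw$contrasts, unlist)
  }
  if (!is.null(raw$band)) raw$band <- as.numeric(unlist(raw$band))
  if (!is.null(raw$epoch_window_ms)) {
    raw$epoch_window_ms <- as.numeric(unlist(raw$epoch_window_ms))
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> preprocess -> wavelet decomposition + dB normalization ->
#' surrogate-thresholded maps and task contrasts (on `stats_channel`) ->
#' band-power summary -> mixed-effects models for each band x window.
#' Deterministic for a fixed config (including seed). When `out_dir` is set,
#' tables and results are written as CSV/JSON and a run manifest (config
#' snapshot, package version, per-file MD5 checksums, timestamps) is written
#' last.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result`: `bandpower` table, `lme` (list per band x
#'   window: anova data.frame + follow-ups), `within` (per-task thresholded
#'   grand maps), `contrasts` (thresholded difference maps), `maps`
#'   (per-session per-task participant maps), `rejections`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  sc <- config$synth
  cohort <- generate_cohort(sc)
  bank <- build_wavelet_bank(config$band[1], config$band[2],
                             n_freqs = config$n_freqs,
                             rate = config$target_rate)
  tasks <- sc$tasks

  map_records <- list()
  stat_tensors <- stats::setNames(
    vector("list", length(cohort$sessions)), names(cohort$sessions))
  rejections <- list()
  for (sn in names(cohort$sessions)) {
    s <- cohort$sessions[[sn]]
    epochs <- preprocess_session(
      s$session, s$annotations, target_rate = config$target_rate,
      line_hz = config$line_hz, band = config$band,
      window_ms = config$epoch_window_ms)
    rejections[[sn]] <- epochs$rejected
    for (ch in seq_along(epochs$labels)) {
      tensor <- db_normalize(wavelet_power(epochs, bank, channels = ch))
      if (ch == config$stats_channel) stat_tensors[[sn]] <- tensor
      for (task in tasks) {
        idx <- which(tensor$tasks == task)
        map_records[[length(map_records) + 1]] <- list(
          participant = s$session$participant_id,
          hemisphere = s$session$hemisphere,
          contact = sub("^[LR]", "", epochs$labels[ch]),
          task = task,
          map = average_maps(tensor, "trials", trials = idx,
                             condition = task))
      }
    }
  }

  # surrogate maps per task (grand level, stats_channel, left hemisphere
  # tensors pooled with right via the per-session list)
  within <- list()
  for (task in tasks) {
    obs <- average_maps(
      unname(lapply(map_records[vapply(map_records, function(r)
        r$task == task &&
          r$contact == sub("^[LR]", "", stat_tensors[[1]]$labels[1]),
        logical(1))], `[[`, "map")), "participants", condition = task)
    null <- build_null(
      restrict_trials(unname(stat_tensors), task),
      n_shuffles = config$n_shuffles,
      seed = derive_seed(sc$seed, 300L + match(task, tasks)))
    within[[task]] <- threshold_map(obs, null, alpha = config$alpha)
  }

  contrasts <- list()
  for (pair in config$contrasts) {
    nm <- paste(pair, collapse = "-")
    contrasts[[nm]] <- contrast_maps(
      unname(stat_tensors), unname(stat_tensors),
      tasks_a = pair[1], tasks_b = pair[2],
      n_shuffles = config$n_shuffles,
      seed = derive_seed(sc$seed, 400L + which(vapply(
        config$contrasts, identical, logical(1), pair))),
      alpha = config$alpha)
  }

  bandpower <- summarize_bandpower(map_records)
  lme <- list()
  for (bn in unique(bandpower$band)) {
    for (wn in unique(bandpower$window)) {
      fit <- fit_bandpower_lme(bandpower, band = bn, window = wn)
      lme[[paste(bn, wn, sep = "_")]] <- list(
        anova = fit$anova, singular = fit$singular,
        followups = followup_contrasts(fit))
    }
  }

  result <- structure(list(
    bandpower = bandpower, lme = lme, within = within,
    contrasts = contrasts, maps = map_records, rejections = rejections,
    config = config, manifest = NULL), class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    result$manifest <- write_pipeline_outputs(result, config, t0)
  }
  result
}

write_pipeline_outputs <- function(result, config, t0) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p <- function(f) file.path(config$out_dir, f)

  utils::write.csv(result$bandpower, p("bandpower.csv"), row.names = FALSE)
  files <- c(files, p("bandpower.csv"))
  for (nm in names(result$lme)) {
    f <- p(sprintf("lme_%s.csv", nm))
    utils::write.csv(result$lme[[nm]]$anova, f, row.names = FALSE)
    files <- c(files, f)
    f2 <- p(sprintf("lme_%s_followups.csv", nm))
    utils::write.csv(result$lme[[nm]]$followups, f2, row.names = FALSE)
    files <- c(files, f2)
  }
  jsonlite::write_json(
    lapply(result$lme, function(x)
      list(anova = x$anova, singular = x$singular)),
    p("lme.json"), auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(files, p("lme.json"))
  rej <- do.call(rbind, result$rejections)
  jsonlite::write_json(
    list(n_rejected = if (is.null(rej)) 0L else nrow(rej)),
    p("rejections.json"), auto_unbox = TRUE)
  files <- c(files, p("rejections.json"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("speechersp")),
    seed = config$synth$seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    files = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d band-power rows, %d LME cells, %d contrasts\n",
    nrow(x$bandpower), length(x$lme), length(x$contrasts)))
  invisible(x)
}
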