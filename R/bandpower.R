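#' Summarize time-frequency maps into band x window mean power
#'
#' Averages dB pixels over the delta/theta (1-8 Hz) and beta (13-30 Hz)
#' bands (inclusive frequency bounds) in the prespeech (-500..0 ms) and
#' during-speech (0..1000 ms) windows. Window intervals are half-open /
#' closed: prespeech is `[-500, 0)` and during is `[0, 1000]`, so the onset
#' sample belongs to the during-speech window. One row per participant x
#' hemisphere x contact x task x band x window.
#'
#' @param maps a data.frame-like list of records, or a list where each
#'   element is a list with fields `participant`, `hemisphere`, `contact`,
#'   `task` and `map` (a `tf_map`).
#' @param bands named list of `c(low, high)` Hz.
#' @param windows named list of `c(start, end)` ms; the first window is
#'   treated as `[start, end)`, windows starting at 0 as `[start, end]`.
#' @return a `band_power_table` data.frame with columns participant,
#'   hemisphere, contact, task, band, window, mean_power.
#' @export
summarize_bandpower <- function(maps,
                                bands = list(theta = c(1, 8),
                                             beta = c(13, 30)),
                                windows = list(prespeech = c(-500, 0),
                                               during = c(0, 1000))) {
  stopifnot(length(maps) >= 1)
  rows <- list()
  for (rec in maps) {
    m <- rec$map
    stopifnot(inherits(m, "tf_map"))
    for (bn in names(bands)) {
      fidx <- which(m$freqs >= bands[[bn]][1] & m$freqs <= bands[[bn]][2])
      for (wn in names(windows)) {
        w <- windows[[wn]]
        tidx <- if (w[2] <= 0) {
          which(m$time_ms >= w[1] & m$time_ms < w[2]) # half-open at onset
        } else {
          which(m$time_ms >= w[1] & m$time_ms <= w[2])
        }
        if (length(fidx) == 0 || length(tidx) == 0) next
        rows[[length(rows) + 1]] <- data.frame(
          participant = rec$participant, hemisphere = rec$hemisphere,
          contact = as.character(rec$contact), task = rec$task,
          band = bn, window = wn,
          mean_power = mean(m$power[fidx, tidx]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  key <- do.call(paste, out[, c("participant", "hemisphere", "contact",
                                "task", "band", "window")])
  if (anyDuplicated(key)) stop("duplicate band-power keys", call. = FALSE)
  class(out) <- c("band_power_table", "data.frame")
  out
}

#' Fit the band-power linear mixed-effects model
#'
#' For one band x window cell of the table, fits
#' `mean_power ~ task * laterality * contact + (1 | participant)` by REML
#' with sum-to-zero contrasts, and reports Type III F tests with
#' Satterthwaite denominator degrees of freedom for all main effects and
#' interactions. On a balanced design with `n` participants the task-effect
#' denominator df equals the classical `24 n - 24 - (n - 1) - ...`
#' residual value (276 at n = 13).
#'
#' @param table a `band_power_table`.
#' @param band,window the cell to model (e.g. `"theta"`, `"during"`); `NULL`
#'   uses all rows (the table must then be a single cell).
#' @return an `lme_result`: `model` (lmerTest fit), `anova` (Type III
#'   Satterthwaite table as a data.frame with effect, F, df1, df2, p),
#'   `singular` flag, and the data used.
#' @export
fit_bandpower_lme <- function(table, band = NULL, window = NULL) {
  stopifnot(inherits(table, "data.frame"),
            all(c("participant", "hemisphere", "contact", "task",
                  "mean_power") %in% names(table)))
  d <- as.data.frame(table)
  if (!is.null(band)) d <- d[d$band == band, ]
  if (!is.null(window)) d <- d[d$window == window, ]
  if (length(unique(d$participant)) < 2) {
    stop("need at least 2 participants", call. = FALSE)
  }
  d$task <- factor(d$task, levels = intersect(
    c("vowel", "ddk", "sentence"), unique(d$task)))
  d$laterality <- factor(d$hemisphere, levels = c("left", "right"))
  d$contact <- factor(as.character(d$contact))
  d$participant <- factor(d$participant)
  ctr <- list(task = "contr.sum", laterality = "contr.sum",
              contact = "contr.sum")
  model <- lmerTest::lmer(
    mean_power ~ task * laterality * contact + (1 | participant),
    data = d, REML = TRUE, contrasts = ctr)
  singular <- lme4::isSingular(model)
  an <- stats::anova(model, type = 3, ddf = "Satterthwaite")
  an_df <- data.frame(effect = rownames(an),
                      F = an[["F value"]],
                      df1 = an[["NumDF"]], df2 = an[["DenDF"]],
                      p = an[["Pr(>F)"]],
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(model = model, anova = an_df, singular = singular,
                 band = band, window = window, data = d),
            class = "lme_result")
}

#' @export
print.lme_result <- function(x, ...) {
  cat(sprintf("<lme_result> band = %s, window = %s%s\n",
              x$band %||% "?", x$window %||% "?",
              if (x$singular) " (singular fit: variance component ~ 0)"
              else ""))
  print(x$anova, digits = 4)
  invisible(x)
}

#' Bonferroni-corrected follow-up contrasts
#'
#' Pairwise task contrasts (family of 3) with Satterthwaite degrees of
#' freedom and Bonferroni adjustment (`p_adj = min(1, p * family)`). When
#' the task x laterality interaction is significant in the Type III table,
#' simple-effect task contrasts within each laterality level (and the
#' laterality contrast within each task) are appended, each family
#' Bonferroni-adjusted at its own size.
#'
#' @param result an `lme_result`.
#' @param alpha significance level used to decide whether interaction
#'   follow-ups are added.
#' @return data.frame of contrasts: family, contrast, estimate, t, df,
#'   p_raw, p_adj.
#' @export
followup_contrasts <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "lme_result"))
  model <- result$model
  out <- contrast_frame(
    emmeans::contrast(emmeans::emmeans(model, ~task), method = "pairwise",
                      adjust = "bonferroni"),
    family = "task")
  an <- result$anova
  ix <- an$effect == "task:laterality"
  if (any(ix) && is.finite(an$p[ix]) && an$p[ix] < alpha) {
    by_lat <- emmeans::contrast(
      emmeans::emmeans(model, ~task | laterality), method = "pairwise",
      adjust = "bonferroni")
    by_task <- emmeans::contrast(
      emmeans::emmeans(model, ~laterality | task), method = "pairwise",
      adjust = "bonferroni")
    out <- rbind(out,
                 contrast_frame(by_lat, family = "task within laterality"),
                 contrast_frame(by_task, family = "laterality within task"))
  }
  out
}

contrast_frame <- function(ctr, family) {
  s <- as.data.frame(summary(ctr, adjust = "bonferroni"))
  lab <- s$contrast
  grp <- setdiff(names(s), c("contrast", "estimate", "SE", "df", "t.ratio",
                             "p.value"))
  if (length(grp)) {
    lab <- paste(lab, apply(s[grp], 1, paste, collapse = " "), sep = " | ")
  }
  raw <- 1 - stats::pt(abs(s$t.ratio), s$df) # one side
  raw <- 2 * raw
  data.frame(family = family, contrast = lab, estimate = s$estimate,
             t = s$t.ratio, df = s$df, p_raw = raw,
             p_adj = s$p.value, stringsAsFactors = FALSE)
}
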