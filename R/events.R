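TASK_LEVELS <- c("vowel", "ddk", "sentence")

normalize_task <- function(x) {
  y <- tolower(trimws(x))
  y[y %in% c("ddk", "diadochokinesis")] <- "ddk"
  bad <- !(y %in% TASK_LEVELS)
  if (any(bad)) {
    stop("unknown task label(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  y
}

#' Read trial annotations
#'
#' Reads per-trial speech-task annotations from a CSV file (columns
#' `trial_id`, `task`, `onset_s`, `offset_s`; `trial_id` optional) or a
#' Praat TextGrid (short or long text format) with one interval tier per
#' task, tier names matching the task labels case-insensitively. Labels are
#' normalized to vowel / ddk / sentence, rows are sorted by onset, rows with
#' `offset <= onset` and overlapping intervals within one tier are rejected
#' with an informative error.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"textgrid"`.
#' @return data.frame with trial_id, task, onset_s, offset_s.
#' @export
read_events <- function(path, format = c("auto", "csv", "textgrid")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.textgrid$", path, ignore.case = TRUE))
      "textgrid" else "csv"
  }
  ann <- if (format == "csv") read_events_csv(path) else
    read_events_textgrid(path)
  bad <- which(ann$offset_s <= ann$onset_s)
  if (length(bad)) {
    stop("offset <= onset in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ann <- ann[order(ann$onset_s), , drop = FALSE]
  ann$trial_id <- seq_len(nrow(ann))
  rownames(ann) <- NULL
  ann[, c("trial_id", "task", "onset_s", "offset_s")]
}

read_events_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("task", "onset_s", "offset_s")
  if (!all(need %in% names(d))) {
    stop("annotation CSV must have columns task, onset_s, offset_s",
         call. = FALSE)
  }
  d$task <- normalize_task(d$task)
  if (is.null(d$trial_id)) d$trial_id <- seq_len(nrow(d))
  d
}

read_events_textgrid <- function(path) {
  tiers <- parse_textgrid(path)
  rows <- list()
  for (tier in tiers) {
    iv <- tier$intervals
    iv <- iv[nzchar(trimws(iv$label)), , drop = FALSE]
    if (nrow(iv) == 0) next
    if (nrow(iv) > 1) {
      iv <- iv[order(iv$xmin), , drop = FALSE]
      overlap <- which(iv$xmin[-1] < iv$xmax[-nrow(iv)] - 1e-9)
      if (length(overlap)) {
        stop(sprintf(
          "overlapping intervals on tier '%s' near t = %s s", tier$name,
          paste(round(iv$xmin[overlap + 1], 3), collapse = ", ")),
          call. = FALSE)
      }
    }
    task <- normalize_task(rep(tier$name, nrow(iv)))
    rows[[length(rows) + 1]] <- data.frame(
      task = task, onset_s = iv$xmin, offset_s = iv$xmax,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no labelled intervals in TextGrid", call. = FALSE)
  do.call(rbind, rows)
}

# parses both long ('xmin = 0') and short (bare values) Praat text formats
parse_textgrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (!any(grepl("TextGrid", lines[1:3]))) {
    stop("not a Praat TextGrid file", call. = FALSE)
  }
  nums <- function(x) as.numeric(sub(".*=\\s*", "", x))
  strs <- function(x) gsub("\"", "", sub(".*=\\s*", "", x))
  long <- any(grepl("^item\\s*\\[", lines))
  tiers <- list()
  if (long) {
    tier_starts <- grep("^item\\s*\\[\\d+\\]", lines)
    tier_starts <- c(tier_starts, length(lines) + 1L)
    for (k in seq_len(length(tier_starts) - 1L)) {
      block <- lines[tier_starts[k]:(tier_starts[k + 1] - 1L)]
      cls <- strs(grep("^class\\s*=", block, value = TRUE)[1])
      if (!identical(cls, "IntervalTier")) next
      name <- strs(grep("^name\\s*=", block, value = TRUE)[1])
      xmin <- nums(grep("^xmin\\s*=", block, value = TRUE)[-1])
      xmax <- nums(grep("^xmax\\s*=", block, value = TRUE)[-1])
      text <- strs(grep("^text\\s*=", block, value = TRUE))
      tiers[[length(tiers) + 1]] <- list(
        name = name,
        intervals = data.frame(xmin = xmin, xmax = xmax, label = text,
                               stringsAsFactors = FALSE))
    }
  } else {
    # short format: after the 6-line header, each IntervalTier is
    # "IntervalTier", name, xmin, xmax, n, then n * (xmin, xmax, text)
    i <- which(lines == "\"IntervalTier\"")
    for (start in i) {
      name <- gsub("\"", "", lines[start + 1])
      n_iv <- as.integer(lines[start + 4])
      iv <- data.frame(xmin = numeric(n_iv), xmax = numeric(n_iv),
                       label = character(n_iv), stringsAsFactors = FALSE)
      pos <- start + 5L
      for (j in seq_len(n_iv)) {
        iv$xmin[j] <- as.numeric(lines[pos])
        iv$xmax[j] <- as.numeric(lines[pos + 1])
        iv$label[j] <- gsub("\"", "", lines[pos + 2])
        pos <- pos + 3L
      }
      tiers[[length(tiers) + 1]] <- list(name = name, intervals = iv)
    }
  }
  if (!length(tiers)) stop("no interval tiers in TextGrid", call. = FALSE)
  tiers
}

#' Write trial annotations
#'
#' @param annotations data.frame with trial_id, task, onset_s, offset_s.
#' @param path output path; `.csv` writes CSV, `.TextGrid` writes a Praat
#'   long-format TextGrid with one interval tier per task.
#' @return `path`, invisibly.
#' @export
write_events <- function(annotations, path) {
  if (grepl("\\.textgrid$", path, ignore.case = TRUE)) {
    write_textgrid(annotations, path)
  } else {
    utils::write.csv(annotations, path, row.names = FALSE)
  }
  invisible(path)
}

write_textgrid <- function(annotations, path) {
  xmax <- max(annotations$offset_s) + 1
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("File type = \"ooTextFile\"")
  w("Object class = \"TextGrid\"")
  w("")
  w("xmin = 0")
  w("xmax = %.6f", xmax)
  w("tiers? <exists>")
  tasks <- unique(annotations$task)
  w("size = %d", length(tasks))
  w("item []:")
  for (k in seq_along(tasks)) {
    a <- annotations[annotations$task == tasks[k], , drop = FALSE]
    a <- a[order(a$onset_s), , drop = FALSE]
    # fill gaps with empty intervals so the tier tiles [0, xmax]
    edges <- c(0, as.vector(rbind(a$onset_s, a$offset_s)), xmax)
    labels <- c(rbind(rep("", nrow(a)), a$task), "")
    w("    item [%d]:", k)
    w("        class = \"IntervalTier\"")
    w("        name = \"%s\"", tasks[k])
    w("        xmin = 0")
    w("        xmax = %.6f", xmax)
    w("        intervals: size = %d", length(labels))
    for (j in seq_along(labels)) {
      w("        intervals [%d]:", j)
      w("            xmin = %.6f", edges[j])
      w("            xmax = %.6f", edges[j + 1])
      w("            text = \"%s\"", labels[j])
    }
  }
  invisible(path)
}
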