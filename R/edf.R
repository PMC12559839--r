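# Minimal European Data Format (EDF) I/O.
#
# EDF stores a fixed-size ASCII header (256 bytes + 256 per signal) followed
# by data records of 16-bit little-endian integers, linearly scaled between a
# physical and a digital range per signal. Only continuous, equal-rate,
# single-record-per-second layouts are produced/consumed here, which is all
# the simulator needs to exchange sessions with other tools.

pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n)
}

#' Write a recording session to an EDF file
#'
#' 16-bit EDF with one data record per second; the final partial second is
#' zero-padded. Channel labels are taken from the session. Physical range is
#' set symmetrically from the data maximum, so quantization error is below
#' `max(abs(data)) / 32767`.
#'
#' @param session a `recording_session`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(session, path) {
  stopifnot(inherits(session, "recording_session"))
  data <- session$data
  rate <- session$sampling_rate_hz
  if (rate != round(rate)) stop("EDF writer needs an integer rate",
                                call. = FALSE)
  ns <- ncol(data)
  n_rec <- ceiling(nrow(data) / rate)
  if (nrow(data) < n_rec * rate) {
    data <- rbind(data, matrix(0, n_rec * rate - nrow(data), ns))
  }
  pmax_ <- max(abs(data), 1e-12)
  dig_max <- 32767L
  scaled <- round(data / pmax_ * dig_max)
  storage.mode(scaled) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad(session$participant_id, 80),
    pad(paste("session", session$hemisphere), 80),
    pad("01.01.26", 8), pad("00.00.00", 8),
    pad(256 * (1 + ns), 8), pad("", 44), pad(n_rec, 8), pad(1, 8),
    pad(ns, 4),
    paste(vapply(session$labels, pad, "", n = 16), collapse = ""),
    paste(rep(pad("LFP", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(rep(pad(sprintf("%.6g", -pmax_), 8), ns), collapse = ""),
    paste(rep(pad(sprintf("%.6g", pmax_), 8), ns), collapse = ""),
    paste(rep(pad(-dig_max, 8), ns), collapse = ""),
    paste(rep(pad(dig_max, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(rate, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * rate + 1):(r * rate)
    writeBin(as.integer(as.vector(scaled[idx, , drop = FALSE])), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording session
#'
#' Supports the continuous 16-bit EDF layout written by [write_edf()] and by
#' common acquisition exports (equal sampling rate across signals).
#'
#' @param path EDF file.
#' @param participant_id,hemisphere,lead_model metadata to stamp on the
#'   session (EDF has no standard fields for them; hemisphere defaults from
#'   the first channel label prefix when it is L or R).
#' @return a `recording_session`.
#' @export
read_edf <- function(path, participant_id = NULL, hemisphere = NULL,
                     lead_model = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file", call. = FALSE)
  pid <- rd(80); rd(80); rd(8); rd(8)
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  rd(80 * ns); rd(8 * ns)
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  if (length(unique(spr)) != 1) {
    stop("EDF reader supports equal sampling rates only", call. = FALSE)
  }
  rate <- spr[1] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)

  data <- matrix(NA_real_, n_rec * spr[1], ns)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = spr[1] * ns, size = 2,
                   endian = "little")
    block <- matrix(raw, spr[1], ns)
    data[((r - 1) * spr[1] + 1):(r * spr[1]), ] <-
      sweep(sweep(block, 2, dig_min), 2, gain, `*`) +
      matrix(phys_min, spr[1], ns, byrow = TRUE)
  }
  if (is.null(hemisphere)) {
    hemisphere <- switch(substr(labels[1], 1, 1), L = "left", R = "right",
                         "left")
  }
  if (is.null(lead_model)) {
    lead_model <- if (ns == 8) "eight_contact_segmented" else "four_contact"
  }
  new_recording_session(data, labels, participant_id %||% pid, hemisphere,
                        rate, lead_model)
}
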