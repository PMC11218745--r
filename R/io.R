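# On-disk formats: BIDS-style events.tsv, a JSON+binary recording container,
# and a minimal EDF reader/writer for interchange with other toolboxes.

POSITIONS <- c("front", "back", "left", "right")

#' Empty stimulus event table
#'
#' @return A zero-row tibble with the canonical event columns.
#' @export
empty_events <- function() {
  tibble(onset_s = numeric(0), duration_s = numeric(0), run = integer(0),
         block = integer(0), position = character(0), is_target = logical(0))
}

validate_events <- function(events) {
  ev <- as_tibble(events)
  need <- c("onset_s", "duration_s", "run", "block", "position", "is_target")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    abort(paste0("events table missing column(s): ", paste(miss, collapse = ", ")))
  bad <- setdiff(unique(ev$position), POSITIONS)
  if (length(bad))
    abort(paste0("unknown stimulus position: ", paste(bad, collapse = ", "),
                 " (allowed: ", paste(POSITIONS, collapse = ", "), ")"))
  if (nrow(ev) && any(ev$onset_s < 0)) abort("event onsets must be >= 0")
  if (nrow(ev)) {
    ord <- unsplit(lapply(split(ev$onset_s, ev$run), function(x) diff(c(-Inf, x)) >= 0),
                   ev$run)
    if (any(!ord)) abort("event onsets must be non-decreasing within a run")
  }
  ev$run <- as.integer(ev$run)
  ev$block <- as.integer(ev$block)
  ev$is_target <- as.logical(ev$is_target)
  ev[need]
}

#' Read and write stimulus event tables
#'
#' Events are exchanged as BIDS-style tab-separated tables with columns
#' `onset_s`, `duration_s`, `run`, `block`, `position`, `is_target`.
#' Positions use the closed vocabulary front/back/left/right; anything else
#' is rejected rather than coerced. Round-trips are lossless.
#'
#' @param path File path of the `.tsv` table.
#' @return `read_events()` returns the validated event tibble.
#' @export
read_events <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_events(ev)
}

#' @rdname read_events
#' @param events Event tibble as returned by [read_events()] or
#'   [schedule_session()].
#' @export
write_events <- function(events, path) {
  ev <- validate_events(events)
  ev$is_target <- as.integer(ev$is_target)
  readr::write_tsv(ev, path, progress = FALSE)
  invisible(path)
}

#' Read and write recordings
#'
#' Two formats are supported, chosen by file extension:
#' * `.json` -- the package's documented container: a JSON sidecar holding
#'   sample rate, channel labels, events and metadata next to a `.dat` file
#'   of little-endian float64 samples (channel-major). Lossless.
#' * `.edf` -- European Data Format (16-bit), for interchange with standard
#'   electrophysiology toolboxes. Signals are quantized to the 16-bit grid
#'   over each channel's physical range; events travel in a companion
#'   `<name>_events.tsv` next to the EDF since classic EDF carries no
#'   annotations.
#'
#' @param path Target path ending in `.json` or `.edf`.
#' @return `read_recording()` returns a [recording()].
#' @export
read_recording <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = read_recording_container(path),
    edf = read_recording_edf(path),
    abort(paste0("unknown recording format: .", ext, " (use .json or .edf)"))
  )
}

#' @rdname read_recording
#' @param rec A [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(is_recording(rec))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = write_recording_container(rec, path),
    edf = write_recording_edf(rec, path),
    abort(paste0("unknown recording format: .", ext, " (use .json or .edf)"))
  )
  invisible(path)
}

events_sidecar <- function(path) {
  file.path(dirname(path),
            paste0(tools::file_path_sans_ext(basename(path)), "_events.tsv"))
}

## ---- internal container -------------------------------------------------

write_recording_container <- function(rec, path) {
  dat <- paste0(tools::file_path_sans_ext(path), ".dat")
  ev <- rec$events
  ev$is_target <- as.logical(ev$is_target)
  side <- list(
    format = "gridtap-recording",
    version = 1L,
    sample_rate = rec$sample_rate,
    channel_labels = channel_labels(rec),
    n_samples = ncol(rec$signal),
    signal_file = basename(dat),
    events = ev[setdiff(names(ev), "sample")],
    meta = rec$meta
  )
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(dat, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(rec$signal)), con, size = 8, endian = "little")
  invisible(path)
}

read_recording_container <- function(path) {
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(side$format, "gridtap-recording"))
    abort("not a gridtap recording sidecar")
  dat <- file.path(dirname(path), side$signal_file)
  n_ch <- length(side$channel_labels)
  con <- file(dat, "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n_ch * side$n_samples, size = 8,
               endian = "little")
  if (length(x) != n_ch * side$n_samples)
    abort("signal block length does not match sidecar label/sample counts")
  sig <- t(matrix(x, nrow = side$n_samples, ncol = n_ch))
  rownames(sig) <- side$channel_labels
  ev <- if (length(side$events)) as_tibble(side$events) else empty_events()
  meta <- if (is.null(side$meta)) list() else side$meta
  recording(sig, side$sample_rate, ev, meta)
}

## ---- EDF ----------------------------------------------------------------

# Classic EDF: 256-byte fixed header + 256 bytes per signal, then data
# records of 16-bit little-endian integers. One-second records; the signal is
# zero-padded to a whole number of records and the true sample count is kept
# in the reserved header field so round-trips preserve length.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

write_recording_edf <- function(rec, path) {
  sig <- rec$signal
  n_ch <- nrow(sig)
  fs <- rec$sample_rate
  if (abs(fs - round(fs)) > 1e-9)
    abort("EDF export requires an integer sample rate")
  fs <- as.integer(round(fs))
  n <- ncol(sig)
  n_rec <- as.integer(ceiling(n / fs))
  pad <- n_rec * fs - n
  pmin_ <- apply(sig, 1, min)
  pmax_ <- apply(sig, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767
  gain <- (pmax_ - pmin_) / (dmax - dmin)

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(edf_pad(x, w), con, nchars = w, eos = NULL)
  wr("0", 8)                                   # version
  wr("gridtap synthetic subject", 80)          # patient id
  wr("gridtap recording", 80)                  # recording id
  wr(format(Sys.Date(), "%d.%m.%y"), 8)
  wr("00.00.00", 8)
  wr(256 * (n_ch + 1), 8)                      # header bytes
  wr(paste0("NSAMP=", n), 44)                  # reserved: true sample count
  wr(n_rec, 8)
  wr("1", 8)                                   # record duration, seconds
  wr(n_ch, 4)
  for (lab in rownames(sig)) wr(lab, 16)
  for (i in seq_len(n_ch)) wr("AgAgCl electrode", 80)
  for (i in seq_len(n_ch)) wr("uV", 8)
  for (v in pmin_) wr(format(v, digits = 7), 8)
  for (v in pmax_) wr(format(v, digits = 7), 8)
  for (i in seq_len(n_ch)) wr(dmin, 8)
  for (i in seq_len(n_ch)) wr(dmax, 8)
  for (i in seq_len(n_ch)) wr("", 80)          # prefilter
  for (i in seq_len(n_ch)) wr(fs, 8)           # samples per record
  for (i in seq_len(n_ch)) wr("", 32)          # reserved

  padded <- cbind(sig, matrix(0, n_ch, pad))
  dig <- round((padded - pmin_) / gain) + dmin
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  if (nrow(rec$events)) write_events(rec$events, events_sidecar(path))
  invisible(path)
}

read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  labels <- vapply(seq_len(n_ch), function(i) rd(16), "")
  for (i in seq_len(n_ch)) rd(80)
  units <- vapply(seq_len(n_ch), function(i) rd(8), "")
  pmin_ <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(n_ch)) rd(80)
  spr <- vapply(seq_len(n_ch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(n_ch)) rd(32)
  if (length(unique(spr)) != 1)
    abort("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / rec_dur
  sig <- matrix(0, n_ch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = n_ch * spr[1], size = 2, signed = TRUE,
                   endian = "little")
    if (length(raw) != n_ch * spr[1]) abort("truncated EDF data record")
    sig[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      t(matrix(raw, nrow = spr[1], ncol = n_ch))
  }
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  sig <- sig * gain + (pmin_ - dmin * gain)
  rownames(sig) <- labels
  if (grepl("^NSAMP=", reserved)) {
    n_true <- as.integer(sub("^NSAMP=", "", reserved))
    sig <- sig[, seq_len(n_true), drop = FALSE]
  }
  ev_path <- events_sidecar(path)
  ev <- if (file.exists(ev_path)) read_events(ev_path) else empty_events()
  recording(sig, fs, ev, meta = list(source = path, format = "edf"))
}
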