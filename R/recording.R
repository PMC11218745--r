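#' Multi-channel EEG recording
#'
#' A recording bundles a channels-by-samples signal matrix in microvolts, its
#' sampling rate, the stimulus event table and free-form provenance metadata.
#' Event onsets are stored in seconds; the 1-based sample index of each onset
#' (nearest sample) is kept alongside in the `sample` column.
#'
#' @param signal Numeric matrix, channels x samples, in uV, with rownames
#'   giving the channel labels.
#' @param sample_rate Sampling rate in Hz (> 0); the study stores 250 Hz.
#' @param events Stimulus event tibble with columns `onset_s`, `duration_s`,
#'   `run`, `block`, `position`, `is_target` (see [read_events()]); may be
#'   empty.
#' @param meta Named list of provenance values.
#' @return An object of class `gt_recording`.
#' @export
recording <- function(signal, sample_rate = 250, events = empty_events(),
                      meta = list()) {
  signal <- as.matrix(signal)
  if (is.null(rownames(signal))) abort("signal needs channel labels as rownames")
  if (anyDuplicated(rownames(signal))) abort("duplicate channel labels")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    abort("sample_rate must be a single positive number")
  events <- validate_events(events)
  if (nrow(events)) {
    events$sample <- as.integer(round(events$onset_s * sample_rate)) + 1L
    if (any(events$sample < 1L) || any(events$sample > ncol(signal)))
      abort("event onset outside the recorded signal range")
  } else {
    events$sample <- integer(0)
  }
  structure(
    list(signal = signal, sample_rate = sample_rate, events = events,
         meta = meta),
    class = "gt_recording"
  )
}

#' @export
print.gt_recording <- function(x, ...) {
  cat("<gt_recording> ", nrow(x$signal), " channels x ", ncol(x$signal),
      " samples @ ", x$sample_rate, " Hz (",
      round(ncol(x$signal) / x$sample_rate, 1), " s), ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' @rdname recording
#' @param x Object to test.
#' @export
is_recording <- function(x) inherits(x, "gt_recording")

channel_labels <- function(rec) rownames(rec$signal)

#' Derive vertical bipolar ear channels
#'
#' Appends one derived channel per bipolar pair of the montage, computed
#' sample-wise as `minuend - subtrahend`. Certain ear-electrode differences
#' with large inter-electrode distance are known to approximate central scalp
#' positions, which is why classification and ERP analysis of the ear arrays
#' run on these derivations. Original channels and events are preserved.
#'
#' @param rec A [recording()].
#' @param montage A [montage()]; defaults to [default_montage()].
#' @return The recording with the derived channels appended.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(2 * 100), 2, 100,
#'                         dimnames = list(c("R2", "R7"), NULL)))
#' m <- default_montage()
#' out <- derive_bipolar(rec, montage(
#'   "toy", c("R2", "R7"),
#'   c(R2 = "ceegrid_right", R7 = "ceegrid_right"),
#'   m$bipolar_pairs[2, ]))
#' rownames(out$signal)
derive_bipolar <- function(rec, montage = default_montage()) {
  stopifnot(is_recording(rec))
  labs <- channel_labels(rec)
  bp <- montage$bipolar_pairs
  missing <- setdiff(unique(c(bp$minuend, bp$subtrahend)), labs)
  if (length(missing))
    abort(paste0("channel(s) missing from recording: ",
                 paste(missing, collapse = ", ")))
  derived <- rec$signal[bp$minuend, , drop = FALSE] -
    rec$signal[bp$subtrahend, , drop = FALSE]
  rownames(derived) <- bp$label
  rec$signal <- rbind(rec$signal, derived)
  rec
}
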