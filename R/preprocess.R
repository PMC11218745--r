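# Offline signal path: band-pass filter -> epoch -> baseline correction ->
# amplitude-threshold artifact rejection -> class averaging.

#' Preprocessing configuration
#'
#' @param bandpass_hz Band-pass corner frequencies in Hz (zero-phase).
#' @param epoch_pre_ms Pre-stimulus context in ms (baseline window).
#' @param epoch_post_ms Post-stimulus window in ms.
#' @param reject_abs_uv Absolute amplitude rejection threshold in uV; an
#'   epoch is rejected when any sample *strictly exceeds* this magnitude on
#'   any scanned channel (a sample at exactly the threshold is kept).
#' @return A list of class `gt_preprocess_config`.
#' @export
preprocess_config <- function(bandpass_hz = c(0.1, 30), epoch_pre_ms = 100,
                              epoch_post_ms = 800, reject_abs_uv = 75) {
  stopifnot(length(bandpass_hz) == 2, bandpass_hz[1] > 0,
            bandpass_hz[1] < bandpass_hz[2],
            epoch_pre_ms > 0, epoch_post_ms > 0, reject_abs_uv > 0)
  structure(as.list(environment()), class = "gt_preprocess_config")
}

#' Zero-phase band-pass filter
#'
#' Filters every channel with a zero-phase (forward-backward) 4th-order
#' Butterworth high-pass at the lower corner followed by a 4th-order
#' Butterworth low-pass at the upper corner. Zero-phase filtering preserves
#' ERP latencies; the high-pass removes DC and drift. Events and metadata are
#' untouched.
#'
#' @param rec A [recording()].
#' @param cfg A [preprocess_config()] (only `bandpass_hz` is used).
#' @return The filtered recording.
#' @export
bandpass <- function(rec, cfg = preprocess_config()) {
  stopifnot(is_recording(rec))
  ny <- rec$sample_rate / 2
  if (cfg$bandpass_hz[2] >= ny)
    abort("upper band-pass corner must lie below the Nyquist frequency")
  hp <- signal::butter(4, cfg$bandpass_hz[1] / ny, type = "high")
  lp <- signal::butter(4, cfg$bandpass_hz[2] / ny, type = "low")
  x <- t(rec$signal)                       # samples x channels
  # pad generously relative to the slow high-pass transient
  pad_hp <- 3 * round(rec$sample_rate / cfg$bandpass_hz[1])
  x <- filtfilt_mat(hp$b, hp$a, x, pad_hp)
  x <- filtfilt_mat(lp$b, lp$a, x, 3 * round(rec$sample_rate / cfg$bandpass_hz[2]))
  rec$signal <- t(x)
  rec$meta$bandpass_hz <- cfg$bandpass_hz
  rec
}

# Zero-phase (forward-backward) IIR filtering of every column of x at once,
# with even-reflection padding at both ends (preserves the local DC level, so
# the slow high-pass sees no spurious step at the pad junctions) and
# steady-state-matched initial conditions per pass. The two passes run in
# compiled code.
filtfilt_mat <- function(b, a, x, pad) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- max(1L, min(n - 1L, as.integer(pad)))
  y <- rbind(x[(p + 1):2, , drop = FALSE], x, x[(n - 1):(n - p), , drop = FALSE])
  y <- cpp_filtfilt(b / a[1], a / a[1], y, lfilter_zi(b / a[1], a / a[1]))
  y[(p + 1):(p + n), , drop = FALSE]
}

# steady-state direct-form-II-transposed filter state for a unit-level
# constant input (the classical lfilter_zi construction): solve
# (I - A') zi = b[-1] - a[-1] * b[1] with A the companion matrix of a
lfilter_zi <- function(b, a) {
  k <- length(a) - 1
  A <- rbind(-a[-1], cbind(diag(1, k - 1, k - 1), 0))
  solve(diag(k) - t(A), b[-1] - a[-1] * b[1])
}

#' Cut a recording into stimulus-locked epochs
#'
#' One epoch per event, covering `[-epoch_pre_ms, epoch_post_ms)` around the
#' stimulus onset under the half-open sample convention (at 250 Hz and the
#' default window: 25 pre- plus 200 post-stimulus samples, 225 in total).
#' Events whose epoch would reach past either end of the recording are
#' dropped with a warning.
#'
#' @param rec A [recording()] with events.
#' @param cfg A [preprocess_config()].
#' @return An object of class `gt_epochs`: epochs as a channels x samples x
#'   epochs array with per-epoch labels, keep flags and latency axis.
#' @export
epoch <- function(rec, cfg = preprocess_config()) {
  stopifnot(is_recording(rec))
  fs <- rec$sample_rate
  pre <- ms_to_samples(cfg$epoch_pre_ms, fs)
  post <- ms_to_samples(cfg$epoch_post_ms, fs)
  ev <- rec$events
  n <- ncol(rec$signal)
  ok <- ev$sample - pre >= 1 & ev$sample + post - 1 <= n
  if (any(!ok))
    warn(paste0(sum(!ok), " event(s) too close to the recording edge were ",
                "excluded from epoching"))
  ev <- ev[ok, , drop = FALSE]
  if (!nrow(ev)) {
    return(new_epochs(array(0, c(nrow(rec$signal), pre + post, 0)),
                      channel_labels(rec), pre, fs, ev,
                      n_edge_dropped = sum(!ok)))
  }
  offs <- seq.int(-pre, post - 1L)
  idx <- outer(offs, ev$sample, "+")      # samples x epochs
  dat <- rec$signal[, as.vector(idx), drop = FALSE]
  dim(dat) <- c(nrow(rec$signal), length(offs), nrow(ev))
  new_epochs(dat, channel_labels(rec), pre, fs, ev, n_edge_dropped = sum(!ok))
}

new_epochs <- function(data, channels, pre_samples, sample_rate, events,
                       baseline_corrected = FALSE, kept = NULL,
                       n_edge_dropped = 0) {
  dimnames(data) <- list(channels, NULL, NULL)
  structure(
    list(data = data, channels = channels,
         times_ms = (seq_len(dim(data)[2]) - 1 - pre_samples) * 1000 / sample_rate,
         pre_samples = pre_samples, sample_rate = sample_rate,
         events = as_tibble(events),
         kept = kept %||% rep(TRUE, dim(data)[3]),
         baseline_corrected = baseline_corrected,
         n_edge_dropped = n_edge_dropped),
    class = "gt_epochs"
  )
}

#' @export
print.gt_epochs <- function(x, ...) {
  cat("<gt_epochs> ", dim(x$data)[3], " epochs x ", length(x$channels),
      " channels x ", dim(x$data)[2], " samples (",
      min(x$times_ms), "..", max(x$times_ms), " ms), ",
      sum(x$kept), " kept", if (x$baseline_corrected) ", baseline-corrected",
      "\n", sep = "")
  invisible(x)
}

n_epochs <- function(eps) dim(eps$data)[3]

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the pre-stimulus samples,
#' so deflections are measured relative to pre-stimulus activity. Applying
#' the correction twice is an error (the pipeline order filter -> epoch ->
#' baseline -> reject -> average is enforced).
#'
#' @param eps A `gt_epochs` object.
#' @return The corrected epochs with `baseline_corrected` set.
#' @export
baseline_correct <- function(eps) {
  stopifnot(inherits(eps, "gt_epochs"))
  if (eps$baseline_corrected) abort("epochs are already baseline-corrected")
  d <- dim(eps$data)
  if (d[3] > 0) {
    pre_idx <- seq_len(eps$pre_samples)
    pre <- eps$data[, pre_idx, , drop = FALSE]
    # channel x epoch means of the pre-stimulus segment, without apply()
    bm <- colMeans(aperm(pre, c(2, 1, 3)))          # channels x epochs
    eps$data <- eps$data - aperm(array(bm, c(d[1], d[3], d[2])), c(1, 3, 2))
  }
  eps$baseline_corrected <- TRUE
  eps
}

#' Reject artifact epochs by amplitude threshold
#'
#' Flags `kept = FALSE` for every epoch containing any sample whose absolute
#' value strictly exceeds the threshold on any of the scanned channels.
#' Scanning is scoped to the channels entering the analysis (by default all
#' channels in the epoch set) so that an unused noisy channel cannot discard
#' data. Requires baseline-corrected epochs; thresholding is applied after
#' correction.
#'
#' @param eps Baseline-corrected `gt_epochs`.
#' @param cfg A [preprocess_config()] providing `reject_abs_uv`.
#' @param channels Channels to scan (default: all in `eps`).
#' @return The epochs with updated `kept` flags; the input epoch count is
#'   preserved.
#' @export
reject_artifacts <- function(eps, cfg = preprocess_config(), channels = NULL) {
  stopifnot(inherits(eps, "gt_epochs"))
  if (!eps$baseline_corrected)
    abort("reject_artifacts() requires baseline-corrected epochs")
  channels <- channels %||% eps$channels
  missing <- setdiff(channels, eps$channels)
  if (length(missing))
    abort(paste0("channel(s) not in epochs: ", paste(missing, collapse = ", ")))
  if (n_epochs(eps) == 0) return(eps)
  sub <- abs(eps$data[channels, , , drop = FALSE])
  mx <- apply(matrix(sub, ncol = n_epochs(eps)), 2, max)
  eps$kept <- eps$kept & (mx <= cfg$reject_abs_uv)
  eps$reject_abs_uv <- cfg$reject_abs_uv
  eps
}

#' Average kept epochs into target and non-target ERPs
#'
#' Sample-wise per-channel means over the kept epochs of each class.
#'
#' @param eps Baseline-corrected `gt_epochs`.
#' @return An object of class `gt_erp_average` with `target` and `nontarget`
#'   channel x sample matrices and the per-class epoch counts.
#' @export
average <- function(eps) {
  stopifnot(inherits(eps, "gt_epochs"))
  if (!eps$baseline_corrected)
    abort("average() requires baseline-corrected epochs")
  keep_t <- eps$kept & eps$events$is_target
  keep_n <- eps$kept & !eps$events$is_target
  if (!any(keep_t)) abort("no kept epochs in class: target")
  if (!any(keep_n)) abort("no kept epochs in class: non-target")
  class_mean <- function(keep) {
    d <- eps$data[, , keep, drop = FALSE]
    m <- rowMeans(matrix(d, ncol = sum(keep)))
    matrix(m, nrow = length(eps$channels),
           dimnames = list(eps$channels, NULL))
  }
  structure(
    list(target = class_mean(keep_t), nontarget = class_mean(keep_n),
         n_target = sum(keep_t), n_nontarget = sum(keep_n),
         times_ms = eps$times_ms, channels = eps$channels,
         sample_rate = eps$sample_rate),
    class = "gt_erp_average"
  )
}

#' @export
print.gt_erp_average <- function(x, ...) {
  cat("<gt_erp_average> ", length(x$channels), " channels, ",
      x$n_target, " target / ", x$n_nontarget, " non-target epochs\n",
      sep = "")
  invisible(x)
}
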