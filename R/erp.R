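# ERP feature extraction: window mean amplitudes and peak latencies from
# class averages.

# channels of interest and their analysis windows; the ear analysis focuses
# on the four large-distance vertical derivations, with the window shifted
# 50 ms later than on the scalp because the deflection peaks later behind
# the ear
erp_channels_of_interest <- function() {
  tibble(
    channel = c("Fz", "Cz", "Pz", "R2-R7", "R3-R6", "L2-L7", "L3-L6"),
    system = c(rep("cap", 3), rep("ceegrid", 4)),
    window_start_ms = c(rep(350, 3), rep(400, 4)),
    window_end_ms = c(rep(650, 3), rep(700, 4))
  )
}

check_window <- function(window_ms, times_ms) {
  if (length(window_ms) != 2 || window_ms[1] >= window_ms[2])
    abort("window must be (start, end) with start < end")
  if (window_ms[1] < min(times_ms) || window_ms[2] > max(times_ms))
    abort("window lies outside the epoch")
}

avg_waveform <- function(avg, channel, class) {
  if (!channel %in% avg$channels)
    abort(paste0("channel not in average: ", channel))
  avg[[class]][channel, ]
}

#' Window mean amplitude of a class average
#'
#' Arithmetic mean of the averaged waveform over all samples whose latency
#' falls in the closed interval `[start, end]` ms post-stimulus. This window
#' mean is the amplitude feature of the physiological analysis (350--650 ms
#' on the scalp, 400--700 ms on the ear derivations).
#'
#' @param avg A `gt_erp_average` from [average()].
#' @param channel Channel label.
#' @param window_ms Window `(start, end)` in ms post-stimulus.
#' @param class `"target"` or `"nontarget"`.
#' @return Mean amplitude in uV.
#' @export
mean_amplitude <- function(avg, channel, window_ms = c(350, 650),
                           class = c("target", "nontarget")) {
  class <- match.arg(class)
  stopifnot(inherits(avg, "gt_erp_average"))
  check_window(window_ms, avg$times_ms)
  w <- avg_waveform(avg, channel, class)
  sel <- avg$times_ms >= window_ms[1] & avg$times_ms <= window_ms[2]
  mean(w[sel])
}

#' Peak latency of a class average
#'
#' Latency of the extreme value of the requested polarity within the search
#' window; ties resolve to the earliest sample. The search window defaults to
#' 300--700 ms, bracketing the deflection of interest on both systems.
#'
#' @inheritParams mean_amplitude
#' @param search_window_ms Search window `(start, end)` in ms.
#' @param polarity `"positive"` (maximum) or `"negative"` (minimum).
#' @return Peak latency in ms (on the sample grid).
#' @export
peak_latency <- function(avg, channel, search_window_ms = c(300, 700),
                         polarity = c("positive", "negative"),
                         class = c("target", "nontarget")) {
  polarity <- match.arg(polarity)
  class <- match.arg(class)
  stopifnot(inherits(avg, "gt_erp_average"))
  check_window(search_window_ms, avg$times_ms)
  w <- avg_waveform(avg, channel, class)
  sel <- which(avg$times_ms >= search_window_ms[1] &
                 avg$times_ms <= search_window_ms[2])
  v <- w[sel]
  i <- if (polarity == "positive") which.max(v) else which.min(v)
  avg$times_ms[sel[i]]
}

#' Per-subject ERP feature table
#'
#' Extracts, for every subject and channel of interest, the target window
#' mean amplitude and peak latency. Channels missing from a subject's average
#' are skipped with a warning. Default channels and windows are Fz/Cz/Pz with
#' 350--650 ms and the four large-distance ear derivations with 400--700 ms.
#'
#' @param averages Named list of `gt_erp_average` objects, one per subject.
#' @param channels Tibble like [erp_channels_of_interest()] with columns
#'   `channel`, `system`, `window_start_ms`, `window_end_ms`.
#' @return A tibble with one row per subject x available channel:
#'   `subject`, `channel`, `system`, window bounds, `mean_amplitude_uv`,
#'   `peak_latency_ms`, `n_epochs`.
#' @export
feature_table <- function(averages, channels = erp_channels_of_interest()) {
  stopifnot(length(averages) >= 1)
  if (is.null(names(averages)))
    names(averages) <- paste0("S", seq_along(averages))
  purrr::imap_dfr(averages, function(avg, subj) {
    present <- channels$channel %in% avg$channels
    if (any(!present))
      warn(paste0("subject ", subj, ": channel(s) missing, skipped: ",
                  paste(channels$channel[!present], collapse = ", ")))
    ch <- channels[present, , drop = FALSE]
    purrr::pmap_dfr(ch, function(channel, system, window_start_ms,
                                 window_end_ms) {
      tibble(
        subject = subj, channel = channel, system = system,
        window_start_ms = window_start_ms, window_end_ms = window_end_ms,
        mean_amplitude_uv = mean_amplitude(
          avg, channel, c(window_start_ms, window_end_ms)),
        peak_latency_ms = peak_latency(avg, channel),
        n_epochs = avg$n_target
      )
    })
  })
}

#' Group summary of a feature table
#'
#' Group means and SDs of the target window amplitudes per channel, in the
#' layout of the study's amplitude table.
#'
#' @param features Tibble from [feature_table()].
#' @return A tibble with one row per channel: `system`, `channel`,
#'   `mean_amplitude_uv`, `sd_amplitude_uv`, `mean_latency_ms`, `n_subjects`.
#' @export
summarise_features <- function(features) {
  features |>
    dplyr::group_by(.data$system, .data$channel) |>
    dplyr::summarise(
      sd_amplitude_uv = sd(.data$mean_amplitude_uv),
      mean_amplitude_uv = mean(.data$mean_amplitude_uv),
      mean_latency_ms = mean(.data$peak_latency_ms),
      n_subjects = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::relocate("mean_amplitude_uv", .before = "sd_amplitude_uv")
}
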