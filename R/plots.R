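# ggplot2 figure methods for the result objects.

#' Plot class-average ERPs
#'
#' Target and non-target average waveforms per channel, stimulus onset at
#' 0 ms.
#'
#' @param object A `gt_erp_average`.
#' @param channels Channels to display (default: the study's channels of
#'   interest present in the average).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gt_erp_average
#' @export
autoplot.gt_erp_average <- function(object,
                                    channels = intersect(
                                      erp_channels_of_interest()$channel,
                                      object$channels), ...) {
  stopifnot(length(channels) >= 1)
  df <- purrr::map_dfr(c("target", "nontarget"), function(cl) {
    purrr::map_dfr(channels, function(ch) {
      tibble(channel = ch, class = cl, time_ms = object$times_ms,
             amplitude_uv = object[[cl]][ch, ])
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$amplitude_uv,
                                   colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "time after stimulus [ms]", y = "amplitude [µV]",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Grand-average ERPs with between-subject standard error
#'
#' Averages the per-subject target/non-target class averages across subjects
#' and shades +/- 1 between-subject standard error.
#'
#' @param averages List of per-subject `gt_erp_average` objects (all sharing
#'   channels and time axis), e.g. one system's entries of
#'   `run_study()$averages`.
#' @param channels Channels to display.
#' @param class `"target"` or `"nontarget"`.
#' @return A ggplot object.
#' @export
plot_grand_average <- function(averages, channels = NULL,
                               class = c("target", "nontarget")) {
  class <- match.arg(class)
  stopifnot(length(averages) >= 2)
  first <- averages[[1]]
  channels <- channels %||% intersect(erp_channels_of_interest()$channel,
                                      first$channels)
  df <- purrr::map_dfr(channels, function(ch) {
    mat <- vapply(averages, function(a) a[[class]][ch, ],
                  numeric(length(first$times_ms)))
    tibble(channel = ch, time_ms = first$times_ms,
           mean_uv = rowMeans(mat),
           se_uv = apply(mat, 1, sd) / sqrt(ncol(mat)))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$mean_uv)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_uv - .data$se_uv,
                                      ymax = .data$mean_uv + .data$se_uv),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "time after stimulus [ms]",
                  y = "grand-average amplitude [µV]") +
    ggplot2::theme_minimal()
}

#' Plot a psychometric fit
#'
#' Response ratios (point size = number of trials), the fitted logistic and
#' the 50%-point threshold.
#'
#' @param object A converged `gt_psychofit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gt_psychofit
#' @export
autoplot.gt_psychofit <- function(object, ...) {
  r <- object$ratios
  p <- ggplot2::ggplot(r, ggplot2::aes(.data$intensity_pct, .data$ratio)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_trials), alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(x = "second stimulus intensity [%]",
                  y = "ratio reported equal", size = "trials") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble(intensity_pct = seq(min(r$intensity_pct),
                                       max(r$intensity_pct), length.out = 200))
    grid$fit <- plogis((grid$intensity_pct - object$midpoint_pct) /
                         object$slope_pct)
    p <- p +
      ggplot2::geom_line(data = grid,
                         ggplot2::aes(.data$intensity_pct, .data$fit),
                         colour = "steelblue") +
      ggplot2::geom_vline(xintercept = object$midpoint_pct,
                          linetype = "dashed") +
      ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted")
  }
  p
}

#' Per-subject accuracy overview
#'
#' Dot plot of both systems' cross-validated accuracies per subject with the
#' chance level, the binomial significance bound and the 70% usability
#' criterion.
#'
#' @param subjects The per-subject accuracy tibble of a `gt_study` (needs
#'   `subject`, `cap_accuracy_pct`, `ceegrid_accuracy_pct`, `n_blocks`).
#' @return A ggplot object.
#' @export
plot_accuracy_overview <- function(subjects) {
  thr <- chance_threshold(subjects$n_blocks[1], 0.25, 0.05)$threshold_pct
  df <- subjects |>
    dplyr::select("subject", cap = "cap_accuracy_pct",
                  ceegrid = "ceegrid_accuracy_pct") |>
    tidyr::pivot_longer(-"subject", names_to = "system",
                        values_to = "accuracy_pct")
  ggplot2::ggplot(df, ggplot2::aes(.data$subject, .data$accuracy_pct,
                                   colour = .data$system)) +
    ggplot2::geom_hline(yintercept = 25, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 70, linetype = "longdash",
                        colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(y = "LOO-CV selection accuracy [%]", x = NULL,
                  colour = NULL,
                  caption = "dotted: chance; dashed: significance bound; long-dashed: usability") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
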