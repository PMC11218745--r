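# broom-style tidiers for the fitted objects.

#' Tidy an SWLDA model
#'
#' @param x A `gt_swlda` model.
#' @param ... Unused.
#' @return A tibble with one row per selected feature (`term`, `channel`,
#'   `bin`, `estimate`) plus the intercept row.
#' @method tidy gt_swlda
#' @export
tidy.gt_swlda <- function(x, ...) {
  rows <- tibble(term = c("(Intercept)", x$feature_names %||%
                            paste0("f", x$selected)),
                 estimate = c(x$intercept, x$weights))
  if (!is.null(x$info))
    rows <- dplyr::left_join(
      rows, dplyr::mutate(x$info, term = paste0(.data$channel, ".b", .data$bin)),
      by = "term")
  rows
}

#' @rdname tidy.gt_swlda
#' @method glance gt_swlda
#' @export
glance.gt_swlda <- function(x, ...) {
  tibble(n_selected = length(x$selected),
         n_candidates = x$n_features_candidate,
         degenerate = x$degenerate,
         n_target = x$n_target, n_nontarget = x$n_nontarget)
}

#' Tidy a cross-validated accuracy result
#'
#' @param x A `gt_accuracy` result.
#' @param ... Unused.
#' @return `tidy()`: the per-block selection table. `glance()`: a one-row
#'   summary with the accuracy, chance bound and usability flag.
#' @method tidy gt_accuracy
#' @export
tidy.gt_accuracy <- function(x, ...) x$selections

#' @rdname tidy.gt_accuracy
#' @method glance gt_accuracy
#' @export
glance.gt_accuracy <- function(x, ...) {
  tibble(channel_set = x$channel_set, n_blocks = x$n_blocks,
         n_correct = x$n_correct, accuracy_pct = x$accuracy_pct,
         chance_pct = x$chance_pct,
         significance_threshold_pct = x$significance_threshold_pct,
         significant = x$significant, meets_usability = x$meets_usability)
}

#' Tidy a psychometric fit
#'
#' @param x A `gt_psychofit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter. `glance()`: a one-row fit
#'   summary.
#' @method tidy gt_psychofit
#' @export
tidy.gt_psychofit <- function(x, ...) {
  tibble(term = c("midpoint_pct", "slope_pct"),
         estimate = c(x$midpoint_pct, x$slope_pct))
}

#' @rdname tidy.gt_psychofit
#' @method glance gt_psychofit
#' @export
glance.gt_psychofit <- function(x, ...) {
  tibble(threshold_pct = x$midpoint_pct, slope_pct = x$slope_pct,
         converged = x$converged, boundary = x$boundary,
         n_trials = x$n_trials, method = x$method)
}

#' Tidy a group-level test result
#'
#' @param x A `gt_group_result`.
#' @param posthoc If `TRUE` and a post-hoc table exists, return it instead of
#'   the omnibus row.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gt_group_result
#' @export
tidy.gt_group_result <- function(x, posthoc = FALSE, ...) {
  if (posthoc) {
    if (is.null(x$posthoc)) abort("this result has no post-hoc table")
    return(x$posthoc)
  }
  x$result
}

#' @rdname tidy.gt_group_result
#' @method glance gt_group_result
#' @export
glance.gt_group_result <- function(x, ...) x$result
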