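# Intensity-discrimination task: adaptive trial scheduling, response ratios,
# sigmoidal psychometric fitting and 50%-point threshold extraction.

#' Adaptive scheduler state
#'
#' The trial scheduler first presents one seeded random sweep over the whole
#' intensity grid, then concentrates on the *ambiguous* intensities -- those
#' whose running response ratio lies strictly inside the ambiguity band
#' (default (0.2, 0.8)), falling back to the full grid when none qualify.
#' Very similar or very different stimulus pairs are answered consistently,
#' so the informative region around the threshold receives more trials. The
#' band and the 53-trial cap are scheduler conventions (the cap matches the
#' largest observed session length); both are configurable.
#'
#' @param grid Intensity grid, percent (descending 5% steps by default).
#' @param seed Integer seed; the full trial sequence is reproducible from it
#'   and the accumulated responses.
#' @param max_trials Trial budget after which no further intensity is
#'   offered.
#' @param ambiguity_band Open interval of response ratios treated as
#'   ambiguous.
#' @return A list of class `gt_scheduler`.
#' @export
scheduler_state <- function(grid = seq(100, 40, by = -5), seed = 1,
                            max_trials = 53, ambiguity_band = c(0.2, 0.8)) {
  stopifnot(length(grid) >= 1, max_trials >= 1,
            ambiguity_band[1] < ambiguity_band[2])
  structure(
    list(grid = as.numeric(grid), seed = seed, max_trials = max_trials,
         ambiguity_band = ambiguity_band,
         sweep_order = with_seed_(seed, sample(as.numeric(grid)))),
    class = "gt_scheduler"
  )
}

#' Next intensity to present
#'
#' Deterministic given the accumulated trials and the scheduler state: the
#' initial phase walks the seeded sweep over the grid; the adaptive phase
#' samples uniformly among the currently ambiguous intensities (full grid if
#' none). Returns `NA` once `max_trials` is reached.
#'
#' @param trials Tibble of trials so far (`intensity_pct`, `reported_equal`);
#'   may be empty.
#' @param state A [scheduler_state()].
#' @return A single intensity (percent), or `NA` when the budget is spent.
#' @export
next_intensity <- function(trials, state) {
  stopifnot(inherits(state, "gt_scheduler"))
  n_done <- nrow(trials)
  if (n_done >= state$max_trials) return(NA_real_)
  if (n_done < length(state$sweep_order)) return(state$sweep_order[n_done + 1])
  ratios <- response_ratios(trials)
  amb <- ratios$intensity_pct[ratios$ratio > state$ambiguity_band[1] &
                                ratios$ratio < state$ambiguity_band[2]]
  pool <- if (length(amb)) amb else state$grid
  # keyed draw: deterministic for a given (seed, trial index) pair
  with_seed_(derive_seed(state$seed, n_done), pool[sample.int(length(pool), 1)])
}

#' Response ratios per intensity
#'
#' Fraction of trials at each presented intensity that were reported as
#' *equal* to the reference, on the 0 (always unequal) to 1 (always equal)
#' scale. Intensities with no trials are absent.
#'
#' @param trials Tibble with `intensity_pct` and `reported_equal`.
#' @return Tibble with `intensity_pct`, `n_trials`, `n_equal`, `ratio`.
#' @export
response_ratios <- function(trials) {
  trials <- as_tibble(trials)
  if (!nrow(trials))
    return(tibble(intensity_pct = numeric(0), n_trials = integer(0),
                  n_equal = integer(0), ratio = numeric(0)))
  trials |>
    dplyr::group_by(intensity_pct = .data$intensity_pct) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     n_equal = sum(.data$reported_equal),
                     ratio = mean(.data$reported_equal),
                     .groups = "drop") |>
    dplyr::arrange(.data$intensity_pct)
}

#' Fit the psychometric sigmoid
#'
#' Fits a two-parameter logistic `ratio = 1 / (1 + exp(-(x - midpoint)/slope))`
#' to the per-intensity response ratios. Asymptotes are fixed at 0 and 1
#' because the response scale is defined that way; no lapse parameters. The
#' default fit is least squares weighted by the per-intensity trial counts
#' (the curve is fitted to the ratio points); a binomial-likelihood fit is
#' available via `method = "binomial"`. The sensitivity threshold is the
#' midpoint -- the intensity reported equal in 50% of trials. One-sided data
#' (responses of only one kind) or optimizer failure yield a non-converged
#' fit with an undefined threshold.
#'
#' @param data Trials tibble (`intensity_pct`, `reported_equal`) or a
#'   ratio table from [response_ratios()].
#' @param method `"wls"` (weighted least squares on the ratios, default) or
#'   `"binomial"` (logistic GLM on the raw counts).
#' @return An object of class `gt_psychofit` with `midpoint_pct`,
#'   `slope_pct`, `converged`, `boundary` (midpoint outside the tested
#'   range), `n_trials` and the fitted ratio table.
#' @export
fit_sigmoid <- function(data, method = c("wls", "binomial")) {
  method <- match.arg(method)
  ratios <- if (all(c("ratio", "n_trials") %in% names(data))) as_tibble(data)
    else response_ratios(data)
  n_trials <- sum(ratios$n_trials)
  failed <- function() structure(
    list(midpoint_pct = NA_real_, slope_pct = NA_real_, converged = FALSE,
         boundary = FALSE, n_trials = n_trials, method = method,
         ratios = ratios),
    class = "gt_psychofit")
  if (nrow(ratios) < 3) return(failed())
  if (!is.null(ratios$n_equal)) {
    n_eq <- sum(ratios$n_equal)
    if (n_eq == 0 || n_eq == n_trials) return(failed())     # one-sided data
  }
  if (max(ratios$ratio) - min(ratios$ratio) < 1e-12) return(failed())
  x <- ratios$intensity_pct; r <- ratios$ratio; w <- ratios$n_trials
  # start values: interpolated 0.5 crossing and a quarter of the tested range
  m0 <- tryCatch(stats::approx(r + seq_along(r) * 1e-9, x, xout = 0.5,
                               rule = 2)$y,
                 error = function(e) stats::weighted.mean(x, w))
  s0 <- max(diff(range(x)) / 8, 1)
  est <- tryCatch({
    if (method == "wls") {
      # multi-start Nelder-Mead on the weighted SSE (log-slope scale), then
      # a Levenberg-Marquardt polish; derivative-free starts make the fit
      # robust to plateau-prone starting points
      obj <- function(p) sum(w * (r - plogis((x - p[1]) / exp(p[2])))^2)
      starts <- list(c(m0, log(s0)), c(median(x), log(2)),
                     c(median(x), log(diff(range(x)) / 4 + 1)))
      fits <- lapply(starts, function(p0)
        stats::optim(p0, obj, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-12)))
      best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
      est0 <- list(m = best$par[1], s = exp(best$par[2]))
      polish <- tryCatch({
        fit <- minpack.lm::nlsLM(
          r ~ 1 / (1 + exp(-(x - m) / s)),
          start = est0, weights = w,
          lower = c(m = min(x) - 100, s = 1e-3),
          upper = c(m = max(x) + 100, s = 1e3),
          control = minpack.lm::nls.lm.control(maxiter = 200))
        as.list(coef(fit))
      }, error = function(e) NULL)
      polish %||% est0
    } else {
      if (is.null(ratios$n_equal)) abort("binomial fit needs raw counts")
      fit <- stats::glm(cbind(n_equal, n_trials - n_equal) ~ intensity_pct,
                        family = stats::binomial(), data = ratios)
      if (!fit$converged || abs(coef(fit)[2]) < 1e-12) abort("glm failed")
      list(m = -coef(fit)[[1]] / coef(fit)[[2]], s = 1 / coef(fit)[[2]])
    }
  }, error = function(e) NULL)
  if (is.null(est) || !is.finite(est$m) || !is.finite(est$s)) return(failed())
  structure(
    list(midpoint_pct = est$m, slope_pct = est$s, converged = TRUE,
         boundary = est$m < min(x) || est$m > max(x),
         n_trials = n_trials, method = method, ratios = ratios),
    class = "gt_psychofit")
}

#' @export
print.gt_psychofit <- function(x, ...) {
  if (x$converged)
    cat("<gt_psychofit> threshold ", round(x$midpoint_pct, 1), "% (slope ",
        round(x$slope_pct, 2), ", ", x$n_trials, " trials",
        if (x$boundary) ", boundary fit", ")\n", sep = "")
  else
    cat("<gt_psychofit> not converged (", x$n_trials,
        " trials); threshold undefined\n", sep = "")
  invisible(x)
}

#' Sensitivity threshold from discrimination trials
#'
#' Fits the psychometric sigmoid and returns the 50%-point threshold; a
#' non-converged fit (inconsistent responses) raises an error rather than
#' producing a number, mirroring the exclusion of participants without a
#' determinable threshold.
#'
#' @inheritParams fit_sigmoid
#' @return One-row tibble: `threshold_pct`, `slope_pct`, `n_trials`,
#'   `boundary`.
#' @export
estimate_threshold <- function(data, method = c("wls", "binomial")) {
  fit <- fit_sigmoid(data, method)
  if (!fit$converged)
    abort("responses too inconsistent to determine a threshold (fit did not converge)")
  tibble(threshold_pct = fit$midpoint_pct, slope_pct = fit$slope_pct,
         n_trials = fit$n_trials, boundary = fit$boundary)
}

#' Run a simulated adaptive discrimination session
#'
#' Chains the adaptive scheduler and the simulated observer for a fixed
#' number of trials (or until the scheduler budget is spent).
#'
#' @param cfg A [psycho_sim_config()] describing the observer.
#' @param n_trials Number of trials to run (capped by the scheduler budget).
#' @param seed Integer seed driving both the scheduler and the observer.
#' @param state Optional pre-built [scheduler_state()].
#' @return Trials tibble (`intensity_pct`, `reported_equal`).
#' @export
simulate_discrimination_task <- function(cfg = psycho_sim_config(),
                                         n_trials = 40, seed = 1,
                                         state = NULL) {
  state <- state %||% scheduler_state(grid = cfg$intensity_grid,
                                      seed = derive_seed(seed, 101))
  trials <- tibble(intensity_pct = numeric(0), reported_equal = logical(0))
  for (i in seq_len(min(n_trials, state$max_trials))) {
    x <- next_intensity(trials, state)
    if (is.na(x)) break
    resp <- simulate_discrimination_responses(x, cfg,
                                              seed = derive_seed(seed, 1000 + i))
    trials <- dplyr::bind_rows(trials, resp)
  }
  trials
}
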