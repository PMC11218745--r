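# Offline classification: time-binned features, stepwise linear discriminant
# analysis (SWLDA), per-block 4-way target selection, block-wise leave-one-out
# cross-validation, and exact binomial chance-level bounds.

#' Classifier configuration
#'
#' @param channel_set `"cap"` (12 scalp channels), `"ceegrid"` (18 ear
#'   channels plus the 8 vertical bipolar derivations, 26 in total) or
#'   `"all"`.
#' @param feature_bin_ms Width of the consecutive time bins averaged into
#'   features (default 50 ms; over 0--800 ms this yields 16 bins per
#'   channel).
#' @param feature_window_ms Post-stimulus window binned into features.
#' @param p_enter,p_remove Partial-F p-value thresholds of the stepwise
#'   selection: a candidate enters while the smallest p-value is below
#'   `p_enter`, an included feature leaves when its p-value rises above
#'   `p_remove`. Defaults 0.10/0.15 with at most 60 features are the
#'   long-standing P300-classifier convention; the study names the stepwise
#'   tool but not its settings.
#' @param max_features Cap on the number of selected features (may be `Inf`).
#' @param reject_for_classification If `TRUE`, artifact-rejected epochs are
#'   excluded from classifier training and scoring; default `FALSE`
#'   (rejection belongs to the physiological analysis).
#' @return A list of class `gt_classifier_config`.
#' @export
classifier_config <- function(channel_set = c("cap", "ceegrid", "all"),
                              feature_bin_ms = 50,
                              feature_window_ms = c(0, 800),
                              p_enter = 0.10, p_remove = 0.15,
                              max_features = 60,
                              reject_for_classification = FALSE) {
  channel_set <- match.arg(channel_set)
  stopifnot(feature_bin_ms > 0, p_enter >= 0, p_remove >= 0,
            max_features >= 1)
  if (p_enter > p_remove)
    abort("p_enter must not exceed p_remove (prevents add/remove cycling)")
  structure(as.list(environment()), class = "gt_classifier_config")
}

#' Build time-binned classification features
#'
#' For every epoch and channel in the configured channel set, averages the
#' samples of consecutive `feature_bin_ms` segments over the post-stimulus
#' feature window and concatenates them (cap: 12 channels x 16 bins = 192
#' features; ear set: 26 channels x 16 = 416). A trailing partial bin is
#' dropped with a warning. Bin edges are laid on the sample grid by latency,
#' so bins may differ by one sample in length at rates where the bin width is
#' not a whole number of samples.
#'
#' @param eps Baseline-corrected `gt_epochs`.
#' @param cfg A [classifier_config()].
#' @param montage The [montage()] used to resolve the channel set.
#' @return A list with the feature matrix `X` (epochs x features), logical
#'   labels `y` (is-target), the per-feature `info` tibble (channel, bin) and
#'   the per-epoch `events` table.
#' @export
build_features <- function(eps, cfg = classifier_config(),
                           montage = default_montage()) {
  stopifnot(inherits(eps, "gt_epochs"))
  if (!eps$baseline_corrected)
    abort("build_features() requires baseline-corrected epochs")
  channels <- resolve_channel_set(montage, cfg$channel_set)
  missing <- setdiff(channels, eps$channels)
  if (length(missing))
    abort(paste0("channel(s) not in epochs: ", paste(missing, collapse = ", ")))
  t_post <- eps$times_ms
  sel <- which(t_post >= cfg$feature_window_ms[1] &
                 t_post < cfg$feature_window_ms[2])
  width <- cfg$feature_window_ms[2] - cfg$feature_window_ms[1]
  n_bins <- width %/% cfg$feature_bin_ms
  if (width %% cfg$feature_bin_ms != 0)
    warn("feature window is not a multiple of the bin width; dropping the partial last bin")
  bin_id <- (t_post[sel] - cfg$feature_window_ms[1]) %/% cfg$feature_bin_ms
  keep <- bin_id < n_bins
  sel <- sel[keep]; bin_id <- bin_id[keep]
  # samples x bins averaging operator
  W <- outer(bin_id, 0:(n_bins - 1), "==") * 1
  W <- sweep(W, 2, colSums(W), "/")
  n_ep <- n_epochs(eps)
  X <- matrix(0, n_ep, length(channels) * n_bins)
  for (i in seq_along(channels)) {
    E <- matrix(eps$data[channels[i], sel, ], nrow = length(sel))  # samples x epochs
    X[, ((i - 1) * n_bins + 1):(i * n_bins)] <- crossprod(E, W)
  }
  info <- tidyr::expand_grid(channel = channels, bin = seq_len(n_bins)) |>
    dplyr::mutate(
      bin_start_ms = cfg$feature_window_ms[1] + (.data$bin - 1) * cfg$feature_bin_ms)
  colnames(X) <- paste0(info$channel, ".b", info$bin)
  list(X = X, y = eps$events$is_target, info = info, events = eps$events,
       kept = eps$kept)
}

## ---- sweep-operator stepwise core ---------------------------------------

# Symmetric sweep of pivot k (Beaton/SWEEP operator); self-inverse up to sign
# bookkeeping handled by the caller tracking in/out status. Mutates A in
# place via the compiled kernel; callers pass freshly-created cross-product
# matrices.
sweep_pivot <- function(A, k) {
  cpp_sweep_inplace(A, as.integer(k))
  A
}

# Forward-backward stepwise least squares on the augmented cross-product
# matrix A = crossprod(cbind(1, X, y)), n observations, p features.
# Returns selected indices (1..p), weights, intercept and the selection path.
swlda_core <- function(A, n, p, p_enter, p_remove, max_features) {
  iy <- p + 2L
  A <- sweep_pivot(A, 1L)                 # intercept always in the model
  d0 <- diag(A)[2:(p + 1)]                # centered SS per feature
  in_model <- logical(p)
  path <- character(0)
  k <- 0L
  for (iter in seq_len(1000L)) {
    changed <- FALSE
    ## forward step: all candidates share df, so the smallest p-value is the
    ## largest partial F -- select on F and evaluate pf() once
    if (k < max_features) {
      cand <- which(!in_model)
      df2 <- n - k - 2L
      if (length(cand) && df2 > 0) {
        jj <- cand + 1L
        ajj <- A[cbind(jj, jj)]
        ajy <- A[cbind(jj, rep(iy, length(jj)))]
        eligible <- d0[cand] > 0 & ajj > 1e-10 * d0[cand]
        if (any(eligible)) {
          rss <- A[iy, iy]
          d_rss <- ajy^2 / ajj
          d_rss[!eligible] <- -Inf
          rem <- pmax(rss - d_rss, 0)
          f <- d_rss * df2 / rem           # Inf when the fit becomes perfect
          f[is.na(f)] <- -Inf              # 0/0 guard (already-perfect fit)
          best <- which.max(f)             # first index on ties
          pv <- pf(f[best], 1, df2, lower.tail = FALSE)
          if (eligible[best] && pv < p_enter) {
            j <- cand[best]
            A <- sweep_pivot(A, j + 1L)
            in_model[j] <- TRUE
            k <- k + 1L
            path <- c(path, paste0("+", j))
            changed <- TRUE
          }
        }
      }
    }
    ## backward steps: the largest p-value is the smallest F
    repeat {
      if (k == 0L) break
      mem <- which(in_model)
      jj <- mem + 1L
      d_rss <- A[cbind(jj, rep(iy, length(jj)))]^2 / (-A[cbind(jj, jj)])
      df2 <- n - 1L - k
      f <- d_rss * df2 / A[iy, iy]
      worst <- which.min(f)                # first index on ties
      pv <- pf(f[worst], 1, df2, lower.tail = FALSE)
      if (is.finite(f[worst]) && pv > p_remove) {
        j <- mem[worst]
        A <- sweep_pivot(A, j + 1L)        # sweep out (self-inverse)
        in_model[j] <- FALSE
        k <- k - 1L
        path <- c(path, paste0("-", j))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  sel <- which(in_model)
  list(
    selected = sel,
    weights = A[cbind(sel + 1L, rep(iy, length(sel)))],
    intercept = A[1L, iy],
    rss = A[iy, iy],
    path = path
  )
}

#' Fit a stepwise linear discriminant (SWLDA) model
#'
#' The classical P300 classifier: ordinary least-squares regression of the
#' class labels (target = +1, non-target = -1) on the features, with
#' forward-backward stepwise selection driven by partial-F p-values -- the
#' candidate with the smallest p-value enters while it is below `p_enter`,
#' and any included feature whose p-value rises above `p_remove` is removed,
#' until no change occurs or `max_features` is reached. The linear scores of
#' the final regression rank epochs by target-likeness; only their ordering
#' is used downstream, so the label coding is immaterial.
#'
#' @param features Feature matrix (epochs x features) or the list returned by
#'   [build_features()].
#' @param labels Logical (is-target) or two-valued labels; ignored when
#'   `features` is a [build_features()] list.
#' @param cfg A [classifier_config()].
#' @return An object of class `gt_swlda`: selected features, weights,
#'   intercept and training metadata. If no feature passes `p_enter` the
#'   model is flagged `degenerate` and scores are constant.
#' @export
swlda_fit <- function(features, labels = NULL, cfg = classifier_config()) {
  if (is.list(features) && !is.null(features$X)) {
    info <- features$info
    labels <- features$y
    features <- features$X
  } else info <- NULL
  features <- as.matrix(features)
  y <- label_pm1(labels)
  n <- nrow(features)
  if (n != length(y)) abort("feature/label length mismatch")
  if (n <= 2) abort("need more than 2 epochs to fit")
  if (length(unique(y)) < 2) abort("both classes must be present")
  A <- crossprod(cbind(1, features, y))
  fit <- swlda_core(A, n, ncol(features), cfg$p_enter, cfg$p_remove,
                    cfg$max_features)
  structure(
    list(selected = fit$selected,
         feature_names = colnames(features)[fit$selected],
         weights = fit$weights, intercept = fit$intercept,
         degenerate = length(fit$selected) == 0,
         n_features_candidate = ncol(features),
         n_target = sum(y > 0), n_nontarget = sum(y < 0),
         info = if (!is.null(info)) info[fit$selected, ] else NULL,
         path = fit$path, cfg = cfg),
    class = "gt_swlda"
  )
}

label_pm1 <- function(labels) {
  if (is.logical(labels)) return(ifelse(labels, 1, -1))
  u <- sort(unique(labels))
  if (length(u) > 2) abort("labels must be two-valued")
  ifelse(labels == u[length(u)], 1, -1)
}

#' @export
print.gt_swlda <- function(x, ...) {
  cat("<gt_swlda> ", length(x$selected), "/", x$n_features_candidate,
      " features selected", if (x$degenerate) " (degenerate)",
      "; trained on ", x$n_target, " target / ", x$n_nontarget,
      " non-target epochs\n", sep = "")
  invisible(x)
}

#' Linear discriminant scores
#'
#' `score()` evaluates `intercept + sum(weight * feature)` per epoch; higher
#' scores are more target-like. A degenerate (empty) model yields constant
#' scores.
#'
#' @param model A `gt_swlda` model.
#' @param features Feature matrix or [build_features()] list with the same
#'   feature dimension the model was trained on.
#' @return Numeric score per epoch.
#' @export
score <- function(model, features) {
  stopifnot(inherits(model, "gt_swlda"))
  if (is.list(features) && !is.null(features$X)) features <- features$X
  features <- as.matrix(features)
  if (ncol(features) != model$n_features_candidate)
    abort("feature dimension does not match the fitted model")
  if (model$degenerate) return(rep(model$intercept, nrow(features)))
  drop(model$intercept +
         features[, model$selected, drop = FALSE] %*% model$weights)
}

#' @export
predict.gt_swlda <- function(object, newdata, ...) score(object, newdata)

#' Select the attended position of one target block
#'
#' Aggregates epoch scores per stimulus position (mean over the block's
#' repetitions) and selects the arg-max. Ties resolve deterministically to
#' the first position in the canonical order front, back, left, right.
#'
#' @param scores Numeric score per epoch of the block.
#' @param events Event tibble rows for the same epochs (needs `position`,
#'   `is_target`, and `run`/`block` for bookkeeping).
#' @return One-row tibble: `run`, `block`, `true_target`, `chosen_position`,
#'   `correct`, plus one aggregated `score_<position>` column per position.
#' @export
select_target <- function(scores, events) {
  events <- as_tibble(events)
  stopifnot(length(scores) == nrow(events))
  positions <- POSITIONS[POSITIONS %in% events$position]
  if (!length(positions)) abort("no scored epochs in the block")
  agg <- vapply(positions, function(p) mean(scores[events$position == p]), 0)
  chosen <- positions[which.max(agg)]      # which.max: first index on ties
  truth <- unique(events$position[events$is_target])
  if (length(truth) != 1)
    abort("block must have exactly one target position")
  out <- tibble(
    run = events$run[1], block = events$block[1],
    true_target = truth, chosen_position = chosen,
    correct = chosen == truth
  )
  for (p in positions) out[[paste0("score_", p)]] <- agg[[p]]
  out
}

#' Block-wise leave-one-out cross-validated selection accuracy
#'
#' The offline accuracy metric: for every target block (8 per run, 48 for a
#' full session), an SWLDA model is trained on all other blocks' epochs and
#' the attended position of the held-out block is selected from the
#' aggregated scores. Leaving out whole target blocks (rather than single
#' epochs) keeps the held-out block's repetitions out of training. A
#' degenerate fold (no feature selected) is counted incorrect and reported.
#'
#' @param eps Baseline-corrected `gt_epochs` of one session.
#' @param cfg A [classifier_config()].
#' @param montage The [montage()] resolving the channel set.
#' @return An object of class `gt_accuracy`: the per-block selection table,
#'   `n_blocks`, `n_correct`, `accuracy_pct`, the exact binomial
#'   chance-significance bound at alpha = 0.05 and the 70% usability flag.
#' @export
loocv_accuracy <- function(eps, cfg = classifier_config(),
                           montage = default_montage()) {
  feats <- build_features(eps, cfg, montage)
  use <- if (cfg$reject_for_classification) feats$kept else
    rep(TRUE, nrow(feats$X))
  X <- feats$X[use, , drop = FALSE]
  ev <- feats$events[use, , drop = FALSE]
  fold <- paste(ev$run, ev$block, sep = ".")
  folds <- unique(fold)
  if (length(folds) < 2) abort("need at least 2 target blocks for LOO-CV")
  y <- ifelse(ev$is_target, 1, -1)
  Z <- cbind(1, X, y)
  A_tot <- crossprod(Z)
  n_tot <- nrow(Z)
  p <- ncol(X)
  selections <- vector("list", length(folds))
  n_degenerate <- 0L
  for (i in seq_along(folds)) {
    test <- fold == folds[i]
    A <- A_tot - crossprod(Z[test, , drop = FALSE])
    fit <- swlda_core(A, n_tot - sum(test), p, cfg$p_enter, cfg$p_remove,
                      cfg$max_features)
    if (length(fit$selected) == 0) {
      n_degenerate <- n_degenerate + 1L
      sel <- select_target(rep(0, sum(test)), ev[test, , drop = FALSE])
      sel$correct <- FALSE                 # degenerate fold counts incorrect
      sel$degenerate <- TRUE
    } else {
      s <- drop(fit$intercept +
                  X[test, fit$selected, drop = FALSE] %*% fit$weights)
      sel <- select_target(s, ev[test, , drop = FALSE])
      sel$degenerate <- FALSE
    }
    selections[[i]] <- sel
  }
  if (n_degenerate > 0)
    inform(paste0(n_degenerate,
                  " degenerate cross-validation fold(s) counted incorrect"))
  selections <- dplyr::bind_rows(selections)
  new_accuracy(selections, channel_set = cfg$channel_set)
}

new_accuracy <- function(selections, channel_set = NA_character_,
                         chance_p = 0.25, alpha = 0.05,
                         usability_pct = 70) {
  n_blocks <- nrow(selections)
  n_correct <- sum(selections$correct)
  thr <- chance_threshold(n_blocks, chance_p, alpha)
  structure(
    list(selections = selections, channel_set = channel_set,
         n_blocks = n_blocks, n_correct = n_correct,
         accuracy_pct = 100 * n_correct / n_blocks,
         chance_pct = 100 * chance_p,
         significance_threshold_pct = thr$threshold_pct,
         significant = n_correct >= thr$min_correct,
         usability_pct = usability_pct,
         meets_usability = 100 * n_correct / n_blocks >= usability_pct),
    class = "gt_accuracy"
  )
}

#' @export
print.gt_accuracy <- function(x, ...) {
  cat("<gt_accuracy> ", x$n_correct, "/", x$n_blocks, " blocks = ",
      round(x$accuracy_pct, 1), "% (chance ", x$chance_pct,
      "%, significance bound ", round(x$significance_threshold_pct, 1),
      "%", if (!x$significant) ", NOT significant",
      if (x$meets_usability) ", usable" else ", below 70% usability",
      ")\n", sep = "")
  invisible(x)
}

#' Exact binomial chance-level bound
#'
#' Smallest number of correct selections k whose exact binomial tail
#' probability P(X >= k | n, chance_p) falls below `alpha`; the corresponding
#' accuracy is the chance-significance bound. For 48 four-choice selections
#' at alpha = 0.05 this gives k = 18, i.e. 37.5% (conventionally floor-rounded
#' to 37% when quoted as an integer).
#'
#' @param n_selections Number of independent selections.
#' @param chance_p Per-selection chance probability (0.25 for four positions).
#' @param alpha Significance level in (0, 1).
#' @return A list with `min_correct`, `threshold_pct` and
#'   `threshold_pct_floor`.
#' @export
#' @examples
#' chance_threshold(48, 0.25, 0.05)
chance_threshold <- function(n_selections, chance_p = 0.25, alpha = 0.05) {
  stopifnot(n_selections >= 1, chance_p > 0, chance_p < 1)
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  k <- 0:n_selections
  tail_p <- pbinom(k - 1, n_selections, chance_p, lower.tail = FALSE)
  min_correct <- k[match(TRUE, tail_p < alpha)]
  if (is.na(min_correct)) min_correct <- n_selections + 1L
  list(min_correct = as.integer(min_correct),
       threshold_pct = 100 * min_correct / n_selections,
       threshold_pct_floor = floor(100 * min_correct / n_selections))
}
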