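# Group-level inference: paired t-test, Pearson correlation, one-way
# within-subject ANOVA with Greenhouse-Geisser correction and Bonferroni
# post-hocs, and the study report tables.

new_group_result <- function(test, statistic, df, p_value, effect_size,
                             effect_type, correction = "none", df2 = NA_real_,
                             estimate = NA_real_, extra = list()) {
  out <- tibble(test = test, statistic = statistic, df = df, df2 = df2,
                p_value = p_value, estimate = estimate,
                effect_size = effect_size, effect_type = effect_type,
                correction = correction)
  structure(c(list(result = out), extra), class = "gt_group_result")
}

#' @export
print.gt_group_result <- function(x, ...) {
  print(x$result)
  if (!is.null(x$posthoc)) {
    cat("post-hoc (Bonferroni):\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' Two-tailed paired t-test
#'
#' Paired comparison of per-subject values (e.g. the two systems'
#' accuracies), via [stats::t.test()]. The effect size reported is the
#' point-biserial-style r = sqrt(t^2 / (t^2 + df)).
#'
#' @param a,b Numeric vectors of per-subject values, paired by position.
#' @return A `gt_group_result`; `statistic` is t, `df` = n - 1.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) abort("paired samples must have equal length")
  if (length(a) < 3) abort("need at least 3 pairs")
  d <- a - b
  if (sd(d) < 1e-12) {
    # zero-variance differences: t is undefined (0/0) except for identical
    # means; report the degenerate case explicitly
    return(new_group_result("paired t", statistic = 0,
                            df = length(a) - 1, p_value = 1,
                            effect_size = 0, effect_type = "r",
                            estimate = mean(d),
                            extra = list(degenerate = TRUE)))
  }
  ht <- t.test(a, b, paired = TRUE)
  r <- sqrt(ht$statistic^2 / (ht$statistic^2 + ht$parameter))
  new_group_result("paired t", statistic = unname(ht$statistic),
                   df = unname(ht$parameter), p_value = ht$p.value,
                   effect_size = unname(r), effect_type = "r",
                   estimate = unname(ht$estimate))
}

#' Pearson correlation test
#'
#' Two-tailed correlation via [stats::cor.test()]; zero-variance input yields
#' an explicit degenerate result with undefined r.
#'
#' @param x,y Numeric vectors (pairwise complete; n >= 3).
#' @return A `gt_group_result`; `estimate` and `effect_size` are r.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) < 1e-12 || sd(y) < 1e-12)
    return(new_group_result("Pearson r", statistic = NA_real_,
                            df = length(x) - 2, p_value = NA_real_,
                            effect_size = NA_real_, effect_type = "r",
                            extra = list(degenerate = TRUE)))
  ht <- cor.test(x, y, method = "pearson")
  new_group_result("Pearson r", statistic = unname(ht$statistic),
                   df = unname(ht$parameter), p_value = ht$p.value,
                   effect_size = unname(ht$estimate), effect_type = "r",
                   estimate = unname(ht$estimate))
}

#' One-way within-subject ANOVA with Greenhouse-Geisser correction
#'
#' Repeated-measures ANOVA of a complete subjects x conditions matrix (e.g.
#' window amplitudes on the channels of interest). Sphericity is assessed
#' with Mauchly's test; when violated at `mauchly_alpha` the
#' Greenhouse-Geisser epsilon deflates both degrees of freedom (reported
#' fractional). Partial eta-squared and all pairwise Bonferroni-corrected
#' paired t post-hocs are included.
#'
#' @param values Numeric matrix or data frame, subjects x conditions,
#'   complete (no missing cells; no imputation is attempted).
#' @param mauchly_alpha Significance level of Mauchly's sphericity test that
#'   triggers the correction (0.05; the policy is fixed, the trigger level a
#'   convention).
#' @return A `gt_group_result` with the (possibly corrected) F test in
#'   `$result`, Mauchly's test in `$mauchly`, `$epsilon_gg`, and the
#'   post-hoc table in `$posthoc`.
#' @export
rm_anova_gg <- function(values, mauchly_alpha = 0.05) {
  Y <- as.matrix(values)
  if (anyNA(Y)) abort("missing cells are not allowed (no imputation)")
  n <- nrow(Y); k <- ncol(Y)
  if (k < 2) abort("need at least 2 conditions")
  if (n < 3) abort("need at least 3 subjects")
  grand <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  f_stat <- if (ss_cond <= 1e-12 * max(ss_tot, 1)) 0
    else if (ms_err <= 0) Inf else ms_cond / ms_err
  eta_p2 <- if (ss_cond + ss_err > 0) ss_cond / (ss_cond + ss_err) else 0

  # Greenhouse-Geisser epsilon from the eigenvalues of the contrast-projected
  # covariance of the condition scores
  S <- stats::cov(Y)
  C <- qr.Q(qr(stats::contr.helmert(k)))    # orthonormal contrasts, k x (k-1)
  E <- crossprod(C, S %*% C)
  ev <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
  eps_gg <- sum(ev)^2 / (df1 * sum(ev^2))
  if (!is.finite(eps_gg)) eps_gg <- 1

  mauchly <- mauchly_test(Y)
  corrected <- is.finite(mauchly$p_value) && mauchly$p_value < mauchly_alpha
  use_df1 <- if (corrected) eps_gg * df1 else df1
  use_df2 <- if (corrected) eps_gg * df2 else df2
  p_value <- pf(f_stat, use_df1, use_df2, lower.tail = FALSE)

  pairs <- utils::combn(k, 2)
  labels <- colnames(Y) %||% paste0("c", seq_len(k))
  m <- ncol(pairs)
  posthoc <- purrr::map_dfr(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    res <- paired_t(Y[, a], Y[, b])$result
    tibble(condition_1 = labels[a], condition_2 = labels[b],
           mean_diff = mean(Y[, a] - Y[, b]),
           statistic = res$statistic, df = res$df,
           p_uncorrected = res$p_value,
           p_bonferroni = pmin(res$p_value * m, 1))
  })

  new_group_result(
    "RM-ANOVA", statistic = f_stat, df = use_df1, df2 = use_df2,
    p_value = p_value, effect_size = eta_p2, effect_type = "partial_eta_sq",
    correction = if (corrected) "greenhouse-geisser" else "none",
    extra = list(
      epsilon_gg = eps_gg, df_uncorrected = c(df1, df2),
      ss = c(condition = ss_cond, subject = ss_subj, error = ss_err),
      mauchly = mauchly, posthoc = posthoc
    )
  )
}

# Mauchly's sphericity test of the within-subject contrasts, delegated to
# stats::mauchly.test on the intercept-only multivariate fit; a degenerate
# covariance (e.g. identical conditions) yields an NA test and no correction
mauchly_test <- function(Y) {
  k <- ncol(Y)
  # the contrast covariance is singular when subjects <= conditions - 1;
  # the test is undefined there and no correction is triggered
  if (k < 3 || nrow(Y) - 1 < k)
    return(list(W = NA_real_, p_value = NA_real_, df = NA_real_))
  tryCatch(suppressWarnings({
    colnames(Y) <- paste0("c", seq_len(k))
    mlm <- stats::lm(Y ~ 1)
    idata <- data.frame(cond = factor(colnames(Y), levels = colnames(Y)))
    mt <- stats::mauchly.test(mlm, M = ~cond, X = ~1, idata = idata)
    list(W = unname(mt$statistic), p_value = mt$p.value,
         df = unname(mt$parameter))
  }), error = function(e) list(W = NA_real_, p_value = NA_real_,
                               df = NA_real_))
}

#' Assemble the study report tables
#'
#' Builds the two report tables of the analysis: the group amplitude table
#' (per-channel mean and SD of the target window amplitudes) and the
#' per-subject overview of offline accuracies and sensitivity thresholds. In
#' the formatted overview, accuracies below the 70% usability criterion are
#' marked `*`, accuracies below the exact binomial chance-significance bound
#' are marked `+`, and missing values are rendered as en-dashes.
#'
#' @param features Feature tibble from [feature_table()].
#' @param accuracies Tibble with one row per subject: `subject`,
#'   `cap_accuracy_pct`, `ceegrid_accuracy_pct` (NA allowed), and optionally
#'   the per-system `significant`/`usable` flags; plus
#'   `sensitivity_threshold_pct` (NA allowed).
#' @param n_blocks Selections per subject behind each accuracy (for the
#'   significance bound; default 48).
#' @param out_dir Optional directory; when given, the tables are written as
#'   `table_amplitudes.csv` and `table_accuracy.csv`.
#' @return A list with tibbles `amplitudes`, `accuracy` (numeric + flags) and
#'   `accuracy_formatted`.
#' @export
report_tables <- function(features, accuracies, n_blocks = 48,
                          out_dir = NULL) {
  amplitudes <- summarise_features(features)
  thr <- chance_threshold(n_blocks, 0.25, 0.05)$threshold_pct
  fmt <- function(acc) {
    dplyr::case_when(
      is.na(acc) ~ "–",
      acc < thr ~ paste0(round(acc), "+"),
      acc < 70 ~ paste0(round(acc), "*"),
      TRUE ~ as.character(round(acc))
    )
  }
  accuracy <- as_tibble(accuracies) |>
    dplyr::mutate(
      cap_significant = .data$cap_accuracy_pct >= thr,
      ceegrid_significant = .data$ceegrid_accuracy_pct >= thr,
      cap_usable = .data$cap_accuracy_pct >= 70,
      ceegrid_usable = .data$ceegrid_accuracy_pct >= 70
    )
  accuracy_formatted <- accuracy |>
    dplyr::transmute(
      subject = .data$subject,
      cap = fmt(.data$cap_accuracy_pct),
      ceegrid = fmt(.data$ceegrid_accuracy_pct),
      sensitivity = ifelse(is.na(.data$sensitivity_threshold_pct), "–",
                           format(round(.data$sensitivity_threshold_pct, 1)))
    )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(amplitudes, file.path(out_dir, "table_amplitudes.csv"))
    readr::write_csv(accuracy, file.path(out_dir, "table_accuracy.csv"))
  }
  list(amplitudes = amplitudes, accuracy = accuracy,
       accuracy_formatted = accuracy_formatted)
}
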