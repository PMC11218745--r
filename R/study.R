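# End-to-end study orchestration: simulate -> preprocess -> ERP/classify ->
# psychophysics -> report, for a cohort of synthetic subjects.

#' Study configuration
#'
#' Bundles every stage's configuration plus the cohort-level heterogeneity
#' model. Per-subject variation emulates the spread seen in real cohorts:
#' log-normal scaling of all ERP amplitudes, a small probability of fully
#' inverted ERP polarity (observed in 2 of 37 participants), log-normal
#' scaling of the noise level, and per-subject psychometric thresholds and
#' trial counts drawn around the group-level values. All distributions are
#' configuration, not measured facts.
#'
#' @param n_subjects Number of simulated subjects.
#' @param master_seed Master seed; all per-subject seeds derive from it via
#'   [derive_seed()].
#' @param paradigm,generator,preprocess A [paradigm_config()],
#'   [generator_config()] and [preprocess_config()].
#' @param cap_classifier,ceegrid_classifier [classifier_config()]s for the
#'   two systems.
#' @param montage The recording [montage()].
#' @param heterogeneity List with `amplitude_sdlog`, `polarity_invert_prob`,
#'   `noise_sdlog`.
#' @param psycho List with observer population parameters: `threshold_mean`,
#'   `threshold_sd`, `slope`, `n_trials_mean`, `n_trials_sd`,
#'   `n_trials_range`.
#' @param out_dir Optional output directory for CSV tables and the
#'   provenance log.
#' @return A list of class `gt_study_config`.
#' @export
study_config <- function(n_subjects = 10, master_seed = 1,
                         paradigm = paradigm_config(),
                         generator = generator_config(),
                         preprocess = preprocess_config(),
                         cap_classifier = classifier_config("cap"),
                         ceegrid_classifier = classifier_config("ceegrid"),
                         montage = default_montage(),
                         heterogeneity = list(amplitude_sdlog = 0.35,
                                              polarity_invert_prob = 2 / 37,
                                              noise_sdlog = 0.15),
                         psycho = list(threshold_mean = 74.6,
                                       threshold_sd = 9.0, slope = 4,
                                       n_trials_mean = 37, n_trials_sd = 8.7,
                                       n_trials_range = c(15, 53)),
                         out_dir = NULL) {
  stopifnot(n_subjects >= 1)
  structure(as.list(environment()), class = "gt_study_config")
}

# per-subject heterogeneity draw, reproducible from the master seed
subject_params <- function(cfg, i) {
  h <- cfg$heterogeneity
  p <- cfg$psycho
  with_seed_(derive_seed(cfg$master_seed, i * 13), {
    thr_range <- range(psycho_sim_config()$intensity_grid)
    list(
      amplitude_scale = stats::rlnorm(1, 0, h$amplitude_sdlog),
      polarity_sign = if (runif(1) < h$polarity_invert_prob) -1 else 1,
      noise_scale = stats::rlnorm(1, 0, h$noise_sdlog),
      psycho_threshold = clamp(rnorm(1, p$threshold_mean, p$threshold_sd),
                               thr_range[1] + 2, thr_range[2] - 2),
      psycho_n_trials = as.integer(clamp(round(rnorm(1, p$n_trials_mean,
                                                     p$n_trials_sd)),
                                         p$n_trials_range[1],
                                         p$n_trials_range[2]))
    )
  })
}

# ERP physiology for one subject: per-system artifact rejection scoped to the
# channels entering that system's analysis, then class averaging
subject_erp <- function(eps, montage, preproc,
                        channels = erp_channels_of_interest()) {
  scalp <- intersect(channels$channel[channels$system == "cap"], eps$channels)
  ear <- intersect(channels$channel[channels$system == "ceegrid"],
                   eps$channels)
  avg_cap <- average(reject_artifacts(eps, preproc, channels = scalp))
  avg_grid <- average(reject_artifacts(eps, preproc, channels = ear))
  feats <- dplyr::bind_rows(
    feature_table(list(s = avg_cap), channels[channels$system == "cap", ]),
    feature_table(list(s = avg_grid), channels[channels$system == "ceegrid", ])
  )
  list(features = feats[-1], avg_cap = avg_cap, avg_grid = avg_grid)
}

#' Run a full simulated study
#'
#' For every simulated subject: schedule the oddball session, synthesize the
#' EEG with that subject's amplitude scale, polarity and noise level, derive
#' the bipolar ear channels, run the offline signal path, extract the ERP
#' features (with per-system scoped artifact rejection), compute block-wise
#' leave-one-out accuracies for both channel systems, and run the adaptive
#' intensity-discrimination task. Group-level statistics (paired t of the
#' systems' accuracies, the amplitude and accuracy correlations,
#' sensitivity-accuracy correlations, and the within-subject channel ANOVA)
#' are computed when at least three subjects are available. A subject whose
#' psychometric fit does not converge gets a missing threshold, mirroring
#' real exclusions; a stage failure skips that subject with a logged reason.
#'
#' @param cfg A [study_config()].
#' @return An object of class `gt_study`: per-subject accuracy table,
#'   feature table, class averages, group statistics, report tables and a
#'   provenance record.
#' @export
run_study <- function(cfg = study_config()) {
  stopifnot(inherits(cfg, "gt_study_config"))
  subjects <- vector("list", cfg$n_subjects)
  features <- vector("list", cfg$n_subjects)
  averages <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    id <- sprintf("P%02d", i)
    res <- tryCatch({
      par <- subject_params(cfg, i)
      gen <- cfg$generator
      gen$amplitude_scale <- gen$amplitude_scale * par$amplitude_scale
      gen$polarity_sign <- gen$polarity_sign * par$polarity_sign
      gen$noise_sd_uv <- gen$noise_sd_uv * par$noise_scale
      sch <- schedule_session(cfg$paradigm,
                              seed = derive_seed(cfg$master_seed, i * 13 + 1))
      rec <- synthesize_recording(sch, cfg$montage, gen,
                                  seed = derive_seed(cfg$master_seed,
                                                     i * 13 + 2))
      rec <- derive_bipolar(rec, cfg$montage)
      rec <- bandpass(rec, cfg$preprocess)
      eps <- baseline_correct(epoch(rec, cfg$preprocess))
      erp <- subject_erp(eps, cfg$montage, cfg$preprocess)
      acc_cap <- loocv_accuracy(eps, cfg$cap_classifier, cfg$montage)
      acc_grid <- loocv_accuracy(eps, cfg$ceegrid_classifier, cfg$montage)
      obs <- psycho_sim_config(true_threshold_pct = par$psycho_threshold,
                               slope_pct = cfg$psycho$slope)
      trials <- simulate_discrimination_task(
        obs, n_trials = par$psycho_n_trials,
        seed = derive_seed(cfg$master_seed, i * 13 + 3))
      thr <- tryCatch(estimate_threshold(trials)$threshold_pct,
                      error = function(e) NA_real_)
      list(
        row = tibble(
          subject = id,
          cap_accuracy_pct = acc_cap$accuracy_pct,
          ceegrid_accuracy_pct = acc_grid$accuracy_pct,
          cap_significant = acc_cap$significant,
          ceegrid_significant = acc_grid$significant,
          cap_usable = acc_cap$meets_usability,
          ceegrid_usable = acc_grid$meets_usability,
          n_blocks = acc_cap$n_blocks,
          sensitivity_threshold_pct = thr,
          psycho_n_trials = nrow(trials),
          amplitude_scale = par$amplitude_scale,
          polarity_sign = par$polarity_sign
        ),
        features = dplyr::bind_cols(tibble(subject = id), erp$features),
        averages = list(cap = erp$avg_cap, ceegrid = erp$avg_grid)
      )
    }, error = function(e) {
      warn(paste0("subject ", id, " failed and was skipped: ",
                  conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    subjects[[i]] <- res$row
    features[[i]] <- res$features
    averages[[i]] <- res$averages
  }
  names(averages) <- sprintf("P%02d", seq_len(cfg$n_subjects))
  ok <- !vapply(subjects, is.null, TRUE)
  subjects <- dplyr::bind_rows(subjects)
  features <- dplyr::bind_rows(features)
  averages <- averages[ok]

  group <- NULL
  if (nrow(subjects) >= 3) {
    amp_wide <- features |>
      dplyr::select("subject", "channel", "mean_amplitude_uv") |>
      tidyr::pivot_wider(names_from = "channel",
                         values_from = "mean_amplitude_uv")
    amp_mat <- as.matrix(amp_wide[-1])
    rownames(amp_mat) <- amp_wide$subject
    coi <- erp_channels_of_interest()$channel
    amp_mat <- amp_mat[, intersect(coi, colnames(amp_mat)), drop = FALSE]
    group <- list(
      accuracy_cap_vs_ceegrid = paired_t(subjects$cap_accuracy_pct,
                                         subjects$ceegrid_accuracy_pct),
      accuracy_correlation = pearson(subjects$cap_accuracy_pct,
                                     subjects$ceegrid_accuracy_pct),
      amplitude_correlation = tryCatch(
        pearson(amp_mat[, "Cz"], amp_mat[, "R2-R7"]),
        error = function(e) NULL),
      sensitivity_vs_cap = tryCatch(
        pearson(subjects$sensitivity_threshold_pct,
                subjects$cap_accuracy_pct), error = function(e) NULL),
      sensitivity_vs_ceegrid = tryCatch(
        pearson(subjects$sensitivity_threshold_pct,
                subjects$ceegrid_accuracy_pct), error = function(e) NULL),
      channel_anova = if (ncol(amp_mat) >= 2) rm_anova_gg(amp_mat)
    )
  }

  tables <- report_tables(features, subjects,
                          n_blocks = subjects$n_blocks[1] %||% 48,
                          out_dir = cfg$out_dir)
  provenance <- list(
    package_version = as.character(packageVersion("gridtap")),
    master_seed = cfg$master_seed, n_subjects = cfg$n_subjects,
    n_completed = nrow(subjects),
    generator = cfg$generator[c("erp_amplitude_uv", "erp_peak_ms",
                                "noise_sd_uv", "noise_spectrum")],
    timestamp = format(Sys.time(), tz = "UTC")
  )
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(provenance,
                         file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(
    list(subjects = subjects, features = features, averages = averages,
         group = group, tables = tables, provenance = provenance,
         config = cfg),
    class = "gt_study"
  )
}

#' @export
print.gt_study <- function(x, ...) {
  cat("<gt_study> ", nrow(x$subjects), " subjects\n", sep = "")
  cat("  mean accuracy: cap ", round(mean(x$subjects$cap_accuracy_pct), 1),
      "%, cEEGrid ", round(mean(x$subjects$ceegrid_accuracy_pct), 1),
      "%\n", sep = "")
  thr <- x$subjects$sensitivity_threshold_pct
  if (any(!is.na(thr)))
    cat("  mean sensitivity threshold: ", round(mean(thr, na.rm = TRUE), 1),
        "% (", sum(is.na(thr)), " undetermined)\n", sep = "")
  invisible(x)
}
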