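test_that("a full session yields 480 target and 1440 non-target stimuli", {
  sch <- schedule_session(paradigm_config(), seed = 1)
  expect_equal(nrow(sch), 1920)
  expect_equal(sum(sch$is_target), 480)
  expect_equal(sum(!sch$is_target), 1440)
  # 8 blocks per run, each position the target exactly twice per run
  per_run <- dplyr::group_by(sch, run)
  expect_equal(unique(dplyr::summarise(per_run,
                                       n = dplyr::n_distinct(block))$n), 8)
  targets <- sch |>
    dplyr::filter(is_target) |>
    dplyr::distinct(run, block, position) |>
    dplyr::count(run, position)
  expect_true(all(targets$n == 2))
})

test_that("block structure holds for any seed: 10 per position, no repeated targets", {
  cfg <- paradigm_config()
  for (seed in 1:100) {
    sch <- schedule_session(cfg, seed = seed)
    counts <- dplyr::count(sch, run, block, position)
    expect_true(all(counts$n == 10))
    tseq <- sch |>
      dplyr::filter(is_target) |>
      dplyr::distinct(run, block, position)
    expect_false(any(tseq$position[-1] == tseq$position[-nrow(tseq)]))
  }
})

test_that("a reduced paradigm is enumerable: 1 run, 1 rep -> 4 target / 12 non-target", {
  sch <- schedule_session(paradigm_config(n_runs = 1,
                                          reps_per_tactor_per_block = 1,
                                          targets_per_position_per_run = 1),
                          seed = 3)
  expect_equal(nrow(sch), 16)
  expect_equal(sum(sch$is_target), 4)
  expect_equal(sum(!sch$is_target), 12)
})

test_that("impossible constraints and single-position no-repeat are rejected", {
  expect_error(schedule_session(paradigm_config(positions = "front"),
                                seed = 1), "single position")
})

test_that("onsets within a block are spaced by the stimulus-onset asynchrony", {
  sch <- schedule_session(paradigm_config(), seed = 5)
  d <- sch |>
    dplyr::group_by(run, block) |>
    dplyr::summarise(gaps = list(round(diff(onset_s), 9)), .groups = "drop")
  expect_true(all(vapply(d$gaps, function(g) all(g == 0.62), TRUE)))
})

test_that("schedules and signals are bit-identical under the same seed", {
  cfg <- paradigm_config(n_runs = 1)
  s1 <- schedule_session(cfg, seed = 7)
  s2 <- schedule_session(cfg, seed = 7)
  expect_identical(s1, s2)
  m <- default_montage()
  gen <- generator_config(noise_sd_uv = 5)
  r1 <- synthesize_recording(s1[1:40, ], m, gen, seed = 8)
  r2 <- synthesize_recording(s1[1:40, ], m, gen, seed = 8)
  expect_identical(r1$signal, r2$signal)
})

test_that("noise-free single-target window means equal the calibrated amplitudes exactly", {
  m <- default_montage()
  ev <- toy_events(c(2, 5), positions = c("front", "back"),
                   is_target = c(TRUE, FALSE))
  rec <- synthesize_recording(ev, m, generator_config(noise_sd_uv = 0),
                              seed = 1)
  eps <- baseline_correct(epoch(derive_bipolar(rec, m)))
  avg <- average(eps)
  expect_equal(mean_amplitude(avg, "Cz", c(350, 650)), 3.53, tolerance = 1e-12)
  expect_equal(mean_amplitude(avg, "Fz", c(350, 650)), 2.70, tolerance = 1e-12)
  expect_equal(mean_amplitude(avg, "R2-R7", c(400, 700)), 1.87,
               tolerance = 1e-12)
  # non-target epochs stay at baseline by default
  expect_equal(mean_amplitude(avg, "Cz", c(350, 650), class = "nontarget"), 0)
  # inverted-polarity subjects flip the deflection sign
  rec2 <- synthesize_recording(ev, m,
                               generator_config(noise_sd_uv = 0,
                                                polarity_sign = -1), seed = 1)
  avg2 <- average(baseline_correct(epoch(derive_bipolar(rec2, m))))
  expect_equal(mean_amplitude(avg2, "Cz", c(350, 650)), -3.53,
               tolerance = 1e-12)
})

test_that("a zero amplitude map with zero noise yields an identically zero recording", {
  ev <- toy_events(2)
  rec <- synthesize_recording(ev, default_montage(),
                              generator_config(erp_amplitude_uv = c(Cz = 0),
                                               noise_sd_uv = 0), seed = 1)
  expect_equal(max(abs(rec$signal)), 0)
})

test_that("amplitude map channels must exist in the montage", {
  ev <- toy_events(2)
  expect_error(
    synthesize_recording(ev, default_montage(),
                         generator_config(erp_amplitude_uv = c(Nope = 1))),
    "Nope")
})

test_that("artifact injections are counted exactly by the rejection stage", {
  m <- default_montage()
  sch <- schedule_session(paradigm_config(n_runs = 1), seed = 2)
  sch <- sch[sch$block <= 3, ]            # 120 epochs
  gen <- generator_config(erp_amplitude_uv = c(Cz = 0), noise_sd_uv = 2,
                          artifact_epoch_rate = 0.1,
                          artifact_amplitude_uv = 120)
  rec <- synthesize_recording(sch, m, gen, seed = 9)
  n_injected <- nrow(rec$meta$artifacts)
  expect_gt(n_injected, 2)
  eps <- reject_artifacts(baseline_correct(epoch(rec)))
  expect_equal(sum(!eps$kept), n_injected)
  expect_setequal(which(!eps$kept), rec$meta$artifacts$event_index)
  # the generator refuses sub-threshold artifact amplitudes
  expect_error(generator_config(artifact_epoch_rate = 0.1,
                                artifact_amplitude_uv = 60), "75")
})

test_that("grand-average difference recovers the injected template shape", {
  m <- default_montage()
  sch <- schedule_session(paradigm_config(n_runs = 1), seed = 4)
  rec <- synthesize_recording(sch, m, generator_config(noise_sd_uv = 0),
                              seed = 5)
  eps <- baseline_correct(epoch(derive_bipolar(rec, m)))
  avg <- average(eps)
  diffw <- avg$target["Cz", ] - avg$nontarget["Cz", ]
  gen <- generator_config()
  tpl <- gridtap:::erp_template(gen$erp_peak_ms[["scalp"]], gen$erp_width_ms,
                                gen$erp_support_ms, 250)
  ref <- rep(0, length(avg$times_ms))
  sel <- match(tpl$offsets * 4, avg$times_ms)
  ref[sel[!is.na(sel)]] <- tpl$values[!is.na(sel)]
  expect_gt(cor(diffw, ref), 0.99)
})

test_that("discrimination responses follow the logistic observer model", {
  cfg <- psycho_sim_config(true_threshold_pct = 75, slope_pct = 4)
  # sigmoid midpoint: P(equal) = 0.5
  r <- simulate_discrimination_responses(rep(75, 10000), cfg, seed = 1)
  expect_lt(abs(mean(r$reported_equal) - 0.5), 3 * sqrt(0.25 / 10000))
  # identical stimuli with a steep slope are reported equal almost surely
  steep <- psycho_sim_config(true_threshold_pct = 75, slope_pct = 0.5)
  r2 <- simulate_discrimination_responses(rep(100, 2000), steep, seed = 2)
  expect_gt(mean(r2$reported_equal), 0.99)
  # empirical ratio at an off-midpoint intensity within 3 binomial SE
  p_true <- plogis((65 - 75) / 4)
  r3 <- simulate_discrimination_responses(rep(65, 10000), cfg, seed = 3)
  expect_lt(abs(mean(r3$reported_equal) - p_true),
            3 * sqrt(p_true * (1 - p_true) / 10000))
  # intensities must lie on the grid
  expect_error(simulate_discrimination_responses(62.5, cfg), "grid")
})
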