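test_that("the paired t-test matches the textbook formula and handles degeneracy", {
  # hand-worked 4-pair example
  a <- c(81, 92, 73, 96)
  b <- c(63, 75, 50, 90)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  p_hand <- 2 * pt(-abs(t_hand), 3)
  res <- paired_t(a, b)$result
  expect_equal(res$statistic, t_hand)
  expect_equal(res$df, 3)
  expect_equal(res$p_value, p_hand)
  # identical samples: t = 0, p = 1
  res0 <- paired_t(a, a)$result
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  expect_error(paired_t(a, b[1:3]), "equal length")
  expect_error(paired_t(1:2, 3:4), "at least 3")
})

test_that("paired-t type-I error is calibrated under the null", {
  withr::with_seed(41, {
    n_rej <- 0
    reps <- 2000
    for (i in seq_len(reps)) {
      a <- rnorm(8)
      b <- rnorm(8)
      if (paired_t(a, b)$result$p_value < 0.05) n_rej <- n_rej + 1
    }
    rate <- n_rej / reps
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
  })
})

test_that("Pearson correlation matches the covariance/SD computation", {
  x <- c(1, 3, 4, 6, 8)
  y <- c(2, 3, 5, 5, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  res <- pearson(x, y)$result
  expect_equal(res$estimate, r_hand)
  expect_equal(res$statistic, t_hand)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 3))
  expect_equal(pearson(x, x)$result$estimate, 1)
  expect_equal(pearson(x, -x)$result$estimate, -1)
  expect_true(isTRUE(pearson(x, rep(1, 5))$degenerate))
  # incomplete pairs are dropped
  expect_equal(pearson(c(x, NA), c(y, 1))$result$df, 3)
})

test_that("the within-subject ANOVA reduces to the squared paired t for 2 conditions", {
  withr::with_seed(42, {
    Y <- cbind(a = rnorm(12, 1), b = rnorm(12))
    res <- rm_anova_gg(Y)
    tt <- paired_t(Y[, 1], Y[, 2])$result
    expect_equal(res$result$statistic, tt$statistic^2, tolerance = 1e-8)
    expect_equal(res$result$p_value, tt$p_value, tolerance = 1e-8)
    # identical columns give F = 0
    expect_equal(rm_anova_gg(cbind(Y[, 1], Y[, 1]))$result$statistic, 0)
  })
})

test_that("F, GG epsilon, corrected dfs and eta_p^2 match car::Anova on random data", {
  skip_if_not_installed("car")
  withr::with_seed(43, {
    for (i in 1:50) {
      n <- sample(6:15, 1)
      k <- sample(3:6, 1)
      # induce heterogeneous covariance so sphericity is often violated
      Y <- matrix(rnorm(n * k), n, k) %*% diag(seq(0.5, 2, length.out = k)) +
        rnorm(n)
      colnames(Y) <- paste0("c", 1:k)
      mine <- rm_anova_gg(Y)
      mlm <- lm(Y ~ 1)
      idata <- data.frame(cond = factor(colnames(Y), levels = colnames(Y)))
      a <- car::Anova(mlm, idata = idata, idesign = ~cond, type = 3)
      s <- suppressWarnings(summary(a, multivariate = FALSE))
      f_ref <- s$univariate.tests["cond", "F value"]
      df1_ref <- s$univariate.tests["cond", "num Df"]
      df2_ref <- s$univariate.tests["cond", "den Df"]
      eps_ref <- s$pval.adjustments["cond", "GG eps"]
      p_gg_ref <- s$pval.adjustments["cond", "Pr(>F[GG])"]
      w_ref <- s$sphericity.tests["cond", "Test statistic"]
      p_mauchly_ref <- s$sphericity.tests["cond", "p-value"]
      expect_equal(mine$result$statistic, unname(f_ref), tolerance = 1e-8)
      expect_equal(mine$epsilon_gg, unname(eps_ref), tolerance = 1e-8)
      expect_equal(mine$df_uncorrected, c(df1_ref, df2_ref))
      expect_equal(mine$mauchly$W, unname(w_ref), tolerance = 1e-8)
      expect_equal(mine$mauchly$p_value, unname(p_mauchly_ref),
                   tolerance = 1e-6)
      if (mine$result$correction == "greenhouse-geisser") {
        expect_equal(mine$result$p_value, unname(p_gg_ref), tolerance = 1e-6)
        expect_equal(mine$result$df, unname(eps_ref * df1_ref),
                     tolerance = 1e-8)
      }
      # partial eta squared from the car sums of squares
      ss_c <- s$univariate.tests["cond", "Sum Sq"]
      ss_e <- s$univariate.tests["cond", "Error SS"]
      expect_equal(mine$result$effect_size, unname(ss_c / (ss_c + ss_e)),
                   tolerance = 1e-8)
    }
  })
})

test_that("paired t and Pearson match independent computations on random data", {
  withr::with_seed(44, {
    for (i in 1:50) {
      n <- sample(5:20, 1)
      a <- rnorm(n); b <- rnorm(n)
      res_t <- paired_t(a, b)$result
      d <- a - b
      expect_equal(res_t$statistic, mean(d) / (sd(d) / sqrt(n)),
                   tolerance = 1e-8)
      expect_equal(res_t$p_value,
                   2 * pt(-abs(mean(d) / (sd(d) / sqrt(n))), n - 1),
                   tolerance = 1e-6)
      res_r <- pearson(a, b)$result
      r_ref <- sum(scale(a) * scale(b)) / (n - 1)
      expect_equal(res_r$estimate, r_ref, tolerance = 1e-8)
    }
  })
})

test_that("Bonferroni post-hocs are monotone corrections capped at 1", {
  withr::with_seed(45, {
    Y <- matrix(rnorm(10 * 4), 10, 4) + rep(c(0, 0.5, 1, 0), each = 10)
    colnames(Y) <- c("Cz", "Fz", "Pz", "R2-R7")
    res <- rm_anova_gg(Y)
    ph <- res$posthoc
    expect_equal(nrow(ph), choose(4, 2))
    expect_true(all(ph$p_bonferroni >= ph$p_uncorrected))
    expect_true(all(ph$p_bonferroni <= 1))
    expect_equal(ph$p_bonferroni,
                 pmin(ph$p_uncorrected * nrow(ph), 1))
    # missing cells are refused
    Y[1, 1] <- NA
    expect_error(rm_anova_gg(Y), "missing")
  })
})

test_that("report tables mirror the study layout with markers and dashes", {
  m <- default_montage()
  ev <- toy_events(c(2, 5), positions = c("front", "back"),
                   is_target = c(TRUE, FALSE))
  rec <- synthesize_recording(ev, m, generator_config(noise_sd_uv = 0),
                              seed = 1)
  avg <- average(baseline_correct(epoch(derive_bipolar(rec, m))))
  ft <- feature_table(list(P01 = avg))
  acc <- tibble::tibble(
    subject = c("P01", "P02", "P03"),
    cap_accuracy_pct = c(90, 65, NA),
    ceegrid_accuracy_pct = c(73, 29, 44),
    sensitivity_threshold_pct = c(83.4, NA, 92.5)
  )
  tabs <- report_tables(ft, acc, n_blocks = 48)
  expect_equal(nrow(tabs$accuracy_formatted), 3)
  # below the 37.5% bound -> "+", below 70% usability -> "*"
  expect_equal(tabs$accuracy_formatted$ceegrid, c("73", "29+", "44*"))
  expect_equal(tabs$accuracy_formatted$cap[2], "65*")
  # missing values render as dashes
  expect_match(tabs$accuracy_formatted$cap[3], "–")
  expect_match(tabs$accuracy_formatted$sensitivity[2], "–")
  # numeric flags survive alongside
  expect_false(tabs$accuracy$ceegrid_significant[2])
  expect_true(tabs$accuracy$cap_usable[1])
  # the amplitude table carries one row per channel of interest
  expect_equal(nrow(tabs$amplitudes), 7)
  # CSV output lands in out_dir
  dir <- withr::local_tempdir()
  report_tables(ft, acc, out_dir = dir)
  expect_true(file.exists(file.path(dir, "table_amplitudes.csv")))
  expect_true(file.exists(file.path(dir, "table_accuracy.csv")))
})
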