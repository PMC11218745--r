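# epochs with a controllable discriminative signal: target epochs carry an
# extra deflection on the first channel
signal_epochs <- function(n_blocks = 2, reps = 10, channels = c("Cz", "Fz"),
                          amp = 5, noise = 1, seed = 1) {
  withr::with_seed(seed, {
    pos <- c("front", "back", "left", "right")
    ev <- purrr::map_dfr(seq_len(n_blocks), function(b) {
      order <- sample(rep(pos, reps))
      toy_events(onsets = seq_along(order), positions = order, run = 1L,
                 block = b, is_target = order == pos[(b - 1) %% 4 + 1])
    })
    n_ep <- nrow(ev)
    vals <- array(rnorm(n_ep * length(channels) * 225, sd = noise),
                  c(n_ep, length(channels), 225))
    bump <- 100:160                         # 300..540 ms post-stimulus
    vals[ev$is_target, 1, bump] <- vals[ev$is_target, 1, bump] + amp
    toy_epochs(vals, channels, ev)
  })
}

test_that("feature construction yields per-channel 50 ms bin means", {
  # 12 channels x 16 bins = 192 features; 26-channel ear set = 416
  m <- default_montage()
  ev <- toy_events(c(2, 4), positions = c("front", "back"),
                   is_target = c(TRUE, FALSE))
  rec <- synthesize_recording(ev, m, generator_config(noise_sd_uv = 1),
                              seed = 1)
  eps <- baseline_correct(epoch(derive_bipolar(rec, m)))
  f_cap <- build_features(eps, classifier_config("cap"), m)
  expect_equal(ncol(f_cap$X), 192)
  f_grid <- build_features(eps, classifier_config("ceegrid"), m)
  expect_equal(ncol(f_grid$X), 416)
  expect_equal(nrow(f_grid$info), 416)
  # constant epochs give constant features
  ev2 <- toy_events(1:2, is_target = c(TRUE, FALSE))
  eps_c <- toy_epochs(array(1, c(2, 1, 225)), "Cz", ev2)
  m1 <- montage("m1", "Cz", c(Cz = "scalp"),
                tibble::tibble(minuend = character(0),
                               subtrahend = character(0),
                               label = character(0)))
  f1 <- build_features(eps_c, classifier_config("cap"), m1)
  expect_true(all(abs(f1$X - 1) < 1e-12))
  expect_equal(ncol(f1$X), 16)
  # bin means agree with a direct slice-mean computation
  eps_r <- toy_epochs(array(rnorm(450), c(2, 1, 225)), "Cz", ev2)
  fr <- build_features(eps_r, classifier_config("cap"), m1)
  post <- eps_r$data[1, 26:225, 1]
  t_post <- (0:199) * 4
  expect_equal(unname(fr$X[1, 3]),
               mean(post[t_post >= 100 & t_post < 150]))
  # a bin width that does not divide the window drops the last partial bin
  expect_warning(
    f_odd <- build_features(eps_r, classifier_config("cap",
                                                     feature_bin_ms = 70),
                            m1), "partial")
  expect_equal(ncol(f_odd$X), 11)
})

test_that("a perfectly separating feature is selected first among noise", {
  withr::with_seed(5, {
    n <- 60
    X <- cbind(matrix(rnorm(n * 4), n, 4), sep = rep(c(2, -2), each = n / 2))
    colnames(X) <- c(paste0("noise", 1:4), "sep")
    y <- rep(c(TRUE, FALSE), each = n / 2)
    fit <- swlda_fit(X, y, classifier_config())
    expect_equal(fit$path[1], "+5")
    expect_true("sep" %in% fit$feature_names)
  })
})

test_that("p_enter = 0 yields a degenerate model with constant scores", {
  withr::with_seed(6, {
    X <- matrix(rnorm(80), 20, 4)
    y <- rep(c(TRUE, FALSE), 10)
    fit <- swlda_fit(X, y, classifier_config(p_enter = 0, p_remove = 0))
    expect_true(fit$degenerate)
    s <- score(fit, X)
    expect_equal(length(unique(s)), 1)
  })
})

test_that("the stepwise path matches an independent lm-based implementation", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      n <- sample(20:60, 1)
      p <- sample(3:8, 1)
      X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", 1:p)))
      beta <- rnorm(p) * rbinom(p, 1, 0.5)
      y <- drop(X %*% beta) + rnorm(n)
      lab <- y > median(y)
      fit <- swlda_fit(X, lab, classifier_config())
      orc <- oracle_stepwise(X, ifelse(lab, 1, -1), 0.10, 0.15, 60)
      expect_setequal(fit$feature_names, orc$selected)
      if (length(fit$selected)) {
        expect_equal(unname(fit$weights),
                     unname(orc$coefs[fit$feature_names]), tolerance = 1e-8)
        expect_equal(fit$intercept, unname(orc$coefs["(Intercept)"]),
                     tolerance = 1e-8)
      }
    }
  })
})

test_that("with selection disabled the fit equals ordinary least squares", {
  withr::with_seed(8, {
    X <- matrix(rnorm(50 * 6), 50, 6)
    y <- rnorm(50) > 0
    fit <- swlda_fit(X, y, classifier_config(p_enter = 1, p_remove = 1,
                                             max_features = Inf))
    ols <- coef(lm(ifelse(y, 1, -1) ~ X))
    expect_equal(length(fit$selected), 6)
    expect_lt(max(abs(fit$weights[order(fit$selected)] - ols[-1])), 1e-8)
    expect_lt(abs(fit$intercept - ols[1]), 1e-8)
  })
})

test_that("scores are the linear discriminant and respect dimensions", {
  withr::with_seed(9, {
    X <- matrix(rnorm(40 * 5), 40, 5)
    y <- rep(c(TRUE, FALSE), 20)
    fit <- swlda_fit(X, y, classifier_config(p_enter = 1, p_remove = 1))
    # hand-computed dot product
    manual <- fit$intercept +
      X[, fit$selected, drop = FALSE] %*% fit$weights
    expect_equal(score(fit, X), drop(manual))
    # duplicate epochs score identically
    expect_equal(score(fit, X[c(1, 1), ]), rep(score(fit, X)[1], 2))
    expect_error(score(fit, X[, 1:3]), "dimension")
    expect_equal(predict(fit, X), score(fit, X))
  })
})

test_that("target selection takes the arg-max with canonical tie-breaking", {
  ev <- toy_events(1:4, positions = c("front", "back", "left", "right"),
                   is_target = c(TRUE, FALSE, FALSE, FALSE))
  sel <- select_target(c(1.0, 0.2, 0.1, 0.0), ev)
  expect_true(sel$correct)
  expect_equal(sel$chosen_position, "front")
  # all-equal scores fall back to the first canonical position
  sel2 <- select_target(rep(0, 4), ev)
  expect_equal(sel2$chosen_position, "front")
  ev3 <- ev
  ev3$is_target <- c(FALSE, TRUE, FALSE, FALSE)
  expect_false(select_target(rep(0, 4), ev3)$correct)
  # aggregation equals a brute-force per-position mean
  withr::with_seed(10, {
    ev4 <- toy_events(1:40,
                      positions = rep(c("front", "back", "left", "right"),
                                      each = 10),
                      is_target = rep(c(FALSE, FALSE, TRUE, FALSE), each = 10))
    s <- rnorm(40)
    sel4 <- select_target(s, ev4)
    agg <- tapply(s, ev4$position, mean)[c("front", "back", "left",
                                           "right")]
    expect_equal(sel4$chosen_position, names(agg)[which.max(agg)])
    expect_equal(sel4$score_left, unname(agg["left"]))
  })
})

test_that("a separable 2-block session reaches 100% LOO-CV accuracy", {
  eps <- signal_epochs(n_blocks = 2, amp = 8, noise = 0.5)
  m2 <- montage("m2", c("Cz", "Fz"), c(Cz = "scalp", Fz = "scalp"),
                tibble::tibble(minuend = character(0),
                               subtrahend = character(0),
                               label = character(0)))
  acc <- loocv_accuracy(eps, classifier_config("cap"), m2)
  expect_equal(acc$accuracy_pct, 100)
  expect_equal(acc$n_blocks, 2)
  # the two folds can be traced by hand: each fold trains on the other
  # block and must pick the held-out block's true target
  f <- build_features(eps, classifier_config("cap"), m2)
  for (b in 1:2) {
    train <- f$events$block != b
    fit <- swlda_fit(f$X[train, ], f$y[train], classifier_config("cap"))
    s <- score(fit, f$X[!train, ])
    sel <- select_target(s, f$events[!train, ])
    expect_true(sel$correct)
    expect_equal(sel$chosen_position,
                 acc$selections$chosen_position[acc$selections$block == b])
  }
})

test_that("LOO-CV accuracy is invariant to epoch order within blocks", {
  eps <- signal_epochs(n_blocks = 3, amp = 3, noise = 2, seed = 12)
  m2 <- montage("m2", c("Cz", "Fz"), c(Cz = "scalp", Fz = "scalp"),
                tibble::tibble(minuend = character(0),
                               subtrahend = character(0),
                               label = character(0)))
  acc1 <- loocv_accuracy(eps, classifier_config("cap"), m2)
  withr::with_seed(13, perm <- sample(dim(eps$data)[3]))
  eps_p <- toy_epochs(aperm(eps$data, c(3, 1, 2))[perm, , , drop = FALSE],
                      eps$channels, eps$events[perm, ])
  acc2 <- loocv_accuracy(eps_p, classifier_config("cap"), m2)
  expect_equal(acc2$accuracy_pct, acc1$accuracy_pct)
  expect_equal(acc2$n_correct, acc1$n_correct)
})

test_that("the exact binomial chance bound reproduces 18/48 = 37.5%", {
  thr <- chance_threshold(48, 0.25, 0.05)
  expect_equal(thr$min_correct, 18)
  expect_equal(thr$threshold_pct, 37.5)
  expect_equal(thr$threshold_pct_floor, 37)
  # hand enumeration for n = 4: P(X >= k) from the 5 binomial terms
  terms <- dbinom(0:4, 4, 0.25)
  tails <- rev(cumsum(rev(terms)))        # P(X >= 0..4)
  k_hand <- min(which(tails < 0.05)) - 1
  expect_equal(chance_threshold(4, 0.25, 0.05)$min_correct, k_hand)
  # near-degenerate alpha: every k has tail < alpha except k = 0 (tail = 1)
  expect_equal(chance_threshold(10, 0.25, 0.999999)$min_correct, 1)
  expect_error(chance_threshold(48, 0.25, 1.5), "alpha")
  # the accuracy container carries the bound and the usability flag
  eps <- signal_epochs(n_blocks = 2, amp = 8, noise = 0.5)
  m2 <- montage("m2", c("Cz", "Fz"), c(Cz = "scalp", Fz = "scalp"),
                tibble::tibble(minuend = character(0),
                               subtrahend = character(0),
                               label = character(0)))
  acc <- loocv_accuracy(eps, classifier_config("cap"), m2)
  expect_true(acc$meets_usability)
  expect_equal(acc$chance_pct, 25)
})

test_that("tidiers expose selected features and the accuracy summary", {
  eps <- signal_epochs(n_blocks = 2, amp = 8, noise = 0.5)
  m2 <- montage("m2", c("Cz", "Fz"), c(Cz = "scalp", Fz = "scalp"),
                tibble::tibble(minuend = character(0),
                               subtrahend = character(0),
                               label = character(0)))
  f <- build_features(eps, classifier_config("cap"), m2)
  fit <- swlda_fit(f, cfg = classifier_config("cap"))
  td <- tidy(fit)
  expect_equal(td$term[1], "(Intercept)")
  expect_true(all(c("channel", "bin") %in% names(td)))
  expect_equal(glance(fit)$n_candidates, 32)
  acc <- loocv_accuracy(eps, classifier_config("cap"), m2)
  expect_equal(nrow(tidy(acc)), 2)
  expect_equal(glance(acc)$accuracy_pct, acc$accuracy_pct)
})
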