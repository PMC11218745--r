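# Shared fixtures and independent oracles used across the suite.

toy_recording <- function(n_ch = 3, n_samp = 250, sample_rate = 250,
                          labels = paste0("ch", seq_len(n_ch)),
                          events = empty_events(), seed = 1) {
  sig <- withr::with_seed(seed,
    matrix(rnorm(n_ch * n_samp), n_ch, n_samp, dimnames = list(labels, NULL)))
  recording(sig, sample_rate, events)
}

toy_events <- function(onsets, positions = "front", run = 1L, block = 1L,
                       is_target = TRUE) {
  tibble::tibble(onset_s = onsets, duration_s = 0.22, run = run,
                 block = block,
                 position = rep_len(positions, length(onsets)),
                 is_target = rep_len(is_target, length(onsets)))
}

# a small schedule with both classes, spaced so epochs fit comfortably
two_class_events <- function(n_per_class = 3, start_s = 2, gap_s = 2) {
  n <- 2 * n_per_class
  toy_events(onsets = start_s + (seq_len(n) - 1) * gap_s,
             positions = rep(c("front", "back"), n_per_class),
             is_target = rep(c(TRUE, FALSE), n_per_class))
}

# hand-built epoch set: values is epochs x channels x samples (intuitive
# order), converted to the package's channels x samples x epochs layout
toy_epochs <- function(values, channels, events, sample_rate = 250,
                       pre_samples = 25, baseline_corrected = TRUE) {
  d <- dim(values)
  data <- aperm(values, c(2, 3, 1))
  gridtap:::new_epochs(data, channels, pre_samples, sample_rate, events,
                       baseline_corrected = baseline_corrected)
}

# independent stepwise-regression oracle built on lm()/add1()/drop1();
# mirrors the documented selection rule but shares no code with the
# sweep-operator implementation
oracle_stepwise <- function(X, y, p_enter, p_remove, max_features) {
  df <- data.frame(y = y, X)
  vars <- colnames(X)
  inm <- character(0)
  for (it in 1:1000) {
    changed <- FALSE
    if (length(inm) < max_features && length(setdiff(vars, inm))) {
      f0 <- stats::lm(stats::reformulate(c("1", inm), "y"), data = df)
      a <- stats::add1(f0, scope = stats::reformulate(vars, "y"), test = "F")
      cand <- setdiff(rownames(a), "<none>")
      pv <- a[cand, "Pr(>F)"]
      pv[is.na(pv)] <- Inf
      best <- which.min(pv)
      if (pv[best] < p_enter) {
        inm <- c(inm, cand[best])
        changed <- TRUE
      }
    }
    repeat {
      if (!length(inm)) break
      d <- stats::drop1(stats::lm(stats::reformulate(c("1", inm), "y"),
                                  data = df), test = "F")
      mem <- setdiff(rownames(d), "<none>")
      pv <- d[mem, "Pr(>F)"]
      worst <- which.max(pv)
      if (is.finite(pv[worst]) && pv[worst] > p_remove) {
        inm <- setdiff(inm, mem[worst])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  fit <- stats::lm(stats::reformulate(c("1", inm), "y"), data = df)
  list(selected = inm, coefs = stats::coef(fit))
}
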