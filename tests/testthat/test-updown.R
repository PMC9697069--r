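test_that("threshold formula matches hand arithmetic", {
  # staircase ending at 2.0 g with a final negative response (k = +0.5)
  s <- session_from_pattern("XXOXO", start_idx = 6)
  est <- estimate_threshold(s)
  expect_equal(est$censored, "none")
  expect_equal(est$threshold_g, 10^(log10(2.0) + 0.5 * s$delta))
  # the worked value at delta = 0.224: 10^(0.3010 + 0.112) ~ 2.59 g
  expect_equal(signif(10^(log10(2.0) + 0.5 * 0.224), 3), 2.59)
})

test_that("sessions exiting the series are censored at the boundary filaments", {
  series <- default_filament_series()
  s_floor <- session_from_pattern("XXXXXXXXX", start_idx = 5)
  e1 <- estimate_threshold(s_floor)
  expect_equal(e1$censored, "floor")
  expect_equal(e1$threshold_g, min(series))
  s_ceil <- session_from_pattern("OOOOO", start_idx = 5)
  e2 <- estimate_threshold(s_ceil)
  expect_equal(e2$censored, "ceiling")
  expect_equal(e2$threshold_g, max(series))
})

test_that("trials beyond the stopping rule are ignored with a warning", {
  s_stop <- session_from_pattern("XOXOXO", start_idx = 5)
  base <- estimate_threshold(s_stop)
  s_extra <- session_from_pattern("XOXOXOXO", start_idx = 5)
  expect_warning(extra <- estimate_threshold(s_extra), "ignored")
  expect_equal(extra$threshold_g, base$threshold_g)
  expect_equal(extra$n_trials, base$n_trials)
})

test_that("session validation rejects forces outside the declared series", {
  expect_error(updown_session("bad", c(2, 3.14), c(TRUE, FALSE)),
               "not in the declared filament series")
})

test_that("steep-slope staircases oscillate between the bracketing filaments", {
  # threshold at 3 g lies between the 2 g and 4 g filaments
  p <- updown_sim_params(true_threshold_g = 3, slope = 60, seed = 5)
  s <- generate_updown_session(p)
  expect_true(all(s$trials$force_g %in% c(2, 4, 6)))
  tail_forces <- utils::tail(s$trials$force_g, 4)
  expect_setequal(unique(tail_forces), c(2, 4))
  # determinism
  s2 <- generate_updown_session(p)
  expect_identical(s$trials, s2$trials)
})

test_that("a threshold far above the strongest filament gives all-negative trials", {
  p <- updown_sim_params(true_threshold_g = 500, slope = 60, seed = 8)
  s <- generate_updown_session(p)
  expect_true(all(!s$trials$response))
  expect_equal(estimate_threshold(s)$censored, "ceiling")
})

test_that("mean estimated threshold tracks the true threshold (consistency, monotonicity)", {
  mean_log_est <- function(true_g, n = 200, seed0 = 1000) {
    est <- vapply(seq_len(n), function(i) {
      p <- updown_sim_params(true_threshold_g = true_g, slope = 50,
                             seed = seed0 + i)
      estimate_threshold(generate_updown_session(p))$threshold_g
    }, numeric(1))
    mean(log10(est))
  }
  delta <- mean(diff(log10(default_filament_series())))
  m3 <- mean_log_est(3)
  expect_lt(abs(m3 - log10(3)), delta)
  # raising the true threshold raises the mean estimate
  m5 <- mean_log_est(5)
  m10 <- mean_log_est(10)
  expect_true(m3 < m5 && m5 < m10)
})

test_that("group summaries report mean, SEM and n", {
  d <- tibble::tibble(group = c("a", "a", "a", "b"),
                      threshold_g = c(2, 4, 6, 5))
  expect_warning(out <- summarize_thresholds(d), "single animal")
  a <- out[out$group == "a", ]
  expect_equal(a$mean_g, 4)
  expect_equal(a$sem_g, 2 / sqrt(3))
  expect_true(is.na(out$sem_g[out$group == "b"]))
  # identical values: SEM 0
  same <- summarize_thresholds(tibble::tibble(group = "g",
                                              threshold_g = c(3, 3, 3)))
  expect_equal(same$sem_g, 0)
})

test_that("tukey_kramer matches TukeyHSD and separates shifted groups", {
  set.seed(77)
  g <- list(a = rnorm(8, 10), b = rnorm(6, 10.8), c = rnorm(7, 12))
  tk <- tukey_kramer(g)
  df <- data.frame(y = unlist(g),
                   grp = factor(rep(names(g), lengths(g))))
  ref <- TukeyHSD(aov(y ~ grp, data = df))$grp
  for (i in seq_len(nrow(tk$pairs))) {
    key <- paste0(tk$pairs$group2[i], "-", tk$pairs$group1[i])
    expect_equal(tk$pairs$p_value[i], ref[key, "p adj"], tolerance = 1e-8)
    expect_equal(abs(tk$pairs$diff[i]), abs(ref[key, "diff"]),
                 tolerance = 1e-10)
  }
  # two identical groups: q = 0, p ~ 1
  tk0 <- tukey_kramer(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(tk0$pairs$q, 0)
  expect_equal(tk0$pairs$p_value, 1)
  # a group shifted by +10 SD is significant at the 1% level
  g$far <- rnorm(6, 10 + 10 * 1)
  tkf <- tukey_kramer(g)
  far_rows <- tkf$pairs$group1 == "far" | tkf$pairs$group2 == "far"
  expect_true(all(tkf$pairs$p_value[far_rows & (tkf$pairs$group1 == "a" |
                                                tkf$pairs$group2 == "a")] < 0.01))
})
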