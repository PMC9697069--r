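#!/usr/bin/env Rscript
# Behavioral arm: estimate 50% withdrawal thresholds from the simulated
# von Frey up-down sessions, summarize groups as mean +/- SEM, and run
# one-way ANOVA with Tukey-Kramer all-pairs comparisons.

library(pipntools)

dir.create("results", showWarnings = FALSE)
sessions <- readr::read_csv("results/data/vonfrey_sessions.csv",
                            col_types = "cidl")

thresholds <- sessions |>
  dplyr::arrange(session_id, trial_index) |>
  dplyr::group_by(session_id) |>
  dplyr::group_map(function(df, key) {
    est <- estimate_threshold(
      updown_session(key$session_id, df$force_g, df$response))
    tibble::tibble(session_id = key$session_id,
                   group = sub("_[0-9]+$", "", key$session_id),
                   threshold_g = est$threshold_g,
                   censored = est$censored, n_trials = est$n_trials)
  }) |>
  dplyr::bind_rows()
readr::write_csv(thresholds, "results/thresholds.csv")

summ <- summarize_thresholds(thresholds)
readr::write_csv(summ, "results/threshold_summary.csv")
print(as.data.frame(summ))

tk <- tukey_kramer(split(thresholds$threshold_g, thresholds$group))
readr::write_csv(tk$pairs, "results/threshold_comparisons.csv")
message("one-way ANOVA: F = ", round(tk$anova$F, 2),
        ", p = ", signif(tk$anova$p_value, 3))
print(as.data.frame(tk$pairs))
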