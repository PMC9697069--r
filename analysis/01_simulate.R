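#!/usr/bin/env Rscript
# Generate the three synthetic datasets that drive the analysis arms:
# a FAERS-like spontaneous-report universe (with known true odds ratio),
# von Frey up-down sessions for three treatment groups, and nerve
# cross-section geometry for a control and a degenerated field.
# Outputs land under results/data/.

library(pipntools)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260101

# --- spontaneous reports: a protective concomitant drug (true OR = 0.5) ----
params <- synthetic_report_params(n_reports = 50000,
                                  exposure_odds_multiplier = 0.5,
                                  seed = seed)
gen <- generate_reports(params)
write_reports(gen$reports,
              file.path(out, "reports_drug.txt"),
              file.path(out, "reports_reac.txt"))
writeLines(jsonlite::toJSON(gen$truth, auto_unbox = TRUE),
           file.path(out, "reports_truth.json"))
message("reports: ", n_reports(gen$reports), " reports; realized cells ",
        paste(unlist(gen$truth[1:4]), collapse = "/"),
        " (true multiplier ", params$exposure_odds_multiplier, ")")

# --- von Frey sessions: vehicle, paclitaxel (allodynic), paclitaxel+drug ---
groups <- list(vehicle = 10, paclitaxel = 1.5, paclitaxel_treated = 5)
rows <- list()
i <- 0
for (g in names(groups)) {
  for (s in 1:8) {
    i <- i + 1
    ses <- generate_updown_session(
      updown_sim_params(true_threshold_g = groups[[g]], slope = 6,
                        seed = seed + i),
      session_id = sprintf("%s_%d", g, s))
    rows[[i]] <- tibble::tibble(session_id = ses$session_id,
                                trial_index = seq_len(nrow(ses$trials)),
                                force_g = ses$trials$force_g,
                                response = ses$trials$response)
  }
}
readr::write_csv(dplyr::bind_rows(rows), file.path(out, "vonfrey_sessions.csv"))
message("von Frey: ", i, " sessions across ", length(groups), " groups")

# --- nerve cross-sections: healthy vs degenerated ---------------------------
for (cond in c(control = 0, degenerated = 0.6)) {
  name <- names(which(c(control = 0, degenerated = 0.6) == cond))[1]
  fibers <- generate_nerve_cross_section(
    nerve_synth_params(n_fibers = 100, degeneration_level = cond,
                       seed = seed + round(100 * cond), field_size_um = 200))
  write_fiber_polygons(fibers, file.path(out, paste0("nerve_", name, ".csv")))
  message("nerve ", name, ": ", length(fibers), " fibers")
}
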