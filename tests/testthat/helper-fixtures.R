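# Six-report paclitaxel stratum used across the disproportionality tests:
# r1 tamsulosin + PIPN, r2 tamsulosin only, r3 PIPN only, r4-r6 neither,
# giving the hand-enumerated table (n11, n12, n21, n22) = (1, 1, 1, 3).
toy_target_set <- function() {
  report_set(
    drugs = tibble::tibble(
      report_id = c("r1", "r1", "r2", "r2", "r3", "r4", "r5", "r6"),
      drug = c("paclitaxel", "tamsulosin", "paclitaxel", "tamsulosin",
               "paclitaxel", "paclitaxel", "paclitaxel", "paclitaxel")
    ),
    events = tibble::tibble(
      report_id = c("r1", "r3"),
      event = c("peripheral neuropathy", "peripheral sensory neuropathy")
    ),
    provenance = "toy"
  )
}

# Regular n-gon of circumradius r centered at (cx, cy).
regular_ngon <- function(n, r = 1, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Random simple star-shaped polygon (radial form, positive radii).
random_star_polygon <- function(n_vertices = 24, irregularity = 0.5) {
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- 1 + irregularity * (stats::runif(n_vertices) - 0.5)
  cbind(r * cos(th), r * sin(th))
}

# Random all-positive 2x2 table.
random_positive_table <- function(max_cell = 500) {
  contingency_table(sample(max_cell, 1), sample(max_cell, 1),
                    sample(max_cell, 1), sample(max_cell, 1))
}

# Build an up-down session directly from a response pattern walked on the
# default series, starting at the given filament index.
session_from_pattern <- function(pattern, start_idx = 5,
                                 series = default_filament_series()) {
  resp <- strsplit(pattern, "")[[1]] == "X"
  idx <- start_idx
  forces <- numeric(length(resp))
  for (i in seq_along(resp)) {
    forces[i] <- series[idx]
    idx <- max(1, min(length(series), idx + if (resp[i]) -1L else 1L))
  }
  updown_session("pat", forces, resp, filament_series = series)
}
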