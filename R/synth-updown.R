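#' Parameters for the simulated von Frey up-down staircase
#'
#' The simulated animal responds according to a logistic psychometric
#' function on the log10-force scale: the response probability at force
#' `F` is `plogis(slope * (log10(F) - log10(true_threshold_g)))`, so the
#' 50\% withdrawal point sits exactly at `true_threshold_g`. Large `slope`
#' makes responses near-deterministic.
#'
#' @param true_threshold_g force (grams) at which the response probability
#'   is 50\%.
#' @param slope psychometric steepness on the log10-force scale (> 0).
#' @param filament_forces_g ascending available filament forces (grams).
#' @param max_trials staircase trial cap.
#' @param n_after_reversal trials collected beyond the first reversal.
#' @param seed integer RNG seed.
#' @return an object of class `updown_sim_params`.
#' @export
updown_sim_params <- function(true_threshold_g = 4,
                              slope = 8,
                              filament_forces_g = default_filament_series(),
                              max_trials = 9,
                              n_after_reversal = 4,
                              seed = 1) {
  assert_that(true_threshold_g > 0, "true_threshold_g must be > 0")
  assert_that(slope > 0, "slope must be > 0")
  assert_that(all(diff(filament_forces_g) > 0) && all(filament_forces_g > 0),
              "filament forces must be positive and strictly increasing")
  structure(list(
    true_threshold_g = true_threshold_g,
    slope = slope,
    filament_forces_g = filament_forces_g,
    max_trials = as.integer(max_trials),
    n_after_reversal = as.integer(n_after_reversal),
    seed = as.integer(seed)
  ), class = "updown_sim_params")
}

#' Simulate one von Frey up-down session
#'
#' Starts at the middle filament of the series (the standard up-down
#' convention). A positive response steps the staircase down one filament,
#' a negative response steps it up. The session terminates when the
#' stopping rule fires (`n_after_reversal` trials beyond the first
#' reversal, or `max_trials`), or earlier if the staircase would step off
#' either end of the series. Deterministic given the seed.
#'
#' @param params an [updown_sim_params()].
#' @param session_id identifier for the generated session.
#' @return an [updown_session()].
#' @export
generate_updown_session <- function(params, session_id = "sim") {
  assert_that(inherits(params, "updown_sim_params"),
              "`params` must come from updown_sim_params()")
  withr::with_seed(params$seed, {
    series <- params$filament_forces_g
    log_thr <- log10(params$true_threshold_g)
    idx <- ceiling(length(series) / 2)
    forces <- numeric(0)
    resp <- logical(0)
    repeat {
      f <- series[idx]
      p <- stats::plogis(params$slope * (log10(f) - log_thr))
      r <- stats::runif(1) < p
      forces <- c(forces, f)
      resp <- c(resp, r)
      n <- length(resp)
      flips <- which(diff(resp) != 0)
      target <- if (length(flips) == 0) params$max_trials
                else min(flips[1] + 1 + params$n_after_reversal,
                         params$max_trials)
      if (n >= target) break
      idx_next <- idx + if (r) -1L else 1L
      if (idx_next < 1 || idx_next > length(series)) break  # exits the series
      idx <- idx_next
    }
    updown_session(session_id, forces, resp, filament_series = series)
  })
}
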