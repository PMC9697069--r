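#' Default von Frey filament series for rats
#'
#' A standard ascending series of calibrated filament forces in grams.
#' The series is a package convention (configurable), not a fact of any
#' particular study; the log10 spacing is approximately uniform, which is
#' what the up-down estimator's delta assumes.
#'
#' @return numeric vector of forces in grams, ascending.
#' @export
default_filament_series <- function() {
  c(0.4, 0.6, 1.0, 2.0, 4.0, 6.0, 8.0, 15.0, 26.0)
}

#' Default terminal-pattern offset table for the up-down estimator
#'
#' The up-down (Dixon staircase) estimate is `10^(X_f + k * delta)` where
#' `X_f` is the final filament's log10 force and `k` is an offset tabulated
#' by the terminal response pattern. The default table is the symmetric
#' midpoint convention: `k = +0.5` after a final negative response (the
#' staircase was about to step up) and `k = -0.5` after a final positive
#' response. Patterns are strings of `"X"` (response) and `"O"` (no
#' response); lookup is by longest matching suffix of the session's
#' response pattern, so a user-supplied table of longer tabulated patterns
#' (e.g. a full Dixon table) takes precedence over the one-character
#' defaults wherever it applies.
#'
#' @return named numeric vector: names are terminal patterns, values are k.
#' @export
default_k_table <- function() {
  c("O" = 0.5, "X" = -0.5)
}

#' Construct a von Frey up-down session
#'
#' @param session_id identifier string.
#' @param forces_g trial-by-trial applied forces in grams (must be members
#'   of the filament series).
#' @param responses logical vector, TRUE = pain-related response (paw
#'   withdrawal), same length as `forces_g`.
#' @param filament_series ascending filament forces in grams.
#' @return an object of class `updown_session` carrying trials on the log10
#'   force scale, the series, and its mean log spacing `delta`.
#' @export
updown_session <- function(session_id, forces_g, responses,
                           filament_series = default_filament_series()) {
  assert_that(length(forces_g) >= 1, "session must have >= 1 trial")
  assert_that(length(forces_g) == length(responses),
              "forces and responses must have equal length")
  assert_that(all(diff(filament_series) > 0) && all(filament_series > 0),
              "filament series must be positive and strictly increasing")
  bad <- setdiff(unique(forces_g), filament_series)
  if (length(bad) > 0) {
    stop("trial force(s) not in the declared filament series: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  log_series <- log10(filament_series)
  structure(list(
    session_id = session_id,
    trials = tibble::tibble(
      force_g = forces_g,
      log_force = log10(forces_g),
      response = as.logical(responses)
    ),
    filament_log_forces = log_series,
    delta = mean(diff(log_series))
  ), class = "updown_session")
}

# Index of the trial at which the stopping rule fires: n_after_reversal
# trials beyond the first response reversal, capped at max_trials.
#' @noRd
stop_index <- function(responses, n_after_reversal = 4, max_trials = 9) {
  n <- length(responses)
  flips <- which(diff(responses) != 0)
  stop_at <- if (length(flips) == 0) max_trials
             else min(flips[1] + 1 + n_after_reversal, max_trials)
  min(stop_at, n)
}

#' Estimate the 50\% withdrawal threshold from an up-down session
#'
#' Applies the staircase stopping rule (`n_after_reversal` trials beyond
#' the first response reversal, at most `max_trials`; later trials are
#' ignored with a warning), then evaluates
#' \deqn{T = 10^{X_f + k\,\delta}}
#' with `X_f` the final used trial's log10 force, `delta` the series' mean
#' log10 spacing, and `k` read from `k_table` by longest-suffix match on
#' the response pattern (see [default_k_table()]). Sessions whose responses
#' are all positive (floor) or all negative (ceiling) are censored at the
#' weakest/strongest filament force, flagged rather than set to infinity so
#' that group means remain computable.
#'
#' @param s an [updown_session()].
#' @param k_table named numeric pattern-offset table.
#' @param n_after_reversal,max_trials stopping-rule parameters.
#' @return list with `threshold_g`, `censored` (`"none"`, `"floor"` or
#'   `"ceiling"`), and `n_trials` (trials actually used).
#' @export
estimate_threshold <- function(s, k_table = default_k_table(),
                               n_after_reversal = 4, max_trials = 9) {
  assert_that(inherits(s, "updown_session"), "`s` must be an updown_session")
  idx <- stop_index(s$trials$response, n_after_reversal, max_trials)
  if (idx < nrow(s$trials)) {
    warning("session ", s$session_id, ": ", nrow(s$trials) - idx,
            " trial(s) after the stopping rule ignored", call. = FALSE)
  }
  resp <- s$trials$response[seq_len(idx)]
  logf <- s$trials$log_force[seq_len(idx)]
  series_min <- min(s$filament_log_forces)
  series_max <- max(s$filament_log_forces)

  if (all(resp)) {
    return(list(threshold_g = 10^series_min, censored = "floor",
                n_trials = idx))
  }
  if (all(!resp)) {
    return(list(threshold_g = 10^series_max, censored = "ceiling",
                n_trials = idx))
  }
  pattern <- paste(ifelse(resp, "X", "O"), collapse = "")
  k <- lookup_k(pattern, k_table)
  list(threshold_g = 10^(logf[idx] + k * s$delta), censored = "none",
       n_trials = idx)
}

# Longest-suffix match of the response pattern against the table's names.
#' @noRd
lookup_k <- function(pattern, k_table) {
  keys <- names(k_table)
  lens <- nchar(keys)
  hit <- vapply(keys, function(key) {
    endsWith(pattern, key)
  }, logical(1))
  if (!any(hit)) {
    stop("no k-table entry matches terminal pattern '", pattern, "'",
         call. = FALSE)
  }
  best <- which(hit)[which.max(lens[hit])]
  unname(k_table[best])
}

#' Summarize per-animal thresholds by group (and optionally week)
#'
#' @param data tibble with columns `group`, `threshold_g`, and optionally
#'   `week` (any extra grouping column is honoured via `...`).
#' @param ... additional grouping columns (tidy-select style bare names).
#' @return tibble with mean, SEM (`sd/sqrt(n)`; `NA` with a warning for
#'   single-animal groups) and n per group.
#' @export
summarize_thresholds <- function(data, ...) {
  assert_that(all(c("group", "threshold_g") %in% names(data)),
              "`data` needs columns group, threshold_g")
  out <- data |>
    dplyr::group_by(.data$group, ...) |>
    dplyr::summarise(
      mean_g = mean(.data$threshold_g),
      sem_g = sem(.data$threshold_g),
      n = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n < 2)) {
    warning("group(s) with a single animal: SEM reported as NA",
            call. = FALSE)
  }
  out
}

#' Tukey-Kramer all-pairs comparison after one-way ANOVA
#'
#' Computes, for every pair of groups, the studentized-range statistic
#' \eqn{q = |\bar y_i - \bar y_j| / \sqrt{(MSE/2)(1/n_i + 1/n_j)}} with the
#' Tukey-Kramer unequal-n standard error, and p-values from the studentized
#' range distribution with (k, N - k) parameters. The one-way ANOVA F test
#' is reported alongside but does not gate the pairwise tests.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   observations).
#' @return list with `anova` (tibble: F, df1, df2, p) and `pairs` (tibble:
#'   group1, group2, diff, se, q, p_value, sig_05, sig_01).
#' @export
tukey_kramer <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2,
              "need >= 2 groups")
  assert_that(all(vapply(groups, length, integer(1)) >= 2),
              "every group needs >= 2 observations")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  k <- length(groups)
  ni <- vapply(groups, length, integer(1))
  mi <- vapply(groups, mean, numeric(1))
  N <- sum(ni)
  df2 <- N - k
  sse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  mse <- sse / df2
  grand <- sum(ni * mi) / N
  ssb <- sum(ni * (mi - grand)^2)
  f <- if (mse > 0) (ssb / (k - 1)) / mse else if (ssb > 0) Inf else 0
  p_f <- if (is.finite(f)) stats::pf(f, k - 1, df2, lower.tail = FALSE)
         else 0

  combs <- utils::combn(k, 2)
  pairs <- purrr::map_dfr(seq_len(ncol(combs)), function(j) {
    i1 <- combs[1, j]; i2 <- combs[2, j]
    se <- sqrt(mse / 2 * (1 / ni[i1] + 1 / ni[i2]))
    d <- unname(mi[i1] - mi[i2])
    q <- if (se > 0) abs(d) / se else if (d == 0) 0 else Inf
    p <- if (is.finite(q)) {
      stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    } else 0
    tibble::tibble(
      group1 = names(groups)[i1], group2 = names(groups)[i2],
      diff = d, se = se, q = unname(q), p_value = unname(p),
      sig_05 = p < 0.05, sig_01 = p < 0.01
    )
  })
  list(
    anova = tibble::tibble(F = f, df1 = k - 1, df2 = df2, p_value = p_f),
    pairs = pairs
  )
}
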