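#' Parameters for the synthetic adverse-event report generator
#'
#' The generator emulates a spontaneous-report universe at desk scale:
#' reports carry a target drug (paclitaxel) with probability
#' `p_target_drug`; a concomitant drug with probability
#' `p_exposed_given_target`; and PIPN case status with baseline probability
#' `baseline_event_prob` among unexposed reports. Exposure multiplies the
#' case *odds* by `exposure_odds_multiplier`, so the multiplier is exactly
#' the estimand of the reporting odds ratio under non-differential
#' reporting. Decoy drugs and decoy event terms are attached independently
#' of case status (no confounding).
#'
#' Defaults: the baseline event probability matches the observed PIPN
#' reporting rate among paclitaxel reports (4.58\%). The target-drug
#' fraction and exposure fraction are set so that a 20,000-report universe
#' yields informative cell counts (a real FAERS extract is ~700x larger;
#' the target fraction is inflated accordingly rather than simulating tens
#' of millions of rows).
#'
#' @param n_reports number of reports to simulate (>= 1).
#' @param p_target_drug probability a report lists the target drug.
#' @param p_exposed_given_target probability a report (any report) also
#'   lists the concomitant drug of interest.
#' @param baseline_event_prob probability an unexposed target-drug report is
#'   a case.
#' @param exposure_odds_multiplier true odds ratio for exposed reports (> 0).
#' @param n_decoy_drugs,n_decoy_events sizes of the background drug/event
#'   vocabularies.
#' @param seed integer RNG seed; the generator is a pure function of
#'   (params, seed).
#' @return an object of class `synthetic_report_params`.
#' @export
synthetic_report_params <- function(n_reports = 20000,
                                    p_target_drug = 0.3,
                                    p_exposed_given_target = 0.2,
                                    baseline_event_prob = 0.0458,
                                    exposure_odds_multiplier = 1,
                                    n_decoy_drugs = 50,
                                    n_decoy_events = 100,
                                    seed = 1) {
  assert_that(is_count(n_reports) && n_reports >= 1, "n_reports must be >= 1")
  for (p in c(p_target_drug, p_exposed_given_target, baseline_event_prob)) {
    assert_that(is_prob(p), "probabilities must lie in [0, 1]")
  }
  assert_that(exposure_odds_multiplier > 0,
              "exposure_odds_multiplier must be > 0")
  if (baseline_event_prob == 1 && exposure_odds_multiplier != 1) {
    stop("degenerate parameters: baseline_event_prob = 1 gives infinite ",
         "baseline odds, the odds multiplier cannot apply", call. = FALSE)
  }
  structure(list(
    n_reports = as.integer(n_reports),
    p_target_drug = p_target_drug,
    p_exposed_given_target = p_exposed_given_target,
    baseline_event_prob = baseline_event_prob,
    exposure_odds_multiplier = exposure_odds_multiplier,
    n_decoy_drugs = as.integer(n_decoy_drugs),
    n_decoy_events = as.integer(n_decoy_events),
    seed = as.integer(seed)
  ), class = "synthetic_report_params")
}

# Odds-scale event probability: logit-additive exposure effect.
#' @noRd
event_prob <- function(p0, multiplier) {
  if (p0 == 0) return(0)
  odds <- p0 / (1 - p0) * multiplier
  odds / (1 + odds)
}

#' Generate a synthetic report set with known ground truth
#'
#' Deterministic given the seed. Alongside the report set, the realized
#' (not expected) 2x2 cell counts within the target-drug stratum are
#' returned, so downstream contingency construction can be verified against
#' the generator's own bookkeeping.
#'
#' @param params a [synthetic_report_params()].
#' @param target_drug,concomitant_drug names used for the two drugs of
#'   interest (defaults `"paclitaxel"`, `"tamsulosin"`).
#' @param case_term event term attached to case reports (default
#'   `"peripheral neuropathy"`).
#' @return list with elements `reports` (a [report_set()]) and `truth`
#'   (list: n11, n12, n21, n22 realized within the target stratum, plus
#'   n_target and the true multiplier).
#' @export
generate_reports <- function(params,
                             target_drug = "paclitaxel",
                             concomitant_drug = "tamsulosin",
                             case_term = "peripheral neuropathy") {
  assert_that(inherits(params, "synthetic_report_params"),
              "`params` must come from synthetic_report_params()")
  withr::with_seed(params$seed, {
    n <- params$n_reports
    ids <- sprintf("r%06d", seq_len(n))
    target <- stats::runif(n) < params$p_target_drug
    exposed <- stats::runif(n) < params$p_exposed_given_target
    p1 <- event_prob(params$baseline_event_prob, params$exposure_odds_multiplier)
    p_case <- ifelse(exposed, p1, params$baseline_event_prob)
    case <- stats::runif(n) < p_case

    # decoy attachment: ~1 extra decoy drug and ~1 decoy event per report
    n_decoy_dr <- 1L + stats::rpois(n, 1)   # >= 1 so every report has a drug
    n_decoy_ev <- stats::rpois(n, 1)
    decoy_drug_pool <- sprintf("drug%03d", seq_len(max(params$n_decoy_drugs, 1)))
    decoy_event_pool <- sprintf("event%03d", seq_len(max(params$n_decoy_events, 1)))

    drugs <- tibble::tibble(
      report_id = c(
        rep(ids, n_decoy_dr),
        ids[target],
        ids[exposed]
      ),
      drug = c(
        sample(decoy_drug_pool, sum(n_decoy_dr), replace = TRUE),
        rep(target_drug, sum(target)),
        rep(concomitant_drug, sum(exposed))
      )
    )
    events <- tibble::tibble(
      report_id = c(
        rep(ids, n_decoy_ev),
        ids[case]
      ),
      event = c(
        sample(decoy_event_pool, sum(n_decoy_ev), replace = TRUE),
        rep(case_term, sum(case))
      )
    )

    truth <- list(
      n11 = sum(target & exposed & case),
      n12 = sum(target & exposed & !case),
      n21 = sum(target & !exposed & case),
      n22 = sum(target & !exposed & !case),
      n_target = sum(target),
      true_multiplier = params$exposure_odds_multiplier
    )
    prov <- sprintf(
      "synthetic: n=%d seed=%d multiplier=%g baseline=%g",
      n, params$seed, params$exposure_odds_multiplier,
      params$baseline_event_prob)
    list(reports = report_set(drugs, events, provenance = prov),
         truth = truth)
  })
}

#' Simulate only the realized 2x2 ground-truth cells
#'
#' Fast path for Monte-Carlo experiments (coverage, parameter recovery)
#' that need thousands of replicates of the target-stratum cell counts but
#' not the full report tables. Draws the same per-report Bernoulli variables
#' as [generate_reports()]; given the same seed the realized cells agree
#' exactly with the full generator's `truth` element (decoy attachment is
#' drawn after the cells, so the cell RNG stream is shared).
#'
#' @param params a [synthetic_report_params()].
#' @return a [contingency_table()] of the realized target-stratum cells.
#' @export
simulate_contingency <- function(params) {
  assert_that(inherits(params, "synthetic_report_params"),
              "`params` must come from synthetic_report_params()")
  withr::with_seed(params$seed, {
    n <- params$n_reports
    target <- stats::runif(n) < params$p_target_drug
    exposed <- stats::runif(n) < params$p_exposed_given_target
    p1 <- event_prob(params$baseline_event_prob, params$exposure_odds_multiplier)
    p_case <- ifelse(exposed, p1, params$baseline_event_prob)
    case <- stats::runif(n) < p_case
    contingency_table(
      n11 = sum(target & exposed & case),
      n12 = sum(target & exposed & !case),
      n21 = sum(target & !exposed & case),
      n22 = sum(target & !exposed & !case)
    )
  })
}
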