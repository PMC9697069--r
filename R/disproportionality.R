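#' Case/non-case 2x2 contingency table
#'
#' Within a target-drug stratum, reports are cross-classified by exposure to
#' a concomitant drug (group) and case status:
#' \describe{
#'   \item{n11}{exposed cases: concomitant drug present, event reported}
#'   \item{n12}{exposed non-cases}
#'   \item{n21}{unexposed cases}
#'   \item{n22}{unexposed non-cases}
#' }
#'
#' @param n11,n12,n21,n22 non-negative integer counts, total >= 1.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(n11, n12, n21, n22) {
  cells <- c(n11 = n11, n12 = n12, n21 = n21, n22 = n22)
  assert_that(all(vapply(cells, is_count, logical(1))),
              "all four cells must be non-negative integers")
  assert_that(sum(cells) >= 1, "table total must be >= 1")
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$n11, x$n12, x$n21, x$n22), 2, 2, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("case", "non-case")))
  print(m)
  invisible(x)
}

#' @noRd
ct_cells <- function(t, haldane = FALSE) {
  x <- as.numeric(c(t$n11, t$n12, t$n21, t$n22))  # doubles: avoid int overflow
  if (haldane) x + 0.5 else x
}

#' Restrict a report set to reports listing a target drug
#'
#' @param rs a [report_set()].
#' @param target_drug normalized drug name (e.g. `"paclitaxel"`); supply a
#'   character vector to accept any of several names (e.g. to include
#'   protein-bound paclitaxel).
#' @return a `report_set` containing only the matching reports; a warning is
#'   issued when none match.
#' @export
select_target_reports <- function(rs, target_drug) {
  assert_that(inherits(rs, "report_set"), "`rs` must be a report_set")
  keep <- unique(rs$drugs$report_id[rs$drugs$drug %in% target_drug])
  if (length(keep) == 0) {
    warning("no report lists target drug(s): ",
            paste(target_drug, collapse = ", "), call. = FALSE)
  }
  report_set(
    rs$drugs[rs$drugs$report_id %in% keep, ],
    rs$events[rs$events$report_id %in% keep, ],
    provenance = paste0(rs$provenance, " | target=",
                        paste(target_drug, collapse = "+"))
  )
}

#' Flag which reports are cases under a case definition
#'
#' A report is a case when its event set intersects the definition's terms.
#'
#' @param rs a `report_set`.
#' @param cd a [case_definition()].
#' @return logical vector, one element per distinct report id (in the order
#'   of first appearance in the drug table), named by report id.
#' @export
is_case <- function(rs, cd) {
  assert_that(inherits(rs, "report_set"), "`rs` must be a report_set")
  assert_that(inherits(cd, "case_definition"), "`cd` must be a case_definition")
  ids <- unique(rs$drugs$report_id)
  case_ids <- unique(rs$events$report_id[rs$events$event %in% cd$terms])
  stats::setNames(ids %in% case_ids, ids)
}

#' Build the exposure-by-case 2x2 table within a target stratum
#'
#' @param target_rs a `report_set` already restricted to the target drug
#'   (see [select_target_reports()]).
#' @param group a [drug_group()]: a report is exposed when its drug set
#'   intersects the group's members.
#' @param cd a [case_definition()].
#' @return a [contingency_table()]; the four cells sum to the number of
#'   reports in `target_rs`.
#' @export
build_contingency <- function(target_rs, group, cd) {
  assert_that(inherits(group, "drug_group"), "`group` must be a drug_group")
  if (n_reports(target_rs) == 0) {
    stop("empty stratum: target report set contains no reports", call. = FALSE)
  }
  case <- is_case(target_rs, cd)
  exposed_ids <- unique(
    target_rs$drugs$report_id[target_rs$drugs$drug %in% group$members])
  exposed <- names(case) %in% exposed_ids
  contingency_table(
    n11 = sum(exposed & case),
    n12 = sum(exposed & !case),
    n21 = sum(!exposed & case),
    n22 = sum(!exposed & !case)
  )
}

#' Reporting odds ratio
#'
#' The disproportionality statistic
#' \deqn{ROR = \frac{n_{11}/n_{21}}{n_{12}/n_{22}} = \frac{n_{11} n_{22}}{n_{12} n_{21}}}
#' i.e. the odds of the event among exposed reports over the odds among
#' unexposed reports. Undefined when `n12` or `n21` is zero; opt in to the
#' Haldane-Anscombe correction (`haldane = TRUE`, +0.5 to every cell) to
#' obtain a finite value — counts are never altered silently.
#'
#' @param t a [contingency_table()].
#' @param haldane apply the +0.5 correction to all four cells (default FALSE).
#' @return the reporting odds ratio (positive real).
#' @export
ror <- function(t, haldane = FALSE) {
  x <- ct_cells(t, haldane)
  if (any(x == 0)) {
    stop("ROR undefined for zero cell(s); set haldane = TRUE to apply the ",
         "Haldane-Anscombe +0.5 correction", call. = FALSE)
  }
  (x[1] * x[4]) / (x[2] * x[3])
}

#' Woolf confidence interval for the reporting odds ratio
#'
#' \deqn{\exp\left[\ln ROR \pm z \sqrt{1/n_{11} + 1/n_{12} + 1/n_{21} + 1/n_{22}}\right]}
#' with `z = 1.96` for a two-sided 95\% interval. Natural logarithm
#' throughout. All four cells must be positive (after the optional Haldane
#' correction).
#'
#' @inheritParams ror
#' @param z standard-normal multiplier (default 1.96).
#' @return named numeric vector `c(low = , high = )`.
#' @export
ror_ci <- function(t, z = 1.96, haldane = FALSE) {
  x <- ct_cells(t, haldane)
  if (any(x == 0)) {
    stop("CI undefined for zero cell(s); set haldane = TRUE to apply the ",
         "Haldane-Anscombe +0.5 correction", call. = FALSE)
  }
  est <- log((x[1] * x[4]) / (x[2] * x[3]))
  se <- sqrt(sum(1 / x))
  c(low = exp(est - z * se), high = exp(est + z * se))
}

#' Pearson chi-squared test for a 2x2 table with a configurable Yates rule
#'
#' The 1-df closed form \eqn{N(|ad - bc|)^2 / (r_1 r_2 c_1 c_2)}; with the
#' Yates continuity correction \eqn{|ad - bc|} is reduced by \eqn{N/2}
#' (floored at zero). The correction is triggered per `yates`:
#' \describe{
#'   \item{"observed"}{any observed cell < 5 (default; literal reading of
#'     "number of cases for each item less than 5")}
#'   \item{"expected"}{any expected cell < 5 (the textbook rule)}
#'   \item{"always"/"never"}{force the correction on or off}
#' }
#'
#' @param t a [contingency_table()].
#' @param yates trigger policy, see Details.
#' @return list with `chi2`, `p_value` (1-df upper tail), `yates_applied`,
#'   and `degenerate` (TRUE when a zero margin makes the test vacuous, in
#'   which case `chi2 = 0`, `p = 1`).
#' @export
chi_squared <- function(t, yates = c("observed", "expected", "always", "never")) {
  yates <- match.arg(yates)
  x <- ct_cells(t)
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  n <- sum(x)
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(list(chi2 = 0, p_value = 1, yates_applied = FALSE, degenerate = TRUE))
  }
  expected <- outer(c(r1, r2), c(c1, c2)) / n
  apply_yates <- switch(yates,
    observed = any(x < 5),
    expected = any(expected < 5),
    always = TRUE,
    never = FALSE
  )
  delta <- abs(a * d - b * c_)
  if (apply_yates) delta <- max(0, delta - n / 2)
  chi2 <- n * delta^2 / (r1 * r2 * c1 * c2)
  list(
    chi2 = unname(chi2),
    p_value = unname(stats::pchisq(chi2, df = 1, lower.tail = FALSE)),
    yates_applied = apply_yates,
    degenerate = FALSE
  )
}

#' Event reporting rate in a report set
#'
#' The fraction of reports that are cases under the definition; e.g. the
#' fraction of paclitaxel reports that mention a peripheral-neuropathy term.
#'
#' @param rs a non-empty `report_set`.
#' @param cd a [case_definition()].
#' @return the proportion of case reports (in `[0, 1]`).
#' @seealso [format_rate_pct()] for the 2-decimal percentage presentation.
#' @export
reporting_rate <- function(rs, cd) {
  n <- n_reports(rs)
  if (n == 0) stop("reporting rate undefined on an empty report set",
                   call. = FALSE)
  sum(is_case(rs, cd)) / n
}

#' Format a proportion as a percentage, 2 decimals, half-up
#' @param p proportion in `[0, 1]`.
#' @return numeric percentage rounded half-up to 2 decimals.
#' @export
format_rate_pct <- function(p) round_half_up(100 * p, 2)

#' Disproportionality signal table for a set of drug groups
#'
#' For each group (individual drugs and/or a pooled class) builds the 2x2
#' table in the target stratum and computes the ROR, its Woolf CI, the
#' chi-squared test, and the exposed/unexposed reporting rates. A group
#' whose table makes the ROR undefined (zero cell, no Haldane) yields a row
#' with `NA` statistics and a note; other groups are unaffected.
#'
#' @param target_rs target-drug `report_set` (non-empty).
#' @param groups list of [drug_group()] objects.
#' @param cd a [case_definition()].
#' @param z CI multiplier (default 1.96).
#' @param yates Yates trigger policy, see [chi_squared()].
#' @param haldane apply the +0.5 correction where a zero cell occurs.
#' @return tibble, one row per group sorted by group name, with columns
#'   group, n11, n12, n21, n22, ror, ci_low, ci_high, chi2, p_value,
#'   yates_applied, haldane_applied, rate_exposed_pct, rate_unexposed_pct,
#'   note.
#' @export
signal_table <- function(target_rs, groups, cd, z = 1.96,
                         yates = "observed", haldane = FALSE) {
  assert_that(n_reports(target_rs) > 0, "target report set is empty")
  if (length(groups) == 0) {
    return(tibble::tibble(
      group = character(), n11 = integer(), n12 = integer(),
      n21 = integer(), n22 = integer(), ror = numeric(),
      ci_low = numeric(), ci_high = numeric(), chi2 = numeric(),
      p_value = numeric(), yates_applied = logical(),
      haldane_applied = logical(), rate_exposed_pct = numeric(),
      rate_unexposed_pct = numeric(), note = character()))
  }
  rows <- lapply(groups, function(g) {
    t <- build_contingency(target_rs, g, cd)
    zero_cell <- any(unlist(t) == 0)
    use_haldane <- haldane && zero_cell
    res <- tryCatch({
      r <- ror(t, haldane = use_haldane)
      ci <- ror_ci(t, z = z, haldane = use_haldane)
      list(ror = r, ci_low = ci[["low"]], ci_high = ci[["high"]], note = "")
    }, error = function(e) {
      list(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           note = conditionMessage(e))
    })
    ch <- chi_squared(t, yates = yates)
    n_exp <- t$n11 + t$n12
    n_unexp <- t$n21 + t$n22
    tibble::tibble(
      group = g$name,
      n11 = t$n11, n12 = t$n12, n21 = t$n21, n22 = t$n22,
      ror = res$ror, ci_low = res$ci_low, ci_high = res$ci_high,
      chi2 = ch$chi2, p_value = ch$p_value,
      yates_applied = ch$yates_applied,
      haldane_applied = use_haldane && !is.na(res$ror),
      rate_exposed_pct = if (n_exp > 0) format_rate_pct(t$n11 / n_exp) else NA_real_,
      rate_unexposed_pct = if (n_unexp > 0) format_rate_pct(t$n21 / n_unexp) else NA_real_,
      note = res$note
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$group)
}

#' Recover 2x2 cell counts from a printed ROR, CI and margins
#'
#' Published disproportionality tables often print only the rounded ROR and
#' confidence bounds plus the stratum margins (total reports, total cases).
#' This oracle enumerates every integer table with those margins whose
#' ROR and Woolf CI, rounded half-up to `decimals` places, reproduce the
#' printed values. The search iterates over the exposed-case cell n11 and,
#' for each, inverts the ROR formula to bracket the feasible exposed
#' non-case cell n12, so the enumeration is linear in `total_cases` rather
#' than quadratic in the margins.
#'
#' @param ror_printed printed (rounded) reporting odds ratio.
#' @param ci_printed length-2 numeric, printed (rounded) CI bounds.
#' @param total_reports stratum size (n11+n12+n21+n22).
#' @param total_cases case margin (n11+n21).
#' @param decimals decimal places of the printed values (default 2).
#' @param z CI multiplier used for the printed interval (default 1.96).
#' @return tibble of matching tables (columns n11, n12, n21, n22, ror,
#'   ci_low, ci_high); zero rows when nothing matches (including an
#'   infeasible printed interval with low > high).
#' @export
invert_counts <- function(ror_printed, ci_printed, total_reports, total_cases,
                          decimals = 2, z = 1.96) {
  assert_that(is_count(total_reports) && total_reports >= 1,
              "`total_reports` must be a positive integer")
  assert_that(is_count(total_cases) && total_cases <= total_reports,
              "`total_cases` must be an integer within the stratum")
  assert_that(decimals >= 1, "`decimals` must be >= 1")
  empty <- tibble::tibble(n11 = integer(), n12 = integer(), n21 = integer(),
                          n22 = integer(), ror = numeric(),
                          ci_low = numeric(), ci_high = numeric())
  if (ci_printed[1] > ci_printed[2]) return(empty)

  half <- 0.5 * 10^(-decimals)
  r_lo <- max(ror_printed - half, 1e-12)
  r_hi <- ror_printed + half
  n_noncases <- total_reports - total_cases
  if (total_cases < 2 || n_noncases < 2) return(empty)

  # For each n11, invert ROR = n11 * (n_noncases - n12) / (n12 * n21) to
  # bracket the feasible n12 (ROR is decreasing in n12), then test every
  # candidate pair exactly — linear in total_cases, vectorized.
  n11 <- seq_len(total_cases - 1)           # need n11 >= 1 and n21 >= 1
  n21 <- total_cases - n11
  n12_hi <- n11 * n_noncases / (r_lo * n21 + n11)
  n12_lo <- n11 * n_noncases / (r_hi * n21 + n11)
  lo <- pmax(1, floor(n12_lo) - 1)
  hi <- pmin(n_noncases - 1, ceiling(n12_hi) + 1)
  width <- pmax(hi - lo + 1, 0)
  keep <- width > 0
  if (!any(keep)) return(empty)
  n11v <- rep(n11[keep], width[keep])
  n21v <- rep(n21[keep], width[keep])
  n12v <- unlist(lapply(which(keep), function(i) lo[i]:hi[i]), use.names = FALSE)
  n22v <- n_noncases - n12v

  r <- (n11v * n22v) / (n12v * n21v)
  se <- sqrt(1 / n11v + 1 / n12v + 1 / n21v + 1 / n22v)
  ci_l <- exp(log(r) - z * se)
  ci_h <- exp(log(r) + z * se)
  ok <- round_half_up(r, decimals) == ror_printed &
    round_half_up(ci_l, decimals) == ci_printed[1] &
    round_half_up(ci_h, decimals) == ci_printed[2]
  if (!any(ok)) return(empty)
  tibble::tibble(n11 = as.integer(n11v[ok]), n12 = as.integer(n12v[ok]),
                 n21 = as.integer(n21v[ok]), n22 = as.integer(n22v[ok]),
                 ror = r[ok], ci_low = ci_l[ok], ci_high = ci_h[ok])
}
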