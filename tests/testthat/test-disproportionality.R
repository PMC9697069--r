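test_that("case selection and target restriction follow exact term matching", {
  rs <- toy_target_set()
  cd <- pipn_case_definition()
  case <- is_case(rs, cd)
  expect_equal(sum(case), 2)
  expect_true(case[["r1"]] && case[["r3"]])

  # a near-miss term is not a case: matching is exact on normalized terms
  rs2 <- report_set(
    tibble::tibble(report_id = "a", drug = "paclitaxel"),
    tibble::tibble(report_id = "a", event = "neuropathy peripheral nos"))
  expect_false(unname(is_case(rs2, cd)))

  sub <- select_target_reports(rs, "paclitaxel")
  expect_equal(n_reports(sub), 6)
  expect_warning(select_target_reports(rs, "absentdrug"), "no report")
})

test_that("build_contingency reproduces the hand-enumerated 6-report table", {
  t <- build_contingency(toy_target_set(),
                         drug_group("tamsulosin", "tamsulosin"),
                         pipn_case_definition())
  expect_equal(unlist(t), c(n11 = 1, n12 = 1, n21 = 1, n22 = 3))

  # group with no members present: all exposure lands in the unexposed row
  t0 <- build_contingency(toy_target_set(),
                          drug_group("ghost", "ghostdrug"),
                          pipn_case_definition())
  expect_equal(unlist(t0), c(n11 = 0, n12 = 0, n21 = 2, n22 = 4))
})

test_that("ror matches hand arithmetic and the Haldane correction", {
  expect_equal(ror(contingency_table(10, 90, 100, 900)), 1.0)
  expect_equal(ror(contingency_table(5, 95, 200, 800)), 4000 / 19000)
  expect_equal(round_half_up(ror(contingency_table(5, 95, 200, 800)), 2), 0.21)
  expect_error(ror(contingency_table(0, 10, 5, 85)), "haldane")
  expect_equal(ror(contingency_table(0, 10, 5, 85), haldane = TRUE),
               (0.5 * 85.5) / (10.5 * 5.5))
})

test_that("Woolf CI matches hand arithmetic and degenerates at z = 0", {
  t <- contingency_table(10, 90, 100, 900)
  ci <- ror_ci(t)
  expect_equal(unname(ci), c(exp(-1.96 * sqrt(0.12222222222)),
                             exp(1.96 * sqrt(0.12222222222))),
               tolerance = 1e-9)
  expect_equal(round(unname(ci), 3), c(0.504, 1.984))
  expect_equal(unname(ror_ci(t, z = 0)), c(1, 1))
  expect_error(ror_ci(contingency_table(0, 1, 1, 1)), "zero cell")
})

test_that("ror and ror_ci agree with a brute-force oracle on random tables", {
  # oracle: direct textbook formula written independently of the package path
  oracle <- function(a, b, c, d, z = 1.96) {
    or <- (a / c) / (b / d)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    c(or, exp(log(or) - z * se), exp(log(or) + z * se))
  }
  set.seed(101)
  for (i in 1:300) {
    t <- random_positive_table()
    got <- c(ror(t), unname(ror_ci(t)))
    want <- oracle(t$n11, t$n12, t$n21, t$n22)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("ror respects the exposure/case relabeling symmetries", {
  set.seed(202)
  for (i in 1:50) {
    t <- random_positive_table()
    # swap rows and columns simultaneously: ROR invariant
    t_both <- contingency_table(t$n22, t$n21, t$n12, t$n11)
    expect_equal(ror(t_both), ror(t), tolerance = 1e-12)
    # swap exposure labels only: ROR -> 1/ROR, CI mirrored on the log scale
    t_row <- contingency_table(t$n21, t$n22, t$n11, t$n12)
    expect_equal(ror(t_row), 1 / ror(t), tolerance = 1e-12)
    ci <- ror_ci(t); ci_row <- ror_ci(t_row)
    expect_equal(unname(ci_row), rev(1 / unname(ci)), tolerance = 1e-12)
    # all-positive cells: low < ROR < high, symmetric in log space
    expect_true(ci[["low"]] < ror(t) && ror(t) < ci[["high"]])
    expect_equal(log(ror(t)) - log(ci[["low"]]),
                 log(ci[["high"]]) - log(ror(t)), tolerance = 1e-9)
  }
})

test_that("chi_squared matches hand-derived values and stats::chisq.test", {
  t <- contingency_table(10, 20, 20, 10)
  un <- chi_squared(t, yates = "never")
  expect_equal(un$chi2, 60 * (100 - 400)^2 / 30^4, tolerance = 1e-12)
  expect_equal(un$chi2, 6.6667, tolerance = 1e-4)
  expect_equal(un$p_value, 0.0098, tolerance = 1e-2)
  ya <- chi_squared(t, yates = "always")
  expect_equal(ya$chi2, 5.4, tolerance = 1e-12)
  expect_equal(ya$p_value, 0.0201, tolerance = 1e-2)
  expect_true(ya$yates_applied)

  # identical rows: no association
  z <- chi_squared(contingency_table(10, 90, 10, 90))
  expect_equal(z$chi2, 0)
  expect_equal(z$p_value, 1)

  # cross-check both variants against the standard implementation
  set.seed(303)
  for (i in 1:200) {
    t <- random_positive_table(80)
    m <- matrix(c(t$n11, t$n21, t$n12, t$n22), 2)
    ref_un <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    ref_ya <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
    got_un <- chi_squared(t, yates = "never")
    got_ya <- chi_squared(t, yates = "always")
    expect_equal(got_un$chi2, unname(ref_un$statistic), tolerance = 1e-10)
    expect_equal(got_un$p_value, ref_un$p.value, tolerance = 1e-10)
    expect_equal(got_ya$chi2, unname(ref_ya$statistic), tolerance = 1e-10)
    expect_true(got_ya$chi2 <= got_un$chi2)
  }
})

test_that("Yates trigger policies and degenerate margins behave as documented", {
  small <- contingency_table(3, 40, 30, 400)   # one observed cell < 5
  expect_true(chi_squared(small, yates = "observed")$yates_applied)
  big <- contingency_table(10, 40, 30, 400)
  expect_false(chi_squared(big, yates = "observed")$yates_applied)
  # expected-cell rule can trigger where the observed rule does not
  t <- contingency_table(6, 6, 6, 300)  # expected n21 cell small
  expect_false(chi_squared(t, yates = "observed")$yates_applied)
  expect_true(chi_squared(t, yates = "expected")$yates_applied)
  # zero margin: vacuous test
  d <- chi_squared(contingency_table(0, 0, 5, 5))
  expect_true(d$degenerate)
  expect_equal(d$chi2, 0)
  expect_equal(d$p_value, 1)
})

test_that("reporting rate reproduces the published PIPN reporting percentage", {
  n_total <- 71351L
  n_cases <- 3268L
  ids <- sprintf("r%05d", seq_len(n_total))
  rs <- report_set(
    tibble::tibble(report_id = ids, drug = "paclitaxel"),
    tibble::tibble(report_id = ids[seq_len(n_cases)],
                   event = "peripheral neuropathy"))
  expect_equal(format_rate_pct(reporting_rate(rs, pipn_case_definition())),
               4.58)
  empty <- report_set(tibble::tibble(report_id = character(),
                                     drug = character()),
                      tibble::tibble(report_id = character(),
                                     event = character()))
  expect_error(reporting_rate(empty, pipn_case_definition()), "empty")
})

test_that("signal_table assembles per-group rows with pooled-class containment", {
  gen <- generate_reports(synthetic_report_params(n_reports = 5000, seed = 4))
  trs <- select_target_reports(gen$reports, "paclitaxel")
  groups <- list(drug_group("tamsulosin", "tamsulosin"),
                 drug_group("doxazosin", "doxazosin"),
                 alpha1_antagonist_group())
  tab <- signal_table(trs, groups, pipn_case_definition(), haldane = TRUE)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$group, sort(tab$group))
  pooled <- tab[tab$group == "alpha1_antagonists", ]
  tam <- tab[tab$group == "tamsulosin", ]
  expect_true(pooled$n11 >= tam$n11 && pooled$n12 >= tam$n12)
  expect_equal(tab$n11 + tab$n12 + tab$n21 + tab$n22,
               rep(n_reports(trs), 3))
  # empty group list -> empty table; zero-cell group yields NA row, not abort
  expect_equal(nrow(signal_table(trs, list(), pipn_case_definition())), 0)
  tab2 <- signal_table(trs, list(drug_group("ghost", "ghostdrug"),
                                 drug_group("tamsulosin", "tamsulosin")),
                       pipn_case_definition())
  expect_true(is.na(tab2$ror[tab2$group == "ghost"]))
  expect_false(is.na(tab2$ror[tab2$group == "tamsulosin"]))
})
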