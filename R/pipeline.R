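#' Validate a pipeline run configuration
#'
#' The configuration is a named list (or YAML file) with top-level keys:
#' \describe{
#'   \item{arm}{one of `"pharmacovigilance"`, `"vonfrey"`, `"morphometry"`,
#'     `"all"`}
#'   \item{seed}{integer; mandatory whenever any arm generates data}
#'   \item{pharmacovigilance}{list with exactly one of `inputs` (paths
#'     `drug_table`, `reaction_table`, optional `delim`) or `generator`
#'     (fields of [synthetic_report_params()]), plus optional `target_drug`,
#'     `z`, `yates`, `haldane`}
#'   \item{vonfrey}{list with exactly one of `inputs` (path `sessions`) or
#'     `generator` (fields of [updown_sim_params()] plus `n_sessions`,
#'     `groups` as named list of true thresholds)}
#'   \item{morphometry}{list with exactly one of `inputs` (path `fibers`,
#'     polygon CSV) or `generator` (fields of [nerve_synth_params()],
#'     optionally a named list `conditions` of degeneration levels)}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return the validated config list (with the arm field normalized).
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    assert_that(file.exists(config), paste0("no such config file: ", config))
    config <- yaml::read_yaml(config)
  }
  assert_that(is.list(config), "config must be a list or a YAML path")
  assert_that(!is.null(config$arm), "config needs an `arm` field")
  config$arm <- match.arg(config$arm,
                          c("pharmacovigilance", "vonfrey", "morphometry",
                            "all"))
  arms <- if (config$arm == "all") {
    c("pharmacovigilance", "vonfrey", "morphometry")
  } else config$arm
  for (arm in arms) {
    spec <- config[[arm]]
    assert_that(is.list(spec), paste0("config needs a `", arm, "` section"))
    has_in <- !is.null(spec$inputs)
    has_gen <- !is.null(spec$generator)
    if (has_in == has_gen) {
      stop("arm `", arm, "`: exactly one of `inputs` or `generator` ",
           "must be given", call. = FALSE)
    }
    if (has_gen && is.null(config$seed)) {
      stop("config needs a `seed` when any arm generates data",
           call. = FALSE)
    }
  }
  config
}

#' Run the analysis pipeline
#'
#' Executes the configured arms (synthesize or load, then analyze), writes
#' one CSV per analysis product plus a JSON manifest (config echo, package
#' version, seed, output row counts and MD5 digests). Identical config and
#' seed give byte-identical outputs. A failing arm is recorded in the
#' manifest with its error message; other arms still run.
#'
#' @param config named list or YAML path, see [validate_run_config()].
#' @param out_dir output directory (created if absent).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  arms <- if (config$arm == "all") {
    c("pharmacovigilance", "vonfrey", "morphometry")
  } else config$arm
  outputs <- list()
  errors <- list()
  for (arm in arms) {
    res <- tryCatch(
      switch(arm,
        pharmacovigilance = run_arm_pharmacovigilance(config, out_dir),
        vonfrey = run_arm_vonfrey(config, out_dir),
        morphometry = run_arm_morphometry(config, out_dir)
      ),
      error = function(e) structure(conditionMessage(e), class = "arm_error")
    )
    if (inherits(res, "arm_error")) {
      errors[[arm]] <- unclass(res)
    } else {
      outputs <- c(outputs, res)
    }
  }
  manifest <- list(
    package = "pipntools",
    version = as.character(utils::packageVersion("pipntools")),
    arm = config$arm,
    seed = config$seed,
    config = config,
    outputs = lapply(outputs, function(p) {
      list(path = basename(p),
           rows = length(readr::read_lines(p, progress = FALSE)) - 1L,
           md5 = unname(tools::md5sum(p)))
    }),
    errors = errors
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (length(errors) > 0) {
    warning("arm(s) failed: ", paste(names(errors), collapse = ", "),
            call. = FALSE)
  }
  invisible(manifest)
}

#' @noRd
run_arm_pharmacovigilance <- function(config, out_dir) {
  spec <- config$pharmacovigilance
  target <- spec$target_drug %||% "paclitaxel"
  if (!is.null(spec$generator)) {
    gp <- spec$generator
    gp$seed <- gp$seed %||% config$seed
    params <- do.call(synthetic_report_params, gp)
    gen <- generate_reports(params)
    rs <- gen$reports
  } else {
    rs <- read_reports(spec$inputs$drug_table, spec$inputs$reaction_table,
                       delim = spec$inputs$delim %||% "$")
  }
  cd <- if (!is.null(spec$case_terms)) {
    case_definition("case", spec$case_terms)
  } else pipn_case_definition()
  groups <- if (!is.null(spec$groups)) {
    purrr::imap(spec$groups, ~ drug_group(.y, .x))
  } else {
    drugs_seen <- alpha1_antagonist_group()$members
    single <- lapply(intersect(drugs_seen, unique(rs$drugs$drug)),
                     function(d) drug_group(d, d))
    c(single, list(alpha1_antagonist_group()))
  }
  target_rs <- select_target_reports(rs, target)
  sig <- signal_table(target_rs, groups, cd,
                      z = spec$z %||% 1.96,
                      yates = spec$yates %||% "observed",
                      haldane = isTRUE(spec$haldane))
  rate <- tibble::tibble(
    target_drug = target,
    n_reports = n_reports(target_rs),
    n_cases = sum(is_case(target_rs, cd)),
    reporting_rate_pct = format_rate_pct(reporting_rate(target_rs, cd))
  )
  p1 <- file.path(out_dir, "signals.csv")
  p2 <- file.path(out_dir, "reporting_rate.csv")
  readr::write_csv(sig, p1)
  readr::write_csv(rate, p2)
  list(signals = p1, reporting_rate = p2)
}

#' @noRd
run_arm_vonfrey <- function(config, out_dir) {
  spec <- config$vonfrey
  if (!is.null(spec$generator)) {
    gp <- spec$generator
    groups <- gp$groups %||% list(control = 4, treated = 4)
    n_sessions <- gp$n_sessions %||% 8
    base_seed <- (gp$seed %||% config$seed)
    rows <- list()
    i <- 0
    for (gname in names(groups)) {
      for (s in seq_len(n_sessions)) {
        i <- i + 1
        params <- updown_sim_params(
          true_threshold_g = groups[[gname]],
          slope = gp$slope %||% 8,
          seed = base_seed + i)
        ses <- generate_updown_session(params,
                                       session_id = paste0(gname, "_", s))
        est <- estimate_threshold(ses)
        rows[[i]] <- tibble::tibble(
          session_id = ses$session_id, group = gname,
          threshold_g = est$threshold_g, censored = est$censored,
          n_trials = est$n_trials)
      }
    }
    thresholds <- dplyr::bind_rows(rows)
  } else {
    sessions <- readr::read_csv(spec$inputs$sessions, col_types = "cidl",
                                progress = FALSE)
    assert_that(all(c("session_id", "trial_index", "force_g", "response")
                    %in% names(sessions)),
                "sessions CSV needs session_id, trial_index, force_g, response")
    thresholds <- sessions |>
      dplyr::arrange(.data$session_id, .data$trial_index) |>
      dplyr::group_by(.data$session_id) |>
      dplyr::group_map(function(df, key) {
        ses <- updown_session(key$session_id, df$force_g, df$response)
        est <- estimate_threshold(ses)
        tibble::tibble(session_id = key$session_id,
                       group = sub("_[0-9]+$", "", key$session_id),
                       threshold_g = est$threshold_g,
                       censored = est$censored, n_trials = est$n_trials)
      }) |>
      dplyr::bind_rows()
  }
  p1 <- file.path(out_dir, "thresholds.csv")
  readr::write_csv(thresholds, p1)
  out <- list(thresholds = p1)
  split_thr <- split(thresholds$threshold_g, thresholds$group)
  if (length(split_thr) >= 2 && all(lengths(split_thr) >= 2)) {
    tk <- tukey_kramer(split_thr)
    p2 <- file.path(out_dir, "comparisons.csv")
    readr::write_csv(tk$pairs, p2)
    out$comparisons <- p2
  }
  out
}

#' @noRd
run_arm_morphometry <- function(config, out_dir) {
  spec <- config$morphometry
  if (!is.null(spec$generator)) {
    gp <- spec$generator
    conditions <- gp$conditions %||% list(field = gp$degeneration_level %||% 0)
    base_seed <- (gp$seed %||% config$seed)
    morph <- purrr::imap_dfr(conditions, function(lvl, cname) {
      params <- nerve_synth_params(
        n_fibers = gp$n_fibers %||% 100,
        degeneration_level = lvl,
        seed = base_seed + match(cname, names(conditions)))
      fibers <- generate_nerve_cross_section(params)
      dplyr::bind_rows(lapply(fibers, measure_fiber)) |>
        dplyr::mutate(condition = cname, .before = 1)
    })
  } else {
    fibers <- read_fiber_polygons(spec$inputs$fibers)
    morph <- dplyr::bind_rows(lapply(fibers, measure_fiber)) |>
      dplyr::mutate(condition = "input", .before = 1)
  }
  p1 <- file.path(out_dir, "morphometry.csv")
  readr::write_csv(morph, p1)
  summ <- morph |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(~ summarize_nerve(.x)) |>
    dplyr::ungroup()
  p2 <- file.path(out_dir, "nerve_summary.csv")
  readr::write_csv(summ, p2)
  list(morphometry = p1, nerve_summary = p2)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
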