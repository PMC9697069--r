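#' Normalize a drug or event name
#'
#' Spontaneous-report databases mix case and spacing freely; all matching in
#' this package is exact on normalized names. Normalization lowercases,
#' trims, and collapses internal whitespace runs to a single space, then
#' applies an optional synonym map (keyed by already-normalized names).
#'
#' @param raw character vector of raw names.
#' @param synonyms optional named character vector mapping normalized
#'   names to canonical names, e.g. `c("tamsulosin hcl" = "tamsulosin")`.
#' @return character vector of normalized names.
#' @export
#' @examples
#' normalize_name("  Peripheral Neuropathy ")
#' normalize_name("TAMSULOSIN  HCL", synonyms = c("tamsulosin hcl" = "tamsulosin"))
normalize_name <- function(raw, synonyms = NULL) {
  assert_that(is.character(raw), "`raw` must be character")
  out <- tolower(trimws(raw))
  out <- gsub("[[:space:]]+", " ", out)
  if (!is.null(synonyms)) {
    assert_that(is.character(synonyms) && !is.null(names(synonyms)),
                "`synonyms` must be a named character vector")
    hit <- match(out, names(synonyms))
    out[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  }
  if (any(!nzchar(out))) {
    stop("name(s) empty after normalization at position(s): ",
         paste(which(!nzchar(out)), collapse = ", "), call. = FALSE)
  }
  out
}

#' Construct a report set
#'
#' A report set is the package's container for FAERS-like spontaneous
#' adverse-event reports: a drug table (one row per report-drug pair) and an
#' event table (one row per report-event pair), both keyed by `report_id`.
#' Every report must list at least one drug; events may be absent. Names are
#' assumed already normalized (see [normalize_name()]).
#'
#' @param drugs tibble/data.frame with columns `report_id`, `drug`.
#' @param events tibble/data.frame with columns `report_id`, `event`.
#' @param provenance free-text label recording where the data came from.
#' @return an object of class `report_set`.
#' @export
report_set <- function(drugs, events, provenance = "unspecified") {
  drugs <- tibble::as_tibble(drugs)
  events <- tibble::as_tibble(events)
  assert_that(all(c("report_id", "drug") %in% names(drugs)),
              "`drugs` needs columns report_id, drug")
  assert_that(all(c("report_id", "event") %in% names(events)),
              "`events` needs columns report_id, event")
  drugs <- dplyr::distinct(drugs[, c("report_id", "drug")])
  events <- dplyr::distinct(events[, c("report_id", "event")])
  orphan <- setdiff(events$report_id, drugs$report_id)
  if (length(orphan) > 0) {
    stop("report(s) with events but no drugs (every report needs >= 1 drug): ",
         paste(utils::head(orphan, 10), collapse = ", "), call. = FALSE)
  }
  structure(
    list(drugs = drugs, events = events, provenance = provenance),
    class = "report_set"
  )
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set> ", n_reports(x), " reports, ",
      nrow(x$drugs), " drug rows, ", nrow(x$events), " event rows\n",
      "provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Number of distinct reports in a report set
#' @param rs a `report_set`.
#' @return integer count of distinct report ids.
#' @export
n_reports <- function(rs) {
  assert_that(inherits(rs, "report_set"), "`rs` must be a report_set")
  dplyr::n_distinct(rs$drugs$report_id)
}

#' Case definition: a named set of event terms
#'
#' A report is a case when its event set intersects `terms`. Matching is
#' exact on normalized terms; there is no MedDRA hierarchy traversal.
#'
#' @param name label for the definition.
#' @param terms character vector of event terms (normalized on input).
#' @return an object of class `case_definition`.
#' @export
case_definition <- function(name, terms) {
  assert_that(length(terms) >= 1, "`terms` must be non-empty")
  structure(list(name = name, terms = unique(normalize_name(terms))),
            class = "case_definition")
}

#' The PIPN case definition
#'
#' Paclitaxel-induced peripheral neuropathy is identified by three
#' MedDRA-style preferred terms: peripheral neuropathy, peripheral sensory
#' neuropathy, and peripheral sensorimotor neuropathy.
#'
#' @return a `case_definition`.
#' @export
pipn_case_definition <- function() {
  case_definition("pipn", c(
    "peripheral neuropathy",
    "peripheral sensory neuropathy",
    "peripheral sensorimotor neuropathy"
  ))
}

#' Drug group: a named set of drug names treated as one exposure
#'
#' @param name group label (a single drug is a group of size 1).
#' @param members character vector of drug names (normalized on input).
#' @return an object of class `drug_group`.
#' @export
drug_group <- function(name, members) {
  assert_that(length(members) >= 1, "`members` must be non-empty")
  structure(list(name = name, members = unique(normalize_name(members))),
            class = "drug_group")
}

#' Default alpha-1 adrenergic receptor antagonist class
#'
#' The pooled exposure class used for the "any alpha-1 antagonist"
#' comparison. The membership is a package default and fully configurable;
#' selective and non-selective alpha-1 blockers in common clinical use.
#'
#' @return a `drug_group` named `"alpha1_antagonists"`.
#' @export
alpha1_antagonist_group <- function() {
  drug_group("alpha1_antagonists", c(
    "tamsulosin", "doxazosin", "alfuzosin", "silodosin",
    "terazosin", "prazosin", "urapidil", "naftopidil"
  ))
}

#' Built-in minimal synonym map for drug names
#'
#' Maps a handful of salt/brand variants to generic names. Users analysing
#' real extracts should supply their own, fuller map.
#'
#' @return named character vector usable as `synonyms` in [normalize_name()].
#' @export
default_drug_synonyms <- function() {
  c(
    "tamsulosin hcl" = "tamsulosin",
    "tamsulosin hydrochloride" = "tamsulosin",
    "doxazosin mesylate" = "doxazosin",
    "paclitaxel protein-bound" = "paclitaxel protein-bound",
    "abraxane" = "paclitaxel protein-bound",
    "taxol" = "paclitaxel"
  )
}

#' Read a report set from delimited drug and reaction tables
#'
#' Mirrors the FAERS quarterly DRUG/REAC file structure reduced to the two
#' columns the case/non-case analysis needs. Both files must have a header
#' row; the default field delimiter is `"$"` (the FAERS ASCII convention),
#' with tab and comma supported. Duplicate (report, drug) or (report, event)
#' rows are collapsed with a message; a report id that appears only in the
#' reaction table is an error, because a report must carry at least one drug.
#'
#' @param drug_table path to the drug file (columns `report_id`, `drug_name`).
#' @param reaction_table path to the reaction file (columns `report_id`,
#'   `event_term`).
#' @param delim field delimiter: `"$"` (default), `"\t"` or `","`.
#' @param synonyms optional synonym map passed to [normalize_name()].
#' @return a [report_set()].
#' @export
read_reports <- function(drug_table, reaction_table, delim = "$",
                         synonyms = NULL) {
  assert_that(file.exists(drug_table), paste0("no such file: ", drug_table))
  assert_that(file.exists(reaction_table),
              paste0("no such file: ", reaction_table))
  dr <- readr::read_delim(drug_table, delim = delim, col_types = "cc",
                          progress = FALSE)
  re <- readr::read_delim(reaction_table, delim = delim, col_types = "cc",
                          progress = FALSE)
  assert_that(all(c("report_id", "drug_name") %in% names(dr)),
              "drug table must have columns report_id, drug_name")
  assert_that(all(c("report_id", "event_term") %in% names(re)),
              "reaction table must have columns report_id, event_term")

  drugs <- tibble::tibble(
    report_id = dr$report_id,
    drug = if (nrow(dr)) normalize_name(dr$drug_name, synonyms) else character()
  )
  events <- tibble::tibble(
    report_id = re$report_id,
    event = if (nrow(re)) normalize_name(re$event_term) else character()
  )
  n_dup <- (nrow(drugs) - nrow(dplyr::distinct(drugs))) +
    (nrow(events) - nrow(dplyr::distinct(events)))
  if (n_dup > 0) message("collapsed ", n_dup, " duplicate row(s)")

  report_set(drugs, events,
             provenance = paste0("files: ", drug_table, " + ", reaction_table))
}

#' Write a report set to delimited drug and reaction tables
#'
#' Inverse of [read_reports()]: `read_reports(write_reports(rs))` recovers
#' `rs` up to row order. UTF-8, LF line endings.
#'
#' @param rs a `report_set`.
#' @param drug_table,reaction_table output paths.
#' @param delim field delimiter (default `"$"`).
#' @return the paths, invisibly.
#' @export
write_reports <- function(rs, drug_table, reaction_table, delim = "$") {
  assert_that(inherits(rs, "report_set"), "`rs` must be a report_set")
  dr <- tibble::tibble(report_id = rs$drugs$report_id,
                       drug_name = rs$drugs$drug)
  re <- tibble::tibble(report_id = rs$events$report_id,
                       event_term = rs$events$event)
  readr::write_delim(dr, drug_table, delim = delim, eol = "\n")
  readr::write_delim(re, reaction_table, delim = delim, eol = "\n")
  invisible(c(drug_table = drug_table, reaction_table = reaction_table))
}
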