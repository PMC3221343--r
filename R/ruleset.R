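#' Default classification rule set
#'
#' The rule set drives the publication-type classifier: ordered precedence
#' lists of MEDLINE publication-type strings per category, term lists
#' operationalizing the systematic-review criteria (comprehensive search,
#' explicit selection criteria, synthesis of primary studies), the
#' study-data heuristics for letters/comments/editorials, and source
#' patterns for reports (government publications, statistical data reports,
#' technology assessments, MMWR, task-force reports) and for synopsis
#' sources (ACP Journal Club, FPIN).
#'
#' The systematic-review criteria in the scheme's original form require
#' full-text judgment; here they are operationalized as abstract/title
#' keyword evidence with a configurable term list, the only
#' desk-reproducible surrogate. All lists can be tightened or loosened and
#' the result shipped as a versioned YAML file ([write_ruleset()]).
#'
#' @param study_data_requires_structure Whether letters/comments/editorials
#'   need a structured-abstract outline *in addition to* a described sample
#'   to count as reporting study data (default `TRUE`).
#' @return A list of class `evicite_ruleset`.
#' @export
#' @examples
#' rules <- default_ruleset()
#' rules$rct_types
default_ruleset <- function(study_data_requires_structure = TRUE) {
  structure(list(
    version = "1.0",
    # precedence tiers (first match wins, tier order fixed)
    guideline_types = c(
      "Guideline", "Practice Guideline",
      "Consensus Development Conference",
      "Consensus Development Conference, NIH"
    ),
    sr_types = c("Meta-Analysis", "Systematic Review"),
    review_types = c("Review", "Scientific Integrity Review"),
    rct_types = c("Randomized Controlled Trial"),
    letter_types = c("Letter", "Comment", "Editorial"),
    study_design_types = c(
      "Clinical Trial", "Controlled Clinical Trial",
      "Clinical Trial, Phase I", "Clinical Trial, Phase II",
      "Clinical Trial, Phase III", "Clinical Trial, Phase IV",
      "Comparative Study", "Multicenter Study", "Observational Study",
      "Case Reports", "Evaluation Study", "Evaluation Studies",
      "Validation Study", "Validation Studies", "Twin Study",
      "Clinical Study"
    ),
    report_types = c("Technical Report", "Government Document",
                     "Government Publications"),
    other_types = c("Book", "Congress", "Abstract", "Published Erratum",
                    "News", "Interview", "Biography", "Historical Article",
                    "Lecture", "Address", "Bibliography", "Thesis",
                    "Electronic Resource"),
    report_source_patterns = c(
      "\\bMMWR\\b", "Morb(idity)?\\.? Mortal(ity)?\\.? W(ee)?kly",
      "technology assessment", "task force", "working group",
      "statistical (data )?report", "government printing office",
      "office (for|of) national statistics", "\\bstatistics\\b.*\\bgov\\b",
      "\\.gov\\b", "\\bAHRQ\\b", "agency for healthcare research"
    ),
    sr_search_patterns = c(
      "we searched", "literature search", "comprehensive search",
      "systematic search", "systematic review", "\\bmedline\\b",
      "\\bembase\\b", "\\bcochrane\\b", "databases? (were|was) searched",
      "search(ed)? (of )?(the )?(electronic )?databases?"
    ),
    sr_selection_patterns = c(
      "inclusion criteria", "exclusion criteria", "eligibility criteria",
      "selection criteria", "criteria for (inclusion|selection)",
      "studies were (selected|included|eligible)"
    ),
    sr_synthesis_patterns = c(
      "\\bpooled\\b", "meta-?analys", "data (were|was) (synthesi[sz]ed|combined)",
      "random-?effects", "fixed-?effects", "\\bforest plot\\b",
      "(included|identified) [0-9]+ (studies|trials|randomi[sz]ed)"
    ),
    study_sample_patterns = c(
      "\\bn\\s*=\\s*[0-9]+", "[0-9]+\\s+(patients|subjects|participants|adults|children|cases|women|men|infants)",
      "\\benrolled\\b", "\\brecruited\\b", "cohort of"
    ),
    section_cue_groups = list(
      opening = "(objectives?|introduction|background|problem)\\s*:",
      methods = "(methods?|subjects|design|patients and methods)\\s*:",
      results = "(results?|findings)\\s*:",
      closing = "(discussion|conclusions?|interpretation)\\s*:"
    ),
    synopsis_source_patterns = c(
      "ACP J(ournal)?\\.? Club", "\\bFPIN\\b",
      "Family Physicians Inquiries Network", "Clin(ical)? Inq(uiries)?",
      "Evid(ence)?.?Based (Medicine|Practice)\\b"
    ),
    study_data_requires_structure = isTRUE(study_data_requires_structure)
  ), class = "evicite_ruleset")
}

#' @export
print.evicite_ruleset <- function(x, ...) {
  cat(sprintf("<evicite_ruleset> version %s\n", x$version))
  cat(sprintf("  %d precedence type lists; study_data_requires_structure = %s\n",
              sum(vapply(x, is.character, logical(1))),
              x$study_data_requires_structure))
  invisible(x)
}

#' Write / read a rule set as YAML
#'
#' Rule sets are shipped and versioned as plain YAML so term lists can be
#' audited and adjusted without touching code. `read_ruleset()` validates
#' that all precedence lists are present.
#'
#' @param rules An `evicite_ruleset`.
#' @param path YAML file path.
#' @return `write_ruleset()` returns `path` invisibly; `read_ruleset()`
#'   returns an `evicite_ruleset`.
#' @export
write_ruleset <- function(rules, path) {
  stopifnot(inherits(rules, "evicite_ruleset"))
  yaml::write_yaml(unclass(rules), path)
  invisible(path)
}

#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  x <- yaml::read_yaml(path)
  needed <- c("guideline_types", "sr_types", "review_types", "rct_types",
              "letter_types", "study_design_types", "report_types",
              "other_types", "report_source_patterns", "sr_search_patterns",
              "sr_selection_patterns", "sr_synthesis_patterns",
              "study_sample_patterns", "section_cue_groups",
              "synopsis_source_patterns")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    abort(paste0("Rule file is missing fields: ",
                 paste(missing, collapse = ", ")))
  }
  x$study_data_requires_structure <-
    isTRUE(x$study_data_requires_structure)
  structure(x, class = "evicite_ruleset")
}
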