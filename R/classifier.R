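#' Classify one citation into the nine-category scheme
#'
#' Applies the deterministic precedence protocol. Tiers, first match wins:
#'
#' 1. unverified citation -> `unknown`;
#' 2. guideline / practice-guideline types -> `guideline`;
#' 3. meta-analysis type, or a review-family type whose abstract/title meets
#'    the systematic-review criteria ([is_systematic_review()]) ->
#'    `systematic_review`;
#' 4. randomized-controlled-trial type -> `randomized_controlled_trial`;
#' 5. animal-only study (MeSH "Animals" without "Humans", with a study-design
#'    type present) -> `animal_study`;
#' 6. report types or report sources (MMWR, government publications,
#'    statistical data reports, technology assessments, task-force reports)
#'    -> `report`;
#' 7. remaining review types -> `review`;
#' 8. letters/comments/editorials -> `primary_research_other` when they
#'    report study data ([reports_study_data()]), else `other`;
#' 9. remaining primary study designs, or an unclear journal-article design
#'    -> `primary_research_other`;
#' 10. books, abstracts, congresses and similar -> `other`; anything left ->
#'    `other`.
#'
#' The function is total: every record receives exactly one category, and
#' permuting the order of `pub_types` never changes the result.
#'
#' @param record A one-row record tibble (see [citation_record()]).
#' @param rules An `evicite_ruleset`, by default [default_ruleset()].
#' @return A one-row tibble: the record columns plus `category` (factor over
#'   [publication_categories()]), `rationale` (list of fired-rule ids),
#'   `sr_flag`, and `study_data_flag` (NA unless tier 8 was evaluated).
#' @export
#' @examples
#' r <- citation_record(title = "Statins for hyperlipidemia", year = 2005,
#'                      pmid = "111", pub_types = "Meta-Analysis",
#'                      product = "P", topic = "hyperlipidemia")
#' classify_citation(r)$category
classify_citation <- function(record, rules = default_ruleset()) {
  rec <- as_tibble(record)
  stopifnot(nrow(rec) == 1)
  cls <- classify_one(
    pub_types = rec$pub_types[[1]],
    mesh_terms = rec$mesh_terms[[1]],
    title = rec$title, abstract = rec$abstract, source = rec$source,
    verified = rec$verified, rules = rules
  )
  rec$category <- factor(cls$category, levels = publication_categories())
  rec$rationale <- list(cls$rationale)
  rec$sr_flag <- cls$sr_flag
  rec$study_data_flag <- cls$study_data_flag
  rec
}

# Core precedence engine on plain fields; returns list(category, rationale,
# sr_flag, study_data_flag).
classify_one <- function(pub_types, mesh_terms, title, abstract, source,
                         verified, rules) {
  pub_types <- pub_types %||% character()
  mesh_terms <- mesh_terms %||% character()
  fired <- character()
  sr_flag <- FALSE
  study_data_flag <- NA

  # candidate logging for multi-type records: which tiers the types touch
  tiers <- c("guideline_types", "sr_types", "review_types", "rct_types",
             "letter_types", "study_design_types", "report_types",
             "other_types")
  touched <- tiers[vapply(tiers, function(t) any(pub_types %in% rules[[t]]),
                          logical(1))]
  candidates <- if (length(touched) > 1) paste0("candidate:", touched)
                else character()

  done <- function(category, rule_id) {
    list(category = category,
         rationale = c(fired, rule_id, candidates),
         sr_flag = sr_flag, study_data_flag = study_data_flag)
  }

  if (isFALSE(verified)) return(done("unknown", "unverified"))

  if (any(pub_types %in% rules$guideline_types)) {
    return(done("guideline", "pt:guideline"))
  }
  if (any(pub_types %in% rules$sr_types)) {
    sr_flag <- TRUE
    return(done("systematic_review", "pt:meta_analysis"))
  }
  is_review <- any(pub_types %in% rules$review_types)
  if (is_review) {
    sr_flag <- sr_criteria_met(title, abstract, rules)
    if (sr_flag) {
      return(done("systematic_review", "review+sr_criteria"))
    }
    fired <- c(fired, "review:sr_criteria_not_met")
  }
  if (any(pub_types %in% rules$rct_types)) {
    return(done("randomized_controlled_trial", "pt:rct"))
  }
  has_study_type <- any(pub_types %in% c(rules$rct_types,
                                         rules$study_design_types))
  if ("Animals" %in% mesh_terms && !("Humans" %in% mesh_terms) &&
      has_study_type) {
    return(done("animal_study", "mesh:animals_only+study_type"))
  }
  if (any(pub_types %in% rules$report_types) ||
      source_matches(source, rules$report_source_patterns)) {
    return(done("report", "report_source"))
  }
  if (is_review) {
    return(done("review", "pt:review"))
  }
  if (any(pub_types %in% rules$letter_types)) {
    study_data_flag <- study_data_met(title, abstract, rules)
    return(done(
      if (study_data_flag) "primary_research_other" else "other",
      if (study_data_flag) "letter:study_data" else "letter:no_study_data"
    ))
  }
  if (any(pub_types %in% rules$study_design_types)) {
    return(done("primary_research_other", "pt:study_design"))
  }
  if (any(pub_types %in% rules$other_types)) {
    return(done("other", "pt:other"))
  }
  if (length(pub_types)) {
    # e.g. bare "Journal Article": unclear study type
    return(done("primary_research_other", "pt:unclear_design"))
  }
  done("other", "no_pt:other")
}

source_matches <- function(source, patterns) {
  if (is.na(source %||% NA)) return(FALSE)
  any(vapply(patterns, function(p) grepl(p, source, ignore.case = TRUE,
                                         perl = TRUE), logical(1)))
}

any_pattern <- function(text, patterns) {
  any(vapply(patterns, function(p) grepl(p, text, ignore.case = TRUE,
                                         perl = TRUE), logical(1)))
}

sr_criteria_met <- function(title, abstract, rules) {
  text <- paste(ifelse(is.na(title), "", title),
                ifelse(is.na(abstract), "", abstract))
  if (!nzchar(trimws(text))) return(FALSE)
  any_pattern(text, rules$sr_search_patterns) &&
    any_pattern(text, rules$sr_selection_patterns) &&
    any_pattern(text, rules$sr_synthesis_patterns)
}

study_data_met <- function(title, abstract, rules) {
  text <- paste(ifelse(is.na(title), "", title),
                ifelse(is.na(abstract), "", abstract))
  if (!nzchar(trimws(text))) return(FALSE)
  sample_ok <- any_pattern(text, rules$study_sample_patterns)
  if (!sample_ok) return(FALSE)
  if (!rules$study_data_requires_structure) return(TRUE)
  cues <- sum(vapply(rules$section_cue_groups, function(p) {
    grepl(p, ifelse(is.na(abstract), "", abstract), ignore.case = TRUE,
          perl = TRUE)
  }, logical(1)))
  cues >= 2
}

#' Does a review-typed citation meet the systematic-review criteria?
#'
#' A citation indexed with a review-family publication type is promoted to
#' `systematic_review` when its title/abstract textually evidences all three
#' hallmarks of a systematic review -- a comprehensive/explicit search, the
#' use of explicit selection criteria, and synthesis of multiple primary
#' studies -- or when it carries a meta-analysis publication type, which
#' short-circuits to `TRUE`.
#'
#' @inheritParams classify_citation
#' @return Logical scalar. Errors when the record carries no review-family
#'   or meta-analysis type (contract violation).
#' @export
is_systematic_review <- function(record, rules = default_ruleset()) {
  rec <- as_tibble(record)
  stopifnot(nrow(rec) == 1)
  pts <- rec$pub_types[[1]]
  if (!any(pts %in% c(rules$review_types, rules$sr_types))) {
    abort("`is_systematic_review()` requires a review-family publication type.")
  }
  if (any(pts %in% rules$sr_types)) return(TRUE)
  sr_criteria_met(rec$title, rec$abstract, rules)
}

#' Does a letter/comment/editorial report study data?
#'
#' Letters, comments and editorials occasionally report original study data
#' and are then counted as primary research rather than `other`. Two
#' criteria are checked: (1) the sample/subjects studied are described
#' characteristically or in quantity (an explicit `n = ...`, an enrollment
#' count, a cohort descriptor) -- always required; and (2) a traditional
#' structured-abstract outline is present (at least two of the section cues
#' Objective/Introduction/Problem, Methods/Subjects, Results,
#' Discussion/Conclusion). Whether criterion 2 is required is governed by
#' the rule set's `study_data_requires_structure` switch (default `TRUE`).
#'
#' @inheritParams classify_citation
#' @return Logical scalar. Errors when the record carries no
#'   letter/comment/editorial type (contract violation).
#' @export
reports_study_data <- function(record, rules = default_ruleset()) {
  rec <- as_tibble(record)
  stopifnot(nrow(rec) == 1)
  if (!any(rec$pub_types[[1]] %in% rules$letter_types)) {
    abort("`reports_study_data()` requires a letter/comment/editorial type.")
  }
  study_data_met(rec$title, rec$abstract, rules)
}

#' Classify every record of a corpus
#'
#' Order-preserving, total: one classified row per record. Identical records
#' always receive identical categories and rationales.
#'
#' @param corpus_tbl An `evicite_corpus` (or compatible record tibble).
#' @inheritParams classify_citation
#' @param quiet Suppress the per-category count summary message.
#' @return A tibble of classified citations: record columns plus `category`,
#'   `rationale`, `sr_flag`, `study_data_flag`.
#' @export
classify_corpus <- function(corpus_tbl, rules = default_ruleset(),
                            quiet = TRUE) {
  records <- as_tibble(corpus_tbl)
  n <- nrow(records)
  category <- character(n)
  rationale <- vector("list", n)
  sr_flag <- logical(n)
  study_data_flag <- rep(NA, n)
  for (i in seq_len(n)) {
    cls <- classify_one(
      pub_types = records$pub_types[[i]],
      mesh_terms = records$mesh_terms[[i]],
      title = records$title[[i]], abstract = records$abstract[[i]],
      source = records$source[[i]], verified = records$verified[[i]],
      rules = rules
    )
    category[[i]] <- cls$category
    rationale[[i]] <- cls$rationale
    sr_flag[[i]] <- cls$sr_flag
    study_data_flag[[i]] <- cls$study_data_flag
  }
  out <- records
  out$category <- factor(category, levels = publication_categories())
  out$rationale <- rationale
  out$sr_flag <- sr_flag
  out$study_data_flag <- study_data_flag
  if (!quiet && n) {
    counts <- table(out$category)
    rlang::inform(paste0(
      "Classified ", n, " citation(s): ",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  }
  out
}
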