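rec <- function(pub_types = character(), mesh = c("Humans"), title = "A title",
                abstract = NA_character_, source = "BMJ", year = 2005,
                pmid = "1234567") {
  citation_record(title = title, pmid = pmid, first_author = "Smith J",
                  source = source, year = year, pub_types = pub_types,
                  mesh_terms = mesh, abstract = abstract,
                  product = "P", topic = "T")
}

category_of <- function(...) as.character(classify_citation(rec(...))$category)

test_that("each precedence tier lands in its category", {
  expect_equal(category_of(pub_types = "Practice Guideline"), "guideline")
  expect_equal(category_of(pub_types = "Meta-Analysis"), "systematic_review")
  expect_equal(category_of(pub_types = "Randomized Controlled Trial"),
               "randomized_controlled_trial")
  expect_equal(category_of(pub_types = "Comparative Study",
                           mesh = c("Animals", "Mice")), "animal_study")
  expect_equal(category_of(pub_types = "Journal Article",
                           source = "MMWR Morb Mortal Wkly Rep"), "report")
  expect_equal(category_of(pub_types = "Review"), "review")
  expect_equal(category_of(pub_types = "Letter"), "other")
  expect_equal(category_of(pub_types = "Comparative Study"),
               "primary_research_other")
  expect_equal(category_of(pub_types = "Journal Article"),
               "primary_research_other")  # unclear study design
  expect_equal(category_of(pub_types = "Book"), "other")
})

test_that("an unverifiable citation is always unknown", {
  r <- citation_record(url = "http://dead.example.org/x", product = "P",
                       topic = "T")
  out <- classify_citation(r)
  expect_equal(as.character(out$category), "unknown")
  expect_true(length(out$rationale[[1]]) >= 1)
})

test_that("animal-only detection needs absent Humans and a study type", {
  expect_equal(category_of(pub_types = "Comparative Study",
                           mesh = c("Animals", "Humans")),
               "primary_research_other")
  # no study-design type present: not classifiable as an animal study
  expect_equal(category_of(pub_types = "Journal Article",
                           mesh = c("Animals")), "primary_research_other")
})

test_that("systematic-review promotion needs all three textual criteria", {
  sr_abs <- paste("We searched MEDLINE and EMBASE.",
                  "Inclusion criteria were applied by two reviewers.",
                  "Results were pooled across trials.")
  expect_equal(category_of(pub_types = "Review", abstract = sr_abs),
               "systematic_review")
  expect_true(is_systematic_review(rec(pub_types = "Review",
                                       abstract = sr_abs)))
  # missing the synthesis criterion: stays a narrative review
  partial <- "We searched MEDLINE. Inclusion criteria were applied."
  expect_equal(category_of(pub_types = "Review", abstract = partial),
               "review")
  # no abstract at all: nothing detectable
  expect_false(is_systematic_review(rec(pub_types = "Review")))
  # meta-analysis type short-circuits
  expect_true(is_systematic_review(rec(pub_types = c("Meta-Analysis",
                                                     "Review"))))
  expect_error(is_systematic_review(rec(pub_types = "Letter")),
               "review-family")
})

test_that("letters with study data become primary research", {
  data_abs <- paste("OBJECTIVE: To report outcomes.",
                    "METHODS: n = 45 patients were enrolled.",
                    "RESULTS: Improvement was observed.")
  expect_true(reports_study_data(rec(pub_types = "Letter",
                                     abstract = data_abs)))
  expect_equal(category_of(pub_types = "Letter", abstract = data_abs),
               "primary_research_other")
  # criterion 1 alone (a sample, but unstructured prose) is not enough
  # under the default rules
  prose <- "We treated 45 patients and they improved considerably."
  expect_false(reports_study_data(rec(pub_types = "Comment",
                                      abstract = prose)))
  # ... unless the structure requirement is switched off
  loose <- default_ruleset(study_data_requires_structure = FALSE)
  expect_true(reports_study_data(rec(pub_types = "Comment",
                                     abstract = prose), loose))
  # pure opinion: neither criterion
  expect_false(reports_study_data(rec(pub_types = "Editorial",
                                      abstract = "An opinion, no data.")))
  expect_error(reports_study_data(rec(pub_types = "Review")),
               "letter/comment/editorial")
})

test_that("precedence is sound and invariant to pub_type order", {
  both <- rec(pub_types = c("Meta-Analysis", "Randomized Controlled Trial"))
  expect_equal(as.character(classify_citation(both)$category),
               "systematic_review")
  withr::with_seed(11, {
    for (pts in list(
      c("Practice Guideline", "Review", "Letter"),
      c("Meta-Analysis", "Randomized Controlled Trial", "Journal Article"),
      c("Randomized Controlled Trial", "Comparative Study"),
      c("Letter", "Comment", "Editorial", "Journal Article")
    )) {
      base <- classify_citation(rec(pub_types = pts))
      for (i in 1:5) {
        perm <- classify_citation(rec(pub_types = sample(pts)))
        expect_equal(as.character(perm$category),
                     as.character(base$category))
      }
    }
  })
})

test_that("classification is total and deterministic over a whole corpus", {
  corpora <- generate_corpora(random_corpus_spec(7))
  classified <- classify_all(corpora)
  expect_false(anyNA(classified$category))
  expect_true(all(lengths(classified$rationale) >= 1))
  again <- classify_all(corpora)
  expect_identical(classified$category, again$category)
  expect_identical(classified$rationale, again$rationale)
})

test_that("homogeneous and empty corpora classify trivially", {
  empty <- corpus(product = "P", topic = "T")
  expect_equal(nrow(classify_corpus(empty)), 0)
  recs <- dplyr::bind_rows(lapply(1:10, function(i) {
    citation_record(title = paste("Trial", i), pmid = as.character(i),
                    year = 2000, pub_types = "Randomized Controlled Trial",
                    product = "P", topic = "T")
  }))
  out <- classify_corpus(corpus(recs, "P", "T"))
  expect_true(all(out$category == "randomized_controlled_trial"))
})

test_that("rule sets round-trip through YAML", {
  rules <- default_ruleset()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_ruleset(rules, path)
  back <- read_ruleset(path)
  expect_equal(back$rct_types, rules$rct_types)
  expect_equal(back$section_cue_groups, rules$section_cue_groups)
  # a classification decision is unchanged under the round-tripped rules
  sr_abs <- "We searched MEDLINE. Inclusion criteria. Data were pooled."
  expect_equal(
    as.character(classify_citation(rec(pub_types = "Review",
                                       abstract = sr_abs), back)$category),
    "systematic_review")
})
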