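mini_rec <- function(pmid = NA, title = "T", year = 2000, author = "Smith J",
                     product = "P", topic = "X") {
  citation_record(title = title, pmid = pmid, first_author = author,
                  source = "BMJ", year = year,
                  pub_types = "Journal Article", product = product,
                  topic = topic)
}

test_that("citation keys identify by PMID first, content second", {
  a <- mini_rec(pmid = "999", title = "Completely different")
  b <- mini_rec(pmid = "999", title = "Another thing entirely")
  expect_equal(make_key(a)$kind, "pmid")
  expect_equal(make_key(a)$value, make_key(b)$value)

  c1 <- mini_rec(title = "Beta blockade after infarction.")
  c2 <- mini_rec(title = "Beta blockade after infarction")
  expect_equal(make_key(c1)$kind, "content")
  expect_equal(make_key(c1)$value, make_key(c2)$value)

  d1 <- mini_rec(title = "Same title", year = 1999)
  d2 <- mini_rec(title = "Same title", year = 2000)
  expect_false(make_key(d1)$value == make_key(d2)$value)
})

test_that("a PMID shared across five products forms one cluster of multiplicity five", {
  corpora <- lapply(paste0("Prod", 1:5), function(p) {
    corpus(mini_rec(pmid = "42", product = p), product = p, topic = "X")
  })
  cl <- match_citations(corpora)
  expect_equal(max(cl$cluster), 1)
  d <- overlap_distribution(cl)
  expect_equal(unname(d$multiplicity_counts[["5"]]), 1L)
  expect_equal(d$total_instances, 5L)
  expect_equal(d$total_distinct, 1L)
})

test_that("disjoint PMID sets give all-unique citations", {
  corpora <- lapply(1:3, function(p) {
    recs <- dplyr::bind_rows(lapply(1:4, function(i) {
      mini_rec(pmid = as.character(p * 100 + i), title = paste("t", p, i),
               product = paste0("Prod", p))
    }))
    corpus(recs, paste0("Prod", p), "X")
  })
  d <- overlap_distribution(match_citations(corpora))
  expect_equal(d$multiplicity_counts, c("1" = 12L))
})

test_that("two identical corpora under different products pair every citation", {
  make <- function(p) {
    recs <- dplyr::bind_rows(lapply(1:3, function(i) {
      mini_rec(pmid = as.character(i), title = paste("t", i), product = p)
    }))
    corpus(recs, p, "X")
  }
  d <- overlap_distribution(match_citations(list(make("A"), make("B"))))
  expect_equal(d$multiplicity_counts, c("2" = 3L))
  expect_equal(d$total_distinct, 3L)
  expect_equal(d$total_instances, 6L)
})

test_that("duplicate product labels are a configuration error", {
  a <- corpus(mini_rec(pmid = "1", product = "A"), "A", "X")
  expect_error(match_citations(list(a, a)), "distinct product")
})

test_that("summary emits both percentage conventions with their rounding", {
  # counts chosen so the arithmetic is checkable by hand:
  # distinct = 4, instances = 5; unique 3/4 = 75.0% of distinct;
  # the found-in-all (k = 2) row: 1/5 = 20.00% of instances, two decimals
  a <- corpus(dplyr::bind_rows(
    mini_rec(pmid = "1", product = "A"), mini_rec(pmid = "2", product = "A"),
    mini_rec(pmid = "3", product = "A")), "A", "X")
  b <- corpus(dplyr::bind_rows(
    mini_rec(pmid = "1", product = "B"), mini_rec(pmid = "4", product = "B")),
    "B", "X")
  s <- overlap_summary(overlap_distribution(match_citations(list(a, b))))
  expect_equal(s$count[s$multiplicity == 1], 3L)
  expect_equal(s$percent_of_distinct[s$multiplicity == 1], 75.0)
  expect_equal(s$percent_of_instances[s$multiplicity == 2], 20.00)
  # all-unique corpus summarizes to 100%
  solo <- overlap_summary(overlap_distribution(match_citations(list(a))))
  expect_equal(solo$percent_of_distinct, 100.0)
  # empty distribution gives an empty table
  e <- overlap_distribution(match_citations(list(corpus(product = "A",
                                                        topic = "X"))))
  expect_equal(nrow(overlap_summary(e)), 0)
})

test_that("fuzzy clustering equals the brute-force oracle on a crafted fixture", {
  base <- "Long-term outcomes of early invasive management in acute coronary syndrome"
  variants <- c(base,
                paste0(base, "s"),                       # near-duplicate
                sub("outcomes", "outcome", base))        # near-duplicate
  recs <- dplyr::bind_rows(c(
    lapply(seq_along(variants), function(i) {
      mini_rec(title = variants[[i]], year = 2003, author = "Chen B",
               product = paste0("P", i))
    }),
    lapply(1:17, function(i) {
      mini_rec(pmid = as.character(1000 + i),
               title = paste("Unrelated study of topic", i,
                             paste(rev(letters[(i %% 13) + 1:6]),
                                   collapse = "")),
               year = 1995 + (i %% 10), product = paste0("P", (i %% 3) + 1))
    })
  ))
  corpora <- lapply(split(recs, recs$product), function(df) {
    corpus(df, df$product[[1]], "X")
  })
  cfg <- match_config(fuzzy_enabled = TRUE, title_similarity_threshold = 0.9)
  cl <- match_citations(corpora, cfg)
  got <- canonical_partition(cl$cluster)
  pooled <- dplyr::bind_rows(lapply(corpora, tibble::as_tibble))
  expect_equal(got, oracle_partition(pooled, cfg))
  # the three near-duplicates were merged into one cluster
  d <- overlap_distribution(cl)
  expect_equal(unname(d$multiplicity_counts[["3"]]), 1L)
})

test_that("raising the similarity threshold never creates more overlap", {
  spec <- random_corpus_spec(303, pmid_less_fraction = 0.3)
  corpora <- generate_corpora(spec)
  thresholds <- c(0.7, 0.8, 0.9, 0.95, 1)
  shared <- vapply(thresholds, function(th) {
    d <- overlap_distribution(match_citations(
      corpora, match_config(fuzzy_enabled = TRUE,
                            title_similarity_threshold = th)))
    k <- as.integer(names(d$multiplicity_counts))
    sum(d$multiplicity_counts[k >= 2])
  }, numeric(1))
  expect_true(all(diff(shared) <= 0))
})

test_that("the distribution is invariant to corpus input order", {
  spec <- random_corpus_spec(99, pmid_less_fraction = 0.2)
  corpora <- generate_corpora(spec)
  d1 <- overlap_distribution(match_citations(corpora))
  d2 <- overlap_distribution(match_citations(rev(corpora)))
  expect_equal(d1$multiplicity_counts, d2$multiplicity_counts)
  expect_equal(d1$total_instances, d2$total_instances)
})
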