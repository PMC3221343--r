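test_that("year binning follows the three-year grouping with a pre-2001 floor", {
  expect_equal(as.character(year_bin(1999)), "pre_2001")
  expect_equal(as.character(year_bin(2000)), "pre_2001")
  expect_equal(as.character(year_bin(2001)), "y2001_2003")
  expect_equal(as.character(year_bin(2006)), "y2004_2006")
  expect_equal(as.character(year_bin(2009)), "y2007_2009")
  expect_equal(as.character(year_bin(2012)), "post_2009")
  expect_equal(as.character(year_bin(NA)), "missing")
})

test_that("year bins partition all years with no gaps or overlaps", {
  years <- 1800:2100
  bins <- year_bin(years)
  expect_false(anyNA(bins))
  expect_true(all(table(bins)[c("pre_2001", "y2001_2003", "y2004_2006",
                                "y2007_2009", "post_2009")] > 0))
  # each year lands in exactly one bin, and bin boundaries are sharp
  expect_equal(sum(bins == "pre_2001"), length(1800:2000))
  expect_equal(sum(bins == "y2001_2003"), 3)
  expect_equal(sum(bins == "y2004_2006"), 3)
  expect_equal(sum(bins == "y2007_2009"), 3)
  expect_equal(sum(bins == "post_2009"), length(2010:2100))
  expect_equal(as.character(year_bin(NA_integer_)), "missing")
})

fixture_classified <- function(seed = 5) {
  classify_all(generate_corpora(random_corpus_spec(seed)))
}

test_that("citation distribution percentages recompute from counts", {
  classified <- fixture_classified()
  dist <- distribution_by_product_topic(classified)
  expect_equal(sum(dist$by_product$n), dist$grand_total)
  expect_equal(dist$by_product$percent,
               unname(vapply(dist$by_product$n, function(n) {
                 floor(1000 * n / dist$grand_total + 0.5 + 1e-9) / 10
               }, numeric(1))))
  # single-product input: that product holds 100% of citations
  one <- classified[classified$product == classified$product[[1]], ]
  d1 <- distribution_by_product_topic(one)
  expect_equal(d1$by_product$percent, 100.0)
})

test_that("currency table zero-fills bins and handles missing years", {
  classified <- fixture_classified(6)
  cur <- currency_table(classified)
  n_products <- length(unique(classified$product))
  expect_equal(nrow(cur), n_products * 6)
  # counts conserve the corpus
  expect_equal(sum(cur$n), nrow(classified))
  # missing bin excluded from denominators by default
  miss <- cur[cur$year_bin == "missing", ]
  expect_true(all(is.na(miss$percent)))
  with_miss <- currency_table(classified,
                              exclude_missing_from_denominator = FALSE)
  expect_true(all(!is.na(with_miss$percent)))
  # an all-pre-2001 corpus is 100% pre_2001
  old <- classified
  old$year <- 1995L
  cur_old <- currency_table(old)
  expect_true(all(cur_old$percent[cur_old$year_bin == "pre_2001"] == 100))
})

test_that("publication-type table has nine zero-filled rows per product", {
  classified <- fixture_classified(8)
  tab <- publication_type_table(classified)
  products <- unique(classified$product)
  expect_equal(nrow(tab), (length(products) + 1) * 9)
  # per-product counts sum to the product column total
  sums <- tapply(tab$n, tab$product, sum)
  totals <- tapply(tab$product_total, tab$product, unique)
  expect_equal(as.integer(sums), as.integer(totals))
  # the Total column equals the sum over products
  expect_equal(sum(tab$n[tab$product == "Total"]), nrow(classified))
  # rounding keeps each column's percent sum near 100
  psums <- tapply(tab$percent, tab$product, sum)
  expect_true(all(psums >= 99.0 & psums <= 101.0))
})

test_that("a homogeneous corpus yields a one-hot type table", {
  recs <- dplyr::bind_rows(lapply(1:7, function(i) {
    citation_record(title = paste("Guide", i), pmid = as.character(i),
                    year = 2002, pub_types = "Practice Guideline",
                    product = "P", topic = "T")
  }))
  tab <- publication_type_table(classify_corpus(corpus(recs, "P", "T")))
  p <- tab[tab$product == "P", ]
  expect_equal(p$percent[p$category == "guideline"], 100.0)
  expect_true(all(p$percent[p$category != "guideline"] == 0))
})

test_that("higher-evidence proportion counts systematic reviews plus RCTs", {
  classified <- fixture_classified(9)
  for (p in unique(classified$product)) {
    sub <- classified[classified$product == p, ]
    expected <- floor(1000 * sum(sub$category %in%
      c("systematic_review", "randomized_controlled_trial")) /
      nrow(sub) + 0.5 + 1e-9) / 10
    expect_equal(higher_evidence_proportion(classified, p), expected)
  }
  expect_error(higher_evidence_proportion(classified, "NoSuchProduct"),
               "not present")
  all_sr <- classified
  all_sr$category <- factor("systematic_review",
                            levels = levels(classified$category))
  expect_equal(higher_evidence_proportion(all_sr,
                                          classified$product[[1]]), 100.0)
})

test_that("synopsis audit counts synopsis-source reviews at integer precision", {
  classified <- fixture_classified(10)
  base <- synopsis_audit(classified)
  expect_equal(base$n_reviews, sum(classified$category == "review"))
  # generator did not request synopsis sources here
  expect_equal(base$n_synopsis, 0L)
  if (base$n_reviews > 0) expect_equal(base$percent, 0)
  # flipping every review source to a synopsis journal gives 100%
  flipped <- classified
  flipped$source[flipped$category == "review"] <- "ACP J Club"
  if (base$n_reviews > 0) {
    expect_equal(synopsis_audit(flipped)$percent, 100)
  }
  # no reviews at all: percent undefined
  no_rev <- classified[classified$category != "review", ]
  expect_true(is.na(synopsis_audit(no_rev)$percent))
})
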