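# Shared fixtures and independent oracles, built in code at test time.

# A small nbib file: three records, the last one without a PMID.
nbib_fixture_lines <- function() {
  c(
    "PMID- 11111111",
    "TI  - Inhaled corticosteroids for chronic asthma in adults: a randomized",
    "      trial",
    "AU  - Smith J",
    "SO  - Chest. 2000;118(2):100-8.",
    "DP  - 2000 Aug",
    "PT  - Randomized Controlled Trial",
    "PT  - Journal Article",
    "MH  - Humans",
    "MH  - Asthma",
    "AB  - A randomized comparison of inhaled corticosteroid regimens.",
    "",
    "PMID- 22222222",
    "TI  - Management of hyperlipidemia: an overview",
    "AU  - Doe A",
    "SO  - BMJ. 2004;328:1-9.",
    "DP  - 2004 Jan-Feb",
    "PT  - Review",
    "MH  - Humans",
    "",
    "TI  - Community surveillance of carbon monoxide poisoning",
    "AU  - Lee K",
    "SO  - State health department series",
    "DP  - 2003",
    "PT  - Journal Article",
    ""
  )
}

write_fixture <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Random but valid corpus spec. Per-product margins are constructed so that
# every product holds enough randomized_controlled_trial / pre_2001 slots to
# cover any possible shared-cluster involvement, keeping generation feasible
# for every draw.
random_corpus_spec <- function(seed, n_singletons = NULL, ...) {
  withr::with_seed(seed, {
    n_prod <- sample(2:5, 1)
    products <- paste0("Product", seq_len(n_prod))
    mult <- setNames(integer(n_prod), as.character(seq_len(n_prod)))
    for (k in 2:n_prod) mult[[as.character(k)]] <- sample.int(4, 1) - 1L
    mult[["1"]] <- if (is.null(n_singletons)) sample(8:25, 1) else n_singletons
    # simulate one feasible product assignment to obtain totals
    totals <- integer(n_prod)
    n_multi <- 0L
    for (k in rep(as.integer(names(mult)), mult)) {
      sel <- if (k == n_prod) seq_len(n_prod) else sample.int(n_prod, k)
      totals[sel] <- totals[sel] + 1L
      if (k > 1) n_multi <- n_multi + 1L
    }
    cats <- publication_categories()
    bins <- c("pre_2001", "y2001_2003", "y2004_2006", "y2007_2009",
              "post_2009", "missing")
    cat_counts <- matrix(0L, length(cats), n_prod,
                         dimnames = list(cats, products))
    bin_counts <- matrix(0L, length(bins), n_prod,
                         dimnames = list(bins, products))
    for (p in seq_len(n_prod)) {
      reserve <- min(n_multi, totals[[p]])
      rest <- totals[[p]] - reserve
      cat_alloc <- tabulate(sample.int(9, rest, replace = TRUE,
                                       prob = c(2, 3, 5, 1, 2, 3, 5, 2, 1)),
                            nbins = 9)
      bin_alloc <- tabulate(sample.int(6, rest, replace = TRUE,
                                       prob = c(5, 3, 3, 2, 1, 1)),
                            nbins = 6)
      cat_counts[, p] <- cat_alloc
      bin_counts[, p] <- bin_alloc
      cat_counts["randomized_controlled_trial", p] <-
        cat_counts["randomized_controlled_trial", p] + reserve
      bin_counts["pre_2001", p] <- bin_counts["pre_2001", p] + reserve
    }
    corpus_spec(products, cat_counts, bin_counts, mult[mult > 0],
                seed = sample.int(.Machine$integer.max, 1), ...)
  })
}

# Independent clustering oracle: exhaustive pairwise match predicate plus
# transitive closure through igraph's connected components. Keys and
# normalization are re-derived here from the documented matching rule, not
# taken from the package internals.
oracle_partition <- function(records, config = match_config()) {
  n <- nrow(records)
  if (n == 0) return(list())
  squish <- function(x) {
    x <- tolower(ifelse(is.na(x), "", x))
    trimws(gsub("\\s+", " ", gsub("[^a-z0-9 ]+", " ", x)))
  }
  titles <- squish(records$title)
  surname <- vapply(strsplit(squish(records$first_author), " "),
                    function(p) if (length(p)) p[[1]] else "", character(1))
  keys <- ifelse(
    !is.na(records$pmid), paste0("P", records$pmid),
    ifelse(nzchar(titles),
           paste0("C", titles, "|", ifelse(is.na(records$year), "",
                                           records$year), "|", surname),
           paste0("U", records$local_id)))
  adj <- outer(keys, keys, "==")
  if (config$fuzzy_enabled) {
    d <- utils::adist(titles)
    len <- nchar(titles)
    denom <- outer(len, len, pmax)
    denom[denom == 0] <- 1
    sim <- 1 - d / denom
    ok_title <- sim >= config$title_similarity_threshold &
      outer(nzchar(titles), nzchar(titles), "&")
    yr <- records$year
    ok_year <- if (config$require_year_match) {
      outer(!is.na(yr), !is.na(yr), "&") &
        abs(outer(ifelse(is.na(yr), 0L, yr), ifelse(is.na(yr), 0L, yr),
                  "-")) <= config$year_tolerance
    } else TRUE
    both_pmid_differ <- outer(!is.na(records$pmid), !is.na(records$pmid),
                              "&") & outer(records$pmid, records$pmid,
                                           "!=") %in% TRUE
    dim(both_pmid_differ) <- c(n, n)
    adj <- adj | (ok_title & ok_year & !both_pmid_differ)
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  membership <- igraph::components(g)$membership
  canonical_partition(membership)
}

canonical_partition <- function(membership) {
  parts <- lapply(split(seq_along(membership), membership), sort)
  parts <- unname(parts)
  parts[order(vapply(parts, `[[`, integer(1), 1))]
}

classify_all <- function(corpora, ...) {
  dplyr::bind_rows(lapply(corpora, classify_corpus, ...))
}

intended_of <- function(corpora) {
  unlist(lapply(corpora, attr, "intended_category"), use.names = FALSE)
}
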