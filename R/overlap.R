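#' Matching configuration for cross-product citation overlap
#'
#' Matching is tiered: PMID-exact first (PMIDs are collected precisely to
#' identify citations), content-key exact second (normalized
#' title | year | first-author surname, for PMID-less web/book citations),
#' and an optional fuzzy third tier that merges pairs whose normalized-title
#' similarity reaches `title_similarity_threshold` and whose years agree
#' within `year_tolerance`. Two records carrying *different* PMIDs are never
#' fuzzy-merged.
#'
#' @param fuzzy_enabled Enable the fuzzy tier (default `FALSE`).
#' @param title_similarity_threshold Similarity fraction in \[0, 1\]
#'   (1 minus normalized Levenshtein distance); default 0.90.
#' @param require_year_match Require both years present and within
#'   `year_tolerance` for a fuzzy merge (default `TRUE`).
#' @param year_tolerance Maximum absolute year difference (default 0).
#' @return A list of class `evicite_match_config`.
#' @export
match_config <- function(fuzzy_enabled = FALSE,
                         title_similarity_threshold = 0.90,
                         require_year_match = TRUE,
                         year_tolerance = 0L) {
  if (title_similarity_threshold < 0 || title_similarity_threshold > 1) {
    abort("`title_similarity_threshold` must be in [0, 1].")
  }
  structure(list(
    fuzzy_enabled = isTRUE(fuzzy_enabled),
    title_similarity_threshold = title_similarity_threshold,
    require_year_match = isTRUE(require_year_match),
    year_tolerance = as.integer(year_tolerance)
  ), class = "evicite_match_config")
}

#' Citation key for overlap matching
#'
#' A PMID-bearing record keys on its PMID; otherwise the key is a pure
#' function of the normalized title, year and first-author surname, so the
#' same article cited with or without a trailing period in the title maps to
#' the same key.
#'
#' @param record A one-row record tibble.
#' @return A list of class `evicite_citation_key` with fields `kind`
#'   (`"pmid"` or `"content"`) and `value`.
#' @export
make_key <- function(record) {
  rec <- as_tibble(record)
  stopifnot(nrow(rec) == 1)
  key <- record_keys(rec)
  kind <- if (startsWith(key, "pmid:")) "pmid" else "content"
  structure(list(kind = kind, value = sub("^(pmid|content):", "", key)),
            class = "evicite_citation_key")
}

# Vectorized key strings for a record tibble.
record_keys <- function(records) {
  content <- paste(
    norm_text(records$title),
    ifelse(is.na(records$year), "", as.character(records$year)),
    author_surname(records$first_author),
    sep = "|"
  )
  # records with no usable title fall back to their local identifier so
  # they never spuriously collapse together
  no_title <- is.na(records$title) | !nzchar(norm_text(records$title))
  content[no_title] <- paste0("id|", records$local_id[no_title])
  ifelse(!is.na(records$pmid),
         paste0("pmid:", records$pmid),
         paste0("content:", content))
}

#' Partition records from several corpora into citation clusters
#'
#' Pools the records of all corpora and clusters records judged to be the
#' same citation: records sharing a key (PMID or content key) always
#' cluster; with the fuzzy tier enabled, pairs whose normalized titles are
#' similar enough (and years compatible) are merged as well. Clustering is
#' the transitive closure of pairwise matches.
#'
#' @param corpora A list of `evicite_corpus` objects (or one corpus). The
#'   corpora must carry distinct product labels.
#' @param config A [match_config()].
#' @return A tibble of class `evicite_clusters`: all pooled records plus
#'   `key` and integer `cluster` columns; attribute `n_products` records the
#'   number of products pooled.
#' @export
match_citations <- function(corpora, config = match_config()) {
  if (inherits(corpora, "evicite_corpus")) corpora <- list(corpora)
  if (length(corpora) < 1) abort("Need at least one corpus.")
  products <- vapply(corpora, function(cc) {
    if (nrow(cc) == 0) NA_character_ else cc$product[[1]]
  }, character(1))
  products <- products[!is.na(products)]
  if (anyDuplicated(products)) {
    abort("Corpora must carry distinct product labels.")
  }
  records <- dplyr::bind_rows(lapply(corpora, as_tibble))
  n <- nrow(records)
  if (n == 0) {
    out <- records
    out$key <- character()
    out$cluster <- integer()
    return(structure(out, class = c("evicite_clusters", class(tibble())),
                     n_products = length(products)))
  }
  keys <- record_keys(records)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[[rj]] <<- ri
  }
  # exact tier: same key
  for (grp in split(seq_len(n), keys)) {
    if (length(grp) > 1) for (j in grp[-1]) union_(grp[[1]], j)
  }
  if (config$fuzzy_enabled) {
    for (pr in fuzzy_pairs(records, config)) union_(pr[[1]], pr[[2]])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- records
  out$key <- keys
  out$cluster <- match(roots, unique(roots))
  structure(out, class = c("evicite_clusters", class(tibble())),
            n_products = length(products))
}

# Candidate fuzzy pairs: normalized-title similarity >= threshold, years
# compatible, and never two distinct PMIDs. Year blocking keeps the pair
# set small when years must match.
fuzzy_pairs <- function(records, config) {
  titles <- norm_text(records$title)
  usable <- which(nzchar(titles))
  if (length(usable) < 2) return(list())
  blocks <- if (config$require_year_match) {
    yrs <- records$year[usable]
    ok <- usable[!is.na(yrs)]
    if (length(ok) < 2) return(list())
    yv <- records$year[ok]
    uy <- sort(unique(yv))
    out <- list()
    for (y in uy) {
      members <- ok[yv >= y & yv <= y + config$year_tolerance]
      # anchor on year y so each unordered block is enumerated once
      if (length(members) > 1 && any(records$year[members] == y)) {
        out[[length(out) + 1L]] <- members
      }
    }
    out
  } else {
    list(usable)
  }
  pairs <- list()
  for (blk in blocks) {
    tt <- titles[blk]
    d <- adist(tt)
    len <- nchar(tt)
    denom <- outer(len, len, pmax)
    denom[denom == 0] <- 1
    sim <- 1 - d / denom
    hit <- which(upper.tri(sim) & sim >= config$title_similarity_threshold,
                 arr.ind = TRUE)
    if (nrow(hit) == 0) next
    for (hh in seq_len(nrow(hit))) {
      i <- blk[[hit[hh, 1]]]; j <- blk[[hit[hh, 2]]]
      if (config$require_year_match &&
          abs(records$year[[i]] - records$year[[j]]) > config$year_tolerance) {
        next
      }
      pi <- records$pmid[[i]]; pj <- records$pmid[[j]]
      if (!is.na(pi) && !is.na(pj) && pi != pj) next
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  pairs
}

#' Overlap-multiplicity distribution
#'
#' The multiplicity of a cluster is the number of *distinct* products whose
#' corpora contain it (a citation listed twice within one product counts
#' once toward that product's presence, but each listing remains an
#' instance). The distribution tallies distinct citations by multiplicity
#' and satisfies the conservation identity
#' `sum(k * n_k) == total_instances`.
#'
#' @param clusters An `evicite_clusters` tibble from [match_citations()].
#' @param n_products Number of products pooled; defaults to the clusters'
#'   attribute.
#' @return A list of class `evicite_overlap`: `multiplicity_counts` (named
#'   integer vector), `n_products`, `total_instances`, `total_distinct`.
#' @export
overlap_distribution <- function(clusters,
                                 n_products = attr(clusters, "n_products")) {
  cl <- as_tibble(clusters)
  if (nrow(cl) == 0) {
    out <- list(multiplicity_counts = setNames(integer(), character()),
                n_products = n_products %||% 0L,
                total_instances = 0L, total_distinct = 0L)
    return(structure(out, class = "evicite_overlap"))
  }
  mult <- vapply(split(cl$product, cl$cluster),
                 function(p) length(unique(p)), integer(1))
  tab <- table(mult)
  counts <- setNames(as.integer(tab), names(tab))
  out <- list(
    multiplicity_counts = counts,
    n_products = as.integer(n_products),
    total_instances = nrow(cl),
    total_distinct = length(mult)
  )
  ks <- as.integer(names(counts))
  stopifnot(all(ks >= 1), all(ks <= out$n_products),
            sum(counts) == out$total_distinct)
  structure(out, class = "evicite_overlap")
}

#' @export
print.evicite_overlap <- function(x, ...) {
  cat(sprintf(
    "<evicite_overlap> %d instance(s), %d distinct citation(s), %d product(s)\n",
    x$total_instances, x$total_distinct, x$n_products))
  print(x$multiplicity_counts)
  invisible(x)
}

#' Summary table of an overlap distribution
#'
#' Two percentage conventions coexist in overlap reporting and both are
#' emitted, explicitly labeled: `percent_of_distinct` uses the number of
#' distinct citations as denominator (the convention under which unique
#' citations are, e.g., 90.9% of 2099), and `percent_of_instances` uses the
#' total citation pool (under which a found-in-all-products count of 2 out
#' of 2330 is 0.09%). Percentages are half-up rounded to one decimal, except
#' the found-in-all-products instance percentage, reported at two decimals.
#'
#' @param dist An `evicite_overlap` from [overlap_distribution()].
#' @return A tibble with columns `multiplicity`, `count`,
#'   `percent_of_distinct`, `percent_of_instances`, ordered by decreasing
#'   multiplicity; empty when the distribution is empty.
#' @export
overlap_summary <- function(dist) {
  stopifnot(inherits(dist, "evicite_overlap"))
  counts <- dist$multiplicity_counts
  if (length(counts) == 0) {
    return(tibble(multiplicity = integer(), count = integer(),
                  percent_of_distinct = double(),
                  percent_of_instances = double()))
  }
  k <- as.integer(names(counts))
  ord <- order(k, decreasing = TRUE)
  k <- k[ord]; n_k <- as.integer(counts[ord])
  pct_distinct <- round_half_up(100 * n_k / dist$total_distinct, 1)
  digits <- ifelse(k == dist$n_products, 2, 1)
  pct_instances <- round_half_up(100 * n_k / dist$total_instances, digits)
  tibble(
    multiplicity = k, count = n_k,
    percent_of_distinct = pct_distinct,
    percent_of_instances = pct_instances
  )
}
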