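#' Currency bin for a publication year
#'
#' Clinicians searching for evidence relevant to current practice rarely
#' request literature more than a decade old, so years are grouped in
#' three-year bins with everything up to 2000 collapsed into one `pre_2001`
#' category. Years after the last three-year bin map to `post_2009`, and a
#' missing year maps to `missing`. The six bins partition all possible
#' years: every year maps to exactly one bin.
#'
#' @param year Integer vector of years; `NA` for missing.
#' @return Factor with levels `pre_2001`, `y2001_2003`, `y2004_2006`,
#'   `y2007_2009`, `post_2009`, `missing`.
#' @export
#' @examples
#' year_bin(c(1999, 2001, 2005, 2008, 2012, NA))
year_bin <- function(year) {
  year <- suppressWarnings(as.integer(year))
  bins <- ifelse(is.na(year), "missing",
          ifelse(year <= 2000, "pre_2001",
          ifelse(year <= 2003, "y2001_2003",
          ifelse(year <= 2006, "y2004_2006",
          ifelse(year <= 2009, "y2007_2009", "post_2009")))))
  factor(bins, levels = year_bin_levels())
}

year_bin_levels <- function() {
  c("pre_2001", "y2001_2003", "y2004_2006", "y2007_2009", "post_2009",
    "missing")
}

check_classified <- function(classified) {
  classified <- as_tibble(classified)
  needed <- c("product", "topic", "year", "category")
  missing <- setdiff(needed, names(classified))
  if (length(missing)) {
    abort(paste0("`classified` is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(classified) == 0) abort("`classified` must be non-empty.")
  classified
}

#' Distribution of citations by product and topic
#'
#' The depth-of-coverage indicator: how many citations each product cites
#' in total and per topic, with each product's share of the grand total as
#' a half-up one-decimal percentage.
#'
#' @param classified A classified-citation tibble from [classify_corpus()]
#'   (rows from several corpora may be bound together).
#' @return A list of class `evicite_distribution`: `by_product_topic`
#'   (product, topic, n), `by_product` (product, n, percent), and
#'   `grand_total`.
#' @export
distribution_by_product_topic <- function(classified) {
  classified <- check_classified(classified)
  by_pt <- classified |>
    dplyr::count(.data$product, .data$topic, name = "n") |>
    dplyr::arrange(.data$product, .data$topic)
  grand <- nrow(classified)
  by_p <- classified |>
    dplyr::count(.data$product, name = "n") |>
    dplyr::mutate(percent = round_half_up(100 * .data$n / grand, 1)) |>
    dplyr::arrange(.data$product)
  structure(list(by_product_topic = by_pt, by_product = by_p,
                 grand_total = grand),
            class = "evicite_distribution")
}

#' @export
print.evicite_distribution <- function(x, ...) {
  cat(sprintf("<evicite_distribution> %d citation(s)\n", x$grand_total))
  print(x$by_product)
  invisible(x)
}

#' Currency table: citations per product by year bin
#'
#' Counts and percentages of citations per product in each currency bin
#' ([year_bin()]). Citations without a usable year are reported in the
#' `missing` bin; by default they are excluded from the percentage
#' denominators (they are "missing from analysis") but stay visible as
#' counts.
#'
#' @inheritParams distribution_by_product_topic
#' @param exclude_missing_from_denominator Exclude `missing`-bin citations
#'   from each product's percentage denominator (default `TRUE`).
#' @return A tibble with columns `product`, `year_bin`, `n`, `percent`,
#'   `denominator`; every combination of product and bin is present
#'   (zero-filled).
#' @export
currency_table <- function(classified,
                           exclude_missing_from_denominator = TRUE) {
  classified <- check_classified(classified)
  tab <- classified |>
    dplyr::mutate(year_bin = year_bin(.data$year)) |>
    dplyr::count(.data$product, .data$year_bin, name = "n") |>
    tidyr::complete(.data$product,
                    year_bin = factor(year_bin_levels(),
                                      levels = year_bin_levels()),
                    fill = list(n = 0L))
  denom <- tab |>
    dplyr::filter(!(exclude_missing_from_denominator &
                      .data$year_bin == "missing")) |>
    dplyr::group_by(.data$product) |>
    dplyr::summarise(denominator = sum(.data$n), .groups = "drop")
  tab <- tab |>
    dplyr::left_join(denom, by = "product") |>
    dplyr::mutate(percent = dplyr::if_else(
      exclude_missing_from_denominator & .data$year_bin == "missing",
      NA_real_,
      round_half_up(100 * .data$n / pmax(.data$denominator, 1L), 1)
    )) |>
    dplyr::select("product", "year_bin", "n", "percent", "denominator") |>
    dplyr::arrange(.data$product, .data$year_bin)
  tab
}

#' Publication-type table: categories by product
#'
#' The type-of-evidence indicator: counts and column percentages of the
#' nine publication-type categories for each product, plus a combined
#' `Total` column. Cell percentages are half-up rounded to one decimal, so
#' column percentage sums may land anywhere in \[99.0, 101.0\] ("may not
#' total 100% due to rounding"). Percentages are always recomputed from the
#' counts; they are never stored independently.
#'
#' @inheritParams distribution_by_product_topic
#' @return A tibble with columns `product` (including the pseudo-product
#'   `"Total"`), `category`, `n`, `percent`, `product_total`. All nine
#'   categories are present for every product (zero-filled).
#' @export
publication_type_table <- function(classified) {
  classified <- check_classified(classified)
  cats <- factor(publication_categories(),
                 levels = publication_categories())
  count_block <- function(df, label) {
    df |>
      dplyr::count(category = factor(.data$category,
                                     levels = publication_categories()),
                   name = "n") |>
      tidyr::complete(category = cats, fill = list(n = 0L)) |>
      dplyr::mutate(product = label, .before = 1)
  }
  per_product <- classified |>
    dplyr::group_by(.data$product) |>
    dplyr::group_map(~ count_block(.x, .y$product[[1]])) |>
    dplyr::bind_rows()
  total <- count_block(classified, "Total")
  dplyr::bind_rows(per_product, total) |>
    dplyr::group_by(.data$product) |>
    dplyr::mutate(product_total = sum(.data$n),
                  percent = round_half_up(
                    100 * .data$n / pmax(.data$product_total, 1L), 1)) |>
    dplyr::ungroup() |>
    dplyr::select("product", "category", "n", "percent", "product_total")
}

#' Proportion of higher-level-evidence citations for a product
#'
#' The share of a product's citations carrying the publication types
#' nearest the top of the evidence hierarchy: systematic reviews plus
#' randomized controlled trials, as a half-up one-decimal percentage of the
#' product's total.
#'
#' @inheritParams distribution_by_product_topic
#' @param product Product label; must be present in `classified`.
#' @return A single numeric percentage.
#' @export
higher_evidence_proportion <- function(classified, product) {
  classified <- check_classified(classified)
  sub <- classified[classified$product == product, ]
  if (nrow(sub) == 0) {
    abort(sprintf("Product '%s' not present in the classified input.",
                  product))
  }
  hi <- sum(sub$category %in% c("systematic_review",
                                "randomized_controlled_trial"))
  round_half_up(100 * hi / nrow(sub), 1)
}

#' Audit of synopsis sources among review-category citations
#'
#' Synopses (brief structured summaries such as ACP Journal Club or FPIN
#' items) are indexed in MEDLINE under the review publication type and so
#' land in the `review` category; this audit counts how many
#' review-category citations come from synopsis sources, with the share
#' reported at integer precision.
#'
#' @inheritParams distribution_by_product_topic
#' @param rules An `evicite_ruleset` supplying `synopsis_source_patterns`.
#' @return A list: `n_synopsis`, `n_reviews`, `percent` (integer-precision
#'   percentage, `NA` when there are no reviews), and `by_product` counts of
#'   synopsis citations.
#' @export
synopsis_audit <- function(classified, rules = default_ruleset()) {
  classified <- check_classified(classified)
  reviews <- classified[classified$category == "review", ]
  if (nrow(reviews) == 0) {
    return(list(n_synopsis = 0L, n_reviews = 0L, percent = NA_real_,
                by_product = tibble(product = character(), n = integer())))
  }
  is_syn <- vapply(reviews$source, source_matches, logical(1),
                   patterns = rules$synopsis_source_patterns)
  by_product <- reviews[is_syn, ] |>
    dplyr::count(.data$product, name = "n")
  list(
    n_synopsis = sum(is_syn),
    n_reviews = nrow(reviews),
    percent = round_half_up(100 * sum(is_syn) / nrow(reviews), 0),
    by_product = by_product
  )
}
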