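#' Construct a citation record
#'
#' A citation record is one bibliographic reference retrieved from a
#' monograph's reference list, together with the MEDLINE indexing metadata
#' used downstream (publication types, MeSH terms) and its provenance (the
#' point-of-care product and disease topic whose monograph cited it).
#'
#' The `verified` flag mirrors the practice of confirming citation details:
#' a record is considered verified when it carries a PMID, or when both a
#' title and a publication year could be established. Unverified records are
#' classified `unknown` downstream.
#'
#' @param title Citation title (free text) or `NA`.
#' @param pmid PubMed identifier as a string of 1--8 decimal digits, or `NA`.
#' @param first_author First author as "Surname AB", or `NA`.
#' @param source Journal, book, or publisher/URL source text.
#' @param year Integer publication year, or `NA`.
#' @param pub_types Character vector of MEDLINE publication-type strings.
#' @param mesh_terms Character vector of MeSH descriptor strings.
#' @param abstract Abstract text or `NA`.
#' @param url URL for web citations, or `NA`.
#' @param product Product label (non-empty).
#' @param topic Topic label (non-empty).
#' @param local_id Optional identifier; when `NA` it is derived with
#'   [assign_local_id()].
#'
#' @return A one-row tibble with the citation-record columns.
#' @export
#' @examples
#' citation_record(
#'   title = "Inhaled corticosteroids for chronic asthma",
#'   pmid = "10796658", year = 2000,
#'   pub_types = "Randomized Controlled Trial",
#'   product = "DynaMed", topic = "asthma"
#' )
citation_record <- function(title = NA_character_, pmid = NA_character_,
                            first_author = NA_character_,
                            source = NA_character_, year = NA_integer_,
                            pub_types = character(), mesh_terms = character(),
                            abstract = NA_character_, url = NA_character_,
                            product = "unspecified", topic = "unspecified",
                            local_id = NA_character_) {
  if (!is.na(pmid) && !grepl("^[0-9]{1,8}$", pmid)) {
    abort("`pmid` must be a string of 1-8 decimal digits.")
  }
  year <- suppressWarnings(as.integer(year))
  if (!is.na(year) && (year < 1800 || year > current_year() + 1)) {
    abort(sprintf("`year` (%d) outside the admissible range [1800, %d].",
                  year, current_year() + 1))
  }
  if (!nzchar(product) || !nzchar(topic)) {
    abort("`product` and `topic` must be non-empty labels.")
  }
  rec <- tibble(
    local_id = as.character(local_id),
    pmid = as.character(pmid),
    title = as.character(title),
    first_author = as.character(first_author),
    source = as.character(source),
    year = year,
    pub_types = list(as.character(pub_types)),
    mesh_terms = list(as.character(mesh_terms)),
    abstract = as.character(abstract),
    url = as.character(url),
    product = product,
    topic = topic,
    verified = NA
  )
  rec$verified <- record_verified(rec)
  if (is.na(rec$local_id)) rec$local_id <- assign_local_id(rec)
  rec
}

current_year <- function() as.integer(format(Sys.Date(), "%Y"))

# Verification is a pure function of content so that corpora round-trip.
record_verified <- function(records) {
  has_pmid <- !is.na(records$pmid)
  has_title <- !is.na(records$title) & nzchar(trimws(records$title))
  has_year <- !is.na(records$year)
  has_pmid | (has_title & has_year)
}

record_columns <- function() {
  c("local_id", "pmid", "title", "first_author", "source", "year",
    "pub_types", "mesh_terms", "abstract", "url", "product", "topic",
    "verified")
}

empty_records <- function() {
  tibble(
    local_id = character(), pmid = character(), title = character(),
    first_author = character(), source = character(), year = integer(),
    pub_types = list(), mesh_terms = list(), abstract = character(),
    url = character(), product = character(), topic = character(),
    verified = logical()
  )
}

#' Assemble a citation corpus
#'
#' A corpus is the ordered set of citation records retrieved from one
#' product's monograph(s) on one topic. All records carry the corpus
#' product/topic labels and `local_id` is unique within the corpus
#' (readers and the generator disambiguate content-identical duplicates
#' with an ordinal suffix; the duplicates themselves are kept, since
#' deduplication is the overlap analysis's job).
#'
#' @param records A tibble of citation records (rows from
#'   [citation_record()], or the result of binding several).
#' @param product,topic Corpus labels; when `NULL`, taken from the records
#'   (which must then be homogeneous).
#' @return A tibble of class `evicite_corpus`.
#' @export
corpus <- function(records = empty_records(), product = NULL, topic = NULL) {
  records <- as_tibble(records)
  proto <- empty_records()
  n <- nrow(records)
  for (col in setdiff(record_columns(), names(records))) {
    records[[col]] <- if (is.list(proto[[col]])) {
      rep(list(character()), n)
    } else {
      rep(proto[[col]][NA_integer_][1], n)
    }
  }
  records <- records[, record_columns()]
  if (!is.null(product)) records$product <- if (n) rep(product, n) else character()
  if (!is.null(topic)) records$topic <- if (n) rep(topic, n) else character()
  if (n) {
    na_ver <- is.na(records$verified)
    if (any(na_ver)) records$verified[na_ver] <- record_verified(records)[na_ver]
    na_id <- is.na(records$local_id)
    if (any(na_id)) {
      records$local_id[na_id] <- vapply(
        which(na_id), function(i) assign_local_id(records[i, ], i),
        character(1))
    }
    records$local_id <- make_unique_local_ids(records$local_id)
  }
  validate_corpus(records)
  structure(records, class = c("evicite_corpus", class(tibble())))
}

validate_corpus <- function(records) {
  if (nrow(records) == 0) return(invisible(records))
  if (length(unique(records$product)) != 1 ||
      length(unique(records$topic)) != 1) {
    abort("All records in a corpus must share one product and one topic.")
  }
  if (anyNA(records$local_id) || any(!nzchar(records$local_id))) {
    abort("Every record must carry a non-empty `local_id`.")
  }
  if (anyDuplicated(records$local_id)) {
    abort("`local_id` must be unique within a corpus.")
  }
  bad_pmid <- !is.na(records$pmid) & !grepl("^[0-9]{1,8}$", records$pmid)
  if (any(bad_pmid)) abort("PMIDs must be strings of 1-8 decimal digits.")
  invisible(records)
}

#' @export
print.evicite_corpus <- function(x, ...) {
  cat(sprintf(
    "<evicite_corpus> %d citation(s) | product: %s | topic: %s\n",
    nrow(x),
    if (nrow(x)) x$product[[1]] else "?",
    if (nrow(x)) x$topic[[1]] else "?"
  ))
  NextMethod()
}

#' Assign a stable local identifier to a citation record
#'
#' Citations lacking a PMID receive a deterministic, content-addressed
#' identifier so that the same bibliographic item always maps to the same
#' identifier ("structured guide" semantics): a digest of the normalized
#' (lowercased, punctuation-stripped, whitespace-collapsed) title, the year,
#' the first author's surname and the normalized source. Records carrying a
#' PMID return `"PMID:<pmid>"`. Records with neither PMID nor title but a
#' URL are identified by the normalized URL; records with none of these fall
#' back to source + product + ordinal and are flagged unverified upstream.
#'
#' @param record A one-row record tibble (or list with the same fields).
#' @param ordinal Position of the record in its corpus, used only in the
#'   degenerate no-pmid/no-title/no-url fallback.
#' @return A single identifier string. Pure function of its inputs.
#' @export
#' @examples
#' r <- citation_record(pmid = "12345", title = "X", year = 2001,
#'                      product = "P", topic = "T")
#' assign_local_id(r)  # "PMID:12345"
assign_local_id <- function(record, ordinal = 1L) {
  pmid <- chr_or_na(record$pmid)
  if (!is.na(pmid)) return(paste0("PMID:", pmid))
  title <- chr_or_na(record$title)
  url <- chr_or_na(record$url)
  if (!is.na(title) && nzchar(trimws(title))) {
    key <- paste(
      norm_text(title),
      chr_or_na(record$year),
      author_surname(chr_or_na(record$first_author)),
      norm_text(chr_or_na(record$source)),
      sep = "|"
    )
    return(paste0("LOC:", content_digest(key)))
  }
  if (!is.na(url) && nzchar(norm_url(url))) {
    return(paste0("URL:", content_digest(norm_url(url))))
  }
  paste0("ANON:", content_digest(paste(
    norm_text(chr_or_na(record$source)),
    chr_or_na(record$product), ordinal, sep = "|"
  )))
}

# Deterministic within-corpus disambiguation of duplicate local_ids.
make_unique_local_ids <- function(ids) {
  if (!anyDuplicated(ids)) return(ids)
  stats::ave(ids, ids, FUN = function(g) {
    if (length(g) == 1) g else paste0(g, c("", paste0("#", seq_along(g)[-1])))
  })
}

# ---------------------------------------------------------------------------
# MEDLINE/nbib flat format

nbib_tag_re <- "^([A-Z][A-Z0-9]{0,3})\\s*- ?(.*)$"

# Fold continuation lines (leading whitespace) into (tag, value) pairs.
parse_tagged_block <- function(lines, tag_re) {
  tags <- character(0); vals <- character(0)
  for (line in lines) {
    m <- regmatches(line, regexec(tag_re, line))[[1]]
    if (length(m) == 3) {
      tags <- c(tags, m[[2]]); vals <- c(vals, m[[3]])
    } else if (grepl("^\\s+\\S", line) && length(vals)) {
      vals[length(vals)] <- paste(vals[length(vals)], trimws(line))
    }
    # other lines are noise and ignored
  }
  list(tags = tags, vals = vals)
}

nbib_block_to_record <- function(lines, product, topic, ordinal) {
  parsed <- parse_tagged_block(lines, nbib_tag_re)
  tags <- parsed$tags; vals <- parsed$vals
  if (length(tags) == 0) return(NULL)
  grab <- function(tag) {
    i <- which(tags == tag)
    if (length(i)) vals[i] else character(0)
  }
  pmid <- chr_or_na(grab("PMID"))
  if (!is.na(pmid) && !grepl("^[0-9]{1,8}$", pmid)) pmid <- NA_character_
  dp <- chr_or_na(grab("DP"))
  citation_record(
    title = chr_or_na(grab("TI")),
    pmid = pmid,
    first_author = chr_or_na(grab("AU")),
    source = chr_or_na(grab("SO")),
    year = if (is.na(dp)) NA_integer_ else first_year(dp),
    pub_types = grab("PT"),
    mesh_terms = grab("MH"),
    abstract = chr_or_na(grab("AB")),
    url = chr_or_na(grab("UR")),
    product = product, topic = topic
  )
}

read_text_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(raw)
  if (!validUTF8(txt)) {
    warn(sprintf("%s is not valid UTF-8; decoding with replacement.", path))
    txt <- iconv(txt, from = "UTF-8", to = "UTF-8", sub = "�")
  }
  Encoding(txt) <- "UTF-8"
  strsplit(txt, "\r?\n")[[1]]
}

#' Read a MEDLINE/nbib citation file
#'
#' Parses the MEDLINE flat ("nbib") format: records are blank-line-separated
#' blocks of `TAG - value` lines with whitespace-indented continuations.
#' Recognized tags: `PMID`, `TI`, `AU` (first occurrence), `SO`, `DP`
#' (publication date; the first four-digit year is taken), `PT` (repeated),
#' `MH` (repeated), `AB`, and the dialect tag `UR` for URLs. Publication
#' types are carried over verbatim -- the reader never invents them.
#' Records without a PMID get a content-addressed identifier via
#' [assign_local_id()]. Malformed blocks (no recognizable tags) are skipped
#' with a warning.
#'
#' @param path Path to an nbib text file.
#' @param product,topic Provenance labels attached to every record.
#' @return An `evicite_corpus`.
#' @export
read_nbib <- function(path, product, topic) {
  lines <- read_text_lines(path)
  blocks <- split_blocks(lines)
  recs <- vector("list", length(blocks))
  skipped <- 0L
  for (i in seq_along(blocks)) {
    rec <- tryCatch(
      nbib_block_to_record(blocks[[i]], product, topic, i),
      error = function(e) {
        warn(sprintf("Skipping malformed nbib block %d: %s", i,
                     conditionMessage(e)))
        NULL
      }
    )
    if (is.null(rec)) skipped <- skipped + 1L
    recs[[i]] <- rec
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  records <- if (length(recs)) dplyr::bind_rows(recs) else empty_records()
  if (nrow(records)) {
    records$local_id <- make_unique_local_ids(records$local_id)
  }
  out <- corpus(records, product = product, topic = topic)
  attr(out, "skipped") <- skipped
  out
}

split_blocks <- function(lines) {
  blank <- !nzchar(trimws(lines))
  grp <- cumsum(blank & !c(TRUE, blank[-length(blank)]))
  grp[blank] <- NA
  blocks <- split(lines[!blank], grp[!blank])
  unname(blocks)
}

# ---------------------------------------------------------------------------
# RIS format

#' RIS reference-type mapping table
#'
#' RIS has no MEDLINE publication-type vocabulary, so `TY` tags are mapped
#' to MEDLINE-style publication-type strings through this documented,
#' versioned constant. Unmapped `TY` values fall back to "Journal Article".
#'
#' @return Named character vector: names are RIS `TY` codes, values the
#'   publication-type string assigned.
#' @export
#' @examples
#' ris_type_map()[["JOUR"]]
ris_type_map <- function() {
  c(
    JOUR = "Journal Article",
    ABST = "Abstract",
    BOOK = "Book",
    CHAP = "Book",
    CONF = "Congress",
    CPAPER = "Congress",
    EDBOOK = "Book",
    ELEC = "Electronic Resource",
    GEN = "Journal Article",
    NEWS = "News",
    RPRT = "Technical Report",
    THES = "Thesis"
  )
}

ris_tag_re <- "^([A-Z][A-Z0-9])  - ?(.*)$"

ris_block_to_record <- function(lines, product, topic, ordinal) {
  parsed <- parse_tagged_block(lines, ris_tag_re)
  tags <- parsed$tags; vals <- parsed$vals
  if (length(tags) == 0) return(NULL)
  grab <- function(...) {
    i <- which(tags %in% c(...))
    if (length(i)) vals[i] else character(0)
  }
  ty <- chr_or_na(grab("TY"))
  map <- ris_type_map()
  pub_types <- if (is.na(ty)) character(0) else
    unname(map[ty]) %||% NA
  if (length(pub_types) && is.na(pub_types)) pub_types <- "Journal Article"
  an <- chr_or_na(grab("AN", "ID"))
  pmid <- if (!is.na(an) && grepl("^[0-9]{1,8}$", an)) an else NA_character_
  yr_raw <- chr_or_na(grab("PY", "Y1"))
  citation_record(
    title = chr_or_na(grab("TI", "T1")),
    pmid = pmid,
    first_author = chr_or_na(grab("AU", "A1")),
    source = chr_or_na(grab("JO", "JF", "T2", "JA", "BT", "PB")),
    year = if (is.na(yr_raw)) NA_integer_ else first_year(yr_raw),
    pub_types = pub_types,
    mesh_terms = grab("KW"),
    abstract = chr_or_na(grab("AB", "N2")),
    url = chr_or_na(grab("UR")),
    product = product, topic = topic
  )
}

#' Read a RIS citation file
#'
#' Records end at the `ER  -` tag. `TY` codes are mapped to publication-type
#' strings via [ris_type_map()]; `KW` keywords are carried as MeSH-slot
#' terms; an all-digit `AN`/`ID` accession of at most 8 digits is treated as
#' a PMID. Duplicated records are kept (deduplication belongs to the overlap
#' analysis).
#'
#' @inheritParams read_nbib
#' @return An `evicite_corpus`.
#' @export
read_ris <- function(path, product, topic) {
  lines <- read_text_lines(path)
  ends <- grepl("^ER  -", lines)
  grp <- cumsum(c(0, head(as.integer(ends), -1)))
  keep <- nzchar(trimws(lines)) & !ends
  blocks <- split(lines[keep], grp[keep])
  recs <- vector("list", length(blocks))
  skipped <- 0L
  for (i in seq_along(blocks)) {
    rec <- tryCatch(
      ris_block_to_record(blocks[[i]], product, topic, i),
      error = function(e) {
        warn(sprintf("Skipping malformed RIS block %d: %s", i,
                     conditionMessage(e)))
        NULL
      }
    )
    if (is.null(rec)) skipped <- skipped + 1L
    recs[[i]] <- rec
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  records <- if (length(recs)) dplyr::bind_rows(recs) else empty_records()
  if (nrow(records)) {
    records$local_id <- make_unique_local_ids(records$local_id)
  }
  out <- corpus(records, product = product, topic = topic)
  attr(out, "skipped") <- skipped
  out
}

# ---------------------------------------------------------------------------
# Writing

#' Write a corpus to an nbib-dialect file
#'
#' Serializes a corpus so that `read_nbib(write_corpus(c), product, topic)`
#' reproduces every field: standard MEDLINE tags plus the dialect tag `UR`
#' for URLs. `local_id` and `verified` are not written; both are pure
#' functions of record content and are re-derived on read. Output is
#' byte-stable for a given corpus.
#'
#' @param corpus_tbl An `evicite_corpus` (or compatible record tibble).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus_tbl, path) {
  validate_corpus(corpus_tbl)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) abort(sprintf(
                    "Cannot open '%s' for writing: %s", path,
                    conditionMessage(e))))
  on.exit(close(con))
  emit <- function(tag, value) {
    value <- value[!is.na(value)]
    for (v in value) {
      writeLines(sprintf("%-4s- %s", tag, v), con, useBytes = TRUE)
    }
  }
  for (i in seq_len(nrow(corpus_tbl))) {
    r <- corpus_tbl[i, ]
    emit("PMID", r$pmid)
    emit("TI", r$title)
    emit("AU", r$first_author)
    emit("SO", r$source)
    emit("DP", if (is.na(r$year)) NA_character_ else as.character(r$year))
    emit("PT", r$pub_types[[1]])
    emit("MH", r$mesh_terms[[1]])
    emit("AB", r$abstract)
    emit("UR", r$url)
    writeLines("", con, useBytes = TRUE)
  }
  invisible(path)
}
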