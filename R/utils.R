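# Internal helpers shared across modules.

# Half-up rounding (round(2.5) -> 3, not banker's). Table percents in the
# indicator outputs use this convention; the small epsilon guards against
# binary representation of values like 0.15 * 100.
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Canonical text normalization for content keys and fuzzy comparison:
# lowercase, strip punctuation, collapse whitespace.
norm_text <- function(x) {
  x <- tolower(ifelse(is.na(x), "", x))
  x <- gsub("[^a-z0-9 ]+", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Surname of a "Surname AB"-style author string (first token after
# normalization).
author_surname <- function(x) {
  first <- vapply(strsplit(norm_text(x), " ", fixed = TRUE),
                  function(p) if (length(p)) p[[1]] else "", character(1))
  first
}

# Normalize a URL for identification: drop scheme, trailing slash, lowercase.
norm_url <- function(x) {
  x <- tolower(ifelse(is.na(x), "", x))
  x <- sub("^https?://", "", x)
  x <- sub("^www\\.", "", x)
  sub("/+$", "", trimws(x))
}

# Small deterministic polynomial hash over UTF-8 code points, emitted as a
# fixed-width hex token. Products stay far below 2^53 so the arithmetic is
# exact in doubles on every platform.
content_digest <- function(s) {
  vapply(s, function(one) {
    h <- 0
    for (cp in utf8ToInt(ifelse(is.na(one), "", one))) {
      h <- (h * 131 + cp) %% 268435399
    }
    sprintf("%07x", h)
  }, character(1), USE.NAMES = FALSE)
}

first_year <- function(x) {
  m <- regmatches(x, regexpr("[12][0-9]{3}", x))
  if (length(m) == 0 || is.na(x)) NA_integer_ else as.integer(m[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

chr_or_na <- function(x) {
  if (is.null(x) || length(x) == 0 || all(is.na(x)) || identical(x, "")) {
    NA_character_
  } else {
    as.character(x[[1]])
  }
}
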