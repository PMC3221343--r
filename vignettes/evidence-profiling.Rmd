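---
title: "Profiling the evidence behind point-of-care references"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the evidence behind point-of-care references}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(evicite)
```

## The problem and the model

Point-of-care (POC) products are electronic bedside references that
summarize medical evidence in per-disease monographs. Whether their
content is "evidence based" can be probed without reading the monographs:
the reference list behind each monograph is itself data. `evicite`
operationalizes a bibliometric design with four indicators over pooled
citation corpora, one corpus per (product, topic):

* **distribution** — citation counts per product and topic;
* **type of evidence** — a nine-category publication-type classification
  guided by the evidence hierarchy, using the citation's MEDLINE indexing
  (publication types and MeSH) as the primary signal;
* **currency** — publication years in three-year bins with everything up
  to 2000 collapsed into `pre_2001` (clinicians rarely ask for literature
  more than a decade old, so finer resolution there adds nothing);
* **overlap** — the number of distinct products citing each distinct
  citation, summarized as a multiplicity distribution.

The unit of analysis is the *citation instance* (one entry in one
product's reference list). Matching instances across products yields
*distinct citations*; the two denominators coexist deliberately, and every
table emits explicitly labeled percentages for whichever denominators
apply.

## The classification protocol and its assumptions

Classification is a total, deterministic, first-match-wins precedence over
a citation's MEDLINE publication types:

1. unverified citation → `unknown`
2. guideline / practice-guideline / consensus types → `guideline`
3. meta-analysis type, or review-family type meeting the
   systematic-review criteria → `systematic_review`
4. randomized-controlled-trial type → `randomized_controlled_trial`
5. MeSH `Animals` without `Humans`, with a study-design type →
   `animal_study`
6. report types or report source patterns → `report`
7. remaining review types → `review`
8. letter/comment/editorial → `primary_research_other` if it reports
   study data, else `other`
9. remaining study designs, or a bare journal article (unclear design) →
   `primary_research_other`
10. books, abstracts, congresses, and anything left → `other`

Three decisions here were genuinely open and deserve their rationale:

* **Systematic-review promotion.** "Systematic review" is not a MEDLINE
  publication type for the study era, so review-typed citations must be
  promoted by evidence of preplanned methods. Full-text appraisal is not
  desk-reproducible, so the three hallmarks — a comprehensive search,
  explicit selection criteria, synthesis of multiple primary studies —
  are operationalized as keyword evidence over title plus abstract, all
  three required, with the term lists exposed in the versioned YAML rule
  file so users can tighten or loosen them. Meta-analysis publication
  types short-circuit to `TRUE`. The modern "Systematic Review" type
  (introduced into MEDLINE later) is honored for usability on current
  records.
* **Study data in letters.** Letters, comments and editorials sometimes
  carry original data. Two criteria are checked: a described sample
  (an explicit `n = ...`, an enrollment count, a cohort descriptor) —
  always required — and a traditional structured-abstract outline (at
  least two of Objective/Introduction, Methods/Subjects, Results,
  Discussion/Conclusion). Whether the second criterion is required is a
  rule-set switch, `study_data_requires_structure`, default `TRUE`: the
  stricter reading is the reproducible one, and the switch documents the
  ambiguity rather than hiding it.
* **Precedence of RCT over animal study.** The precedence order places
  the RCT tier before the animal tier, so a veterinary RCT would classify
  as an RCT. Animal-only detection is MeSH-based (`Animals` without
  `Humans`) because the category label gives no operational rule; it
  additionally requires a study-design type so that, e.g., a narrative
  review about animal welfare is not captured.

`unknown` is reserved for citations whose details could not be verified;
verification is a pure function of content (a PMID, or a title plus a
year), so it survives serialization round-trips.

## Identification and overlap matching

Records carrying a PMID are identified by it (`PMID:<pmid>`). PMID-less
records get a content-addressed identifier: a digest of the normalized
(lowercased, punctuation-stripped, whitespace-collapsed) title, the year,
the first author's surname and the source. URL-only citations are
identified by normalized URL and flagged unverified unless a title and
year could be established.

Overlap matching is tiered:

1. **PMID-exact** — PMIDs exist precisely to identify citations;
2. **content-key exact** — normalized title | year | surname, for the
   PMID-less web/book citations;
3. **fuzzy (optional, off by default)** — pairs whose normalized-title
   similarity (1 − Levenshtein/length) reaches a threshold, default 0.90,
   with years required to agree exactly by default. Two records carrying
   *different* PMIDs are never fuzzy-merged: a PMID is an authoritative
   identity. Clustering is the transitive closure of pairwise matches.

A cluster's multiplicity is the number of *distinct* products citing it.
The identity Σₖ k·nₖ = total instances holds whenever each product lists
each citation at most once (the generator always does); a within-product
duplicate keeps its own instance but counts once toward the product's
presence, which the documentation of `overlap_distribution()` spells out.

Percentages follow the printed-precision conventions of the field's
tables: half-up rounding to one decimal (so column sums may land in
[99.0, 101.0]), two decimals for the found-in-all-products share of the
instance pool, integer precision for the synopsis share.

## What the synthetic generator emulates

`generate_corpora()` turns a `corpus_spec()` — per-product category
margins, per-product year-bin margins, an overlap multiplicity vector, a
PMID-less fraction, a noise rate, a seed — into nbib-writable corpora:

* distinct articles receive category-specific publication types, MeSH and
  template abstracts engineered so the classifier recovers the intended
  category (systematic reviews alternate between meta-analysis typing and
  review typing with criteria-bearing abstracts; a quarter of primary
  research articles are letters with structured, sample-bearing
  abstracts; reports carry surveillance sources such as MMWR);
* articles shared by k products carry identical content and PMID in all k
  corpora, and draw a (category, year-bin) jointly available in every
  member product, so per-product margins are met exactly while the
  article stays bibliographically consistent;
* each title embeds a random 12-letter token, keeping normalized titles
  of distinct articles far below any sensible fuzzy threshold, so
  fuzzy matching cannot spuriously merge them;
* `classification_noise` degrades exactly ⌊p·n⌋ records to an ambiguous
  form (generic publication type, no abstract) — it can cost the intended
  category but never relabels toward a specific wrong class, so recovery
  is bounded below by 1 − p by construction;
* `pmid_less_fraction` removes PMIDs from eligible articles (never the
  unverifiable ones, never those with missing years), forcing the
  content-key tier to carry the overlap structure.

What the generator does **not** emulate: real titling and abstract prose
(templates exercise the heuristics, not natural language), within-product
duplicate listings, indexing errors in MEDLINE itself, and per-topic
structure (one topic label per run; the per-topic breakdown is exercised
by the distribution table, not by the fixture). Green tests therefore
show that the pipeline is internally coherent and recovers controlled
structure exactly; they do not show that the text heuristics match human
full-text judgment on real abstracts, which is the method's irreducible
limitation.

## The packaged fixture

`table3_fixture()` encodes a five-product comparison: product totals 531,
254, 1131, 153 and 261 (2330 instances), the published per-product
category counts, and overlap multiplicities 1907/161/25/4/2 (2099
distinct). Year bins are only partially pinned down by published
statements — DynaMed 170 of 1131 in 2007–2009, Clinical Evidence zero in
2007–2009, one missing-year web citation each in Clinical Evidence and
UpToDate — so the remaining bins are fixed illustrative values following
the published qualitative pattern (pre-2001 largest everywhere except
FirstCONSULT, where 2001–2003 leads; 2007–2009 smallest). Those filled-in
values are *not* published data and the currency table should be read
accordingly.

```{r fixture}
spec <- table3_fixture()
corpora <- generate_corpora(spec)
classified <- dplyr::bind_rows(lapply(corpora, classify_corpus))

overlap_summary(overlap_distribution(match_citations(corpora)))
publication_type_table(classified) |>
  dplyr::filter(product == "Total")
higher_evidence_proportion(classified, "FirstCONSULT")
synopsis_audit(classified)[c("n_synopsis", "n_reviews", "percent")]
```

## Numerical choices and degenerate inputs

* Half-up rounding (not banker's) at each table's printed precision, with
  an epsilon guard against binary-representation artifacts.
* Missing years are excluded from currency percentage denominators by
  default (reported separately in a `missing` bin); a switch includes
  them.
* Empty corpora, empty distributions and zero-review synopsis audits all
  return well-formed empty/NA results rather than errors; absent products
  and contract violations (e.g., asking the systematic-review test of a
  non-review) error loudly.
* Duplicate `local_id`s arising from genuinely duplicated records are
  disambiguated with an ordinal suffix at corpus assembly;
  `assign_local_id()` itself stays a pure function of content.
* Cluster assignment in the generator tries weighted random placement and
  falls back to a deterministic largest-capacity greedy, erroring only
  when the requested multiplicities are infeasible for the totals.

## Problem sizes used in the checks

The shipped suite regenerates everything from code: the 2330-instance
fixture end to end; 1,000 small random specs for the conservation
identity; 100 random corpora against an exhaustive all-pairs
brute-force clustering oracle (independent normalization, igraph
components); and 100 noise-free corpora of roughly 500 records each for
exact category recovery. These sizes give the properties thousands of
chances to fail while keeping a full run in the low minutes on one core.

## Known limitations

* The systematic-review and study-data heuristics are surrogates for
  full-text human judgment; on real corpora their error is unknown and
  rule-list dependent.
* Fuzzy matching is O(pairs) within year blocks; with
  `require_year_match = FALSE` it is quadratic in corpus size and is
  intended for corpora of a few thousand records at most.
* The nine categories deliberately stop short of methodological quality
  appraisal and of finer evidence grading (GRADE, Oxford levels); the
  tool profiles *types*, not quality.
* Books and conference abstracts without MEDLINE records land in `other`
  when identifiable and `unknown` when not verifiable; the boundary is
  only as good as the verification metadata.
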