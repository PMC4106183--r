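---
title: "Ranked key-term annotation of gene lists: method and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranked key-term annotation of gene lists: method and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genekeyr)
```

## The procedure

`genekeyr` annotates a gene table by searching ranked regular-expression
key terms against the text fields of per-gene database records and,
optionally, the titles and abstracts of the PubMed articles those records
reference. The procedure, per gene, is:

1. **Resolve** the gene's record by its official symbol — first from the
   local file cache, then (when the policy allows) from an online
   fetcher, saving the fetched document back into the cache. Matching on
   the official symbol rather than any alias avoids synonym ambiguity; a
   fetched record whose official symbol differs from the query is treated
   as absent rather than risking annotating the wrong gene.
2. **Parse** the record into an ordered list of field entries. The
   searchable fields are Description, OtherAliases, OtherDesignations,
   Summary, GeneRIF, Pathways, Process, Function, Component, Interactions
   and Phenotypes. Fields may repeat — a record often carries many
   GeneRIFs — and each occurrence is a separate search unit with its own
   ordinal. Each linked article adds two more units, PubMedTitle and
   PubMedAbstract.
3. **Search** every (term, field entry) pair. A *hit* is one such pair
   with at least one match, and carries all match locations.
4. **Summarise** into three columns appended to the gene's input row:
   the smallest matching term rank (*Highest Rank*), that term's pattern
   (*Highest Rank Term*), and the number of hits (*Total Matched
   Entries* — i.e. summed over terms, the number of entries where the
   term occurs at least once). A gene with no hits gets three empty
   cells, never zeros, so spreadsheets distinguish "no evidence" from
   "evidence of absence of matches".

Rows are emitted incrementally (the output is flushed after every gene),
so an interrupted run keeps everything already computed — relevant for
runs over tens of thousands of genes.

## Search semantics

Patterns use the PCRE dialect (R's `perl = TRUE` engine), unanchored,
with multiline and dotall off and **no implicit case folding**: `tumor
cell` matches exactly that text, while `([Cc]ancer|[Tt]umou?r) [Cc]ell`
is the idiomatic way to cover variants. Matching is the conventional
find-all: non-overlapping, left to right (`aa` in `aaaa` matches at
offsets 0 and 2, not three times). Offsets are 0-based and half-open,
which makes context highlighting an exact slicing operation. Zero-width
matches are discarded — a pattern like `z*` technically matches
everywhere and would otherwise flood the output with empty spans.

Each field entry is an isolated search unit: a term cannot match across
the boundary between two GeneRIFs. This is the conservative reading — a
cross-entry "match" would be an artefact of storage order, not of the
curated text.

Ranks come from line order in the term file (rank 1 = line 1 = most
important). Blank lines and `#` comments are skipped; duplicated patterns
are dropped with a warning, keeping the first occurrence's rank, because
a duplicate can only ever lower the reported rank by accident.

## The cache

Records live one per file at `<root>/<organism>/<shard>/<SYMBOL>.xml`
with 256 shard directories. The shard is the first byte of the MD5 digest
of the symbol's UTF-8 bytes: stable across runs, processes and platforms,
and uniform enough that no shard holds more than a few times the mean
(the test suite checks a loose 3x bound over 10,000 symbols). A
filesystem cache was chosen over an embedded database for simplicity and
because each record is read at most once per run. Writes are
write-then-rename, so a crash can never leave a truncated record that a
later run would trust. Snapshot ingestion scans the byte stream for
record boundaries and parses one record at a time, bounding memory by a
single record rather than the snapshot (full-organism snapshots are
~10 GB class). The PubMed shelf (`<root>/pubmed/...`) is populated only
by online fetches — bulk bibliographic snapshots have different terms of
use and are out of scope.

Within a run, articles referenced by several genes are scanned once: a
memo keyed by PMID stores per-term match results and is valid only for
the term list it was created with (using it with another list is a
contract error, since stale results would silently corrupt counts).

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `organism` | `"Homo sapiens"` | the common case; any organism name is accepted and becomes a cache shelf |
| `include_pubmed` | `FALSE` | article search can dominate runtime and is opt-in, as title/abstract text is noisier than curated fields |
| `rate_limit` | 3 requests/s | the public E-utilities courtesy limit without an API key |
| retries | 3, exponential backoff | transient network failures are retried; persistent ones become per-gene warnings, never aborts |
| context window | 300 characters | long fields are truncated to windows around each match in the HTML report; full text would make reports unwieldy |
| `shard_count` | 256 (fixed) | part of the on-disk layout contract, not a tuning knob |

Online mode is intended for small gene lists (under ~100): per-gene
network latency dominates there, and larger runs should populate the
cache from a snapshot first.

## The synthetic-data generator

All tests run offline against corpora from `generate_corpus()`. A corpus
plan fixes, *before any text exists*, how many times each literal term
occurs in each field entry and article unit; texts are then assembled by
inserting those occurrences at random positions in a stream of filler
tokens. Two safeguards keep the ground truth exact: the filler vocabulary
is invented non-words checked for substring collisions against every
planted term, and after generation every text is re-scanned — a realised
count differing from the plan (e.g. a term accidentally formed across a
token boundary, or one planted term containing another) is a hard
generation error, never a silent miscount. Generation is deterministic
given the plan's seed, and the generator restores the caller's RNG state.

What the corpora emulate: the *structure* of gene records (repeated
fields, article references shared across genes, empty fields, absent
genes) and exact, countable term placement. What they do not emulate:
biomedical prose, real field-length distributions, or the true base rate
of keyword occurrences. Passing tests therefore demonstrate that the
machinery — parsing, search, counting, ranking, caching, memoization,
reporting — is exact; they say nothing about how *discriminative* any
particular keyword is on real records, which depends on the curation of
the live database and the user's choice of terms.

Acceptance-style checks in the test suite run the full pipeline
(snapshot → cache → annotate, articles included) on 50 random corpora of
200 genes, 20 terms and 40 articles each — chosen as a realistic
desk-scale load — and require exact agreement with an independent
brute-force oracle that re-extracts fields with line regexes and counts
terms with fixed-substring scans (no shared code path with the
implementation). On such corpora, classifying a gene as positive when it
has at least one match recovers the planted-positive set exactly
(sensitivity = specificity = 1.0): with literal terms, disjoint filler
and verified counts there is, by construction, no mechanism for a false
call, so anything below 1.0 would indicate a pipeline defect rather than
a property of the data. Real-data performance of the same classification
rule is a different quantity, driven by off-target keyword occurrences,
and cannot be measured from synthetic corpora.

## Numerical and degenerate-input choices

* Multi-part abstracts are joined with a single space so character
  offsets stay well defined.
* Duplicate PubMed references within one record are deduplicated
  (first-seen order) to avoid double-counting article units.
* An empty term file (or one reduced to nothing by comment/blank
  stripping) is a fatal error; an empty gene record is fine and yields no
  hits.
* Tie-breaks: hits are ordered by (field document order, term rank);
  *Highest Rank Term* is unambiguous because ranks are unique.
* Symbols differing only in case are distinct logical genes and distinct
  cache files; on a case-insensitive filesystem the later write wins,
  which mirrors the overwrite rule for duplicate snapshot records.
* The `Gene` header match is exact and case-sensitive; delimiter
  detection is "tab in the header line, else comma", and output is
  always CSV.

## The HTML report

One self-contained HTML5 file: a meta block (version, command line,
timestamp, ranked terms), then one section per gene *with at least one
hit*, in input order — a matchless run states so explicitly. Each section
links to the public gene page (keyed by GeneID), shows a per-term table
of rank, field, matching-entry count and total frequency, and a context
list with every match wrapped in a highlight span. All field text is
HTML-escaped; stripping tags from a rendered context reproduces the
escaped original exactly (a tested invariant). The hide/show toggle is
embedded JavaScript that *hides contexts on load*, so with scripting
disabled the report degrades to everything visible — an archival-
robustness choice.

## Known limitations

* No synonym or ontology expansion: a gene whose relevant evidence is
  phrased differently from every supplied pattern will not be found.
  Single-match positives are deliberately liberal; users wanting fewer
  false positives should filter on *Total Matched Entries* or rank.
* The online fetcher maps live database documents onto the package's
  record dialect with a best-effort field mapping and requires network
  access; the test suite exercises everything through injected fakes and
  never touches the network.
* Record parsing is DOM-based per record; memory is bounded by one
  record (enforced by the streaming snapshot reader), not by one field.
* Regular expressions are applied as given: a pattern matching the empty
  string, or one with catastrophic backtracking, is the user's
  responsibility — patterns are validated for compilability only.
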