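# genekeyr

Ranked key-term annotation of gene lists from Entrez Gene and PubMed
records.

## The problem

High-throughput studies (rare-variant calling, RNA-Seq, ChIP-Seq, siRNA
screens) routinely end with a list of hundreds or thousands of candidate
genes, only a handful of which are relevant to the biological question.
Deciding which ones deserve follow-up means reading, for every gene, its
curated database record — nomenclature, summary, GeneRIFs, pathways,
interactions, phenotypes — and often the linked literature. Done by hand
that is days of work and is impossible to fold into a pipeline.

`genekeyr` automates it. The user supplies two files:

* a **gene table** (CSV or TSV, any columns, one of them headed exactly
  `Gene`), and
* a **term file** — one regular expression per line, in descending order
  of importance, e.g.

  ```
  [Bb]reast [Cc]ancer
  DNA [Rr]epair
  ```

  Line order defines the rank: the first pattern is rank 1. Regular
  expressions let a single line cover spelling and case variants —
  `([Cc]ancer|[Tt]umou?r) [Cc]ell` matches "cancer cell", "Tumour cell",
  and so on; a plain literal like `tumor cell` matches exactly (and only)
  that text.

Every gene is resolved to its database record by **official symbol**
(avoiding synonym ambiguity), each searchable field of the record is
scanned against every term, and — optionally — so are the titles and
abstracts of the PubMed articles the record references. The searchable
gene fields are Description, OtherAliases, OtherDesignations, Summary,
GeneRIF (repeated; each occurrence is its own entry), Pathways, Process,
Function, Component, Interactions and Phenotypes; each linked article
contributes two more units, PubMedTitle and PubMedAbstract.

## The output statistic

Three columns are appended to the input table (which is otherwise
preserved):

* **Highest Rank** — the smallest (most important) rank among the terms
  that matched the gene. Sort on this column to order genes by the
  importance of their best-matching term.
* **Highest Rank Term** — that term's pattern text.
* **Total Matched Entries** — summed over all terms, the number of field
  entries in which the term matched at least once. Each GeneRIF, each
  article title and each article abstract counts as its own entry; this
  is the weight of evidence behind the gene.

A gene with no matches gets three empty cells. A detailed HTML report
(optional) shows, per matching gene, a per-term table of fields,
matching-entry counts and match frequencies, plus every match highlighted
in its surrounding context behind a hide/show toggle, with hyperlinks to
the public gene record.

## Records, cache, online mode

Records are Entrez-Gene-style XML documents served from a local file
cache laid out as `<root>/<organism>/<shard>/<SYMBOL>.xml`, where the
shard is the first byte of the MD5 digest of the symbol (256
sub-directories, so no single directory grows large). The cache is
populated in bulk from a database snapshot with
`populate_from_snapshot()`, which streams the snapshot record by record —
full-organism dumps run to tens of gigabytes and never fit in memory.
For small gene lists (roughly under a hundred) the cache can instead be
filled on demand by a rate-limited online fetcher (`entrez_fetcher()`,
3 requests/second); fetched PubMed entries are cached the same way under
`<root>/pubmed/`. Within one run, articles shared by several genes are
scanned exactly once (a memo table keyed by PMID).

## Worked example

The package ships a deterministic synthetic-corpus generator (used
throughout its test suite), including a three-gene demonstration corpus:

```r
library(genekeyr)

corpus <- generate_corpus(example_corpus_plan())
layout <- cache_layout("democache")
populate_from_snapshot(layout, corpus$snapshot)

writeLines(c("Gene", "RPA1", "BRCA1", "CANT1"), "genes.csv")
writeLines(c("[Bb]reast [Cc]ancer", "DNA [Rr]epair"), "terms.txt")

run_annotation(run_config("genes.csv", "terms.txt", cache_root = "democache"))
```

which prints:

```
Gene,Highest Rank,Highest Rank Term,Total Matched Entries
RPA1,2,DNA [Rr]epair,10
BRCA1,1,[Bb]reast [Cc]ancer,3
CANT1,,,
```

RPA1's best match is the rank-2 term `DNA [Rr]epair`, found in 10 field
entries (once each in Process and Pathways, once in each of eight
GeneRIFs). BRCA1 matches the rank-1 term, so it sorts first. CANT1
matched nothing and its annotations are empty.

The same run from a shell, via the installed script:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/genekey.R", package="genekeyr"))') \
  --terms terms.txt --genes genes.csv --cache-dir democache --report report.html
```

## Scope notes

`genekeyr` is a targeted annotation tool, not an enrichment method: it
applies a user-ranked search, with no statistical test against a
reference gene set, no synonym expansion and no ontology-aware matching.
See `vignette("gene-key-annotation")` for the method, its assumptions and
its limitations.
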