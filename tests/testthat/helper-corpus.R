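# Shared fixture plumbing for the tests: build corpora, populate caches,
# write input files.

make_cache <- function(corpus, organism = "Homo sapiens") {
  layout <- cache_layout(file.path(tempfile("cache")), organism = organism)
  suppressWarnings(populate_from_snapshot(layout, corpus$snapshot))
  layout
}

cache_articles <- function(layout, corpus) {
  for (pmid in names(corpus$article_xml)) {
    store_article(layout, pmid, corpus$article_xml[[pmid]])
  }
  invisible(layout)
}

write_gene_list <- function(symbols, path = tempfile(fileext = ".csv")) {
  writeLines(c("Gene", symbols), path)
  path
}

write_term_file <- function(patterns, path = tempfile(fileext = ".txt")) {
  writeLines(patterns, path)
  path
}

# Run the full pipeline (snapshot -> cache -> annotate) over a corpus and
# return summaries, hits and the output CSV lines.
run_pipeline <- function(corpus, patterns, include_pubmed = TRUE,
                         report_path = NULL) {
  layout <- make_cache(corpus)
  cache_articles(layout, corpus)
  symbols <- vapply(corpus$plan$genes, `[[`, "", "symbol")
  out <- tempfile(fileext = ".csv")
  cfg <- run_config(genes_path = write_gene_list(symbols),
                    terms_path = write_term_file(patterns),
                    include_pubmed = include_pubmed,
                    cache_root = layout$root,
                    report_path = report_path,
                    output = out)
  res <- suppressWarnings(run_annotation(cfg))
  res$csv <- readLines(out)
  res$symbols <- symbols
  res
}

# A tiny three-entry record for parser tests.
minimal_record_xml <- function() {
  build_record_xml("6117", "RPA1", "Homo sapiens",
                   data.frame(field_name = c("Summary", "GeneRIF", "GeneRIF"),
                              text = c("replication protein", "first rif",
                                       "second rif"),
                              stringsAsFactors = FALSE),
                   pmids = c("111", "222", "111"))
}
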