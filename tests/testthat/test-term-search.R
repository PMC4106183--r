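test_that("terms load with rank = line order, skipping blanks and comments", {
  path <- write_term_file(c("[Bb]reast [Cc]ancer", "", "# a comment",
                            "  DNA [Rr]epair  "))
  terms <- load_terms(path)
  expect_equal(terms$rank, c(1L, 2L))
  expect_equal(terms$pattern, c("[Bb]reast [Cc]ancer", "DNA [Rr]epair"))
})

test_that("duplicate patterns keep the first rank with a warning; empty files error", {
  path <- write_term_file(c("A", "B", "A"))
  expect_warning(terms <- load_terms(path), class = "genekey_duplicate_terms")
  expect_equal(terms$pattern, c("A", "B"))
  expect_equal(terms$rank, c(1L, 2L))

  expect_error(load_terms(write_term_file(c("", "   "))),
               class = "genekey_empty_terms")
})

test_that("an uncompilable pattern errors with its line number", {
  path <- write_term_file(c("fine", "(unclosed"))
  err <- tryCatch(load_terms(path), error = identity)
  expect_s3_class(err, "genekey_input_error")
  expect_match(conditionMessage(err), "line 2")
  expect_match(conditionMessage(err), "(unclosed", fixed = TRUE)
})

test_that("regex matching is unanchored, case-exact and non-overlapping", {
  # alternation with optional spelling
  m <- find_matches("([Cc]ancer|[Tt]umou?r) [Cc]ell", "a tumour cell line")
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 2L)
  expect_equal(m$end, 13L)
  # no implicit case folding
  expect_equal(nrow(find_matches("tumor cell", "Tumor cell")), 0L)
  # non-overlapping left-to-right
  m2 <- find_matches("aa", "aaaa")
  expect_equal(m2$start, c(0L, 2L))
  expect_equal(m2$end, c(2L, 4L))
  # empty text and zero-width matches yield nothing
  expect_equal(nrow(find_matches("x", "")), 0L)
  expect_equal(nrow(find_matches("z*", "aaa")), 0L)
})

test_that("search_record yields one hit per matching (term, entry), ordered by field then rank", {
  rec <- parse_gene_record(build_record_xml(
    "1", "G1", "Homo sapiens",
    data.frame(field_name = c("Summary", "GeneRIF", "GeneRIF"),
               text = c("has DNA repair here", "nothing", "DNA repair and DNA repair"),
               stringsAsFactors = FALSE)))
  terms <- term_list(c("nothing", "DNA [Rr]epair"))
  hits <- search_record(rec, terms)
  expect_equal(hits$field_name, c("Summary", "GeneRIF", "GeneRIF"))
  expect_equal(hits$field_ordinal, c(1L, 1L, 2L))
  expect_equal(hits$term_rank, c(2L, 1L, 2L))
  expect_equal(hits$n_matches, c(1L, 1L, 2L))
  # match spans index into the entry text
  expect_equal(hits$match_starts[[1]], 4L)
  expect_equal(hits$match_ends[[1]], 14L)
})

test_that("a record with no occurrences yields no hits", {
  rec <- parse_gene_record(build_record_xml(
    "1", "G1", "Homo sapiens",
    data.frame(field_name = "Summary", text = "plain filler",
               stringsAsFactors = FALSE)))
  expect_equal(nrow(search_record(rec, term_list("absent"))), 0L)
})

test_that("search_record agrees with the brute-force oracle on a random corpus", {
  plan <- random_corpus_plan(seed = 11L, n_genes = 30L, n_terms = 8L,
                             n_articles = 0L)
  corpus <- generate_corpus(plan)
  terms <- term_list(attr(plan, "terms"))
  for (sym in names(corpus$gene_xml)) {
    hits <- search_record(parse_gene_record(corpus$gene_xml[[sym]]), terms)
    expect_identical(hit_key(pipeline_hit_frame(hits)),
                     hit_key(oracle_gene_hits(corpus, sym, terms$pattern)),
                     info = sym)
  }
})

test_that("title and abstract are separate searchable units with the article's ordinal", {
  arts <- list(pubmed_article("1", "DNA repair in title", "no match"),
               pubmed_article("2", "xx", "abstract DNA repair text"))
  hits <- search_articles(arts, term_list("DNA [Rr]epair"), gene_symbol = "G")
  expect_equal(hits$field_name, c("PubMedTitle", "PubMedAbstract"))
  expect_equal(hits$field_ordinal, c(1L, 2L))
})

test_that("the memo scans each distinct article once and never changes results", {
  terms <- term_list(c("alpha", "beta"))
  arts <- list(pubmed_article("10", "alpha one", "beta two"),
               pubmed_article("11", "nothing", "alpha"))
  memo <- new_article_memo(terms)
  h1 <- search_articles(arts, terms, memo, gene_symbol = "G1")
  expect_equal(memo$scans, 2L)
  # second gene shares PMID 10: zero new scans for it
  h2 <- search_articles(arts[1], terms, memo, gene_symbol = "G2")
  expect_equal(memo$scans, 2L)
  # memoized vs memo-free are identical apart from the symbol
  fresh <- search_articles(arts[1], terms, gene_symbol = "G2")
  expect_equal(h2[setdiff(names(h2), "gene_symbol")],
               fresh[setdiff(names(fresh), "gene_symbol")])
})

test_that("a memo built under a different term list is rejected", {
  memo <- new_article_memo(term_list("alpha"))
  expect_error(search_articles(list(pubmed_article("1", "t", "a")),
                               term_list("beta"), memo),
               class = "genekey_contract_error")
})

test_that("adding a term only appends hits (monotonicity)", {
  plan <- random_corpus_plan(seed = 3L, n_genes = 10L, n_terms = 6L,
                             n_articles = 0L)
  corpus <- generate_corpus(plan)
  pats <- attr(plan, "terms")
  base <- term_list(pats[1:5])
  extended <- term_list(pats)
  for (sym in names(corpus$gene_xml)[1:5]) {
    rec <- parse_gene_record(corpus$gene_xml[[sym]])
    h_base <- pipeline_hit_frame(search_record(rec, base))
    h_ext <- pipeline_hit_frame(search_record(rec, extended))
    expect_identical(hit_key(h_ext[h_ext$term_rank <= 5L, ]), hit_key(h_base),
                     info = sym)
  }
})

test_that("identical inputs yield identical hit listings (determinism)", {
  rec <- parse_gene_record(minimal_record_xml())
  terms <- term_list(c("rif", "protein"))
  expect_identical(search_record(rec, terms), search_record(rec, terms))
})
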