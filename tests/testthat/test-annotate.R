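test_that("gene tables auto-detect the delimiter and preserve all columns", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("Gene", "RPA1", "BRCA1", "CANT1"), csv)
  tab <- read_gene_table(csv)
  expect_equal(tab$header, "Gene")
  expect_equal(tab$gene_col, 1L)
  expect_equal(nrow(tab$rows), 3L)

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("Chrom\tGene\tEffect", "chr17\tBRCA1\tmissense"), tsv)
  tab2 <- read_gene_table(tsv)
  expect_equal(tab2$gene_col, 2L)
  expect_equal(tab2$header, c("Chrom", "Gene", "Effect"))
  expect_equal(tab2$rows[1, 3], "missense")
})

test_that("the Gene header match is exact and case-sensitive; empty files error", {
  bad <- tempfile()
  writeLines(c("gene", "BRCA1"), bad)
  expect_error(read_gene_table(bad), class = "genekey_input_error")
  empty <- tempfile()
  file.create(empty)
  expect_error(read_gene_table(empty), class = "genekey_input_error")
})

test_that("summaries follow the min-rank / entry-count rules", {
  terms <- term_list(c("[Bb]reast [Cc]ancer", "DNA [Rr]epair"))
  # rank-2 term matched in Process, Pathways and 8 GeneRIF entries -> (2, pattern, 10)
  rec <- parse_gene_record(build_record_xml(
    "6117", "RPA1", "Homo sapiens",
    data.frame(field_name = c("Process", "Pathways", rep("GeneRIF", 8)),
               text = rep("about DNA repair", 10), stringsAsFactors = FALSE)))
  s <- summarize_hits(search_record(rec, terms), terms)
  expect_equal(s$highest_rank, 2L)
  expect_equal(s$highest_rank_term, "DNA [Rr]epair")
  expect_equal(s$total_matched_entries, 10L)

  # no hits -> all-empty summary
  s0 <- summarize_hits(search_record(rec, term_list("absent")), terms)
  expect_true(is.na(s0$highest_rank) && is.na(s0$highest_rank_term) &&
                is.na(s0$total_matched_entries))

  # two terms matching the same single entry count as two matched entries
  rec2 <- parse_gene_record(build_record_xml(
    "1", "G", "Homo sapiens",
    data.frame(field_name = "Summary", text = "breast cancer DNA repair",
               stringsAsFactors = FALSE)))
  s2 <- summarize_hits(search_record(rec2, terms), terms)
  expect_equal(s2$total_matched_entries, 2L)
  expect_equal(s2$highest_rank, 1L)
})

test_that("annotated output appends the three columns and quotes per CSV", {
  header <- c("Gene", "Note")
  rows <- data.frame(Gene = c("A", "B"), Note = c("plain", "has,comma"),
                     stringsAsFactors = FALSE)
  terms <- term_list(c("x,y", "z"))
  summaries <- list(
    structure(list(highest_rank = 1L, highest_rank_term = "x,y",
                   total_matched_entries = 2L), class = "gene_summary"),
    summarize_hits(NULL, terms))
  out <- tempfile()
  write_annotated_table(header, rows, summaries, out)
  lines <- readLines(out)
  expect_equal(lines[1], "Gene,Note,Highest Rank,Highest Rank Term,Total Matched Entries")
  expect_equal(lines[2], "A,plain,1,\"x,y\",2")
  expect_equal(lines[3], "B,\"has,comma\",,,")

  # zero data rows: header only
  out2 <- tempfile()
  write_annotated_table("Gene", data.frame(Gene = character()), list(), out2)
  expect_equal(readLines(out2),
               "Gene,Highest Rank,Highest Rank Term,Total Matched Entries")
})

test_that("the pubmed flag controls whether article-only genes annotate", {
  plan <- corpus_plan(
    genes = list(gene_plan("ARTG1", "1", entries = list(entry_plan("Summary")),
                           pmids = "555001")),
    articles = list(article_plan("555001",
                                 abstract_plants = c("querix01" = 2L))),
    seed = 9L)
  corpus <- generate_corpus(plan)
  layout <- make_cache(corpus)
  cache_articles(layout, corpus)
  genes <- write_gene_list("ARTG1")
  terms <- write_term_file("querix01")

  out1 <- tempfile()
  run_annotation(run_config(genes, terms, include_pubmed = FALSE,
                            cache_root = layout$root, output = out1))
  expect_equal(readLines(out1)[2], "ARTG1,,,")

  out2 <- tempfile()
  run_annotation(run_config(genes, terms, include_pubmed = TRUE,
                            cache_root = layout$root, output = out2))
  expect_equal(readLines(out2)[2], "ARTG1,1,querix01,1")
})

test_that("genes missing from the cache get empty summaries and a warning", {
  corpus <- generate_corpus(example_corpus_plan())
  layout <- make_cache(corpus)
  out <- tempfile()
  cfg <- run_config(write_gene_list(c("RPA1", "NOSUCH")),
                    write_term_file("DNA [Rr]epair"),
                    cache_root = layout$root, output = out)
  expect_warning(run_annotation(cfg), class = "genekey_gene_absent")
  lines <- readLines(out)
  expect_match(lines[2], "^RPA1,1,DNA \\[Rr\\]epair,10$")
  expect_equal(lines[3], "NOSUCH,,,")
})

test_that("duplicate gene rows annotate identically without re-searching", {
  corpus <- generate_corpus(example_corpus_plan())
  layout <- make_cache(corpus)
  out <- tempfile()
  cfg <- run_config(write_gene_list(c("RPA1", "RPA1")),
                    write_term_file("DNA [Rr]epair"),
                    cache_root = layout$root, output = out,
                    policy = fetch_policy("offline_only"))
  res <- run_annotation(cfg)
  lines <- readLines(out)
  expect_equal(lines[2], lines[3])
  expect_identical(res$summaries[[1]], res$summaries[[2]])
})

test_that("column preservation: output minus the appended columns equals the input", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("Chrom\tGene\tEffect",
               "chr17\tRPA1\tstop", "chr5\tCANT1\tsilent"), tsv)
  corpus <- generate_corpus(example_corpus_plan())
  layout <- make_cache(corpus)
  out <- tempfile()
  run_annotation(run_config(tsv, write_term_file("DNA [Rr]epair"),
                            cache_root = layout$root, output = out))
  got <- read.csv(out, colClasses = "character", check.names = FALSE)
  expect_equal(got[, 1:3],
               read.delim(tsv, colClasses = "character", check.names = FALSE))
})

test_that("rows already emitted survive a mid-run termination", {
  corpus <- generate_corpus(random_corpus_plan(seed = 13L, n_genes = 10L,
                                               n_terms = 3L, n_articles = 0L))
  layout <- make_cache(corpus)
  out <- tempfile()
  boom <- function(i, sym) if (i == 4L) stop("killed")
  cfg <- run_config(write_gene_list(names(corpus$gene_xml)),
                    write_term_file(attr(corpus$plan, "terms")[1:3]),
                    cache_root = layout$root, output = out,
                    progress_fn = boom)
  expect_error(suppressWarnings(run_annotation(cfg)), "killed")
  lines <- readLines(out)
  expect_equal(length(lines), 1L + 4L)  # header + the first 4 gene rows
  expect_match(lines[5], "^GENE0004")
})
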