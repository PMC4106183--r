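test_that("shard_of is deterministic, in range, and equals the reference digest", {
  expect_identical(shard_of("BRCA1"), shard_of("BRCA1"))
  # first byte of the MD5 digest, computed independently beforehand
  expect_equal(shard_of(c("BRCA1", "RPA1", "CANT1", "TP53", "12345")),
               c(170L, 32L, 131L, 196L, 130L))
  syms <- sprintf("SYM%05d", 1:2000)
  sh <- shard_of(syms)
  expect_true(all(sh >= 0L & sh <= 255L))
})

test_that("shards are loosely uniform over many symbols", {
  syms <- sprintf("GENE%05d", 1:10000)
  counts <- tabulate(shard_of(syms) + 1L, nbins = 256L)
  expect_lte(max(counts), 3 * mean(counts))
})

test_that("gene storage round-trips, overwrites, and shares shard directories", {
  layout <- cache_layout(tempfile("cache"))
  doc1 <- charToRaw("<EntrezgeneRecord>1</EntrezgeneRecord>")
  doc2 <- charToRaw("<EntrezgeneRecord>2</EntrezgeneRecord>")

  expect_null(retrieve_gene(layout, "BRCA1"))
  p <- store_gene(layout, "BRCA1", doc1)
  expect_identical(retrieve_gene(layout, "BRCA1"), doc1)
  expect_match(p, file.path("Homo sapiens", "aa", "BRCA1.xml"), fixed = TRUE)

  # overwrite rule: the second store wins
  store_gene(layout, "BRCA1", doc2)
  expect_identical(retrieve_gene(layout, "BRCA1"), doc2)

  # two symbols hashing to one shard live as distinct files in one directory
  probe <- sprintf("P%04d", 1:300)   # pigeonhole: a collision is certain
  psh <- shard_of(probe)
  dup_shard <- psh[duplicated(psh)][1]
  pair <- probe[psh == dup_shard][1:2]
  for (s in pair) store_gene(layout, s, doc1)
  shard_dir <- file.path(layout$root, layout$organism,
                         sprintf("%02x", dup_shard))
  expect_true(all(file.exists(file.path(shard_dir, paste0(pair, ".xml")))))
})

test_that("article storage round-trips under the pubmed shelf", {
  layout <- cache_layout(tempfile("cache"))
  expect_null(retrieve_article(layout, "12345"))
  doc <- charToRaw(build_article_xml("12345", "t", "a"))
  p <- store_article(layout, "12345", doc)
  expect_identical(retrieve_article(layout, "12345"), doc)
  expect_match(p, file.path("pubmed", "82", "12345.xml"), fixed = TRUE)
})

test_that("snapshot population writes one retrievable record per gene", {
  plan <- random_corpus_plan(seed = 5L, n_genes = 25L, n_terms = 4L,
                             n_articles = 0L)
  corpus <- generate_corpus(plan)
  layout <- cache_layout(tempfile("cache"))
  expect_equal(populate_from_snapshot(layout, corpus$snapshot), 25L)
  for (sym in names(corpus$gene_xml)) {
    bytes <- retrieve_gene(layout, sym)
    expect_false(is.null(bytes), info = sym)
    expect_equal(parse_gene_record(bytes)$official_symbol, sym)
  }
})

test_that("snapshot population is idempotent (same files, same bytes)", {
  corpus <- generate_corpus(random_corpus_plan(seed = 6L, n_genes = 8L,
                                               n_terms = 3L, n_articles = 0L))
  layout <- cache_layout(tempfile("cache"))
  populate_from_snapshot(layout, corpus$snapshot)
  files1 <- sort(list.files(layout$root, recursive = TRUE))
  bytes1 <- lapply(file.path(layout$root, files1),
                   function(f) readBin(f, "raw", file.size(f)))
  populate_from_snapshot(layout, corpus$snapshot)
  files2 <- sort(list.files(layout$root, recursive = TRUE))
  bytes2 <- lapply(file.path(layout$root, files2),
                   function(f) readBin(f, "raw", file.size(f)))
  expect_identical(files1, files2)
  expect_identical(bytes1, bytes2)
})

test_that("empty snapshots warn; duplicate symbols warn and overwrite", {
  layout <- cache_layout(tempfile("cache"))
  expect_warning(n <- populate_from_snapshot(layout, "<EntrezgeneSet></EntrezgeneSet>"),
                 class = "genekey_empty_snapshot")
  expect_equal(n, 0L)

  rec_a <- build_record_xml("1", "DUP1", "Homo sapiens",
                            data.frame(field_name = "Summary", text = "first"))
  rec_b <- build_record_xml("1", "DUP1", "Homo sapiens",
                            data.frame(field_name = "Summary", text = "second"))
  snap <- paste("<EntrezgeneSet>", rec_a, rec_b, "</EntrezgeneSet>", sep = "\n")
  expect_warning(n2 <- populate_from_snapshot(layout, snap),
                 class = "genekey_duplicate_record")
  expect_equal(n2, 2L)
  rec <- parse_gene_record(retrieve_gene(layout, "DUP1"))
  expect_equal(rec$entries$text, "second")
})

test_that("a malformed record mid-stream errors with its ordinal, keeping prior records", {
  good <- build_record_xml("1", "OK1", "Homo sapiens",
                           data.frame(field_name = "Summary", text = "x"))
  bad <- "<EntrezgeneRecord><GeneID>9</GeneID></EntrezgeneRecord>"  # no symbol
  snap <- paste("<EntrezgeneSet>", good, bad, "</EntrezgeneSet>", sep = "\n")
  layout <- cache_layout(tempfile("cache"))
  err <- tryCatch(populate_from_snapshot(layout, snap), error = identity)
  expect_s3_class(err, "genekey_parse_error")
  expect_match(conditionMessage(err), "record 2")
  expect_false(is.null(retrieve_gene(layout, "OK1")))
})

test_that("snapshots stream from disk in small chunks", {
  corpus <- generate_corpus(random_corpus_plan(seed = 8L, n_genes = 12L,
                                               n_terms = 3L, n_articles = 0L))
  snap_path <- tempfile(fileext = ".xml")
  writeLines(corpus$snapshot, snap_path)
  layout <- cache_layout(tempfile("cache"))
  # chunk far smaller than one record forces many buffer refills
  expect_equal(populate_from_snapshot(layout, snap_path, chunk_size = 64L), 12L)
  expect_false(is.null(retrieve_gene(layout, names(corpus$gene_xml)[12])))
})
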