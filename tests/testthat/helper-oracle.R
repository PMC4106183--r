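# Independent brute-force oracle: scans corpus XML with line-regex field
# extraction and an iterated fixed-substring search (no PCRE, no package
# parsers), so agreement with the pipeline is a genuine dual-route check.
# Oracle terms are the literal strings planted by the corpus generator.

oracle_unescape <- function(x) {
  x <- gsub("&lt;", "<", x, fixed = TRUE)
  x <- gsub("&gt;", ">", x, fixed = TRUE)
  gsub("&amp;", "&", x, fixed = TRUE)
}

# All <Tag>text</Tag> lines of one generated record/entry document.
oracle_elements <- function(xml_text) {
  lines <- strsplit(xml_text, "\n", fixed = TRUE)[[1]]
  m <- regmatches(lines, regexec("^\\s*<([A-Za-z]+)>(.*)</\\1>$", lines))
  m <- m[vapply(m, length, 0L) == 3L]
  data.frame(tag = vapply(m, `[[`, "", 2L),
             text = oracle_unescape(vapply(m, `[[`, "", 3L)),
             stringsAsFactors = FALSE)
}

# Left-to-right non-overlapping fixed-substring count.
oracle_count <- function(text, term) {
  n <- 0L
  from <- 1L
  w <- nchar(term)
  repeat {
    rest <- substr(text, from, nchar(text))
    p <- regexpr(term, rest, fixed = TRUE)
    if (p == -1L) return(n)
    n <- n + 1L
    from <- from + p + w - 1L
  }
}

# Per-gene oracle hits over a generated corpus: one row per (term, field
# entry) with >= 1 occurrence, including PubMedTitle/PubMedAbstract units
# in the gene's reference order. `terms` are literal strings in rank order.
oracle_gene_hits <- function(corpus, symbol, terms) {
  els <- oracle_elements(corpus$gene_xml[[symbol]])
  fields <- els[els$tag %in% gene_search_fields(), , drop = FALSE]
  if (nrow(fields)) {
    fields$ordinal <- as.integer(stats::ave(seq_len(nrow(fields)), fields$tag,
                                            FUN = seq_along))
  }
  pmids <- els$text[els$tag == "PubMedId"]
  pmids <- pmids[!duplicated(pmids)]

  v_rank <- integer(0); v_field <- character(0)
  v_ord <- integer(0); v_count <- integer(0)
  addrow <- function(rank, field, ordinal, count) {
    v_rank[length(v_rank) + 1L] <<- rank
    v_field[length(v_field) + 1L] <<- field
    v_ord[length(v_ord) + 1L] <<- ordinal
    v_count[length(v_count) + 1L] <<- count
  }
  for (i in seq_len(nrow(fields))) {
    for (j in seq_along(terms)) {
      cnt <- oracle_count(fields$text[i], terms[j])
      if (cnt > 0L) addrow(j, fields$tag[i], fields$ordinal[i], cnt)
    }
  }
  for (k in seq_along(pmids)) {
    art <- corpus$article_xml[[pmids[k]]]
    if (is.null(art) || is.na(art)) next
    ae <- oracle_elements(art)
    title <- paste(ae$text[ae$tag == "ArticleTitle"], collapse = " ")
    abstract <- paste(ae$text[ae$tag == "AbstractText"], collapse = " ")
    for (j in seq_along(terms)) {
      cnt <- oracle_count(title, terms[j])
      if (cnt > 0L) addrow(j, "PubMedTitle", k, cnt)
      cnt <- oracle_count(abstract, terms[j])
      if (cnt > 0L) addrow(j, "PubMedAbstract", k, cnt)
    }
  }
  data.frame(symbol = rep(symbol, length(v_rank)), term_rank = v_rank,
             field_name = v_field, field_ordinal = v_ord,
             n_matches = v_count, stringsAsFactors = FALSE)
}

oracle_summary <- function(oracle_hits, terms) {
  if (!nrow(oracle_hits)) {
    return(list(highest_rank = NA_integer_, highest_rank_term = NA_character_,
                total_matched_entries = NA_integer_))
  }
  r <- min(oracle_hits$term_rank)
  list(highest_rank = r, highest_rank_term = terms[r],
       total_matched_entries = nrow(oracle_hits))
}

# Canonical sortable key for hit comparison.
hit_key <- function(df) {
  k <- sprintf("%s|%d|%s|%d|%d", df$symbol, df$term_rank, df$field_name,
               df$field_ordinal, df$n_matches)
  sort(k)
}

pipeline_hit_frame <- function(hits) {
  data.frame(symbol = hits$gene_symbol, term_rank = hits$term_rank,
             field_name = hits$field_name, field_ordinal = hits$field_ordinal,
             n_matches = hits$n_matches, stringsAsFactors = FALSE)
}
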