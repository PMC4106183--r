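# Ranked search terms and regex matching over record fields and article
# texts.

#' Build a ranked term list
#'
#' @param patterns Character vector of regular-expression patterns, in rank
#'   order (first = rank 1 = most important).
#' @return A `term_list`: a data frame with columns `rank` and `pattern`.
#' @export
term_list <- function(patterns) {
  patterns <- as.character(patterns)
  if (!length(patterns)) {
    genekey_error("term list contains no search terms", "genekey_empty_terms")
  }
  if (anyDuplicated(patterns)) {
    genekey_error("term list contains duplicate patterns", "genekey_input_error")
  }
  for (i in seq_along(patterns)) assert_regex(patterns[i], i)
  structure(data.frame(rank = seq_along(patterns), pattern = patterns,
                       stringsAsFactors = FALSE),
            class = c("term_list", "data.frame"))
}

assert_regex <- function(pattern, where) {
  ok <- tryCatch({ grepl(pattern, "", perl = TRUE); TRUE },
                 error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) {
    genekey_error(sprintf("line %d: invalid regular expression: %s",
                          where, pattern),
                  "genekey_input_error")
  }
  invisible(TRUE)
}

#' Load ranked search terms from a text file
#'
#' One regular expression per line; the line order defines the rank
#' (1 = most important). Leading/trailing whitespace is stripped; blank
#' lines and lines starting with `#` (comments) are skipped. Duplicate
#' patterns are dropped with a warning, keeping the first occurrence's
#' rank. A line that does not compile as a regular expression is an error
#' naming the line number and pattern.
#'
#' @param path Path to the term file (UTF-8).
#' @return A [term_list()].
#' @export
load_terms <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  stripped <- trimws(lines)
  keep <- nzchar(stripped) & !startsWith(stripped, "#")
  pats <- stripped[keep]
  line_no <- which(keep)
  for (i in seq_along(pats)) assert_regex(pats[i], line_no[i])
  dup <- duplicated(pats)
  if (any(dup)) {
    genekey_warning(sprintf("dropping duplicate search term(s): %s",
                            paste(unique(pats[dup]), collapse = ", ")),
                    "genekey_duplicate_terms")
    pats <- pats[!dup]
  }
  if (!length(pats)) {
    genekey_error(sprintf("no search terms found in '%s'", path),
                  "genekey_empty_terms")
  }
  term_list(pats)
}

#' Find all matches of one pattern in a text
#'
#' Unanchored substring search returning all non-overlapping, left-to-right
#' matches (the conventional find-all semantics of the PCRE engine via
#' `gregexpr(..., perl = TRUE)`). Case handling is exactly as the pattern
#' specifies; there is no implicit case folding. Zero-width matches are
#' discarded.
#'
#' @param pattern Regular expression (PCRE dialect; multiline/dotall off).
#' @param text A single string to scan.
#' @return Data frame with 0-based `start` and exclusive `end` character
#'   offsets, one row per match, sorted by `start`.
#' @export
find_matches <- function(pattern, text) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1L]]
  spans_from_gregexpr(m)
}

spans_from_gregexpr <- function(m) {
  v <- span_vectors(m)
  if (is.null(v)) empty_spans() else data.frame(start = v$start, end = v$end)
}

# Fast path: NULL when no (non-empty) match, else integer start/end vectors.
span_vectors <- function(m) {
  if (m[1L] == -1L) return(NULL)
  len <- attr(m, "match.length")
  keep <- len > 0L
  if (!any(keep)) return(NULL)
  s <- as.integer(m[keep]) - 1L
  list(start = s, end = s + as.integer(len[keep]))
}

empty_spans <- function() data.frame(start = integer(), end = integer())

# A hit table holds one row per (term, field entry) pair with >= 1 match.
# match_starts / match_ends are list-columns of integer vectors (0-based,
# half-open spans); `text` keeps the searched text for context rendering.
empty_hits <- function() {
  data.frame(gene_symbol = character(), term_rank = integer(),
             term_pattern = character(), field_name = character(),
             field_ordinal = integer(), n_matches = integer(),
             match_starts = I(list()), match_ends = I(list()),
             text = character(), stringsAsFactors = FALSE)
}

make_hits <- function(gene_symbol, rank, pattern, field_name, field_ordinal,
                      starts, ends, text) {
  data.frame(gene_symbol = gene_symbol, term_rank = as.integer(rank),
             term_pattern = pattern, field_name = field_name,
             field_ordinal = as.integer(field_ordinal),
             n_matches = vapply(starts, length, integer(1)),
             match_starts = I(starts), match_ends = I(ends),
             text = text, stringsAsFactors = FALSE)
}

bind_hits <- function(lst) {
  lst <- lst[vapply(lst, function(h) !is.null(h) && nrow(h) > 0, logical(1))]
  if (!length(lst)) return(empty_hits())
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

#' Search a gene record's fields for every term
#'
#' Scans each field entry of the record against each term and returns one
#' hit per (term, field entry) pair with at least one match, ordered by
#' (field document order, term rank). Linked articles are searched
#' separately by [search_articles()].
#'
#' @param record A [gene_record()].
#' @param terms A [term_list()].
#' @param gene_symbol Symbol recorded on the hits; defaults to the
#'   record's official symbol.
#' @return A hit data frame (see [search_articles()] for the article
#'   counterpart); zero rows when nothing matches.
#' @export
search_record <- function(record, terms, gene_symbol = record$official_symbol) {
  entries <- record$entries
  if (!nrow(entries)) return(empty_hits())
  entry_idx <- integer(0); rank <- integer(0)
  starts <- list(); ends <- list()
  for (j in seq_len(nrow(terms))) {
    ms <- gregexpr(terms$pattern[j], entries$text, perl = TRUE)
    for (i in seq_along(ms)) {
      sp <- span_vectors(ms[[i]])
      if (is.null(sp)) next
      entry_idx <- c(entry_idx, i)
      rank <- c(rank, j)
      starts[[length(starts) + 1L]] <- sp$start
      ends[[length(ends) + 1L]] <- sp$end
    }
  }
  if (!length(entry_idx)) return(empty_hits())
  ord <- order(entry_idx, rank)
  make_hits(gene_symbol,
            rank = terms$rank[rank[ord]],
            pattern = terms$pattern[rank[ord]],
            field_name = entries$field_name[entry_idx[ord]],
            field_ordinal = entries$ordinal[entry_idx[ord]],
            starts = starts[ord], ends = ends[ord],
            text = entries$text[entry_idx[ord]])
}

#' Memo table for article searches
#'
#' Within one run, many genes can reference the same PubMed article. The
#' memo caches per-article, per-term match results keyed by PMID so each
#' distinct article is scanned exactly once. A memo is valid only for the
#' term list it was created with.
#'
#' @param terms The [term_list()] the memo is bound to.
#' @return An `article_memo` (an environment; mutated in place by
#'   [search_articles()]). `memo$scans` counts articles actually scanned.
#' @export
new_article_memo <- function(terms) {
  memo <- new.env(parent = emptyenv())
  memo$patterns <- terms$pattern
  memo$tab <- new.env(parent = emptyenv())
  memo$scans <- 0L
  class(memo) <- "article_memo"
  memo
}

scan_article <- function(article, terms) {
  scan_one <- function(text) {
    lapply(gregexpr_all(terms$pattern, text), span_vectors)
  }
  list(title = scan_one(article$title), abstract = scan_one(article$abstract))
}

gregexpr_all <- function(patterns, text) {
  lapply(patterns, function(p) gregexpr(p, text, perl = TRUE)[[1L]])
}

#' Search linked PubMed articles for every term
#'
#' Each article contributes two searchable units, `PubMedTitle` and
#' `PubMedAbstract`; the hit's `field_ordinal` is the 1-based position of
#' the article in the gene's reference list. Articles already present in
#' the memo are not re-scanned; newly scanned articles extend the memo.
#' Results are identical whether or not the memo was pre-populated.
#'
#' @param articles List of [pubmed_article()] in the gene's reference
#'   order.
#' @param terms A [term_list()]; must be the list the memo was built with.
#' @param memo An [new_article_memo()] to share across genes, or `NULL`
#'   for an unshared scan.
#' @param gene_symbol Symbol recorded on the hits.
#' @return A hit data frame.
#' @export
search_articles <- function(articles, terms, memo = NULL, gene_symbol = "") {
  if (is.null(memo)) memo <- new_article_memo(terms)
  if (!identical(memo$patterns, terms$pattern)) {
    genekey_error("article memo was built under a different term list",
                  "genekey_contract_error")
  }
  out <- vector("list", 2L * length(articles) * nrow(terms))
  k <- 0L
  for (a in seq_along(articles)) {
    art <- articles[[a]]
    res <- memo$tab[[art$pmid]]
    if (is.null(res)) {
      res <- scan_article(art, terms)
      memo$tab[[art$pmid]] <- res
      memo$scans <- memo$scans + 1L
    }
    for (j in seq_len(nrow(terms))) {
      tsp <- res$title[[j]]
      if (!is.null(tsp)) {
        k <- k + 1L
        out[[k]] <- make_hits(gene_symbol, terms$rank[j], terms$pattern[j],
                              "PubMedTitle", a, list(tsp$start), list(tsp$end),
                              art$title)
      }
      asp <- res$abstract[[j]]
      if (!is.null(asp)) {
        k <- k + 1L
        out[[k]] <- make_hits(gene_symbol, terms$rank[j], terms$pattern[j],
                              "PubMedAbstract", a, list(asp$start),
                              list(asp$end), art$abstract)
      }
    }
  }
  bind_hits(out[seq_len(k)])
}
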