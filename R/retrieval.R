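# Offline-first record access: cache, then (optionally) a rate-limited
# online fetcher, saving fetched entries back into the cache.

#' Fetch policy
#'
#' @param mode `"offline_only"` (cache misses are absences) or
#'   `"online_allowed"` (cache misses fall back to the fetcher and the
#'   result is saved through to the cache). Online mode is intended for
#'   small gene lists (roughly under a hundred genes); larger runs should
#'   populate the cache from a snapshot first.
#' @param organism Scientific name used in gene queries.
#' @param rate_limit Maximum fetcher requests per rolling second
#'   (default 3, the public E-utilities courtesy limit without an API
#'   key).
#' @param contact_identity Identity string passed to the remote service.
#' @return A `fetch_policy` object.
#' @export
fetch_policy <- function(mode = c("offline_only", "online_allowed"),
                         organism = "Homo sapiens",
                         rate_limit = 3,
                         contact_identity = "genekeyr@example.org") {
  mode <- match.arg(mode)
  if (!is.numeric(rate_limit) || rate_limit <= 0) {
    genekey_error("rate_limit must be > 0", "genekey_input_error")
  }
  structure(list(mode = mode, organism = organism,
                 rate_limit = rate_limit,
                 contact_identity = contact_identity),
            class = "fetch_policy")
}

#' Rolling-window rate limiter
#'
#' Returns a function that, when called before each request, blocks (via
#' `sleep_fn`) until issuing the request would not exceed `rate` requests
#' in any rolling one-second window. Clock and sleep are injectable so the
#' limiter can be tested with a fake clock and no real waiting.
#'
#' @param rate Maximum requests per rolling second.
#' @param now_fn Zero-argument function returning the current time in
#'   seconds (numeric).
#' @param sleep_fn One-argument function sleeping for that many seconds.
#' @return A zero-argument function to call before each request; it
#'   returns (invisibly) the timestamp at which the request was admitted.
#' @export
rate_limiter <- function(rate, now_fn = function() as.numeric(Sys.time()),
                         sleep_fn = Sys.sleep) {
  stamps <- numeric(0)
  function() {
    now <- now_fn()
    stamps <<- stamps[stamps > now - 1]
    if (length(stamps) >= rate) {
      wait <- (stamps[1L] + 1) - now
      if (wait > 0) sleep_fn(wait)
      now <- now_fn()
      stamps <<- stamps[stamps > now - 1]
    }
    stamps <<- c(stamps, now)
    invisible(now)
  }
}

#' Wrap a fetcher with a rate limiter
#'
#' @param fetcher A fetcher (list with `fetch_gene(organism, symbol)` and
#'   `fetch_articles(pmids)`).
#' @param rate Maximum requests per rolling second.
#' @inheritParams rate_limiter
#' @return A fetcher observing the limit on every call.
#' @export
rate_limited_fetcher <- function(fetcher, rate,
                                 now_fn = function() as.numeric(Sys.time()),
                                 sleep_fn = Sys.sleep) {
  wait <- rate_limiter(rate, now_fn, sleep_fn)
  list(
    fetch_gene = function(organism, symbol) {
      wait()
      fetcher$fetch_gene(organism, symbol)
    },
    fetch_articles = function(pmids) {
      wait()
      fetcher$fetch_articles(pmids)
    }
  )
}

# Retry an action up to `times` attempts with exponential backoff.
# Exhausted retries re-raise the last error as a genekey_fetch_error.
with_retries <- function(action, times = 3L, base_wait = 0.2,
                         sleep_fn = Sys.sleep) {
  last <- NULL
  for (attempt in seq_len(times)) {
    res <- tryCatch(list(value = action()), error = function(e) e)
    if (!inherits(res, "error")) return(res$value)
    last <- res
    if (attempt < times) sleep_fn(base_wait * 2^(attempt - 1L))
  }
  genekey_error(sprintf("fetch failed after %d attempts: %s",
                        times, conditionMessage(last)),
                "genekey_fetch_error")
}

#' Resolve one gene record (cache, then optional online fetch)
#'
#' Looks the symbol up in the local cache first; on a miss, and only when
#' the policy allows online access, asks the fetcher, saves the fetched
#' document through to the cache, and parses it. A fetched record whose
#' official symbol differs from the requested symbol is treated as absent
#' (with a warning) rather than annotating the wrong gene. Fetch failures
#' are retried (3 attempts, exponential backoff) and then surfaced as a
#' per-gene warning, never an abort.
#'
#' @param policy A [fetch_policy()].
#' @param layout A [cache_layout()].
#' @param fetcher A fetcher, e.g. [make_fake_fetcher()] or
#'   [entrez_fetcher()]. May be `NULL` for pure-offline use.
#' @param symbol Gene symbol to resolve.
#' @param sleep_fn Sleep function used for retry backoff (injectable for
#'   tests).
#' @return A [gene_record()], or `NULL` when the gene cannot be resolved.
#' @export
get_gene_record <- function(policy, layout, fetcher, symbol,
                            sleep_fn = Sys.sleep) {
  raw_doc <- retrieve_gene(layout, symbol)
  if (!is.null(raw_doc)) {
    return(parse_gene_record(raw_doc))
  }
  if (policy$mode != "online_allowed" || is.null(fetcher)) return(NULL)
  raw_doc <- tryCatch(
    with_retries(function() fetcher$fetch_gene(policy$organism, symbol),
                 sleep_fn = sleep_fn),
    genekey_fetch_error = function(e) {
      genekey_warning(sprintf("gene '%s': %s", symbol, conditionMessage(e)),
                      "genekey_fetch_warning")
      NULL
    })
  if (is.null(raw_doc)) return(NULL)
  rec <- parse_gene_record(raw_doc)
  if (!identical(rec$official_symbol, symbol)) {
    genekey_warning(sprintf(
      "fetched record for '%s' has official symbol '%s'; treating as absent",
      symbol, rec$official_symbol), "genekey_symbol_mismatch")
    return(NULL)
  }
  store_gene(layout, symbol, raw_doc)
  rec
}

#' Resolve PubMed entries (cache, then one batched online fetch)
#'
#' Each requested PMID is looked up in the cache; the remaining set is
#' requested from the fetcher in a single batched call (when the policy
#' allows), and fetched entries are saved through to the cache. Entries
#' that cannot be resolved are omitted from the result with a warning.
#'
#' @inheritParams get_gene_record
#' @param pmids Character vector of PubMed IDs (duplicates collapsed).
#' @return Named list mapping PMID to [pubmed_article()]; unresolved PMIDs
#'   are absent.
#' @export
get_articles <- function(policy, layout, fetcher, pmids,
                         sleep_fn = Sys.sleep) {
  pmids <- unique(as.character(pmids))
  out <- list()
  uncached <- character(0)
  for (pmid in pmids) {
    raw_doc <- retrieve_article(layout, pmid)
    if (is.null(raw_doc)) uncached <- c(uncached, pmid)
    else out[[pmid]] <- parse_pubmed_entry(raw_doc)
  }
  if (length(uncached) && policy$mode == "online_allowed" &&
      !is.null(fetcher)) {
    fetched <- tryCatch(
      with_retries(function() fetcher$fetch_articles(uncached),
                   sleep_fn = sleep_fn),
      genekey_fetch_error = function(e) {
        genekey_warning(conditionMessage(e), "genekey_fetch_warning")
        list()
      })
    for (pmid in intersect(uncached, names(fetched))) {
      doc <- fetched[[pmid]]
      if (is.null(doc)) next
      store_article(layout, pmid, doc)
      out[[pmid]] <- parse_pubmed_entry(doc)
    }
    uncached <- setdiff(uncached, names(out))
  }
  if (length(uncached)) {
    genekey_warning(sprintf("PubMed entries not available: %s",
                            paste(uncached, collapse = ", ")),
                    "genekey_missing_articles")
  }
  out
}

#' Online Entrez fetcher (E-utilities)
#'
#' A fetcher implementing the remote-service contract against the NCBI
#' E-utilities: genes are located with `esearch` on
#' `"<symbol>[Official Symbol] AND <organism>[Organism]"` against the gene
#' database and retrieved with `efetch`; articles are retrieved by PMID
#' list from the pubmed database. Requires network access; wrap with
#' [rate_limited_fetcher()] (done automatically here using the policy's
#' rate limit). All tests of this package use injected fake fetchers; this
#' constructor exists for live use.
#'
#' Fetched documents are converted to the package's record dialect before
#' caching.
#'
#' @param policy A [fetch_policy()].
#' @param base_url Base URL of the E-utilities service.
#' @return A fetcher.
#' @export
entrez_fetcher <- function(policy,
                           base_url = "https://eutils.ncbi.nlm.nih.gov/entrez/eutils") {
  http_get <- function(url) {
    con <- url(url, open = "rb")
    on.exit(close(con), add = TRUE)
    chunks <- list()
    repeat {
      b <- readBin(con, "raw", n = 65536L)
      if (!length(b)) break
      chunks[[length(chunks) + 1L]] <- b
    }
    do.call(c, chunks)
  }
  q <- function(...) paste0(..., "&tool=genekeyr&email=",
                            utils::URLencode(policy$contact_identity,
                                             reserved = TRUE))
  raw_fetcher <- list(
    fetch_gene = function(organism, symbol) {
      term <- utils::URLencode(sprintf("%s[Official Symbol] AND %s[Organism]",
                                       symbol, organism), reserved = TRUE)
      ids <- xml2::xml_text(xml2::xml_find_all(
        xml2::read_xml(http_get(q(base_url, "/esearch.fcgi?db=gene&term=", term))),
        "//IdList/Id"))
      if (!length(ids)) return(NULL)
      doc <- xml2::read_xml(http_get(q(base_url,
                                       "/efetch.fcgi?db=gene&retmode=xml&id=",
                                       ids[1L])))
      entrezgene_to_record_xml(doc, organism)
    },
    fetch_articles = function(pmids) {
      doc <- xml2::read_xml(http_get(q(base_url,
                                       "/efetch.fcgi?db=pubmed&retmode=xml&id=",
                                       paste(pmids, collapse = ","))))
      arts <- xml2::xml_find_all(doc, "//PubmedArticle")
      out <- list()
      for (a in arts) {
        pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//PMID"))
        if (is.na(pmid)) next
        out[[pmid]] <- pubmed_to_entry_xml(a, pmid)
      }
      out
    }
  )
  rate_limited_fetcher(raw_fetcher, policy$rate_limit)
}

# Convert a native efetch Entrezgene document to the cache dialect
# (best-effort field mapping; untestable without network, kept minimal).
entrezgene_to_record_xml <- function(doc, organism) {
  first <- function(xp) {
    v <- xml2::xml_text(xml2::xml_find_first(doc, xp))
    if (is.na(v)) "" else v
  }
  symbol <- first("//Entrezgene_gene//Gene-ref_locus")
  gene_id <- first("//Entrezgene_track-info//Gene-track_geneid")
  rifs <- xml2::xml_text(xml2::xml_find_all(
    doc, "//Gene-commentary[Gene-commentary_type[@value='generif']]/Gene-commentary_text"))
  pmids <- unique(xml2::xml_text(xml2::xml_find_all(doc, "//PubMedId")))
  build_record_xml(
    gene_id = gene_id, symbol = symbol, organism = organism,
    entries = data.frame(
      field_name = c("Description", "Summary", rep("GeneRIF", length(rifs))),
      text = c(first("//Entrezgene_gene//Gene-ref_desc"),
               first("//Entrezgene_summary"), rifs),
      stringsAsFactors = FALSE),
    pmids = pmids)
}

pubmed_to_entry_xml <- function(node, pmid) {
  title <- xml2::xml_text(xml2::xml_find_first(node, ".//ArticleTitle"))
  parts <- xml2::xml_text(xml2::xml_find_all(node, ".//AbstractText"))
  build_article_xml(pmid, if (is.na(title)) "" else title,
                    paste(parts, collapse = " "))
}
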