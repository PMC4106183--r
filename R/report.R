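# Detailed HTML report: run metadata, per-gene match-summary tables and
# hidden-by-default highlighted match contexts.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Report model
#'
#' @param terms The [term_list()] searched.
#' @param sections Ordered list of per-gene sections — exactly the genes
#'   with at least one hit, in input order. Each section is a list with
#'   `symbol`, `gene_id` and `hits` (the gene's hit table).
#' @param command_line Command line recorded in the meta block.
#' @param timestamp Run timestamp.
#' @param version Tool version.
#' @return A `report_model`.
#' @export
report_model <- function(terms, sections, command_line = "",
                         timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
                         version = as.character(utils::packageVersion("genekeyr"))) {
  structure(list(terms = terms, sections = sections,
                 command_line = command_line, timestamp = timestamp,
                 version = version),
            class = "report_model")
}

#' Render a match context fragment
#'
#' Produces the HTML for one searched text with its matches wrapped in
#' `<span class="match">` highlights. All text is HTML-escaped; stripping
#' the tags from the fragment reproduces the escaped original text
#' exactly. Spans must be sorted, non-overlapping and within bounds.
#'
#' @param field_text The searched text.
#' @param starts,ends Integer vectors of 0-based, half-open match spans.
#' @return HTML fragment (character scalar).
#' @export
render_context <- function(field_text, starts, ends) {
  n <- nchar(field_text)
  if (length(starts) != length(ends) ||
      any(starts < 0L) || any(ends > n) || any(starts >= ends) ||
      (length(starts) > 1L && any(diff(starts) <= 0L)) ||
      (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)]))) {
    genekey_error("match spans must be sorted, non-overlapping and within bounds",
                  "genekey_contract_error")
  }
  out <- character(0)
  pos <- 0L
  for (i in seq_along(starts)) {
    if (starts[i] > pos) {
      out <- c(out, html_escape(substr(field_text, pos + 1L, starts[i])))
    }
    out <- c(out, "<span class=\"match\">",
             html_escape(substr(field_text, starts[i] + 1L, ends[i])),
             "</span>")
    pos <- ends[i]
  }
  if (pos < n) out <- c(out, html_escape(substr(field_text, pos + 1L, n)))
  paste(out, collapse = "")
}

# Split long field texts into windows of ~`width` characters around each
# match (merging overlapping windows) so contexts stay readable; each
# window is rendered with render_context and joined with ellipses.
context_windows <- function(field_text, starts, ends, width = 300L) {
  n <- nchar(field_text)
  if (n <= width || !length(starts)) {
    return(render_context(field_text, starts, ends))
  }
  half <- width %/% 2L
  lo <- pmax(0L, starts - half)
  hi <- pmin(n, ends + half)
  # merge overlapping windows
  merged_lo <- lo[1L]; merged_hi <- hi[1L]
  out <- character(0)
  flushw <- function(wlo, whi) {
    sel <- starts >= wlo & ends <= whi
    frag <- render_context(substr(field_text, wlo + 1L, whi),
                           starts[sel] - wlo, ends[sel] - wlo)
    paste0(if (wlo > 0L) "…", frag, if (whi < n) "…")
  }
  for (i in seq_along(lo)[-1L]) {
    if (lo[i] <= merged_hi) {
      merged_hi <- max(merged_hi, hi[i])
    } else {
      out <- c(out, flushw(merged_lo, merged_hi))
      merged_lo <- lo[i]; merged_hi <- hi[i]
    }
  }
  out <- c(out, flushw(merged_lo, merged_hi))
  paste(out, collapse = " ")
}

gene_url <- function(gene_id) {
  paste0("https://www.ncbi.nlm.nih.gov/gene/", gene_id)
}

#' Build the detailed HTML report
#'
#' A single self-contained HTML5 document: a meta block (tool version,
#' command line, timestamp, the ranked term list), then one section per
#' gene with at least one hit, in input order. Each gene section carries
#' hyperlinks to the public gene record (and its GeneRIF and PubMed
#' reference lists), a summary table with one row per matching
#' (term, field) pair — rank, field, number of matching field entries and
#' total match frequency — and a context section, hidden by default behind
#' a per-gene "hide/show details" toggle, showing every match highlighted
#' within its field text. With scripting disabled the contexts remain
#' visible. A run with no matching genes produces an explicit notice.
#'
#' @param model A [report_model()].
#' @return The HTML document as a character scalar.
#' @export
build_report <- function(model) {
  stopifnot(inherits(model, "report_model"))
  h <- character(0)
  add <- function(...) h <<- c(h, paste0(...))

  add("<!DOCTYPE html>")
  add("<html lang=\"en\"><head><meta charset=\"utf-8\">")
  add("<title>Gene key-term search report</title>")
  add("<style>")
  add("body{font-family:sans-serif;margin:2em;}",
      "table.term-summary{border-collapse:collapse;background:#e6f4e6;}",
      "table.term-summary th,table.term-summary td{border:1px solid #9c9;",
      "padding:0.3em 0.7em;}",
      "span.match{background:#ffe36e;font-weight:bold;}",
      ".contexts{margin:0.5em 0 1.5em 1em;}",
      ".context-entry{margin-bottom:0.6em;}",
      "h2{border-top:2px solid #ccc;padding-top:0.7em;}")
  add("</style>")
  add("<script>")
  add("function toggleDetails(id){var el=document.getElementById(id);",
      "el.style.display=(el.style.display==='none')?'block':'none';}")
  add("document.addEventListener('DOMContentLoaded',function(){",
      "var els=document.getElementsByClassName('contexts');",
      "for(var i=0;i<els.length;i++){els[i].style.display='none';}});")
  add("</script>")
  add("</head><body>")
  add("<h1>Gene key-term search report</h1>")

  add("<div class=\"meta\"><h2>Search</h2><dl>")
  add("<dt>Tool version</dt><dd>genekeyr ", html_escape(model$version), "</dd>")
  add("<dt>Command line</dt><dd><code>", html_escape(model$command_line),
      "</code></dd>")
  add("<dt>Date</dt><dd>", html_escape(model$timestamp), "</dd>")
  add("<dt>Search terms (rank: pattern)</dt><dd><ol>")
  for (j in seq_len(nrow(model$terms))) {
    add("<li><code>", html_escape(model$terms$pattern[j]), "</code></li>")
  }
  add("</ol></dd></dl></div>")

  if (!length(model$sections)) {
    add("<p class=\"no-matches\">No search terms matched any gene.</p>")
  }

  for (k in seq_along(model$sections)) {
    sec <- model$sections[[k]]
    hits <- sec$hits
    url <- gene_url(sec$gene_id)
    add("<section class=\"gene\">")
    add("<h2>", html_escape(sec$symbol), "</h2>")
    add("<p><a href=\"", url, "\">Gene record</a> | <a href=\"", url,
        "#gene-rifs\">GeneRIFs</a> | ",
        "<a href=\"https://pubmed.ncbi.nlm.nih.gov/?linkname=gene_pubmed",
        "&amp;from_uid=", sec$gene_id, "\">PubMed references</a></p>")

    add("<table class=\"term-summary\">")
    add("<tr><th>Term</th><th>Rank</th><th>Field</th>",
        "<th>Matching entries</th><th>Total matches</th></tr>")
    agg_key <- paste(hits$term_rank, hits$field_name, sep = "\r")
    for (key in unique(agg_key)) {
      rows <- hits[agg_key == key, , drop = FALSE]
      add("<tr><td><code>", html_escape(rows$term_pattern[1L]), "</code></td>",
          "<td>", rows$term_rank[1L], "</td>",
          "<td>", html_escape(rows$field_name[1L]), "</td>",
          "<td>", nrow(rows), "</td>",
          "<td>", sum(rows$n_matches), "</td></tr>")
    }
    add("</table>")

    ctx_id <- paste0("ctx-", k)
    add("<button onclick=\"toggleDetails('", ctx_id, "')\">",
        "hide/show details</button>")
    add("<div class=\"contexts\" id=\"", ctx_id, "\">")
    for (r in seq_len(nrow(hits))) {
      add("<div class=\"context-entry\"><b>", html_escape(hits$term_pattern[r]),
          "</b> in ", html_escape(hits$field_name[r]), " #",
          hits$field_ordinal[r], ":<br>",
          context_windows(hits$text[r], hits$match_starts[[r]],
                          hits$match_ends[[r]]),
          "</div>")
    }
    add("</div></section>")
  }

  add("</body></html>")
  paste(h, collapse = "\n")
}
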