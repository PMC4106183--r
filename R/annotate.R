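# The annotation pipeline: read the gene table, search each gene, append
# the three summary columns, stream the annotated CSV out.

SUMMARY_COLUMNS <- c("Highest Rank", "Highest Rank Term", "Total Matched Entries")

#' Run configuration
#'
#' @param genes_path Gene table: comma- or tab-separated text with at
#'   least one column headed exactly `Gene`.
#' @param terms_path Term file: one regular expression per line, line
#'   order = rank.
#' @param organism Organism searched (default human).
#' @param include_pubmed Also search the titles and abstracts of linked
#'   PubMed articles?
#' @param policy A [fetch_policy()].
#' @param cache_root Local cache directory.
#' @param report_path Optional path for the detailed HTML report.
#' @param output Destination for the annotated CSV: a path or a writable
#'   connection (default standard output).
#' @param fetcher Optional fetcher for online mode.
#' @param progress_fn Optional callback `function(i, symbol)` invoked
#'   after each gene's row has been emitted.
#' @return A `run_config` object.
#' @export
run_config <- function(genes_path, terms_path, organism = "Homo sapiens",
                       include_pubmed = FALSE,
                       policy = fetch_policy("offline_only", organism = organism),
                       cache_root = file.path(tempdir(), "genekey-cache"),
                       report_path = NULL, output = NULL, fetcher = NULL,
                       progress_fn = NULL) {
  if (missing(genes_path) || missing(terms_path)) {
    genekey_error("genes_path and terms_path are required", "genekey_input_error")
  }
  structure(list(genes_path = genes_path, terms_path = terms_path,
                 organism = organism, include_pubmed = include_pubmed,
                 policy = policy, cache_root = cache_root,
                 report_path = report_path, output = output,
                 fetcher = fetcher, progress_fn = progress_fn),
            class = "run_config")
}

#' Read a gene table
#'
#' The delimiter is auto-detected from the header line (tab if one is
#' present, else comma). All columns are preserved verbatim; the table
#' must contain a column headed exactly `Gene` (case-sensitive). Duplicate
#' gene symbols are allowed; each row is annotated independently.
#'
#' @param path Path to the gene table.
#' @return List with `header` (column names), `rows` (character data
#'   frame) and `gene_col` (index of the Gene column).
#' @export
read_gene_table <- function(path) {
  first <- tryCatch(readLines(path, n = 1L, warn = FALSE),
                    error = function(e) {
                      genekey_error(sprintf("cannot read gene table '%s'", path),
                                    "genekey_input_error")
                    })
  if (!length(first) || !nzchar(first)) {
    genekey_error(sprintf("gene table '%s' is empty", path),
                  "genekey_input_error")
  }
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  rows <- utils::read.table(path, sep = sep, header = TRUE,
                            colClasses = "character", check.names = FALSE,
                            quote = "\"", comment.char = "",
                            na.strings = character(), encoding = "UTF-8")
  gene_col <- unname(which(names(rows) == "Gene"))
  if (!length(gene_col)) {
    genekey_error("gene table has no column headed \"Gene\"",
                  "genekey_input_error")
  }
  list(header = names(rows), rows = rows, gene_col = gene_col[1L])
}

#' Summarise one gene's hits
#'
#' The three summary annotations: `highest_rank` is the smallest (most
#' important) rank among the gene's matching terms; `highest_rank_term` is
#' that term's pattern text; `total_matched_entries` is, summed over all
#' terms, the number of field entries in which the term matches at least
#' once — each repeated entry (each GeneRIF, each article title, each
#' article abstract) counts separately. All three are `NA` when the gene
#' has no hits.
#'
#' @param hits Hit data frame for one gene ([search_record()] /
#'   [search_articles()] output).
#' @param terms The [term_list()] searched.
#' @return A `gene_summary` list.
#' @export
summarize_hits <- function(hits, terms) {
  if (is.null(hits) || !nrow(hits)) {
    return(structure(list(highest_rank = NA_integer_,
                          highest_rank_term = NA_character_,
                          total_matched_entries = NA_integer_),
                     class = "gene_summary"))
  }
  r <- min(hits$term_rank)
  structure(list(highest_rank = r,
                 highest_rank_term = terms$pattern[terms$rank == r],
                 total_matched_entries = nrow(hits)),
            class = "gene_summary")
}

csv_cell <- function(x) {
  x <- ifelse(is.na(x), "", as.character(x))
  needs <- grepl("[\",\n\r]", x)
  x[needs] <- paste0("\"", gsub("\"", "\"\"", x[needs], fixed = TRUE), "\"")
  x
}

format_csv_row <- function(cells) paste(csv_cell(cells), collapse = ",")

summary_cells <- function(s) {
  c(ifelse(is.na(s$highest_rank), "", as.character(s$highest_rank)),
    ifelse(is.na(s$highest_rank_term), "", s$highest_rank_term),
    ifelse(is.na(s$total_matched_entries), "",
           as.character(s$total_matched_entries)))
}

#' Write an annotated gene table
#'
#' Appends the three summary columns (`Highest Rank`, `Highest Rank Term`,
#' `Total Matched Entries`) to every row and writes the result as CSV —
#' the output delimiter is a comma regardless of the input delimiter.
#' Empty summaries render as empty cells; row order is preserved; cells
#' containing commas, quotes or newlines are quoted per the CSV standard.
#'
#' @param header Input column names.
#' @param rows Character data frame of input rows.
#' @param summaries List of `gene_summary`, one per row.
#' @param destination Path or writable connection.
#' @return The CSV text, invisibly (one string per line).
#' @export
write_annotated_table <- function(header, rows, summaries, destination = stdout()) {
  stopifnot(nrow(rows) == length(summaries))
  lines <- c(format_csv_row(c(header, SUMMARY_COLUMNS)),
             vapply(seq_len(nrow(rows)), function(i) {
               format_csv_row(c(unlist(rows[i, , drop = TRUE], use.names = FALSE),
                                summary_cells(summaries[[i]])))
             }, character(1)))
  con <- if (is.character(destination)) {
    on.exit(close(con), add = TRUE)
    file(destination, "w")
  } else destination
  writeLines(lines, con)
  invisible(lines)
}

#' Run the annotation pipeline
#'
#' For each row of the gene table, in order: resolve the gene record
#' (cache first, then the fetcher when the policy allows), search every
#' record field against the ranked terms, optionally search linked PubMed
#' titles/abstracts through a run-wide article memo, summarise, and emit
#' the annotated row immediately (the output connection is flushed after
#' every gene, so an interrupted run keeps all rows already emitted).
#' Genes absent from the database get empty summaries and a warning.
#' Duplicate rows for one symbol are annotated identically without
#' re-searching. If `report_path` is set, the detailed HTML report is
#' written after the last gene.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `summaries` (per input row), `hits`
#'   (combined hit table), `terms`, and `table` (the parsed input).
#' @export
run_annotation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  terms <- load_terms(config$terms_path)
  tab <- read_gene_table(config$genes_path)
  layout <- cache_layout(config$cache_root, organism = config$organism)

  dest <- config$output
  con <- if (is.null(dest)) {
    stdout()
  } else if (is.character(dest)) {
    fcon <- file(dest, "w")
    on.exit(close(fcon), add = TRUE)
    fcon
  } else dest

  writeLines(format_csv_row(c(tab$header, SUMMARY_COLUMNS)), con)
  flush(con)

  memo <- new_article_memo(terms)
  by_symbol <- new.env(parent = emptyenv())
  summaries <- vector("list", nrow(tab$rows))
  sections <- list()
  seen_sections <- character(0)
  row_cells <- as.matrix(tab$rows)   # avoids slow data.frame row slicing

  for (i in seq_len(nrow(tab$rows))) {
    sym <- unname(row_cells[i, tab$gene_col])
    res <- by_symbol[[sym]]
    if (is.null(res)) {
      rec <- tryCatch(
        get_gene_record(config$policy, layout, config$fetcher, sym),
        genekey_error = function(e) {
          genekey_warning(sprintf("gene '%s': %s", sym, conditionMessage(e)),
                          "genekey_gene_skipped")
          NULL
        })
      if (is.null(rec)) {
        genekey_warning(sprintf("no database record for gene '%s'", sym),
                        "genekey_gene_absent")
        hits <- empty_hits()
      } else {
        hits <- search_record(rec, terms, gene_symbol = sym)
        if (config$include_pubmed && length(rec$pubmed_ids)) {
          arts <- get_articles(config$policy, layout, config$fetcher,
                               rec$pubmed_ids)
          arts <- arts[rec$pubmed_ids[rec$pubmed_ids %in% names(arts)]]
          if (length(arts)) {
            hits <- bind_hits(list(hits,
                                   search_articles(unname(arts), terms, memo,
                                                   gene_symbol = sym)))
          }
        }
      }
      res <- list(record = rec, hits = hits,
                  summary = summarize_hits(hits, terms))
      by_symbol[[sym]] <- res
    }
    summaries[[i]] <- res$summary
    writeLines(format_csv_row(c(row_cells[i, ],
                                summary_cells(res$summary))), con)
    flush(con)
    if (nrow(res$hits) && !(sym %in% seen_sections)) {
      sections[[length(sections) + 1L]] <- list(
        symbol = sym,
        gene_id = if (!is.null(res$record)) res$record$gene_id else "",
        hits = res$hits)
      seen_sections <- c(seen_sections, sym)
    }
    if (!is.null(config$progress_fn)) config$progress_fn(i, sym)
  }

  all_hits <- bind_hits(lapply(sections, `[[`, "hits"))
  if (!is.null(config$report_path)) {
    model <- report_model(terms = terms, sections = sections,
                          command_line = deparse_config(config))
    writeLines(build_report(model), config$report_path)
  }
  invisible(list(summaries = summaries, hits = all_hits, terms = terms,
                 table = tab))
}

deparse_config <- function(config) {
  sprintf("--genes %s --terms %s --organism \"%s\"%s%s",
          config$genes_path, config$terms_path, config$organism,
          if (config$include_pubmed) " --pubmed" else "",
          if (config$policy$mode == "online_allowed") " --online" else "")
}
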