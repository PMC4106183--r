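# Domain model for gene records and PubMed articles, and the XML parsers
# that build them.

#' Searchable fields of a gene record
#'
#' The named text fields of an Entrez-Gene-style record that the key-term
#' search scans. `GeneRIF` may occur many times in one record; each
#' occurrence is a separate searchable field entry with its own ordinal.
#' Linked PubMed articles contribute two further searchable units per
#' article, `PubMedTitle` and `PubMedAbstract`.
#'
#' @return Character vector of field labels.
#' @export
gene_search_fields <- function() {
  c("Description", "OtherAliases", "OtherDesignations", "Summary",
    "GeneRIF", "Pathways", "Process", "Function", "Component",
    "Interactions", "Phenotypes")
}

#' @rdname gene_search_fields
#' @export
article_search_fields <- function() c("PubMedTitle", "PubMedAbstract")

#' Construct a gene record
#'
#' @param gene_id GeneID as a string (numeric identifier assigned by the
#'   database).
#' @param official_symbol The record's official gene symbol; must be
#'   non-empty. Gene lists are joined to records on this symbol.
#' @param organism Scientific name of the organism.
#' @param entries Data frame with columns `field_name`, `ordinal` (1-based
#'   index among entries sharing a field name) and `text`. May have zero
#'   rows.
#' @param pubmed_ids Character vector of linked PubMed IDs; duplicates are
#'   removed keeping first-seen order.
#' @return An object of class `gene_record`.
#' @export
gene_record <- function(gene_id, official_symbol, organism,
                        entries = empty_entries(), pubmed_ids = character()) {
  if (!is_scalar_string(official_symbol) || !nzchar(official_symbol)) {
    genekey_error("gene record has no official symbol", "genekey_record_invalid")
  }
  stopifnot(is.data.frame(entries),
            all(c("field_name", "ordinal", "text") %in% names(entries)))
  if (nrow(entries)) {
    if (any(entries$ordinal < 1L)) {
      genekey_error("field entry ordinals must be >= 1", "genekey_record_invalid")
    }
    key <- paste(entries$field_name, entries$ordinal)
    if (anyDuplicated(key)) {
      genekey_error("duplicate (field_name, ordinal) in gene record entries",
                    "genekey_record_invalid")
    }
  }
  pubmed_ids <- as.character(pubmed_ids)
  pubmed_ids <- pubmed_ids[!duplicated(pubmed_ids)]
  structure(list(gene_id = as.character(gene_id),
                 official_symbol = official_symbol,
                 organism = as.character(organism),
                 entries = entries,
                 pubmed_ids = pubmed_ids),
            class = "gene_record")
}

empty_entries <- function() {
  data.frame(field_name = character(), ordinal = integer(),
             text = character(), stringsAsFactors = FALSE)
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record> %s (GeneID %s, %s): %d field entries, %d PubMed refs\n",
              x$official_symbol, x$gene_id, x$organism,
              nrow(x$entries), length(x$pubmed_ids)))
  invisible(x)
}

#' Construct a PubMed article
#'
#' @param pmid PubMed ID; must be a non-empty string of digits.
#' @param title Article title (may be empty).
#' @param abstract Abstract text; multi-part abstracts are stored as a
#'   single string (parts joined by one space).
#' @return An object of class `pubmed_article`.
#' @export
pubmed_article <- function(pmid, title = "", abstract = "") {
  if (!is_scalar_string(pmid) || !grepl("^[0-9]+$", pmid)) {
    genekey_error("PubMed article has a missing or non-numeric PMID",
                  "genekey_record_invalid")
  }
  structure(list(pmid = pmid, title = as.character(title),
                 abstract = as.character(abstract)),
            class = "pubmed_article")
}

#' @export
print.pubmed_article <- function(x, ...) {
  cat(sprintf("<pubmed_article> PMID %s: %s\n", x$pmid, x$title))
  invisible(x)
}

# Read raw bytes / XML text / file path into an xml2 document, mapping
# libxml2 failures to a genekey_parse_error naming the location libxml2
# reports (line:column).
read_xml_doc <- function(x) {
  tryCatch(
    {
      if (is.raw(x)) {
        xml2::read_xml(x)
      } else if (inherits(x, "connection")) {
        xml2::read_xml(x)
      } else if (is_scalar_string(x)) {
        xml2::read_xml(x)
      } else {
        genekey_error("expected raw bytes, a string, or a connection",
                      "genekey_parse_error")
      }
    },
    error = function(e) {
      if (inherits(e, "genekey_error")) stop(e)
      genekey_error(paste0("malformed XML: ", conditionMessage(e)),
                    "genekey_parse_error")
    }
  )
}

#' Parse one Entrez-Gene-style XML record
#'
#' Reads a single `<EntrezgeneRecord>` document (as stored in the local
#' cache, one record per file) into a [gene_record()]. Entries cover
#' exactly the searchable fields present in the document, in document
#' order; repeated fields such as `GeneRIF` receive consecutive ordinals.
#' `<PubMedId>` references are collected with duplicates dropped,
#' preserving first-seen order.
#'
#' @param x Raw bytes, a character scalar holding XML text, a file path,
#'   or a connection.
#' @return A [gene_record()].
#' @export
parse_gene_record <- function(x) {
  doc <- read_xml_doc(x)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "EntrezgeneRecord") {
    genekey_error(sprintf("expected an EntrezgeneRecord document, found <%s>",
                          xml2::xml_name(root)),
                  "genekey_record_invalid")
  }
  kids <- xml2::xml_children(root)
  nm <- xml2::xml_name(kids)
  txt <- xml2::xml_text(kids)

  symbol <- txt[nm == "OfficialSymbol"][1]
  if (is.na(symbol) || !nzchar(symbol)) {
    genekey_error("gene record has no official symbol", "genekey_record_invalid")
  }
  gene_id <- txt[nm == "GeneID"][1]
  organism <- txt[nm == "Organism"][1]
  if (is.na(organism)) organism <- ""

  is_field <- nm %in% gene_search_fields()
  field_name <- nm[is_field]
  entries <- data.frame(
    field_name = field_name,
    ordinal = as.integer(stats::ave(seq_along(field_name), field_name,
                                    FUN = seq_along)),
    text = txt[is_field],
    stringsAsFactors = FALSE
  )
  gene_record(gene_id = if (is.na(gene_id)) "" else gene_id,
              official_symbol = symbol,
              organism = organism,
              entries = entries,
              pubmed_ids = txt[nm == "PubMedId"])
}

#' Parse one PubMed-style XML entry
#'
#' Reads a single `<PubmedArticle>` document into a [pubmed_article()].
#' Multi-part abstracts (repeated `<AbstractText>` elements) are joined in
#' document order with a single space so that character offsets into the
#' abstract are well defined.
#'
#' @inheritParams parse_gene_record
#' @return A [pubmed_article()].
#' @export
parse_pubmed_entry <- function(x) {
  doc <- read_xml_doc(x)
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "PubmedArticle") {
    genekey_error(sprintf("expected a PubmedArticle document, found <%s>",
                          xml2::xml_name(root)),
                  "genekey_record_invalid")
  }
  pmid <- xml2::xml_text(xml2::xml_find_first(doc, "./PMID"))
  if (is.na(pmid) || !nzchar(pmid)) {
    genekey_error("PubMed entry has no PMID", "genekey_record_invalid")
  }
  title <- xml2::xml_text(xml2::xml_find_first(doc, "./ArticleTitle"))
  if (is.na(title)) title <- ""
  parts <- xml2::xml_text(xml2::xml_find_all(doc, "./AbstractText"))
  pubmed_article(pmid = pmid, title = title,
                 abstract = paste(parts, collapse = " "))
}
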