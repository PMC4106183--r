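# Local file cache: sharded layout, atomic storage, snapshot population.

#' Describe a cache directory layout
#'
#' Gene records live at `<root>/<organism>/<shard>/<SYMBOL>.xml` and
#' article records at `<root>/pubmed/<shard>/<PMID>.xml`, where `<shard>`
#' is the two-hex-digit shard directory chosen by [shard_of()]. Sharding
#' spreads the files over 256 sub-directories to keep any one directory
#' small. Symbols are stored verbatim; symbols differing only by case are
#' distinct logical genes.
#'
#' @param root Cache root directory (created on demand).
#' @param organism Scientific name of the organism the gene shelf holds.
#' @param shard_count Number of shard sub-directories; fixed at 256.
#' @return A `cache_layout` object.
#' @export
cache_layout <- function(root, organism = "Homo sapiens", shard_count = 256L) {
  stopifnot(is_scalar_string(root), is_scalar_string(organism),
            identical(as.integer(shard_count), 256L))
  structure(list(root = root, organism = organism, shard_count = 256L),
            class = "cache_layout")
}

#' Stable shard index of a gene symbol or PMID
#'
#' The shard is the first byte of the MD5 digest of the UTF-8 encoding of
#' the name, so it is deterministic across runs, processes and platforms.
#'
#' @param name Character vector of non-empty gene symbols or PMIDs.
#' @return Integer vector of shard indices in `[0, 255]`.
#' @export
shard_of <- function(name) {
  stopifnot(is.character(name), length(name) > 0L, all(nzchar(name)))
  files <- vapply(name, function(s) {
    f <- tempfile("shard")
    writeBin(charToRaw(enc2utf8(s)), f)
    f
  }, character(1), USE.NAMES = FALSE)
  on.exit(unlink(files), add = TRUE)
  digests <- tools::md5sum(files)
  strtoi(substr(unname(digests), 1L, 2L), base = 16L)
}

shard_dirname <- function(shard) sprintf("%02x", shard)

gene_path <- function(layout, gene_symbol) {
  file.path(layout$root, layout$organism,
            shard_dirname(shard_of(gene_symbol)),
            paste0(gene_symbol, ".xml"))
}

article_path <- function(layout, pmid) {
  file.path(layout$root, "pubmed", shard_dirname(shard_of(pmid)),
            paste0(pmid, ".xml"))
}

as_xml_bytes <- function(x) {
  if (is.raw(x)) x else charToRaw(enc2utf8(paste(x, collapse = "\n")))
}

# Atomic write: write to a temporary file in the destination directory,
# then rename over the target, so a crash never leaves a truncated record
# that a later run would trust.
atomic_write <- function(path, bytes) {
  dir <- dirname(path)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE) &&
      !dir.exists(dir)) {
    genekey_error(sprintf("cannot create cache directory '%s'", dir),
                  "genekey_io_error")
  }
  tmp <- tempfile(basename(path), tmpdir = dir)
  ok <- tryCatch({ writeBin(bytes, tmp); TRUE },
                 error = function(e) FALSE)
  if (!ok || !file.rename(tmp, path)) {
    unlink(tmp)
    genekey_error(sprintf("cannot write cache file '%s'", path),
                  "genekey_io_error")
  }
  invisible(path)
}

read_bytes <- function(path) {
  n <- file.size(path)
  tryCatch(readBin(path, "raw", n = n),
           error = function(e) {
             genekey_error(sprintf("cannot read cache file '%s': %s",
                                   path, conditionMessage(e)),
                           "genekey_io_error")
           })
}

#' Store and retrieve cached gene records
#'
#' `store_gene()` writes the XML document for a gene atomically
#' (write-then-rename), overwriting any prior version, and returns the
#' file path. `retrieve_gene()` returns the stored bytes, or `NULL` when
#' the gene is not cached (absence is not an error).
#'
#' @param layout A [cache_layout()].
#' @param gene_symbol Gene symbol the record is filed under.
#' @param xml_document Raw bytes or character XML text.
#' @return `store_gene()`: the path written; `retrieve_gene()`: raw bytes
#'   or `NULL`.
#' @export
store_gene <- function(layout, gene_symbol, xml_document) {
  atomic_write(gene_path(layout, gene_symbol), as_xml_bytes(xml_document))
}

#' @rdname store_gene
#' @export
retrieve_gene <- function(layout, gene_symbol) {
  p <- gene_path(layout, gene_symbol)
  if (!file.exists(p)) return(NULL)
  read_bytes(p)
}

#' Store and retrieve cached PubMed entries
#'
#' As [store_gene()]/[retrieve_gene()], but filed under
#' `<root>/pubmed/<shard>/<PMID>.xml`. The article cache is populated only
#' from online fetches, never from a bulk snapshot.
#'
#' @inheritParams store_gene
#' @param pmid PubMed ID the entry is filed under.
#' @return `store_article()`: the path written; `retrieve_article()`: raw
#'   bytes or `NULL`.
#' @export
store_article <- function(layout, pmid, xml_document) {
  atomic_write(article_path(layout, pmid), as_xml_bytes(xml_document))
}

#' @rdname store_article
#' @export
retrieve_article <- function(layout, pmid) {
  p <- article_path(layout, pmid)
  if (!file.exists(p)) return(NULL)
  read_bytes(p)
}

#' Populate the gene cache from a database snapshot
#'
#' Reads a snapshot — a well-formed `<EntrezgeneSet>` wrapping a sequence
#' of `<EntrezgeneRecord>` elements — and writes one cache file per
#' record, filed under its official symbol. The snapshot is consumed
#' incrementally in fixed-size chunks, holding at most one record plus a
#' read buffer in memory, so snapshots far larger than memory (full-
#' organism dumps run to tens of gigabytes) can be ingested. A later
#' record with the same symbol overwrites an earlier one with a warning.
#' A malformed record aborts with an error naming its ordinal; records
#' already processed remain on disk.
#'
#' @param layout A [cache_layout()].
#' @param snapshot File path, connection, raw bytes, or a character scalar
#'   of XML text.
#' @param chunk_size Bytes read per chunk.
#' @return Number of gene records written (invisibly 0 with a warning for
#'   an empty set).
#' @export
populate_from_snapshot <- function(layout, snapshot, chunk_size = 65536L) {
  con <- open_snapshot(snapshot)
  on.exit(close(con), add = TRUE)
  end_tag <- charToRaw("</EntrezgeneRecord>")
  start_tag <- charToRaw("<EntrezgeneRecord")
  buffer <- raw(0)
  n_written <- 0L
  seen <- new.env(parent = emptyenv())
  repeat {
    chunk <- readBin(con, "raw", n = chunk_size)
    eof <- length(chunk) == 0L
    if (!eof) buffer <- c(buffer, chunk)
    repeat {
      e <- grepRaw(end_tag, buffer, fixed = TRUE)
      if (!length(e)) break
      e <- e[1L]
      s <- grepRaw(start_tag, buffer, fixed = TRUE)
      if (!length(s) || s[1L] > e) {
        genekey_error(sprintf("snapshot record %d is malformed", n_written + 1L),
                      "genekey_parse_error")
      }
      rec_bytes <- buffer[s[1L]:(e + length(end_tag) - 1L)]
      buffer <- buffer[-seq_len(e + length(end_tag) - 1L)]
      rec <- tryCatch(parse_gene_record(rec_bytes),
                      genekey_error = function(err) {
                        genekey_error(sprintf("snapshot record %d: %s",
                                              n_written + 1L,
                                              conditionMessage(err)),
                                      "genekey_parse_error")
                      })
      if (!is.null(seen[[rec$official_symbol]])) {
        genekey_warning(sprintf(
          "snapshot contains duplicate symbol '%s'; later record overwrites earlier",
          rec$official_symbol), "genekey_duplicate_record")
      }
      seen[[rec$official_symbol]] <- TRUE
      store_gene(layout, rec$official_symbol, rec_bytes)
      n_written <- n_written + 1L
    }
    if (eof) break
  }
  if (length(grepRaw(start_tag, buffer, fixed = TRUE))) {
    genekey_error(sprintf("snapshot record %d is truncated", n_written + 1L),
                  "genekey_parse_error")
  }
  if (n_written == 0L) {
    genekey_warning("snapshot contained no gene records", "genekey_empty_snapshot")
  }
  n_written
}

open_snapshot <- function(snapshot) {
  if (inherits(snapshot, "connection")) {
    if (!isOpen(snapshot)) open(snapshot, "rb")
    return(snapshot)
  }
  if (is.raw(snapshot)) return(rawConnection(snapshot, "r"))
  if (is_scalar_string(snapshot)) {
    if (startsWith(trimws(substr(snapshot, 1L, 64L)), "<")) {
      return(rawConnection(charToRaw(enc2utf8(snapshot)), "r"))
    }
    return(file(snapshot, "rb"))
  }
  genekey_error("snapshot must be a path, connection, raw vector or XML text",
                "genekey_input_error")
}
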