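# Synthetic-corpus generator: Entrez-Gene-like and PubMed-like XML with
# planted, exactly counted term occurrences, plus a fake fetcher. Every
# module of the package is testable offline against these corpora.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x
}

#' Build one Entrez-Gene-style record document
#'
#' @param gene_id,symbol,organism Scalar record identifiers.
#' @param entries Data frame with columns `field_name` and `text`, emitted
#'   in row order (ordinals are implied by document order).
#' @param pmids Character vector of linked PubMed IDs.
#' @return XML text (character scalar).
#' @export
build_record_xml <- function(gene_id, symbol, organism, entries, pmids = character()) {
  body <- c(
    sprintf("  <GeneID>%s</GeneID>", xml_escape(gene_id)),
    sprintf("  <OfficialSymbol>%s</OfficialSymbol>", xml_escape(symbol)),
    sprintf("  <Organism>%s</Organism>", xml_escape(organism)),
    if (nrow(entries)) sprintf("  <%s>%s</%s>", entries$field_name,
                               xml_escape(entries$text), entries$field_name),
    if (length(pmids)) sprintf("  <PubMedId>%s</PubMedId>", xml_escape(pmids))
  )
  paste(c("<EntrezgeneRecord>", body, "</EntrezgeneRecord>"), collapse = "\n")
}

#' Build one PubMed-style entry document
#'
#' @param pmid,title,abstract Scalar entry content. `abstract` may be a
#'   character vector; each element becomes one `<AbstractText>` section.
#' @return XML text (character scalar).
#' @export
build_article_xml <- function(pmid, title, abstract = character()) {
  abstract <- abstract[nzchar(abstract)]
  body <- c(
    sprintf("  <PMID>%s</PMID>", xml_escape(pmid)),
    sprintf("  <ArticleTitle>%s</ArticleTitle>", xml_escape(title)),
    if (length(abstract)) sprintf("  <AbstractText>%s</AbstractText>",
                                  xml_escape(abstract))
  )
  paste(c("<PubmedArticle>", body, "</PubmedArticle>"), collapse = "\n")
}

default_filler <- function() {
  # Invented non-word tokens: guaranteed disjoint from any real key term
  # and from each other as substrings. The generator emulates the *shape*
  # of record prose (tokenised free text), not biomedical language.
  c("flib", "grun", "zorp", "quam", "brel", "stov", "plin", "drak",
    "mose", "vint", "crel", "dunt", "harv", "jent", "kolb", "nurm")
}

#' Plan one gene of a synthetic corpus
#'
#' @param symbol,gene_id,organism Record identifiers.
#' @param entries List of field-entry plans, each created by
#'   [entry_plan()].
#' @param pmids PubMed IDs the record references, in order.
#' @return A `gene_plan` list.
#' @export
gene_plan <- function(symbol, gene_id, organism = "Homo sapiens",
                      entries = list(), pmids = character()) {
  structure(list(symbol = symbol, gene_id = as.character(gene_id),
                 organism = organism, entries = entries,
                 pmids = as.character(pmids)),
            class = "gene_plan")
}

#' @rdname gene_plan
#' @param field_name Searchable field this entry belongs to (see
#'   [gene_search_fields()]).
#' @param plants Named integer vector: literal term -> number of planted
#'   occurrences in this entry's text. May be empty.
#' @param n_filler Number of filler tokens interleaved around the planted
#'   occurrences.
#' @export
entry_plan <- function(field_name, plants = integer(), n_filler = 8L) {
  stopifnot(field_name %in% gene_search_fields())
  structure(list(field_name = field_name, plants = plants,
                 n_filler = as.integer(n_filler)),
            class = "entry_plan")
}

#' @rdname gene_plan
#' @param pmid PubMed ID of the planned article.
#' @param title_plants,abstract_plants Named integer vectors of planted
#'   occurrences for the article title and abstract.
#' @export
article_plan <- function(pmid, title_plants = integer(),
                         abstract_plants = integer(), n_filler = 8L) {
  structure(list(pmid = as.character(pmid), title_plants = title_plants,
                 abstract_plants = abstract_plants,
                 n_filler = as.integer(n_filler)),
            class = "article_plan")
}

#' Plan a synthetic corpus
#'
#' A corpus plan fixes, before any text is generated, exactly how many
#' times each literal term occurs in each field entry of each gene and in
#' each article title/abstract. [generate_corpus()] turns the plan into
#' XML plus a ground-truth table and *verifies at generation time* that the
#' realised texts contain each planned term exactly the planned number of
#' times (so filler collisions or term/term overlaps are an error, never a
#' silent miscount).
#'
#' @param genes List of [gene_plan()]s (symbols must be unique).
#' @param articles List of [article_plan()]s (PMIDs must be unique).
#' @param filler_vocabulary Word list used for filler text; no word may
#'   contain a planted term as a substring.
#' @param seed RNG seed making generation deterministic.
#' @return A `corpus_plan`.
#' @export
corpus_plan <- function(genes, articles = list(),
                        filler_vocabulary = default_filler(), seed = 1L) {
  syms <- vapply(genes, `[[`, "", "symbol")
  if (anyDuplicated(syms)) {
    genekey_error("corpus plan has duplicate gene symbols", "genekey_input_error")
  }
  pmids <- vapply(articles, `[[`, "", "pmid")
  if (anyDuplicated(pmids)) {
    genekey_error("corpus plan has duplicate PMIDs", "genekey_input_error")
  }
  structure(list(genes = genes, articles = articles,
                 filler_vocabulary = filler_vocabulary,
                 seed = as.integer(seed)),
            class = "corpus_plan")
}

plan_terms <- function(plan) {
  terms <- character(0)
  for (g in plan$genes) for (e in g$entries) terms <- c(terms, names(e$plants))
  for (a in plan$articles) terms <- c(terms, names(a$title_plants),
                                      names(a$abstract_plants))
  unique(terms)
}

# Count non-overlapping left-to-right occurrences of a literal term.
count_fixed <- function(text, term) {
  m <- gregexpr(term, text, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

# Assemble one text with exact planted counts: planted occurrences are
# placed at random positions in a stream of filler tokens, all separated
# by single spaces. Realised counts are verified corpus-wide afterwards
# (see verify_counts).
plant_text <- function(plants, n_filler, filler) {
  occurrences <- rep(names(plants), times = plants)
  tokens <- sample(filler, n_filler, replace = TRUE)
  if (length(occurrences)) {
    # slot k in 0..n_filler: the occurrence is inserted after the k-th token
    slots <- sample.int(length(tokens) + 1L, length(occurrences),
                        replace = TRUE) - 1L
    ord <- order(slots)
    occurrences <- occurrences[ord]
    slots <- slots[ord]
    out <- character(0)
    prev <- 0L
    for (i in seq_along(occurrences)) {
      if (slots[i] > prev) {
        out <- c(out, tokens[(prev + 1L):slots[i]])
        prev <- slots[i]
      }
      out <- c(out, occurrences[i])
    }
    if (prev < length(tokens)) out <- c(out, tokens[(prev + 1L):length(tokens)])
    text <- paste(out, collapse = " ")
  } else {
    text <- paste(tokens, collapse = " ")
  }
  text
}

# Corpus-wide generation-time check: every text must realise every term in
# the corpus's term universe exactly the planned number of times. One
# vectorised fixed-string scan per term.
verify_counts <- function(texts, plant_list, all_terms) {
  for (t in all_terms) {
    ms <- gregexpr(t, texts, fixed = TRUE)
    got <- vapply(ms, function(m) if (m[1L] == -1L) 0L else length(m),
                  integer(1))
    want <- vapply(plant_list, function(p) {
      if (t %in% names(p)) as.integer(p[[t]]) else 0L
    }, integer(1))
    if (any(got != want)) {
      i <- which(got != want)[1L]
      genekey_error(sprintf(
        "generated text realises term '%s' %d time(s), planned %d (filler collision or overlapping terms)",
        t, got[i], want[i]), "genekey_generation_error")
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic corpus from a plan
#'
#' @param plan A [corpus_plan()].
#' @return A `corpus` list with elements: `snapshot` (one
#'   `<EntrezgeneSet>` XML text concatenating all gene records),
#'   `gene_xml` (named character vector, per-record XML), `article_xml`
#'   (named character vector keyed by PMID), `truth` (data frame with one
#'   row per (gene, term, field entry) giving the exact planted count;
#'   article units appear per referencing gene with `field_ordinal` equal
#'   to the article's position in that gene's reference list), and `plan`.
#'   Generation is deterministic given the plan's seed.
#' @export
generate_corpus <- function(plan) {
  stopifnot(inherits(plan, "corpus_plan"))
  all_terms <- plan_terms(plan)
  for (t in all_terms) {
    if (any(vapply(plan$filler_vocabulary,
                   function(w) grepl(t, w, fixed = TRUE) || grepl(w, t, fixed = TRUE),
                   logical(1)))) {
      genekey_error(sprintf(
        "filler vocabulary collides with planted term '%s'", t),
        "genekey_generation_error")
    }
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()),
          add = TRUE)
  set.seed(plan$seed)

  t_sym <- character(0); t_term <- character(0); t_field <- character(0)
  t_ord <- integer(0); t_count <- integer(0)
  add_truth <- function(symbol, term, field_name, field_ordinal, count) {
    i <- length(t_sym) + 1L
    t_sym[i] <<- symbol; t_term[i] <<- term; t_field[i] <<- field_name
    t_ord[i] <<- as.integer(field_ordinal); t_count[i] <<- as.integer(count)
  }

  gen_texts <- character(0)   # every generated text, for verify_counts
  gen_plants <- list()        # its planned counts, aligned with gen_texts
  note_text <- function(text, plants) {
    gen_texts[[length(gen_texts) + 1L]] <<- text
    gen_plants[[length(gen_plants) + 1L]] <<- plants
    text
  }

  # Articles first so gene truth can refer to their realised counts.
  article_xml <- character(0)
  article_counts <- list()   # pmid -> list(title = named counts, abstract = ...)
  for (a in plan$articles) {
    title <- note_text(plant_text(a$title_plants, max(3L, a$n_filler %/% 2L),
                                  plan$filler_vocabulary), a$title_plants)
    abstract <- note_text(plant_text(a$abstract_plants, a$n_filler,
                                     plan$filler_vocabulary), a$abstract_plants)
    article_xml[[a$pmid]] <- build_article_xml(a$pmid, title, abstract)
    article_counts[[a$pmid]] <- list(title = a$title_plants,
                                     abstract = a$abstract_plants)
  }

  gene_xml <- character(0)
  for (g in plan$genes) {
    field_names <- vapply(g$entries, `[[`, "", "field_name")
    ordinals <- as.integer(stats::ave(seq_along(field_names), field_names,
                                      FUN = seq_along))
    texts <- character(length(g$entries))
    for (i in seq_along(g$entries)) {
      e <- g$entries[[i]]
      texts[i] <- note_text(plant_text(e$plants, e$n_filler,
                                       plan$filler_vocabulary), e$plants)
      for (t in names(e$plants)) {
        if (e$plants[[t]] > 0L) {
          add_truth(g$symbol, t, e$field_name, ordinals[i], e$plants[[t]])
        }
      }
    }
    gene_xml[[g$symbol]] <- build_record_xml(
      g$gene_id, g$symbol, g$organism,
      data.frame(field_name = field_names, text = texts,
                 stringsAsFactors = FALSE),
      g$pmids)
    for (j in seq_along(g$pmids)) {
      ac <- article_counts[[g$pmids[j]]]
      if (is.null(ac)) next
      for (t in names(ac$title)) {
        if (ac$title[[t]] > 0L) {
          add_truth(g$symbol, t, "PubMedTitle", j, ac$title[[t]])
        }
      }
      for (t in names(ac$abstract)) {
        if (ac$abstract[[t]] > 0L) {
          add_truth(g$symbol, t, "PubMedAbstract", j, ac$abstract[[t]])
        }
      }
    }
  }

  verify_counts(gen_texts, gen_plants, all_terms)

  truth <- data.frame(symbol = t_sym, term = t_term, field_name = t_field,
                      field_ordinal = t_ord, count = t_count,
                      stringsAsFactors = FALSE)
  snapshot <- paste(c("<EntrezgeneSet>", unname(gene_xml), "</EntrezgeneSet>"),
                    collapse = "\n")
  structure(list(snapshot = snapshot, gene_xml = gene_xml,
                 article_xml = article_xml, truth = truth, plan = plan),
            class = "corpus")
}

#' Fake fetcher serving a synthetic corpus
#'
#' Serves the corpus's documents and records every call, so retrieval
#' tests can assert cache-first behaviour and call counts without any
#' network access. Unknown symbols/PMIDs are absent.
#'
#' @param corpus A [generate_corpus()] result.
#' @param fail_times Number of times each call errors before succeeding
#'   (to exercise retry logic).
#' @return A fetcher with observables: `$gene_calls` / `$article_calls`
#'   (zero-argument functions returning the recorded call logs).
#' @export
make_fake_fetcher <- function(corpus, fail_times = 0L) {
  log <- new.env(parent = emptyenv())
  log$genes <- character(0)
  log$articles <- list()
  log$failures <- 0L
  maybe_fail <- function() {
    if (log$failures < fail_times) {
      log$failures <- log$failures + 1L
      stop("simulated transient fetch failure")
    }
  }
  list(
    fetch_gene = function(organism, symbol) {
      maybe_fail()
      log$genes <- c(log$genes, symbol)
      xml <- corpus$gene_xml[symbol]
      if (is.na(xml)) return(NULL)
      charToRaw(enc2utf8(unname(xml)))
    },
    fetch_articles = function(pmids) {
      maybe_fail()
      log$articles <- c(log$articles, list(pmids))
      found <- intersect(pmids, names(corpus$article_xml))
      out <- lapply(corpus$article_xml[found],
                    function(x) charToRaw(enc2utf8(x)))
      names(out) <- found
      out
    },
    gene_calls = function() log$genes,
    article_calls = function() log$articles
  )
}

#' Random corpus plan
#'
#' Draws a corpus of `n_genes` genes and `n_articles` articles with terms
#' planted at random: each gene is positive (receives at least one planted
#' occurrence of some term, possibly via a linked article) with
#' probability `p_positive`; negatives receive none. Terms are literal
#' tokens chosen to be substring-free of the filler vocabulary and of each
#' other, so planted counts are exact.
#'
#' @param seed RNG seed (also the generation seed).
#' @param n_genes,n_articles Corpus dimensions.
#' @param n_terms Number of distinct literal terms.
#' @param p_positive Probability a gene receives planted occurrences.
#' @param organism Organism stamped on every record.
#' @return A [corpus_plan()]; the literal terms are attached as
#'   `attr(plan, "terms")`.
#' @export
random_corpus_plan <- function(seed, n_genes = 200L, n_terms = 20L,
                               n_articles = 40L, p_positive = 0.5,
                               organism = "Homo sapiens") {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()),
          add = TRUE)
  set.seed(seed)
  terms <- sprintf("querix%02d", seq_len(n_terms))
  fields <- gene_search_fields()

  rand_plants <- function() {
    k <- sample(1:2, 1L)
    p <- sample(terms, k)
    stats::setNames(sample(1:3, k, replace = TRUE), p)
  }
  articles <- lapply(seq_len(n_articles), function(i) {
    pos <- stats::runif(1) < p_positive
    article_plan(
      pmid = as.character(100000L + i),
      title_plants = if (pos && stats::runif(1) < 0.5) rand_plants() else integer(),
      abstract_plants = if (pos) rand_plants() else integer()
    )
  })
  pos_pmids <- vapply(Filter(function(a) {
    length(a$title_plants) + length(a$abstract_plants) > 0
  }, articles), `[[`, "", "pmid")
  neg_pmids <- setdiff(vapply(articles, `[[`, "", "pmid"), pos_pmids)

  genes <- lapply(seq_len(n_genes), function(i) {
    sym <- sprintf("GENE%04d", i)
    positive <- stats::runif(1) < p_positive
    n_entries <- sample(3:8, 1L)
    fnames <- c(sample(fields, min(n_entries, 3L)),
                sample(c("GeneRIF", fields), max(0L, n_entries - 3L),
                       replace = TRUE))
    entries <- lapply(fnames, function(f) entry_plan(f))
    pmids <- character(0)
    if (positive) {
      # plant in 1-3 gene fields, or rely solely on a linked article
      via_article <- length(pos_pmids) > 0 && stats::runif(1) < 0.15
      if (via_article) {
        pmids <- sample(pos_pmids, 1L)
      } else {
        for (k in sample(seq_along(entries), sample(1:min(3L, length(entries)), 1L))) {
          entries[[k]] <- entry_plan(fnames[k], rand_plants())
        }
        if (length(pos_pmids) && stats::runif(1) < 0.3) {
          pmids <- sample(pos_pmids, 1L)
        }
      }
    } else if (length(neg_pmids) && stats::runif(1) < 0.3) {
      pmids <- sample(neg_pmids, 1L)
    }
    gene_plan(sym, gene_id = as.character(1000L + i), organism = organism,
              entries = entries, pmids = pmids)
  })
  plan <- corpus_plan(genes, articles, seed = seed)
  attr(plan, "terms") <- terms
  plan
}

#' The worked-example corpus
#'
#' A three-gene corpus mirroring the package's introductory example: RPA1
#' carries the literal "DNA repair" once in its Process and Pathways
#' fields and once in each of eight GeneRIF entries (so the rank-2 pattern
#' `DNA [Rr]epair` yields 10 matched entries); BRCA1 carries "breast
#' cancer" (matched by the rank-1 pattern `[Bb]reast [Cc]ancer`); CANT1
#' carries nothing and annotates as empty.
#'
#' @param seed Generation seed.
#' @return A [corpus_plan()].
#' @export
example_corpus_plan <- function(seed = 42L) {
  rpa1_entries <- c(
    list(entry_plan("Summary"),
         entry_plan("Process", c("DNA repair" = 1L)),
         entry_plan("Pathways", c("DNA repair" = 1L))),
    rep(list(entry_plan("GeneRIF", c("DNA repair" = 1L))), 8L)
  )
  brca1_entries <- list(
    entry_plan("Summary", c("breast cancer" = 2L)),
    entry_plan("Description", c("breast cancer" = 1L)),
    entry_plan("GeneRIF", c("DNA repair" = 1L))
  )
  cant1_entries <- list(entry_plan("Summary"), entry_plan("GeneRIF"))
  corpus_plan(
    genes = list(
      gene_plan("RPA1", "6117", entries = rpa1_entries),
      gene_plan("BRCA1", "672", entries = brca1_entries),
      gene_plan("CANT1", "124583", entries = cant1_entries)
    ),
    seed = seed
  )
}
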