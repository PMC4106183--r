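Package: genekeyr
Title: Ranked Key-Term Annotation of Gene Lists from Entrez Gene and
    PubMed Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates a table of genes with the results of a ranked
    regular-expression key-term search over Entrez-Gene-style XML records
    and the titles and abstracts of linked PubMed articles. Genes are
    matched by their official symbol; records are served from a sharded
    local file cache that can be populated from a database snapshot or,
    for small gene lists, from a rate-limited online fetcher. The search
    produces a sortable CSV summary (highest matching term rank, the term
    itself, and the total number of matched field entries) and a detailed
    self-contained HTML report with highlighted match contexts. A
    deterministic synthetic-corpus generator with exact planted-occurrence
    ground truth supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
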