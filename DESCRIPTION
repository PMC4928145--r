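Package: PhenoRanker
Title: Phenotype-Driven Candidate Gene Prioritization from Annotation Text
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks candidate genes (for example, the gene list remaining
    after filtering an annotated VCF from an exome experiment) against a
    free-text Boolean phenotype query. Each gene is represented by a
    section-structured annotation document; direct relevance is scored by
    term frequency/inverse document frequency with per-section boosting,
    and indirect ("guilt-by-association") relevance is scored through
    implicating genes that both mention the candidate's symbol and match
    the phenotype query. Direct and indirect rankings are merged into a
    single interlaced list whose mixing is quantified by a normalized
    adjacent-transposition (inversion) metric, used to calibrate the
    direct/indirect normalization factor. Includes a synthetic corpus
    generator with planted ground truth, contextual evidence snippets,
    and TSV/XLSX report export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
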