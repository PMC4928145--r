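#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' GeneCorpus: a collection of section-structured gene documents
#'
#' One document per gene, each split into named sections (e.g. Disorders,
#' Function, Summaries). The corpus carries a section registry (the ordered
#' set of legal section names), an alias map from case-folded identifiers to
#' official symbols, and the set of identifiers found to be ambiguous
#' (mapping to more than one official symbol). Ambiguity is flagged, never
#' silently resolved.
#'
#' @slot documents named list (by official symbol) of documents; each
#'   document is a list with elements `symbol` (character), `aliases`
#'   (character vector) and `sections` (named character vector of section
#'   texts).
#' @slot sectionRegistry ordered character vector of legal section names.
#' @slot aliasMap named list: case-folded identifier -> character vector of
#'   official symbols owning it.
#' @slot ambiguous character vector of case-folded identifiers owned by
#'   more than one gene.
#'
#' @seealso [readCorpus()], [writeCorpus()], [syntheticCorpus()]
#' @export
setClass("GeneCorpus",
  representation(documents = "list",
                 sectionRegistry = "character",
                 aliasMap = "list",
                 ambiguous = "character"))

setValidity("GeneCorpus", function(object) {
  msgs <- character(0)
  if (length(object@documents) < 1L) msgs <- c(msgs, "corpus must contain at least one document")
  syms <- vapply(object@documents, function(d) d$symbol, character(1))
  if (anyDuplicated(tolower(syms))) {
    msgs <- c(msgs, sprintf("duplicate official symbol (case-insensitive): %s",
                            paste(unique(syms[duplicated(tolower(syms))]), collapse = ", ")))
  }
  for (d in object@documents) {
    bad <- setdiff(names(d$sections), object@sectionRegistry)
    if (length(bad)) {
      msgs <- c(msgs, sprintf("gene %s uses section(s) not in registry: %s",
                              d$symbol, paste(bad, collapse = ", ")))
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' InvertedIndex: term and phrase lookup over a GeneCorpus
#'
#' Immutable after construction. Single-token postings are held in a sparse
#' term-by-(gene,section) count matrix; token streams are retained per
#' section so quoted phrases can be counted as contiguous token runs and so
#' evidence snippets can be cut. Phrase postings are computed on demand and
#' memoised in an internal cache environment.
#'
#' @slot counts dgCMatrix, rows = terms, columns = gene/section cells.
#' @slot geneCounts dgCMatrix, rows = terms, columns = genes (section sums).
#' @slot colGene,colSection character vectors mapping columns of `counts`
#'   to gene symbol and section name.
#' @slot genes official symbols, corpus order.
#' @slot sectionRegistry section names, registry order.
#' @slot tokenStreams list gene -> list section -> character token vector.
#' @slot corpusHash content hash of the indexed corpus.
#' @slot phraseCache environment memoising phrase counts.
#' @seealso [buildIndex()], [termScore()]
#' @export
setClass("InvertedIndex",
  representation(counts = "ANY",
                 geneCounts = "ANY",
                 colGene = "character",
                 colSection = "character",
                 genes = "character",
                 sectionRegistry = "character",
                 tokenStreams = "list",
                 corpusHash = "character",
                 phraseCache = "environment"))

setValidity("InvertedIndex", function(object) {
  if (ncol(object@counts) != length(object@colGene)) return("column map out of step with counts")
  if (length(object@colGene) != length(object@colSection)) return("colGene/colSection length mismatch")
  if (ncol(object@geneCounts) != length(object@genes)) return("geneCounts columns must be genes")
  TRUE
})

#' ScoringConfig: tunable parameters of the prioritization engine
#'
#' @slot sectionBoosts named positive numeric vector; sections absent from
#'   the vector implicitly have boost 1.
#' @slot F direct/indirect normalization factor (default 0.05).
#' @slot K maximum number of implicating genes retained per implicated gene
#'   (default 5).
#' @slot idfVariant label of the inverse-document-frequency formula in use.
#' @slot includeAliasesInMatrix logical; whether gene-gene links may also be
#'   established through aliases (default FALSE, official symbol only).
#' @seealso [scoringConfig()]
#' @export
setClass("ScoringConfig",
  representation(sectionBoosts = "numeric",
                 F = "numeric",
                 K = "integer",
                 idfVariant = "character",
                 includeAliasesInMatrix = "logical"))

setValidity("ScoringConfig", function(object) {
  if (any(object@sectionBoosts <= 0)) return("all section boosts must be > 0")
  if (length(object@F) != 1L || object@F <= 0) return("F must be a single positive number")
  if (length(object@K) != 1L || object@K < 1L) return("K must be >= 1")
  TRUE
})

#' GeneGeneMatrix: directional gene-to-gene mention scores
#'
#' Entry (A, B) holds the text-scoring propensity of gene A's symbol inside
#' gene B's document (A = implicated, B = implicating). Stored sparse; no
#' self-entries.
#'
#' @slot scores dgCMatrix, rows = implicated gene A, cols = implicating
#'   gene B.
#' @slot corpusHash content hash of the corpus the matrix was built over.
#' @seealso [buildGeneMatrix()]
#' @export
setClass("GeneGeneMatrix",
  representation(scores = "ANY", corpusHash = "character"))

setValidity("GeneGeneMatrix", function(object) {
  m <- object@scores
  if (nrow(m) != ncol(m)) return("gene-gene matrix must be square")
  if (any(Matrix::diag(m) != 0)) return("gene-gene matrix must have no self-entries")
  if (any(m@x < 0)) return("gene-gene scores must be non-negative")
  TRUE
})

#' PrioritizationResult: one complete prioritization run
#'
#' Holds the query, the symbolization report, the ranked direct and indirect
#' hits, the interlaced merged list, the un-hit genes and a config snapshot
#' sufficient to reproduce the run against the same corpus.
#'
#' @slot query the raw query string.
#' @slot symbolization list with elements `identified`, `unidentified`,
#'   `droppedDuplicates` (see [symbolize()]).
#' @slot direct data.frame of ranked direct hits.
#' @slot indirect data.frame of ranked indirect hits with attribute
#'   `evidence` (named list of evidence data.frames).
#' @slot interlaced data.frame: merged list with class labels.
#' @slot unhit character vector of submitted genes with no evidence.
#' @slot config the ScoringConfig used.
#' @slot corpusHash content hash of the corpus scored against.
#' @seealso [prioritize()], [exportReport()]
#' @export
setClass("PrioritizationResult",
  representation(query = "character",
                 symbolization = "list",
                 direct = "data.frame",
                 indirect = "data.frame",
                 interlaced = "data.frame",
                 unhit = "character",
                 config = "ScoringConfig",
                 corpusHash = "character"))
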