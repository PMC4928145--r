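#' Default section registry
#'
#' The six annotation sections a gene document is segmented into by default:
#' Disorders, Function, Summaries, Pathways, Publications, Expression.
#' Disorders and Function are the sections conventionally given scoring
#' boosts (see [scoringConfig()]).
#'
#' @return character vector of section names, registry order.
#' @export
defaultSections <- function() {
  c("Disorders", "Function", "Summaries", "Pathways", "Publications", "Expression")
}

#' Construct a gene document
#'
#' @param symbol official gene symbol (non-empty).
#' @param sections named character vector or list of section texts; empty
#'   texts are kept (a section may legitimately be empty).
#' @param aliases character vector of alternative identifiers.
#' @return a plain list with elements `symbol`, `aliases`, `sections`.
#' @export
geneDocument <- function(symbol, sections = character(0), aliases = character(0)) {
  stopifnot(is.character(symbol), length(symbol) == 1L, nzchar(symbol))
  sections <- vapply(as.list(sections), function(x) as.character(x)[1L], character(1))
  if (length(sections) && is.null(names(sections)))
    stop("sections must be named")
  list(symbol = symbol,
       aliases = as.character(aliases),
       sections = sections)
}

# Build alias map + ambiguity set from documents.
.buildAliasMap <- function(documents) {
  ids <- unlist(lapply(documents, function(d) tolower(c(d$symbol, d$aliases))),
                use.names = FALSE)
  owner <- unlist(lapply(documents, function(d) rep(d$symbol, 1L + length(d$aliases))),
                  use.names = FALSE)
  aliasMap <- lapply(split(owner, ids), unique)
  ambiguous <- names(aliasMap)[lengths(aliasMap) > 1L]
  list(aliasMap = aliasMap, ambiguous = ambiguous)
}

#' Construct a GeneCorpus from documents
#'
#' @param documents list of documents from [geneDocument()].
#' @param sectionRegistry ordered legal section names; defaults to the union
#'   of [defaultSections()] and every section used by a document.
#' @return a [GeneCorpus-class] object.
#' @export
geneCorpus <- function(documents, sectionRegistry = NULL) {
  if (length(documents) < 1L) stop("empty corpus")
  used <- unique(unlist(lapply(documents, function(d) names(d$sections)), use.names = FALSE))
  if (is.null(sectionRegistry))
    sectionRegistry <- union(defaultSections(), used)
  names(documents) <- vapply(documents, function(d) d$symbol, character(1))
  am <- .buildAliasMap(documents)
  obj <- new("GeneCorpus", documents = documents,
             sectionRegistry = as.character(sectionRegistry),
             aliasMap = am$aliasMap, ambiguous = am$ambiguous)
  validObject(obj)
  obj
}

#' @describeIn geneCorpus number of genes in the corpus.
#' @param x,object a GeneCorpus.
#' @export
nGenes <- function(x) length(x@documents)

#' Official symbols of a corpus or index
#'
#' @param x a [GeneCorpus-class] or [InvertedIndex-class].
#' @return character vector of official symbols, corpus order.
#' @export
geneSymbols <- function(x) {
  if (is(x, "GeneCorpus")) return(unname(vapply(x@documents, function(d) d$symbol, character(1))))
  if (is(x, "InvertedIndex")) return(x@genes)
  stop("no geneSymbols method for class ", class(x))
}

#' @rdname geneCorpus
#' @export
sectionRegistry <- function(x) x@sectionRegistry

#' Look up a single gene document
#'
#' @param corpus a [GeneCorpus-class].
#' @param symbol official symbol (case-insensitive).
#' @return the document list, or error if absent.
#' @export
getDocument <- function(corpus, symbol) {
  hit <- match(tolower(symbol), tolower(names(corpus@documents)))
  if (is.na(hit)) stop("gene not in corpus: ", symbol)
  corpus@documents[[hit]]
}

#' Identifiers flagged as ambiguous in a corpus
#'
#' An identifier is ambiguous when it is owned (as symbol or alias) by more
#' than one gene; such identifiers are never auto-resolved.
#'
#' @param corpus a [GeneCorpus-class].
#' @return character vector of case-folded ambiguous identifiers.
#' @export
ambiguousIdentifiers <- function(corpus) corpus@ambiguous

# One JSON line per document.
.docToJSON <- function(d) {
  secs <- as.list(d$sections)
  if (length(secs) == 0L) secs <- structure(list(), names = character(0))
  jsonlite::toJSON(list(symbol = jsonlite::unbox(d$symbol),
                        aliases = as.character(d$aliases),
                        sections = lapply(secs, jsonlite::unbox)),
                   auto_unbox = FALSE)
}

#' Write a corpus as JSON Lines
#'
#' One gene per line: `{"symbol": ..., "aliases": [...], "sections": {...}}`.
#' The write is UTF-8 and deterministic, so identical corpora produce
#' byte-identical files.
#'
#' @param corpus a [GeneCorpus-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @seealso [readCorpus()]
#' @export
writeCorpus <- function(corpus, path) {
  lines <- vapply(corpus@documents, function(d) as.character(.docToJSON(d)), character(1))
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read a JSON Lines corpus
#'
#' Parses one gene document per line, validates symbol uniqueness, builds
#' the alias map and flags ambiguous identifiers (an alias equal to another
#' gene's official symbol, or shared between genes, is reported via
#' [ambiguousIdentifiers()] rather than silently resolved).
#'
#' @param path path to a JSONL corpus file.
#' @param sectionRegistry optional explicit section registry.
#' @return a [GeneCorpus-class].
#' @export
readCorpus <- function(path, sectionRegistry = NULL) {
  if (!file.exists(path)) stop("corpus file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty corpus: ", path)
  documents <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) stop(sprintf("malformed corpus line %d: %s",
                                                     i, conditionMessage(e)), call. = FALSE))
    if (is.null(rec$symbol)) stop(sprintf("malformed corpus line %d: missing symbol", i))
    secs <- vapply(rec$sections %||% list(), function(x) as.character(x)[1L], character(1))
    documents[[i]] <- geneDocument(as.character(rec$symbol),
                                   sections = secs,
                                   aliases = unlist(rec$aliases %||% character(0), use.names = FALSE))
  }
  syms <- vapply(documents, function(d) d$symbol, character(1))
  if (anyDuplicated(tolower(syms)))
    stop("duplicate official symbol in corpus: ",
         paste(unique(syms[duplicated(tolower(syms))]), collapse = ", "))
  geneCorpus(documents, sectionRegistry = sectionRegistry)
}

#' Content hash of a corpus
#'
#' Hash of the canonical JSONL serialization; used to key on-disk caches
#' (index, gene-gene matrix) and recorded in result config snapshots.
#'
#' @param corpus a [GeneCorpus-class].
#' @return md5 hex string.
#' @export
corpusHash <- function(corpus) {
  contentHash(vapply(corpus@documents, function(d) as.character(.docToJSON(d)), character(1)))
}

setMethod("show", "GeneCorpus", function(object) {
  cat(sprintf("GeneCorpus with %d gene document(s)\n", nGenes(object)))
  cat("  sections:", paste(object@sectionRegistry, collapse = ", "), "\n")
  cat(sprintf("  identifiers: %d (%d ambiguous)\n",
              length(object@aliasMap), length(object@ambiguous)))
  syms <- geneSymbols(object)
  cat("  genes:", paste(head(syms, 6L), collapse = ", "),
      if (length(syms) > 6L) "..." else "", "\n")
})
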