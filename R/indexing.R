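#' Build the inverted index over a corpus
#'
#' Tokenizes every section of every document (case-folded, split on
#' non-alphanumeric runs, digits kept, no stemming) and assembles sparse
#' term-by-(gene,section) and term-by-gene count matrices. Token streams
#' are retained per section for phrase counting and evidence snippets.
#' The index is treated as immutable after build; phrase counts are
#' memoised lazily in an internal cache.
#'
#' @param corpus a [GeneCorpus-class].
#' @return an [InvertedIndex-class].
#' @examples
#' cs <- geneCorpus(list(
#'   geneDocument("TTC37", c(Disorders = "diarrhea diarrhea diarrhea")),
#'   geneDocument("TLN1", c(Function = "adhesion"))))
#' idx <- buildIndex(cs)
#' termCount(idx, "TTC37", "diarrhea")
#' @export
buildIndex <- function(corpus) {
  genes <- geneSymbols(corpus)
  streams <- vector("list", length(genes))
  names(streams) <- genes

  colGene <- character(0)
  colSection <- character(0)
  tokAll <- list()
  colAll <- list()
  cellId <- 0L
  for (g in seq_along(genes)) {
    doc <- corpus@documents[[g]]
    secs <- doc$sections
    streams[[g]] <- lapply(as.list(secs), tokenize)
    for (s in names(secs)) {
      cellId <- cellId + 1L
      colGene[cellId] <- genes[g]
      colSection[cellId] <- s
      toks <- streams[[g]][[s]]
      if (length(toks)) {
        tokAll[[length(tokAll) + 1L]] <- toks
        colAll[[length(colAll) + 1L]] <- rep.int(cellId, length(toks))
      }
    }
  }
  toks <- unlist(tokAll, use.names = FALSE)
  cols <- unlist(colAll, use.names = FALSE)
  terms <- sort(unique(toks))
  if (length(terms) == 0L) {
    counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                   dims = c(0L, cellId))
  } else {
    counts <- Matrix::sparseMatrix(i = match(toks, terms), j = cols, x = 1,
                                   dims = c(length(terms), cellId),
                                   dimnames = list(terms, NULL))
  }
  # collapse sections: term x gene counts
  geneFac <- match(colGene, genes)
  collapse <- Matrix::sparseMatrix(i = seq_len(cellId), j = geneFac, x = 1,
                                   dims = c(cellId, length(genes)),
                                   dimnames = list(NULL, genes))
  geneCounts <- counts %*% collapse

  obj <- new("InvertedIndex",
             counts = methods::as(counts, "CsparseMatrix"),
             geneCounts = methods::as(geneCounts, "CsparseMatrix"),
             colGene = colGene, colSection = colSection,
             genes = genes, sectionRegistry = corpus@sectionRegistry,
             tokenStreams = streams,
             corpusHash = corpusHash(corpus),
             phraseCache = new.env(parent = emptyenv()))
  validObject(obj)
  obj
}

# Per-(gene, section) counts of a token sequence; phrase counts computed
# from token streams and memoised. Returns numeric vector over columns of
# index@counts.
.phraseCellCounts <- function(index, tokens) {
  key <- paste(tokens, collapse = "")
  cached <- index@phraseCache[[key]]
  if (!is.null(cached)) return(cached)
  out <- numeric(length(index@colGene))
  for (j in seq_along(out)) {
    st <- index@tokenStreams[[index@colGene[j]]][[index@colSection[j]]]
    out[j] <- countPhrase(st, tokens)
  }
  assign(key, out, envir = index@phraseCache)
  out
}

# Counts of a term (single token or phrase) per (gene, section) cell.
.termCellCounts <- function(index, tokens) {
  if (length(tokens) == 1L) {
    if (!tokens %in% rownames(index@counts)) return(numeric(length(index@colGene)))
    as.numeric(index@counts[tokens, ])
  } else {
    .phraseCellCounts(index, tokens)
  }
}

# Per-gene totals for a term.
.termGeneCounts <- function(index, tokens) {
  if (length(tokens) == 1L) {
    if (!tokens %in% rownames(index@geneCounts))
      return(setNames(numeric(length(index@genes)), index@genes))
    setNames(as.numeric(index@geneCounts[tokens, ]), index@genes)
  } else {
    cell <- .termCellCounts(index, tokens)
    out <- setNames(numeric(length(index@genes)), index@genes)
    agg <- tapply(cell, index@colGene, sum)
    out[names(agg)] <- agg
    out
  }
}

#' Occurrence count and document frequency lookups
#'
#' `termCount()` returns the total occurrence count of a term (single word
#' or multi-word phrase, given as one string) in one gene's document,
#' optionally restricted to a section. `docFreq()` returns the number of
#' genes whose document contains the term at least once; phrase document
#' frequency is computed from contiguous phrase occurrences, not from the
#' intersection of its tokens.
#'
#' @param index an [InvertedIndex-class].
#' @param gene official gene symbol.
#' @param term term string; tokenized with the index tokenizer, multiple
#'   tokens are matched as a contiguous phrase within a single section.
#' @param section optional section name restriction.
#' @return integer count.
#' @export
termCount <- function(index, gene, term, section = NULL) {
  tokens <- tokenize(term)
  if (length(tokens) == 0L) return(0L)
  cell <- .termCellCounts(index, tokens)
  keep <- index@colGene == gene
  if (!is.null(section)) keep <- keep & index@colSection == section
  as.integer(sum(cell[keep]))
}

#' @rdname termCount
#' @export
docFreq <- function(index, term) {
  tokens <- tokenize(term)
  if (length(tokens) == 0L) return(0L)
  sum(.termGeneCounts(index, tokens) > 0)
}

#' @rdname termCount
#' @export
indexedTerms <- function(index) rownames(index@counts)

setMethod("show", "InvertedIndex", function(object) {
  cat(sprintf("InvertedIndex: %d term(s) over %d gene(s), %d section cell(s)\n",
              nrow(object@counts), length(object@genes), ncol(object@counts)))
  cat("  corpus hash:", object@corpusHash, "\n")
})

#' Resolve raw gene identifiers to official symbols
#'
#' Exact official symbols (case-insensitive) pass through unchanged; an
#' alias uniquely owned by one gene is translated; an unknown or ambiguous
#' identifier is reported as unidentified together with ranked suggestions
#' (exact alias owners first, then case-insensitive prefix matches, at most
#' 10). After resolution, duplicates collapse to the first occurrence and
#' the rest are reported as dropped. Lists longer than 4000 identifiers are
#' accepted with a warning.
#'
#' @param rawIds character vector of input identifiers.
#' @param corpus a [GeneCorpus-class].
#' @return list with components `identified` (data.frame input/symbol),
#'   `unidentified` (data.frame input/suggestions, suggestions
#'   comma-joined), `droppedDuplicates` (character).
#' @examples
#' cs <- geneCorpus(list(
#'   geneDocument("TTC37", c(Function = "x"), aliases = "KIAA0372"),
#'   geneDocument("TLN1", c(Function = "y"))))
#' symbolize(c("ttc37", "KIAA0372", "NOPE"), cs)
#' @export
symbolize <- function(rawIds, corpus) {
  stopifnot(length(rawIds) >= 1L)
  if (length(rawIds) > 4000L)
    warning("gene list exceeds 4000 identifiers; all will be processed")
  officials <- geneSymbols(corpus)
  offLower <- tolower(officials)
  identifiedIn <- character(0); identifiedSym <- character(0)
  unidIn <- character(0); unidSug <- character(0)
  dropped <- character(0)
  seen <- character(0)
  allIds <- names(corpus@aliasMap)
  for (id in rawIds) {
    key <- tolower(trimws(id))
    if (!nzchar(key)) next
    hit <- match(key, offLower)
    sym <- NA_character_
    if (!is.na(hit)) {
      sym <- officials[hit]
    } else {
      owners <- corpus@aliasMap[[key]]
      if (!is.null(owners) && length(owners) == 1L && !(key %in% corpus@ambiguous)) {
        sym <- owners[[1L]]
      }
    }
    if (!is.na(sym)) {
      if (sym %in% seen) {
        dropped <- c(dropped, id)
      } else {
        seen <- c(seen, sym)
        identifiedIn <- c(identifiedIn, id)
        identifiedSym <- c(identifiedSym, sym)
      }
    } else {
      exact <- sort(unique(corpus@aliasMap[[key]] %||% character(0)))
      prefix <- allIds[startsWith(allIds, key)]
      prefixOwners <- sort(unique(unlist(corpus@aliasMap[prefix], use.names = FALSE)))
      sugg <- head(unique(c(exact, setdiff(prefixOwners, exact))), 10L)
      unidIn <- c(unidIn, id)
      unidSug <- c(unidSug, paste(sugg, collapse = ","))
    }
  }
  list(identified = data.frame(input = identifiedIn, symbol = identifiedSym,
                               stringsAsFactors = FALSE),
       unidentified = data.frame(input = unidIn, suggestions = unidSug,
                                 stringsAsFactors = FALSE),
       droppedDuplicates = dropped)
}

#' Read a plain-text gene list
#'
#' One identifier per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file path.
#' @return character vector of raw identifiers.
#' @export
readGeneList <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
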