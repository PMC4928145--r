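#' Run the full prioritization pipeline
#'
#' Symbolizes the submitted identifiers, parses and validates the query,
#' ranks the identified genes directly and indirectly, interlaces the two
#' rankings and partitions the submitted genes into direct hits,
#' indirect-only hits and un-hit genes (a gene with both kinds of evidence
#' counts as direct).
#'
#' @param corpus a [GeneCorpus-class].
#' @param genes character vector of raw gene identifiers.
#' @param query free-text Boolean phenotype query.
#' @param config a [ScoringConfig-class].
#' @param index optional prebuilt [InvertedIndex-class] over `corpus`.
#' @param matrix optional prebuilt [GeneGeneMatrix-class] over `corpus`.
#' @return a [PrioritizationResult-class].
#' @examples
#' sim <- syntheticCorpus(nGenes = 20, vocabSize = 150,
#'                        backgroundTokensPerSection = 30, seed = 42)
#' res <- prioritize(sim$corpus, geneSymbols(sim$corpus),
#'                   paste(sim$truth$plantedDirectTerms, collapse = " OR "))
#' directHits(res)[1, ]
#' @export
prioritize <- function(corpus, genes, query, config = scoringConfig(),
                       index = NULL, matrix = NULL) {
  ast <- parseQuery(query)
  if (is.null(index)) index <- buildIndex(corpus)
  if (is.null(matrix)) matrix <- buildGeneMatrix(corpus, index, config)
  sym <- symbolize(genes, corpus)
  identified <- sym$identified$symbol
  if (length(identified) == 0L)
    stop("no submitted identifier could be resolved to an official symbol")
  direct <- prioritizeDirect(identified, ast, index, config)
  indirect <- prioritizeIndirect(identified, ast, index, matrix, config)
  merged <- interlaceResults(direct, indirect)
  unhit <- setdiff(identified, merged$gene)
  new("PrioritizationResult",
      query = query, symbolization = sym,
      direct = direct, indirect = indirect, interlaced = merged,
      unhit = unhit, config = config, corpusHash = index@corpusHash)
}

#' Accessors for PrioritizationResult
#'
#' @param result a [PrioritizationResult-class].
#' @return `directHits()` / `indirectHits()` / `interlaced()` return the
#'   ranked data.frames; `unhitGenes()` the un-hit symbols;
#'   `symbolizationReport()` the identifier-resolution report;
#'   `indirectEvidence()` the named list of evidence data.frames.
#' @name result-accessors
NULL

#' @rdname result-accessors
#' @export
directHits <- function(result) result@direct

#' @rdname result-accessors
#' @export
indirectHits <- function(result) result@indirect

#' @rdname result-accessors
#' @export
interlaced <- function(result) result@interlaced

#' @rdname result-accessors
#' @export
unhitGenes <- function(result) result@unhit

#' @rdname result-accessors
#' @export
symbolizationReport <- function(result) result@symbolization

#' @rdname result-accessors
#' @export
indirectEvidence <- function(result) attr(result@indirect, "evidence")

setMethod("show", "PrioritizationResult", function(object) {
  cat("PrioritizationResult\n")
  cat("  query:", object@query, "\n")
  cat(sprintf("  submitted: %d identified, %d unidentified, %d duplicate(s) dropped\n",
              nrow(object@symbolization$identified),
              nrow(object@symbolization$unidentified),
              length(object@symbolization$droppedDuplicates)))
  cat(sprintf("  hits: %d direct, %d indirect, %d un-hit\n",
              nrow(object@direct), nrow(object@indirect), length(object@unhit)))
  if (nrow(object@interlaced) > 0) {
    top <- head(object@interlaced, 5L)
    cat("  top of interlaced list:\n")
    for (k in seq_len(nrow(top)))
      cat(sprintf("    %2d. %-12s %-8s %.4f\n", top$n[k], top$gene[k],
                  top$kind[k], top$score[k]))
  }
})
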