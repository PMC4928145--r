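#' Generate a synthetic corpus with planted ground truth
#'
#' Emulates the spiked-probe benchmark design for phenotype-driven gene
#' prioritization on a fully synthetic corpus. Background section text is
#' drawn from a Zipf-distributed vocabulary disjoint from all gene symbols
#' and phenotype terms, so that every phenotype or gene-symbol occurrence
#' in the corpus is planted, never accidental. Two signals are planted:
#'
#' * a *causal* (probe) gene whose highest-boost section (`directSection`)
#'   receives each planted phenotype term `Poisson(injectionRate)` times --
#'   this gene should be recoverable at the top of the direct ranking;
#' * an *implicated* gene that receives no phenotype terms at all, while
#'   each of `nImplicating` implicating genes receives the phenotype terms
#'   in `implicatingSection` and the implicated gene's symbol in
#'   `mentionSection` -- this gene should be recoverable only through the
#'   indirect (guilt-by-association) ranking.
#'
#' Identical `(config, seed)` pairs regenerate a bit-identical corpus.
#'
#' @param nGenes total number of genes (>= 2 + nImplicating); default 500.
#' @param vocabSize background vocabulary size (>= 100); default 2000.
#' @param sections section registry for the generated documents.
#' @param backgroundTokensPerSection background tokens drawn per section.
#' @param plantedDirectTerms phenotype terms planted for the causal gene;
#'   these also form the natural OR-query for recovery experiments.
#' @param nImplicating number of implicating genes for the indirect plant.
#' @param injectionRate Poisson mean of injected occurrences per term and
#'   section; 0 plants nothing.
#' @param directSection section receiving the causal gene's phenotype terms
#'   (the highest-boost section under the default [scoringConfig()]).
#' @param implicatingSection section receiving the implicating genes'
#'   phenotype mentions.
#' @param mentionSection section receiving the implicating genes' mentions
#'   of the implicated gene's symbol.
#' @param zipfExponent Zipf exponent of the background vocabulary.
#' @param seed integer seed; fully determines the output.
#' @return list with elements `corpus` (a [GeneCorpus-class]) and `truth`
#'   (list: `causalGene`, `plantedDirectTerms`, `implicatedGene`,
#'   `implicatingGenes`, `injectionRate`, `seed`).
#' @examples
#' sim <- syntheticCorpus(nGenes = 20, vocabSize = 150,
#'                        backgroundTokensPerSection = 30, seed = 1)
#' sim$truth$causalGene
#' @export
syntheticCorpus <- function(nGenes = 500L,
                            vocabSize = 2000L,
                            sections = defaultSections(),
                            backgroundTokensPerSection = 100L,
                            plantedDirectTerms = c("ataxia", "seizures",
                                                   "nystagmus", "hypotonia"),
                            nImplicating = 3L,
                            injectionRate = 3,
                            directSection = "Disorders",
                            implicatingSection = "Publications",
                            mentionSection = "Pathways",
                            zipfExponent = 1.1,
                            seed) {
  if (missing(seed)) stop("seed must be supplied explicitly")
  if (nGenes < 2L + nImplicating)
    stop("nGenes must be at least 2 + nImplicating")
  if (vocabSize < 100L) stop("vocabSize must be >= 100")
  if (!all(c(directSection, implicatingSection, mentionSection) %in% sections))
    stop("planting sections must be members of the section registry")

  symbols <- sprintf("GENE%04d", seq_len(nGenes))
  aliases <- sprintf("KIAA%04d", seq_len(nGenes))
  vocab <- sprintf("tok%05d", seq_len(vocabSize))
  planted <- tolower(plantedDirectTerms)
  reserved <- tolower(c(symbols, aliases, planted))
  if (any(vocab %in% reserved))
    stop("vocabulary collides with gene symbols or planted terms")
  if (any(duplicated(planted)))
    stop("planted phenotype terms must be distinct")

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  probs <- zipfProbs(vocabSize, zipfExponent)
  roles <- sample.int(nGenes, 2L + nImplicating)
  causal <- symbols[roles[1L]]
  implicated <- symbols[roles[2L]]
  implicating <- symbols[roles[-(1:2)]]

  insertTokens <- function(tokens, extra) {
    if (length(extra) == 0L) return(tokens)
    pos <- sample.int(length(tokens) + 1L, length(extra), replace = TRUE)
    ord <- order(pos)
    out <- tokens
    # insert back-to-front so earlier positions stay valid
    for (k in rev(seq_along(extra))) {
      p <- pos[ord[k]]
      out <- append(out, extra[ord[k]], after = p - 1L)
    }
    out
  }

  documents <- vector("list", nGenes)
  for (g in seq_len(nGenes)) {
    secTexts <- character(length(sections))
    names(secTexts) <- sections
    for (s in sections) {
      toks <- vocab[sample.int(vocabSize, backgroundTokensPerSection,
                               replace = TRUE, prob = probs)]
      extra <- character(0)
      if (symbols[g] == causal && s == directSection && injectionRate > 0) {
        counts <- rpois(length(planted), injectionRate)
        extra <- c(extra, rep(planted, counts))
      }
      if (symbols[g] %in% implicating && injectionRate > 0) {
        if (s == implicatingSection) {
          counts <- rpois(length(planted), injectionRate)
          extra <- c(extra, rep(planted, counts))
        }
        if (s == mentionSection) {
          extra <- c(extra, rep(implicated, rpois(1L, injectionRate)))
        }
      }
      toks <- insertTokens(toks, extra)
      secTexts[[s]] <- paste(toks, collapse = " ")
    }
    documents[[g]] <- geneDocument(symbols[g], sections = secTexts,
                                   aliases = aliases[g])
  }

  corpus <- geneCorpus(documents, sectionRegistry = sections)
  truth <- list(causalGene = causal,
                plantedDirectTerms = planted,
                implicatedGene = implicated,
                implicatingGenes = implicating,
                injectionRate = injectionRate,
                seed = seed)
  list(corpus = corpus, truth = truth)
}
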