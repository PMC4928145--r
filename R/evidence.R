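#' Contextual evidence snippets ("minicards") for term hits
#'
#' Locates every occurrence of the given terms in a gene's document and
#' cuts snippet windows around them: hits in the same section closer than
#' `window` tokens apart merge into one snippet; each snippet extends
#' `window` tokens to each side of its hit cluster. Highlights are
#' character offset pairs into the snippet (1-based, inclusive), so any
#' renderer (terminal, HTML, spreadsheet) can mark them up.
#'
#' @param gene official symbol.
#' @param terms list of TERM nodes (see [queryTerms()]) or character vector
#'   of term strings.
#' @param corpus a [GeneCorpus-class].
#' @param window snippet half-width in tokens (default 12).
#' @param kind evidence kind label: "phenotype-hit" or "gene-to-gene-hit".
#' @return list of minicards, each a list with `gene`, `section`,
#'   `snippet`, `highlights` (data.frame `start`, `end`, `term`), `kind`;
#'   ordered by section registry order then position. Empty list if no
#'   hits.
#' @export
makeMiniCards <- function(gene, terms, corpus, window = 12L,
                          kind = "phenotype-hit") {
  doc <- getDocument(corpus, gene)
  if (is.character(terms)) terms <- lapply(terms, function(x) list(kind = "TERM", tokens = tokenize(x), raw = x))
  cards <- list()
  secOrder <- intersect(corpus@sectionRegistry, names(doc$sections))
  for (s in secOrder) {
    text <- doc$sections[[s]]
    off <- tokenizeOffsets(text)
    if (nrow(off) == 0L) next
    # hit = token-index range [ti, tj] of one term occurrence
    hits <- list()
    for (t in terms) {
      tk <- t$tokens
      if (length(tk) == 0L || nrow(off) < length(tk)) next
      starts <- which(off$token == tk[1L])
      for (st in starts) {
        en <- st + length(tk) - 1L
        if (en > nrow(off)) next
        if (all(off$token[st:en] == tk)) {
          hits[[length(hits) + 1L]] <- list(ti = st, tj = en, raw = t$raw)
        }
      }
    }
    if (length(hits) == 0L) next
    ord <- order(vapply(hits, `[[`, integer(1), "ti"))
    hits <- hits[ord]
    # cluster hits whose gap is < window tokens
    clusters <- list(); cur <- list(hits[[1L]])
    if (length(hits) > 1L) {
      for (k in 2L:length(hits)) {
        if (hits[[k]]$ti - cur[[length(cur)]]$tj <= window) {
          cur[[length(cur) + 1L]] <- hits[[k]]
        } else {
          clusters[[length(clusters) + 1L]] <- cur
          cur <- list(hits[[k]])
        }
      }
    }
    clusters[[length(clusters) + 1L]] <- cur
    for (cl in clusters) {
      lo <- max(1L, cl[[1L]]$ti - window)
      hi <- min(nrow(off), cl[[length(cl)]]$tj + window)
      snipStart <- off$start[lo]
      snipEnd <- off$end[hi]
      snippet <- substr(text, snipStart, snipEnd)
      hl <- do.call(rbind, lapply(cl, function(h) {
        data.frame(start = off$start[h$ti] - snipStart + 1L,
                   end = off$end[h$tj] - snipStart + 1L,
                   term = h$raw, stringsAsFactors = FALSE)
      }))
      cards[[length(cards) + 1L]] <- list(gene = doc$symbol, section = s,
                                          snippet = snippet, highlights = hl,
                                          kind = kind)
    }
  }
  cards
}

#' Two-tier evidence for an indirect hit
#'
#' Tier 1, in evidence-rank order: one entry per implicating gene B, with
#' gene-to-gene minicards showing where the implicated gene's symbol
#' occurs inside B's document. Tier 2, inside each entry: phenotype
#' minicards showing where the query terms hit B's document. Every
#' retained implicating gene has both kinds by construction (AB > 0 and
#' BP > 0).
#'
#' @param implicated implicated gene symbol (a row of
#'   [prioritizeIndirect()] results).
#' @param evidence the evidence data.frame for that gene (from the
#'   `evidence` attribute of [prioritizeIndirect()]).
#' @param ast query AST.
#' @param corpus a [GeneCorpus-class].
#' @param window snippet half-width in tokens.
#' @return list, one element per implicating gene in rank order:
#'   `list(implicating, i, AB, BP, geneToGene = <minicards>,
#'   phenotype = <minicards>)`.
#' @export
makeIndirectEvidence <- function(implicated, evidence, ast, corpus,
                                 window = 12L) {
  stopifnot(nrow(evidence) >= 1L)
  terms <- queryTerms(ast)
  lapply(seq_len(nrow(evidence)), function(k) {
    b <- evidence$implicating[k]
    list(implicating = b, i = evidence$i[k],
         AB = evidence$AB[k], BP = evidence$BP[k],
         geneToGene = makeMiniCards(b, implicated, corpus, window,
                                    kind = "gene-to-gene-hit"),
         phenotype = makeMiniCards(b, terms, corpus, window,
                                   kind = "phenotype-hit"))
  })
}

#' Serialize evidence to JSON
#'
#' @param cards minicard list (from [makeMiniCards()] or
#'   [makeIndirectEvidence()]).
#' @param path output path.
#' @export
writeEvidenceJSON <- function(cards, path) {
  json <- jsonlite::toJSON(cards, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}
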