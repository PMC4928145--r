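#' Scoring configuration
#'
#' Assembles the tunable parameters of the engine. Defaults: section boosts
#' Disorders 4, Function 2, every other section 1 (gene-phenotype links
#' found in disorder/function annotations carry more weight than incidental
#' mentions in, say, publication lists); direct/indirect normalization
#' `F = 0.05`; at most `K = 5` implicating genes per implicated gene; idf
#' formula `1 + ln((N + 1)/(df + 1))` (label `"smooth-ln"`), a smoothed
#' variant that is positive, finite for df = N, and monotone decreasing in
#' document frequency.
#'
#' @param sectionBoosts named positive numerics; sections not named get 1.
#' @param F positive normalization factor for indirect scores.
#' @param K maximum implicating genes retained (>= 1).
#' @param idfVariant label of the idf formula; only `"smooth-ln"` is
#'   implemented.
#' @param includeAliasesInMatrix also link genes through aliases when
#'   building the gene-gene matrix (default FALSE: official symbol only,
#'   so alias ambiguity cannot inflate links).
#' @return a [ScoringConfig-class].
#' @examples
#' scoringConfig()
#' scoringConfig(sectionBoosts = c(Disorders = 8), F = 0.1)
#' @export
scoringConfig <- function(sectionBoosts = c(Disorders = 4, Function = 2),
                          F = 0.05, K = 5L,
                          idfVariant = "smooth-ln",
                          includeAliasesInMatrix = FALSE) {
  if (!identical(idfVariant, "smooth-ln"))
    stop("unknown idf variant: ", idfVariant)
  obj <- new("ScoringConfig",
             sectionBoosts = sectionBoosts, F = as.numeric(F),
             K = as.integer(K), idfVariant = idfVariant,
             includeAliasesInMatrix = isTRUE(includeAliasesInMatrix))
  validObject(obj)
  obj
}

#' Read a scoring configuration from JSON or YAML
#'
#' Recognized keys: `section_boosts` (map), `F`, `K`, `idf_variant`,
#' `include_aliases_in_matrix`. Unknown sections in `section_boosts` are a
#' configuration error when the config is later applied to an index whose
#' registry lacks them.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a [ScoringConfig-class].
#' @export
readScoringConfig <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  boosts <- unlist(raw$section_boosts %||% c(Disorders = 4, Function = 2))
  scoringConfig(sectionBoosts = boosts,
                F = raw$F %||% 0.05,
                K = raw$K %||% 5L,
                idfVariant = raw$idf_variant %||% "smooth-ln",
                includeAliasesInMatrix = raw$include_aliases_in_matrix %||% FALSE)
}

setMethod("show", "ScoringConfig", function(object) {
  cat("ScoringConfig\n")
  cat("  boosts:", paste(sprintf("%s=%g", names(object@sectionBoosts),
                                 object@sectionBoosts), collapse = ", "),
      "(others 1)\n")
  cat(sprintf("  F = %g, K = %d, idf = %s, aliases in matrix: %s\n",
              object@F, object@K, object@idfVariant,
              object@includeAliasesInMatrix))
})

# boost per index column; errors on boost sections unknown to the registry
.columnBoosts <- function(index, config) {
  bad <- setdiff(names(config@sectionBoosts), index@sectionRegistry)
  if (length(bad))
    stop("boost configured for unknown section(s): ", paste(bad, collapse = ", "))
  b <- rep(1, length(index@colSection))
  hit <- match(index@colSection, names(config@sectionBoosts))
  b[!is.na(hit)] <- config@sectionBoosts[hit[!is.na(hit)]]
  b
}

# idf with +1 smoothing in numerator and denominator
.idf <- function(nGenes, df) 1 + log((nGenes + 1) / (df + 1))

#' Score one term in one gene's document
#'
#' Term frequency/inverse document frequency with per-section boosting:
#' `sum over sections s of boost(s) * tf(term, gene, s) * idf(term)` with
#' `idf = 1 + ln((N + 1)/(df + 1))`, `N` the corpus size and `df` the
#' term's document frequency. Zero when the term is absent. Quoted phrases
#' are scored on contiguous-phrase counts with phrase document frequency.
#'
#' @param index an [InvertedIndex-class].
#' @param gene official symbol.
#' @param term a TERM node from [parseQuery()]/[queryTerms()], or a plain
#'   string (tokenized; several tokens mean a phrase).
#' @param config a [ScoringConfig-class].
#' @return non-negative numeric score.
#' @export
termScore <- function(index, gene, term, config = scoringConfig()) {
  tokens <- if (is.list(term)) term$tokens else tokenize(term)
  if (length(tokens) == 0L) return(0)
  cell <- .termCellCounts(index, tokens)
  keep <- index@colGene == gene
  tfPart <- sum(cell[keep] * .columnBoosts(index, config)[keep])
  if (tfPart == 0) return(0)
  df <- sum(.termGeneCounts(index, tokens) > 0)
  tfPart * .idf(length(index@genes), df)
}

# Vectorized: boosted tf-idf of one term for every gene at once.
.termScoreAllGenes <- function(index, tokens, config, boosts = NULL) {
  if (is.null(boosts)) boosts <- .columnBoosts(index, config)
  cell <- .termCellCounts(index, tokens)
  boosted <- cell * boosts
  agg <- setNames(numeric(length(index@genes)), index@genes)
  nz <- which(boosted != 0)
  if (length(nz)) {
    s <- tapply(boosted[nz], index@colGene[nz], sum)
    agg[names(s)] <- s
  }
  geneTotals <- .termGeneCounts(index, tokens)
  df <- sum(geneTotals > 0)
  if (df == 0) return(agg)
  agg * .idf(length(index@genes), df)
}

#' Rank genes by direct phenotype relevance
#'
#' The full Boolean query first gates the gene set (a gene failing an AND
#' clause is excluded however well it matches one term); the query is then
#' decomposed into its positive terms, each scored independently with
#' [termScore()], and the per-term scores are summed. Hits are sorted by
#' score descending, ties by symbol. Genes from `genes` with no hit are
#' reported in the `unhit` attribute.
#'
#' @param genes character vector of official symbols to rank.
#' @param ast query AST from [parseQuery()].
#' @param index an [InvertedIndex-class].
#' @param config a [ScoringConfig-class].
#' @return data.frame with columns `rank`, `gene`, `score`,
#'   `matchedPhenotypeCount`, `matchedTerms` (semicolon-joined
#'   `term(score)` pairs) and a list column `termScores`; attribute
#'   `unhit` lists the submitted genes that did not match.
#' @export
prioritizeDirect <- function(genes, ast, index, config = scoringConfig()) {
  matched <- evaluateBoolean(ast, index, genes)
  terms <- queryTerms(ast)
  boosts <- .columnBoosts(index, config)
  perTerm <- lapply(terms, function(t) .termScoreAllGenes(index, t$tokens, config, boosts))
  if (length(matched)) {
    mat <- vapply(perTerm, function(v) v[matched], numeric(length(matched)))
    mat <- matrix(mat, nrow = length(matched),
                  dimnames = list(matched, vapply(terms, `[[`, character(1), "raw")))
    score <- rowSums(mat)
    cnt <- rowSums(mat > 0)
    ord <- order(-score, matched)
    hits <- data.frame(rank = seq_along(ord), gene = matched[ord],
                       score = unname(score[ord]),
                       matchedPhenotypeCount = as.integer(unname(cnt[ord])),
                       stringsAsFactors = FALSE)
    hits$matchedTerms <- vapply(seq_len(nrow(hits)), function(i) {
      r <- mat[hits$gene[i], , drop = TRUE]
      nz <- r[r > 0]
      paste(sprintf("%s(%.6g)", names(nz), nz), collapse = ";")
    }, character(1))
    hits$termScores <- lapply(hits$gene, function(g) mat[g, , drop = TRUE])
  } else {
    hits <- data.frame(rank = integer(0), gene = character(0), score = numeric(0),
                       matchedPhenotypeCount = integer(0),
                       matchedTerms = character(0), stringsAsFactors = FALSE)
    hits$termScores <- list()
  }
  attr(hits, "unhit") <- setdiff(genes, hits$gene)
  hits
}

#' Build the directional gene-to-gene mention matrix
#'
#' Entry (A, B), A != B, is the tf-idf/boost score of gene A's official
#' symbol as a term inside gene B's document -- the propensity of A's
#' symbol within B's annotation text. With
#' `includeAliasesInMatrix = TRUE` in the config, A's aliases contribute
#' additively as extra terms. Stored sparse.
#'
#' @param corpus the [GeneCorpus-class] the index was built from.
#' @param index an [InvertedIndex-class] over `corpus`.
#' @param config a [ScoringConfig-class].
#' @return a [GeneGeneMatrix-class].
#' @export
buildGeneMatrix <- function(corpus, index, config = scoringConfig()) {
  genes <- index@genes
  boosts <- .columnBoosts(index, config)
  n <- length(genes)
  iAll <- list(); jAll <- list(); xAll <- list()
  for (a in seq_len(n)) {
    termsA <- list(tokenize(genes[a]))
    if (config@includeAliasesInMatrix) {
      doc <- corpus@documents[[genes[a]]]
      termsA <- c(termsA, lapply(doc$aliases, tokenize))
    }
    sc <- numeric(n)
    for (tk in termsA) {
      if (length(tk) == 0L) next
      sc <- sc + .termScoreAllGenes(index, tk, config, boosts)
    }
    sc[a] <- 0
    nz <- which(sc > 0)
    if (length(nz)) {
      iAll[[length(iAll) + 1L]] <- rep.int(a, length(nz))
      jAll[[length(jAll) + 1L]] <- nz
      xAll[[length(xAll) + 1L]] <- sc[nz]
    }
  }
  m <- Matrix::sparseMatrix(i = unlist(iAll) %||% integer(0),
                            j = unlist(jAll) %||% integer(0),
                            x = unlist(xAll) %||% numeric(0),
                            dims = c(n, n), dimnames = list(genes, genes))
  obj <- new("GeneGeneMatrix", scores = methods::as(m, "CsparseMatrix"),
             corpusHash = index@corpusHash)
  validObject(obj)
  obj
}

#' @rdname buildGeneMatrix
#' @param x a GeneGeneMatrix.
#' @export
geneMatrixScores <- function(x) x@scores

setMethod("show", "GeneGeneMatrix", function(object) {
  cat(sprintf("GeneGeneMatrix: %d x %d genes, %d nonzero link(s)\n",
              nrow(object@scores), ncol(object@scores),
              length(object@scores@x)))
})

#' Write / read a gene-gene matrix as 3-column TSV
#'
#' Columns `A`, `B`, `AB`; the corpus hash is stored in a header comment so
#' a cached matrix can be matched to its corpus.
#'
#' @param matrix a [GeneGeneMatrix-class].
#' @param path file path.
#' @export
writeGeneMatrix <- function(matrix, path) {
  m <- methods::as(matrix@scores, "TsparseMatrix")
  df <- data.frame(A = rownames(matrix@scores)[m@i + 1L],
                   B = colnames(matrix@scores)[m@j + 1L],
                   AB = m@x, stringsAsFactors = FALSE)
  df <- df[order(df$A, df$B), , drop = FALSE]
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(c(sprintf("# corpus_hash=%s", matrix@corpusHash),
               "A\tB\tAB",
               sprintf("%s\t%s\t%s", df$A, df$B, formatNum(df$AB))),
             con, useBytes = TRUE)
  invisible(path)
}

# The weighted evidence kernel of the indirect score: given compound
# AB*BP products sorted descending, retain at most K and weight the i-th
# by 2^(1-i). Exposed for closed-form verification.
weightedEvidenceScore <- function(compound, F = 0.05, K = 5L) {
  top <- sort(compound, decreasing = TRUE)
  top <- top[seq_len(min(K, length(top)))]
  F * sum(2^(1 - seq_along(top)) * top)
}

#' Rank genes by indirect (guilt-by-association) relevance
#'
#' For each submitted gene A, the candidate implicating genes are every
#' other gene B, corpus-wide, with a nonzero gene-to-gene score AB (A's
#' symbol occurs in B's document) and a positive direct phenotype score BP
#' for the full Boolean query (B must itself satisfy the query). The top
#' `K` candidates by compound `AB * BP` are retained (ties by symbol) and
#'
#' `score(A) = F * sum over i of 2^(1 - i) * AB_i * BP_i`
#'
#' with i = 1..K the evidence rank. Genes with no retained evidence are
#' omitted. Implicating genes need not be in the submitted list.
#'
#' @inheritParams prioritizeDirect
#' @param matrix a [GeneGeneMatrix-class] built over the same corpus.
#' @return data.frame with columns `rank`, `gene`, `score`, `nEvidence`,
#'   and attribute `evidence`: named list (by implicated gene) of
#'   data.frames with columns `i`, `implicating`, `AB`, `BP`, `weight`,
#'   `contribution`.
#' @export
prioritizeIndirect <- function(genes, ast, index, matrix,
                               config = scoringConfig()) {
  if (!identical(matrix@corpusHash, index@corpusHash))
    warning("gene-gene matrix and index were built from different corpora")
  allGenes <- index@genes
  matchedAll <- evaluateBoolean(ast, index, allGenes)
  terms <- queryTerms(ast)
  boosts <- .columnBoosts(index, config)
  bp <- setNames(numeric(length(allGenes)), allGenes)
  if (length(matchedAll)) {
    for (t in terms) {
      v <- .termScoreAllGenes(index, t$tokens, config, boosts)
      bp[matchedAll] <- bp[matchedAll] + v[matchedAll]
    }
    bp[setdiff(allGenes, matchedAll)] <- 0
  }
  sc <- matrix@scores
  out <- list(); evidence <- list()
  for (a in genes) {
    if (!a %in% rownames(sc)) next
    row <- sc[a, ]
    cand <- names(row)[row > 0]
    cand <- cand[cand != a & bp[cand] > 0]
    if (length(cand) == 0L) next
    ab <- as.numeric(row[cand])
    compound <- ab * bp[cand]
    ord <- order(-compound, cand)
    keep <- head(ord, config@K)
    i <- seq_along(keep)
    w <- 2^(1 - i)
    contrib <- w * compound[keep]
    score <- config@F * sum(contrib)
    evidence[[a]] <- data.frame(i = i, implicating = cand[keep],
                                AB = ab[keep], BP = as.numeric(bp[cand][keep]),
                                weight = w,
                                contribution = config@F * contrib,
                                stringsAsFactors = FALSE)
    out[[a]] <- data.frame(gene = a, score = score,
                           nEvidence = length(keep), stringsAsFactors = FALSE)
  }
  if (length(out)) {
    hits <- do.call(rbind, out)
    ord <- order(-hits$score, hits$gene)
    hits <- hits[ord, , drop = FALSE]
    hits <- data.frame(rank = seq_len(nrow(hits)), hits,
                       row.names = NULL, stringsAsFactors = FALSE)
  } else {
    hits <- data.frame(rank = integer(0), gene = character(0),
                       score = numeric(0), nEvidence = integer(0),
                       stringsAsFactors = FALSE)
  }
  attr(hits, "evidence") <- evidence
  hits
}
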