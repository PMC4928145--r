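#' Merge direct and indirect rankings into one interlaced list
#'
#' Direct scores are used as-is; indirect scores already carry the
#' normalization factor F, so the two classes are directly comparable. A
#' gene present in both lists keeps only its direct entry. Entries are
#' sorted by score descending with ties broken by symbol; within-class
#' relative order is preserved.
#'
#' @param direct data.frame from [prioritizeDirect()].
#' @param indirect data.frame from [prioritizeIndirect()].
#' @return data.frame with columns `n` (merged position), `gene`, `kind`
#'   ("direct"/"indirect"), `score`, `withinRank` (rank inside its own
#'   class, after dedup).
#' @export
interlaceResults <- function(direct, indirect) {
  ind <- indirect[!indirect$gene %in% direct$gene, , drop = FALSE]
  rows <- rbind(
    if (nrow(direct)) data.frame(gene = direct$gene, kind = "direct",
                                 score = direct$score, stringsAsFactors = FALSE),
    if (nrow(ind)) data.frame(gene = ind$gene, kind = "indirect",
                              score = ind$score, stringsAsFactors = FALSE))
  if (is.null(rows) || nrow(rows) == 0L)
    return(data.frame(n = integer(0), gene = character(0), kind = character(0),
                      score = numeric(0), withinRank = integer(0),
                      stringsAsFactors = FALSE))
  ord <- order(-rows$score, rows$gene)
  rows <- rows[ord, , drop = FALSE]
  rows$n <- seq_len(nrow(rows))
  rows$withinRank <- NA_integer_
  rows$withinRank[rows$kind == "direct"] <- seq_len(sum(rows$kind == "direct"))
  rows$withinRank[rows$kind == "indirect"] <- seq_len(sum(rows$kind == "indirect"))
  rows[, c("n", "gene", "kind", "score", "withinRank"), drop = FALSE]
}

#' Interlacing separation score
#'
#' Quantifies how intermixed the direct and indirect classes are in a
#' merged list: the number of adjacent transpositions needed to reach
#' perfect separation (all direct first), divided by the maximum possible
#' (`N_D * N_I`, the fully reversed order). 0 means every direct entry
#' precedes every indirect entry; 1 the reverse. Computed as
#' `sum over indirect entries at merged position n of (r_n + N_D - n)`
#' normalized by `N_D * N_I`, where `r_n` is the entry's rank within the
#' indirect class -- each such summand counts the direct entries that sit
#' below that indirect entry, i.e. the inverted (indirect, direct) pairs.
#'
#' @param merged data.frame from [interlaceResults()] (columns `kind`,
#'   `n`, `withinRank`), or a character vector of class labels
#'   ("direct"/"indirect" or "D"/"I") in merged order.
#' @return numeric in `[0, 1]`.
#' @examples
#' interlaceScore(c("D", "D", "I", "I")) # 0: perfectly separated
#' interlaceScore(c("I", "I", "D", "D")) # 1: fully reversed
#' interlaceScore(c("D", "I", "D", "I")) # 0.25
#' @export
interlaceScore <- function(merged) {
  if (is.character(merged)) {
    kind <- ifelse(toupper(substr(merged, 1L, 1L)) == "D", "direct", "indirect")
    merged <- data.frame(kind = kind, n = seq_along(kind), stringsAsFactors = FALSE)
    merged$withinRank <- NA_integer_
    merged$withinRank[merged$kind == "direct"] <- seq_len(sum(merged$kind == "direct"))
    merged$withinRank[merged$kind == "indirect"] <- seq_len(sum(merged$kind == "indirect"))
  }
  nD <- sum(merged$kind == "direct")
  nI <- sum(merged$kind == "indirect")
  if (nD == 0L || nI == 0L)
    stop("interlace score undefined: need at least one direct and one indirect entry (N_D = ",
         nD, ", N_I = ", nI, ")")
  ind <- merged[merged$kind == "indirect", , drop = FALSE]
  sum(ind$withinRank + nD - ind$n) / (nD * nI)
}

#' Calibrate the direct/indirect normalization factor F
#'
#' Re-scores a set of benchmark queries at each candidate F, computes the
#' mean interlace score over the queries that yield both direct and
#' indirect results, and returns the grid value whose mean is nearest the
#' target (ties: the smaller F). A target of 0.5 asks for direct and
#' indirect results to be maximally intermixed, i.e. on a comparable score
#' scale. Mean interlace is non-decreasing in F, since raising F raises
#' every indirect score and can only move indirect entries up.
#'
#' @param queries list of `list(genes = <character>, query = <string>)`.
#' @param corpus a [GeneCorpus-class].
#' @param config base [ScoringConfig-class]; its F is ignored in favour of
#'   the grid.
#' @param target desired mean interlace score (default 0.5).
#' @param grid candidate F values.
#' @param index,matrix optional prebuilt index and gene-gene matrix.
#' @return list with `F` (chosen value) and `table` (data.frame: `F`,
#'   `meanInterlace`, `medianInterlace`, `nQueries`).
#' @export
calibrateF <- function(queries, corpus, config = scoringConfig(),
                       target = 0.5, grid = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1),
                       index = NULL, matrix = NULL) {
  stopifnot(length(queries) >= 1L, length(grid) >= 1L)
  if (is.null(index)) index <- buildIndex(corpus)
  if (is.null(matrix)) matrix <- buildGeneMatrix(corpus, index, config)
  unitCfg <- scoringConfig(sectionBoosts = config@sectionBoosts, F = 1,
                           K = config@K, idfVariant = config@idfVariant,
                           includeAliasesInMatrix = config@includeAliasesInMatrix)
  runs <- lapply(queries, function(q) {
    ast <- parseQuery(q$query)
    sym <- symbolize(q$genes, corpus)
    genes <- sym$identified$symbol
    dir <- prioritizeDirect(genes, ast, index, unitCfg)
    ind <- prioritizeIndirect(genes, ast, index, matrix, unitCfg)
    ind <- ind[!ind$gene %in% dir$gene, , drop = FALSE]
    list(direct = dir, indirectUnit = ind)
  })
  qualifying <- vapply(runs, function(r) nrow(r$direct) >= 1L && nrow(r$indirectUnit) >= 1L,
                       logical(1))
  if (!any(qualifying))
    stop("calibration error: no query yields both direct and indirect results")
  runs <- runs[qualifying]
  grid <- sort(grid)
  tab <- data.frame(F = grid, meanInterlace = NA_real_,
                    medianInterlace = NA_real_, nQueries = length(runs))
  for (k in seq_along(grid)) {
    scores <- vapply(runs, function(r) {
      ind <- r$indirectUnit
      ind$score <- ind$score * grid[k]
      interlaceScore(interlaceResults(r$direct, ind))
    }, numeric(1))
    tab$meanInterlace[k] <- mean(scores)
    tab$medianInterlace[k] <- median(scores)
  }
  dist <- abs(tab$meanInterlace - target)
  best <- which(dist == min(dist))[1L] # grid sorted, so first = smallest F
  list(F = grid[best], table = tab)
}
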