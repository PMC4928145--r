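# Fixed report layouts. Direct: rank, symbol, score, matched-phenotype
# count, matched terms. Indirect: one row per implicating-gene evidence
# line under its implicated gene. Scores are never rescaled for display --
# scores from different queries are not comparable and are left alone.

.directSheet <- function(result) {
  d <- result@direct
  data.frame(rank = d$rank, symbol = d$gene, score = d$score,
             matched_phenotype_count = d$matchedPhenotypeCount,
             matched_terms = d$matchedTerms, stringsAsFactors = FALSE)
}

.indirectSheet <- function(result) {
  hits <- result@indirect
  ev <- attr(hits, "evidence")
  if (nrow(hits) == 0L) {
    return(data.frame(rank = integer(0), implicated = character(0),
                      score = numeric(0), evidence_rank = integer(0),
                      implicating = character(0), AB = numeric(0),
                      BP = numeric(0), weighted_contribution = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_len(nrow(hits)), function(k) {
    e <- ev[[hits$gene[k]]]
    data.frame(rank = hits$rank[k], implicated = hits$gene[k],
               score = hits$score[k], evidence_rank = e$i,
               implicating = e$implicating, AB = e$AB, BP = e$BP,
               weighted_contribution = e$contribution,
               stringsAsFactors = FALSE)
  }))
}

.interlacedSheet <- function(result) {
  m <- result@interlaced
  data.frame(n = m$n, symbol = m$gene, class = m$kind, score = m$score,
             within_class_rank = m$withinRank, stringsAsFactors = FALSE)
}

.inputSheet <- function(result) {
  sym <- result@symbolization
  status <- c(rep("identified", nrow(sym$identified)),
              rep("unidentified", nrow(sym$unidentified)),
              rep("dropped_duplicate", length(sym$droppedDuplicates)))
  data.frame(input = c(sym$identified$input, sym$unidentified$input,
                       sym$droppedDuplicates),
             status = status,
             symbol = c(sym$identified$symbol,
                        sym$unidentified$suggestions,
                        rep("", length(sym$droppedDuplicates))),
             stringsAsFactors = FALSE)
}

.writeTSV <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- formatNum(df[[j]])
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  lines <- c(paste(names(out), collapse = "\t"),
             if (nrow(out)) do.call(paste, c(unname(as.list(out)), sep = "\t")))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

#' Export a prioritization result
#'
#' TSV mode writes `direct.tsv`, `indirect.tsv` (one row per
#' implicating-gene evidence line), `interlaced.tsv`, `unhit.tsv` and
#' `input.tsv` into a directory; XLSX mode writes one workbook with
#' Direct / Indirect / Interlaced / Input worksheets. Numbers are written
#' at full double precision and output is deterministic. Evidence
#' snippets are serialized separately ([writeEvidenceJSON()]); with
#' `embedEvidence = TRUE`, an `evidence.json` is written next to the
#' tables.
#'
#' @param result a [PrioritizationResult-class].
#' @param path output directory (tsv) or `.xlsx` file path (xlsx).
#' @param format `"tsv"` or `"xlsx"`.
#' @param embedEvidence also write `evidence.json` with minicards for all
#'   direct hits (requires `corpus`).
#' @param corpus the corpus, needed only when `embedEvidence = TRUE`.
#' @return invisibly, the paths written.
#' @export
exportReport <- function(result, path, format = c("tsv", "xlsx"),
                         embedEvidence = FALSE, corpus = NULL) {
  format <- match.arg(format)
  sheets <- list(Direct = .directSheet(result),
                 Indirect = .indirectSheet(result),
                 Interlaced = .interlacedSheet(result),
                 Input = .inputSheet(result))
  if (format == "tsv") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    paths <- c(file.path(path, "direct.tsv"), file.path(path, "indirect.tsv"),
               file.path(path, "interlaced.tsv"), file.path(path, "unhit.tsv"),
               file.path(path, "input.tsv"))
    .writeTSV(sheets$Direct, paths[1L])
    .writeTSV(sheets$Indirect, paths[2L])
    .writeTSV(sheets$Interlaced, paths[3L])
    .writeTSV(data.frame(symbol = result@unhit, stringsAsFactors = FALSE), paths[4L])
    .writeTSV(sheets$Input, paths[5L])
  } else {
    writeXlsx(sheets, path)
    paths <- path
  }
  if (embedEvidence) {
    if (is.null(corpus)) stop("embedEvidence = TRUE requires the corpus")
    ast <- parseQuery(result@query)
    terms <- queryTerms(ast)
    ev <- lapply(result@direct$gene, function(g)
      makeMiniCards(g, terms, corpus))
    names(ev) <- result@direct$gene
    evPath <- if (format == "tsv") file.path(path, "evidence.json")
              else sub("\\.xlsx$", ".evidence.json", path)
    writeEvidenceJSON(ev, evPath)
    paths <- c(paths, evPath)
  }
  invisible(paths)
}

#' Read back a TSV report table
#'
#' Companion to [exportReport()]'s TSV mode; numeric columns come back as
#' doubles parsed from the full-precision rendering.
#'
#' @param path a TSV file written by [exportReport()].
#' @return data.frame.
#' @export
readReportTSV <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = NA, check.names = FALSE)
}
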