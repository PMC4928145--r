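# Shared fixture builders. All corpora are built in code; nothing is read
# from disk except files the tests themselves write to tempdir().

# A tiny hand-written clinical-flavoured corpus used across modules.
tinyCorpus <- function() {
  geneCorpus(list(
    geneDocument("TTC37",
      sections = c(Disorders = "trichohepatoenteric syndrome with intractable diarrhea and woolly hair",
                   Function = "component of the SKI complex",
                   Publications = "diarrhea diarrhea in infancy"),
      aliases = c("KIAA0372", "SKIC3")),
    geneDocument("TLN1",
      sections = c(Function = "actin cytoskeleton adhesion protein",
                   Pathways = "integrin signalling with IL6 crosstalk",
                   Publications = "focal adhesion dynamics"),
      aliases = "TLN"),
    geneDocument("IL6",
      sections = c(Disorders = "inflammation and capillary leak syndrome",
                   Publications = "TLN1 regulation by interleukin signalling; capillary leak reported"),
      aliases = "BSF2"),
    geneDocument("NDUFAF2",
      sections = c(Disorders = "leigh syndrome with nystagmus and apnea",
                   Function = "mitochondrial complex I assembly factor"),
      aliases = "B17.2L")))
}

# Random small corpus over a tiny vocabulary, for exhaustive oracles.
randomCorpus <- function(nGenes = 6, vocab = c("alpha", "beta", "gamma",
                                               "delta", "epsilon"),
                         sections = c("Disorders", "Function", "Publications"),
                         maxTokens = 8) {
  docs <- lapply(seq_len(nGenes), function(g) {
    secs <- vapply(sections, function(s) {
      n <- sample(0:maxTokens, 1)
      paste(sample(vocab, n, replace = TRUE), collapse = " ")
    }, character(1))
    geneDocument(sprintf("G%03d", g), sections = secs,
                 aliases = sprintf("AL%03d", g))
  })
  geneCorpus(docs, sectionRegistry = sections)
}

# Independent oracle: naive recount of a term in a section text.
naiveCount <- function(text, term) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  p <- strsplit(tolower(term), "[^a-z0-9]+")[[1]]
  p <- p[nzchar(p)]
  if (length(p) == 0 || length(toks) < length(p)) return(0L)
  hits <- 0L
  for (i in seq_len(length(toks) - length(p) + 1L)) {
    if (all(toks[i:(i + length(p) - 1L)] == p)) hits <- hits + 1L
  }
  hits
}

# Independent oracle: bubble-sort (adjacent transposition) distance from a
# label sequence to perfect separation (all direct first), normalized.
bubbleDistanceScore <- function(labels) {
  x <- ifelse(toupper(substr(labels, 1, 1)) == "D", 0L, 1L)
  nD <- sum(x == 0L); nI <- sum(x == 1L)
  stopifnot(nD >= 1, nI >= 1)
  swaps <- 0L
  y <- x
  repeat {
    moved <- FALSE
    for (i in seq_len(length(y) - 1L)) {
      if (y[i] > y[i + 1L]) {
        tmp <- y[i]; y[i] <- y[i + 1L]; y[i + 1L] <- tmp
        swaps <- swaps + 1L
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  swaps / (nD * nI)
}

# Build an interlaced data.frame directly from a label sequence, scores
# chosen strictly decreasing so interlaceResults() preserves the order.
mergedFromLabels <- function(labels) {
  kind <- ifelse(toupper(substr(labels, 1, 1)) == "D", "direct", "indirect")
  df <- data.frame(n = seq_along(kind), gene = sprintf("G%02d", seq_along(kind)),
                   kind = kind, score = rev(seq_along(kind)),
                   stringsAsFactors = FALSE)
  df$withinRank <- NA_integer_
  df$withinRank[df$kind == "direct"] <- seq_len(sum(df$kind == "direct"))
  df$withinRank[df$kind == "indirect"] <- seq_len(sum(df$kind == "indirect"))
  df
}
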