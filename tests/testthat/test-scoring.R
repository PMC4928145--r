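test_that("term score matches the closed-form tf-idf with section boosts", {
  # 10 background genes + 1 carrier: tf = 3 in one boost-1 section,
  # doc freq 1, n = 11 -> score = 3 * (1 + ln(12/2))
  docs <- c(list(geneDocument("CARRIER",
                              c(Publications = "apnea filler apnea filler apnea"))),
            lapply(1:10, function(i)
              geneDocument(sprintf("BG%02d", i), c(Publications = "filler text"))))
  cs <- geneCorpus(docs)
  idx <- buildIndex(cs)
  cfg <- scoringConfig()
  expect_equal(termScore(idx, "CARRIER", "apnea", cfg), 3 * (1 + log(12 / 2)))
  expect_equal(termScore(idx, "BG01", "apnea", cfg), 0)

  # linearity in boost: same text in Disorders (boost 4) scores exactly 4x
  docs2 <- c(list(geneDocument("CARRIER",
                               c(Disorders = "apnea filler apnea filler apnea"))),
             lapply(1:10, function(i)
               geneDocument(sprintf("BG%02d", i), c(Publications = "filler text"))))
  idx2 <- buildIndex(geneCorpus(docs2))
  expect_equal(termScore(idx2, "CARRIER", "apnea", cfg),
               4 * 3 * (1 + log(12 / 2)))

  # boost for a section unknown to the registry is a configuration error
  bad <- scoringConfig(sectionBoosts = c(NoSuchSection = 2))
  expect_error(termScore(idx, "CARRIER", "apnea", bad), "unknown section")
})

test_that("term score is increasing in tf, decreasing in df, linear in boost", {
  mkCorpus <- function(tfCarrier, nCarriers) {
    docs <- lapply(1:12, function(i) {
      txt <- if (i <= nCarriers) {
        paste(c(rep("apnea", if (i == 1) tfCarrier else 1), "pad"), collapse = " ")
      } else "pad only text"
      geneDocument(sprintf("G%02d", i), c(Function = txt))
    })
    buildIndex(geneCorpus(docs))
  }
  cfg <- scoringConfig()
  sc <- vapply(1:5, function(tf) termScore(mkCorpus(tf, 1), "G01", "apnea", cfg),
               numeric(1))
  expect_true(all(diff(sc) > 0))
  scDf <- vapply(1:6, function(df) termScore(mkCorpus(2, df), "G01", "apnea", cfg),
                 numeric(1))
  expect_true(all(diff(scDf) < 0))
  idx <- mkCorpus(2, 1)
  s1 <- termScore(idx, "G01", "apnea", scoringConfig(sectionBoosts = c(Function = 1)))
  s7 <- termScore(idx, "G01", "apnea", scoringConfig(sectionBoosts = c(Function = 7)))
  expect_equal(s7, 7 * s1)
})

test_that("direct prioritization gates on the full query and sums term scores", {
  cs <- tinyCorpus()
  idx <- buildIndex(cs)
  cfg <- scoringConfig()
  # single-term query: sole hit with score = termScore
  d <- prioritizeDirect(geneSymbols(cs), parseQuery("nystagmus"), idx, cfg)
  expect_equal(d$gene, "NDUFAF2")
  expect_equal(d$score, termScore(idx, "NDUFAF2", "nystagmus", cfg))
  expect_setequal(attr(d, "unhit"), c("TTC37", "TLN1", "IL6"))
  # AND-gated gene is excluded despite a nonzero single-term score
  dAnd <- prioritizeDirect(geneSymbols(cs), parseQuery("diarrhea AND nystagmus"),
                           idx, cfg)
  expect_equal(nrow(dAnd), 0)
  expect_true(termScore(idx, "TTC37", "diarrhea", cfg) > 0)
  # OR additivity: score equals the sum of the single-term runs
  dOr <- prioritizeDirect(geneSymbols(cs), parseQuery("leigh OR nystagmus"), idx, cfg)
  expect_equal(dOr$score[dOr$gene == "NDUFAF2"],
               termScore(idx, "NDUFAF2", "leigh", cfg) +
                 termScore(idx, "NDUFAF2", "nystagmus", cfg))
  expect_equal(dOr$matchedPhenotypeCount[dOr$gene == "NDUFAF2"], 2L)
  # NOT terms gate but never score
  dNot <- prioritizeDirect(geneSymbols(cs), parseQuery("syndrome AND NOT leigh"),
                           idx, cfg)
  expect_setequal(dNot$gene, c("TTC37", "IL6"))
  expect_equal(dNot$score[dNot$gene == "TTC37"],
               termScore(idx, "TTC37", "syndrome", cfg))
})

test_that("gene-gene matrix equals an exhaustive pair oracle", {
  cs <- tinyCorpus()
  idx <- buildIndex(cs)
  cfg <- scoringConfig()
  m <- buildGeneMatrix(cs, idx, cfg)
  sc <- geneMatrixScores(m)
  genes <- geneSymbols(cs)
  for (a in genes) {
    for (b in genes) {
      want <- if (a == b) 0 else termScore(idx, b, a, cfg)
      expect_equal(sc[a, b], want, info = sprintf("(%s,%s)", a, b))
    }
  }
  # the only nonzero link in tinyCorpus: TLN1's symbol inside IL6's document
  # and IL6's symbol inside TLN1's document
  expect_true(sc["TLN1", "IL6"] > 0)
  expect_true(sc["IL6", "TLN1"] > 0)
  expect_equal(sum(sc > 0), 2)
})

test_that("gene-gene matrix on random corpora matches brute force; no self links", {
  set.seed(13)
  for (k in 1:5) {
    cs <- randomCorpus(nGenes = sample(3:8, 1))
    # mention some symbols inside other genes' documents
    docs <- cs@documents
    syms <- geneSymbols(cs)
    for (j in seq_along(docs)) {
      if (runif(1) < 0.6) {
        other <- sample(setdiff(syms, docs[[j]]$symbol), 1)
        docs[[j]]$sections["Publications"] <-
          paste(docs[[j]]$sections["Publications"], other, other)
      }
    }
    cs <- geneCorpus(docs, sectionRegistry = sectionRegistry(cs))
    idx <- buildIndex(cs)
    cfg <- scoringConfig()
    sc <- geneMatrixScores(buildGeneMatrix(cs, idx, cfg))
    for (a in syms) for (b in syms) {
      want <- if (a == b) 0 else termScore(idx, b, a, cfg)
      expect_equal(sc[a, b], want)
    }
  }
})

test_that("aliases extend gene-gene links only when configured", {
  cs <- geneCorpus(list(
    geneDocument("AA", c(Function = "x"), aliases = "OLDNAME"),
    geneDocument("BB", c(Publications = "OLDNAME mentioned here"))))
  idx <- buildIndex(cs)
  scOff <- geneMatrixScores(buildGeneMatrix(cs, idx, scoringConfig()))
  expect_equal(scOff["AA", "BB"], 0)
  scOn <- geneMatrixScores(buildGeneMatrix(
    cs, idx, scoringConfig(includeAliasesInMatrix = TRUE)))
  expect_true(scOn["AA", "BB"] > 0)
})

test_that("indirect score implements F * sum 2^(1-i) AB_i BP_i with top-K truncation", {
  # closed-form kernel: 6 equal compounds of 1.0, F = 0.05 -> 0.096875 and
  # the 6th candidate contributes nothing
  expect_equal(PhenoRanker:::weightedEvidenceScore(rep(1, 6), F = 0.05, K = 5),
               0.096875)
  expect_equal(PhenoRanker:::weightedEvidenceScore(rep(1, 5), F = 0.05, K = 5),
               PhenoRanker:::weightedEvidenceScore(rep(1, 9), F = 0.05, K = 5))
  expect_equal(PhenoRanker:::weightedEvidenceScore(c(4, 2), F = 0.05, K = 5),
               0.05 * (4 + 0.5 * 2))

  # end-to-end: 7 implicating genes mention TARGET and match the query;
  # exactly 5 evidence rows retained, score recomputable from the rows
  docs <- c(list(geneDocument("TARGET", c(Function = "background words only"))),
            lapply(1:7, function(i)
              geneDocument(sprintf("IMP%d", i),
                           c(Publications = paste(c(rep("TARGET", i), rep("apnea", i)),
                                                  collapse = " ")))),
            lapply(1:4, function(i)
              geneDocument(sprintf("BG%d", i), c(Function = "quiet filler"))))
  cs <- geneCorpus(docs)
  idx <- buildIndex(cs)
  cfg <- scoringConfig()
  m <- buildGeneMatrix(cs, idx, cfg)
  ast <- parseQuery("apnea")
  ind <- prioritizeIndirect("TARGET", ast, idx, m, cfg)
  expect_equal(ind$gene, "TARGET")
  expect_equal(ind$nEvidence, 5L)
  ev <- attr(ind, "evidence")$TARGET
  expect_equal(nrow(ev), 5)
  # rows sorted by compound descending; weights are 2^(1-i)
  expect_true(all(diff(ev$AB * ev$BP) <= 0))
  expect_equal(ev$weight, 2^(1 - (1:5)))
  expect_equal(ind$score, cfg@F * sum(ev$weight * ev$AB * ev$BP))
  expect_equal(ind$score, PhenoRanker:::weightedEvidenceScore(
    geneMatrixScores(m)["TARGET", sprintf("IMP%d", 1:7)] *
      vapply(sprintf("IMP%d", 1:7), function(g) termScore(idx, g, "apnea", cfg),
             numeric(1)), F = cfg@F, K = cfg@K))
  # AB and BP positive in every retained row; dropping a row lowers the score
  expect_true(all(ev$AB > 0 & ev$BP > 0))
  expect_true(all(ev$contribution > 0))
})

test_that("indirect candidates are corpus-wide and gated by the full query", {
  # implicating gene IL6 is NOT in the submitted list, mirrors the
  # submitted-TLN1 / implicating-IL6 situation
  cs <- tinyCorpus()
  idx <- buildIndex(cs)
  cfg <- scoringConfig()
  m <- buildGeneMatrix(cs, idx, cfg)
  ind <- prioritizeIndirect("TLN1", parseQuery('"capillary leak"'), idx, m, cfg)
  expect_equal(ind$gene, "TLN1")
  expect_equal(attr(ind, "evidence")$TLN1$implicating, "IL6")
  # direct score of TLN1 for this query is zero: indirect-only evidence
  expect_equal(termScore(idx, "TLN1", "capillary leak", cfg), 0)
  # with an AND query IL6 cannot satisfy, the link dies
  ind2 <- prioritizeIndirect("TLN1", parseQuery('"capillary leak" AND nystagmus'),
                             idx, m, cfg)
  expect_equal(nrow(ind2), 0)
  # a gene nobody mentions has no indirect entry
  ind3 <- prioritizeIndirect("NDUFAF2", parseQuery('"capillary leak"'), idx, m, cfg)
  expect_equal(nrow(ind3), 0)
})

test_that("planted indirect gene is found end-to-end on a synthetic corpus", {
  sim <- syntheticCorpus(nGenes = 40, vocabSize = 300,
                         backgroundTokensPerSection = 40, seed = 5)
  idx <- buildIndex(sim$corpus)
  cfg <- scoringConfig()
  m <- buildGeneMatrix(sim$corpus, idx, cfg)
  ast <- parseQuery(paste(sim$truth$plantedDirectTerms, collapse = " OR "))
  d <- prioritizeDirect(geneSymbols(sim$corpus), ast, idx, cfg)
  expect_false(sim$truth$implicatedGene %in% d$gene)
  ind <- prioritizeIndirect(geneSymbols(sim$corpus), ast, idx, m, cfg)
  expect_true(sim$truth$implicatedGene %in% ind$gene)
  expect_true(ind$score[ind$gene == sim$truth$implicatedGene] > 0)
  ev <- attr(ind, "evidence")[[sim$truth$implicatedGene]]
  expect_true(all(ev$implicating %in% sim$truth$implicatingGenes))
})
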