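# Fixture VCF with snpEff-style ANN annotations, written in code.
writeFixtureVCF <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    '##INFO=<ID=ANN,Number=.,Type=String,Description="Functional annotations: \'Allele | Annotation | Annotation_Impact | Gene_Name | Gene_ID\'">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t100\t.\tA\tG\t50\tPASS\tDP=10;ANN=G|missense_variant|MODERATE|TTC37|ENSG1",
    "1\t200\t.\tC\tT\t50\tPASS\tANN=T|stop_gained|HIGH|TTC37|ENSG1;DP=12",
    # multi-allelic: two ANN entries for different genes
    "2\t300\t.\tG\tA,C\t50\tPASS\tANN=A|missense_variant|MODERATE|TLN1|ENSG2,C|synonymous_variant|LOW|IL6|ENSG3"),
    path)
}

writeFixtureVEP <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=CSQ,Number=.,Type=String,Description="Consequence annotations from VEP. Format: Allele|Consequence|IMPACT|SYMBOL|Gene">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t100\t.\tA\tG\t50\tPASS\tCSQ=G|missense_variant|MODERATE|NDUFAF2|ENSG4",
    "1\t200\t.\tC\tT\t50\tPASS\tCSQ=T|missense_variant|MODERATE|IL6|ENSG3"),
    path)
}

test_that("gene lists extract from annotated VCFs with variant counts", {
  f <- tempfile(fileext = ".vcf")
  writeFixtureVCF(f)
  genes <- extractGeneList(f, "snpeff-ANN")
  expect_equal(as.character(genes), c("TTC37", "TLN1", "IL6"))
  vc <- attr(genes, "variantCounts")
  expect_equal(vc[["TTC37"]], 2L)
  expect_equal(vc[["TLN1"]], 1L)
  expect_equal(vc[["IL6"]], 1L)
  # VEP CSQ with SYMBOL sub-field
  f2 <- tempfile(fileext = ".vcf")
  writeFixtureVEP(f2)
  expect_equal(as.character(extractGeneList(f2, "vep-CSQ")), c("NDUFAF2", "IL6"))
  # missing annotation errors and names available INFO keys
  expect_error(extractGeneList(f2, "snpeff-ANN"), "CSQ")
  expect_error(extractGeneList(f, "info-key:GENE"), "DP")
})

test_that("pipeline partitions submitted genes into direct / indirect-only / un-hit", {
  cs <- tinyCorpus()
  res <- prioritize(cs, geneSymbols(cs), '"capillary leak" OR nystagmus')
  d <- directHits(res)$gene
  iOnly <- setdiff(indirectHits(res)$gene, d)
  u <- unhitGenes(res)
  # IL6 and NDUFAF2 hit directly; TLN1 only through IL6; TTC37 un-hit
  expect_setequal(d, c("IL6", "NDUFAF2"))
  expect_equal(iOnly, "TLN1")
  expect_equal(u, "TTC37")
  expect_setequal(c(d, iOnly, u), geneSymbols(cs))
  expect_equal(length(d) + length(iOnly) + length(u), nGenes(cs))
  # partition invariant over randomized synthetic pipelines
  for (seed in 1:5) {
    sim <- syntheticCorpus(nGenes = 25, vocabSize = 200,
                           backgroundTokensPerSection = 25, seed = seed)
    r <- prioritize(sim$corpus, geneSymbols(sim$corpus),
                    paste(sim$truth$plantedDirectTerms, collapse = " OR "))
    dd <- directHits(r)$gene
    ii <- setdiff(indirectHits(r)$gene, dd)
    expect_setequal(c(dd, ii, unhitGenes(r)), geneSymbols(sim$corpus))
    expect_equal(length(dd) + length(ii) + length(unhitGenes(r)),
                 nGenes(sim$corpus))
  }
})

test_that("TSV export lays out evidence rows and round-trips at 12 digits", {
  cs <- tinyCorpus()
  res <- prioritize(cs, c("TTC37", "tln1", "IL6", "NDUFAF2", "KIAA0372"),
                    '"capillary leak" OR nystagmus OR leigh')
  dir1 <- file.path(tempdir(), "rep1")
  exportReport(res, dir1, format = "tsv")
  direct <- readReportTSV(file.path(dir1, "direct.tsv"))
  expect_equal(direct$symbol, directHits(res)$gene)
  expect_equal(direct$score, directHits(res)$score, tolerance = 1e-12)
  indirect <- readReportTSV(file.path(dir1, "indirect.tsv"))
  # one row per implicating-gene evidence line
  ev <- indirectEvidence(res)
  expect_equal(nrow(indirect), sum(vapply(ev, nrow, integer(1))))
  expect_equal(indirect$AB, unlist(lapply(ev, `[[`, "AB"), use.names = FALSE),
               tolerance = 1e-12)
  inter <- readReportTSV(file.path(dir1, "interlaced.tsv"))
  expect_equal(inter$symbol, interlaced(res)$gene)
  expect_equal(readReportTSV(file.path(dir1, "unhit.tsv"))$symbol, unhitGenes(res))
  input <- readReportTSV(file.path(dir1, "input.tsv"))
  expect_equal(nrow(input), 5) # every submitted id appears with a status
  expect_true("dropped_duplicate" %in% input$status) # KIAA0372 duplicates TTC37
  # byte-identical re-export
  dir2 <- file.path(tempdir(), "rep2")
  exportReport(res, dir2, format = "tsv")
  for (f in list.files(dir1)) {
    expect_identical(readBin(file.path(dir1, f), "raw", file.size(file.path(dir1, f))),
                     readBin(file.path(dir2, f), "raw", file.size(file.path(dir2, f))))
  }
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("empty result classes export as header-only tables", {
  cs <- tinyCorpus()
  res <- prioritize(cs, geneSymbols(cs), "absentterm OR woolly")
  d <- file.path(tempdir(), "rep-empty")
  exportReport(res, d, format = "tsv")
  ind <- readReportTSV(file.path(d, "indirect.tsv"))
  expect_equal(nrow(ind), 0)
  expect_equal(names(ind), c("rank", "implicated", "score", "evidence_rank",
                             "implicating", "AB", "BP", "weighted_contribution"))
  unlink(d, recursive = TRUE)
})

test_that("xlsx workbook carries four sheets readable by an independent parser", {
  cs <- tinyCorpus()
  res <- prioritize(cs, geneSymbols(cs), '"capillary leak" OR nystagmus')
  f <- tempfile(fileext = ".xlsx")
  exportReport(res, f, format = "xlsx")
  exdir <- tempfile()
  files <- utils::unzip(f, exdir = exdir)
  expect_true(any(grepl("workbook.xml$", files)))
  wb <- xml2::read_xml(file.path(exdir, "xl", "workbook.xml"))
  names <- xml2::xml_attr(xml2::xml_find_all(wb, ".//d1:sheet",
                                             xml2::xml_ns(wb)), "name")
  expect_equal(names, c("Direct", "Indirect", "Interlaced", "Input"))
  # direct sheet cell values match the in-memory result
  sh <- xml2::read_xml(file.path(exdir, "xl", "worksheets", "sheet1.xml"))
  ns <- xml2::xml_ns(sh)
  rows <- xml2::xml_find_all(sh, ".//d1:row", ns)
  expect_equal(length(rows), nrow(directHits(res)) + 1L)
  firstDataRow <- xml2::xml_find_all(rows[[2]], ".//d1:c", ns)
  vals <- vapply(firstDataRow, function(c) xml2::xml_text(c), character(1))
  expect_equal(vals[2], directHits(res)$gene[1])
  expect_equal(as.numeric(vals[3]), directHits(res)$score[1], tolerance = 1e-12)
  # deterministic: re-export is byte-identical
  f2 <- tempfile(fileext = ".xlsx")
  exportReport(res, f2, format = "xlsx")
  expect_identical(readBin(f, "raw", file.size(f)), readBin(f2, "raw", file.size(f2)))
})

test_that("whole runs are reproducible: same corpus, config and inputs, same bytes", {
  sim <- syntheticCorpus(nGenes = 25, vocabSize = 200,
                         backgroundTokensPerSection = 25, seed = 17)
  q <- paste(sim$truth$plantedDirectTerms, collapse = " OR ")
  r1 <- prioritize(sim$corpus, geneSymbols(sim$corpus), q)
  r2 <- prioritize(sim$corpus, geneSymbols(sim$corpus), q)
  d1 <- file.path(tempdir(), "repro1"); d2 <- file.path(tempdir(), "repro2")
  exportReport(r1, d1, format = "tsv"); exportReport(r2, d2, format = "tsv")
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
  }
  expect_equal(r1@corpusHash, corpusHash(sim$corpus))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("gene-gene matrix TSV cache round-trips scores", {
  cs <- tinyCorpus()
  idx <- buildIndex(cs)
  m <- buildGeneMatrix(cs, idx, scoringConfig())
  f <- tempfile(fileext = ".tsv")
  writeGeneMatrix(m, f)
  lines <- readLines(f)
  expect_match(lines[1], m@corpusHash, fixed = TRUE)
  df <- utils::read.delim(f, skip = 1)
  sc <- geneMatrixScores(m)
  for (r in seq_len(nrow(df))) {
    expect_equal(df$AB[r], sc[df$A[r], df$B[r]], tolerance = 1e-12)
  }
  expect_equal(nrow(df), sum(sc > 0))
})
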