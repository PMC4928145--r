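# PhenoRanker

Phenotype-driven prioritization of candidate genes from annotation text.

After variant filtering, an exome or panel experiment still leaves tens to
thousands of candidate genes. PhenoRanker ranks them against a free-text
Boolean phenotype query (e.g. `seizures OR "optic atrophy" OR apnea`) using
each gene's section-structured annotation document, and surfaces the
evidence behind every score. It is aimed at users doing NGS gene-disease
interpretation who want a transparent, self-contained, scriptable ranking
engine that works on any corpus they can express as one JSON line per gene.

## The model

Two complementary scores per gene:

* **Direct** — the whole Boolean query first gates the gene set (an
  unsatisfied `AND` excludes a gene however well one term matches); the
  query is then decomposed into its positive terms, each scored by boosted
  tf-idf and summed:

      score(t, g) = Σ_s b_s · tf(t, g, s) · (1 + ln((N + 1)/(df_t + 1)))

  with per-section boosts `b_s` (defaults: Disorders 4, Function 2, others
  1). Quoted phrases count contiguous token runs within a section.

* **Indirect (guilt by association)** — gene A is scored through the up to
  K = 5 implicating genes B with the strongest compound of `AB` (the
  tf-idf propensity of A's symbol inside B's document, from a precomputed
  directional gene-gene matrix) and `BP` (B's own direct score for the
  query):

      score(A) = F · Σ_{i=1..5} 2^(1−i) · AB_i · BP_i,   F = 0.05

The two rankings are merged into one interlaced list; how intermixed the
classes are is measured by a normalized adjacent-transposition (inversion)
metric in [0, 1] — 0 when every direct entry precedes every indirect one,
1 in the reverse — which `calibrateF()` uses to tune F toward a target
mean of 0.5 on benchmark query sets.

A synthetic-corpus generator with planted ground truth (Zipf background
vocabulary, a spiked causal gene, and an implicated/implicating gene
cluster) underpins the test suite and provides reproducible benchmarks.

## Worked example

```r
library(PhenoRanker)

sim <- syntheticCorpus(nGenes = 60, vocabSize = 300,
                       backgroundTokensPerSection = 40, seed = 42)
sim$truth$causalGene      # "GENE0049"  (phenotype terms planted in Disorders)
sim$truth$implicatedGene  # "GENE0037"  (no phenotype terms of its own)

res <- prioritize(sim$corpus, geneSymbols(sim$corpus),
                  "ataxia OR seizures OR nystagmus OR hypotonia")
res
#> PrioritizationResult
#>   query: ataxia OR seizures OR nystagmus OR hypotonia
#>   submitted: 60 identified, 0 unidentified, 0 duplicate(s) dropped
#>   hits: 4 direct, 1 indirect, 55 un-hit
#>   top of interlaced list:
#>      1. GENE0049     direct   140.0574
#>      2. GENE0010     direct   52.5215
#>      3. GENE0001     direct   42.0172
#>      4. GENE0025     direct   38.5158
#>      5. GENE0037     indirect 29.1801
```

The planted causal gene tops the direct ranking with all four query terms
matched (`matchedPhenotypeCount = 4`); its score of 140.06 is the sum of
its four per-term boosted tf-idf scores. GENE0037, which never mentions
the phenotype, is recovered purely indirectly; its evidence rows
reconstruct the score exactly:

```r
indirectEvidence(res)[["GENE0037"]]
#>          i implicating       AB       BP weight contribution
#> GENE0010 1    GENE0010 7.449159 52.52154   1.00    19.562065
#> GENE0001 2    GENE0001 7.449159 42.01723   0.50     7.824826
#> GENE0025 3    GENE0025 3.724580 38.51580   0.25     1.793189
```

(0.05 · (1.00·7.449·52.52 + 0.50·7.449·42.02 + 0.25·3.725·38.52) = 29.18,
the indirect score above.) Evidence snippets show each hit in context:

```r
makeMiniCards("GENE0049", "ataxia", sim$corpus, window = 4)[[1]]$snippet
#> "seizures tok00002 tok00001 tok00082 ataxia seizures tok00003 tok00050 tok00010"
```

Results export as TSV files or a four-worksheet XLSX workbook
(`exportReport(res, "report", format = "tsv")`), gene lists can be read
from annotated VCFs (`extractGeneList(vcf, "snpeff-ANN")`), and
`inst/cli/phenoranker.R` wraps the same functions for shell use.

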