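---
title: "Phenotype-driven gene prioritization: model, parameters and design"
author: "PhenoRanker authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-driven gene prioritization: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhenoRanker)
```

## The problem

An exome or gene-panel experiment typically leaves tens to thousands of
candidate genes after variant filtering. PhenoRanker ranks such a
candidate list against a clinician's free-text description of the
phenotype. Each gene is represented by a *document* — its annotation text
segmented into named sections (Disorders, Function, Summaries, Pathways,
Publications, Expression) — and the engine asks two questions for a
Boolean phenotype query:

* **Direct**: how strongly does this gene's own document match the query?
* **Indirect (guilt by association)**: even if the gene's document says
  nothing about the phenotype, do *other* genes that mention this gene's
  symbol match the query? A gene B that both cites gene A and matches the
  phenotype *implicates* A.

The second mode matters because annotation depth is uneven: a poorly
annotated gene can still be the causal gene, discoverable through its
well-annotated interaction partners, paralogs or pathway neighbours.

## Direct scoring

Queries are free text with Boolean structure: bare words, quoted phrases,
`AND`/`OR`/`NOT` (case-insensitive) and parentheses, precedence
`NOT > AND > OR`. Unquoted adjacent terms are joined by `OR`, because the
common use is a list of symptom synonyms; clinicians who want conjunction
write `AND` explicitly. Matching is deliberately free-text — no ontology
translation — so rare or newly coined clinical vocabulary is searchable
verbatim. Tokenization case-folds, splits on any non-alphanumeric
character, keeps digits, and applies no stemming: stemming risks merging
distinct rare medical terms, which is exactly where this tool must be
precise. A quoted phrase matches only as a contiguous token run inside a
single section, and its document frequency is computed from phrase
occurrences, never from the intersection of its tokens.

Evaluation is match-then-decompose: the whole Boolean expression first
selects the genes that satisfy it over their entire document (a term is
satisfied by one occurrence anywhere), then the query is decomposed into
its positive terms, each scored independently, and the per-term scores
summed. `NOT` terms gate matching but contribute nothing to scores. For a
term $t$ and gene $g$:

$$\mathrm{score}(t, g) \;=\; \sum_{s \in \text{sections}} b_s \cdot
\mathrm{tf}(t, g, s) \cdot \left(1 + \ln\frac{N + 1}{\mathrm{df}(t) + 1}\right)$$

where $\mathrm{tf}$ is the raw occurrence count in section $s$, $N$ the
number of genes, $\mathrm{df}$ the number of gene documents containing
$t$, and $b_s$ a per-section boost. The idf form is a standard smoothed
variant: positive and finite even when $\mathrm{df} = N$, strictly
decreasing in $\mathrm{df}$. Exact parity with any particular search
engine's internals is a non-goal (those internals are version-dependent);
what the package guarantees, and tests, are the monotonicity properties —
strictly increasing in tf, non-increasing in df, linear in boost — and the
closed form above.

Default boosts are Disorders 4, Function 2, all other sections 1. The
choice encodes that a phenotype term inside a disorder annotation is much
stronger evidence of a gene–disease link than the same term in a
publication title list; the 4/2/1 ladder is a package default, exposed in
`scoringConfig()` for users whose corpora weight sections differently. No
document-length normalization is applied: heavily studied genes do score
higher, a known bias of annotation-text scoring that we surface rather
than hide, since correcting it silently would distort the evidence shown
to the user.

## Indirect scoring

A precomputed directional gene-to-gene matrix holds, for every ordered
pair, the propensity of gene A's symbol inside gene B's document —
`termScore` applied to A's official symbol as a term in B's document. Only
the official symbol is used by default: aliases are often shared or
clash with common words, which would inflate spurious links
(`includeAliasesInMatrix = TRUE` opts in). For a submitted gene A, every
other gene B corpus-wide with a nonzero AB entry and a positive direct
query score BP is a candidate implicating gene; candidates are ranked by
the compound $AB_i \cdot BP_i$ and at most $K = 5$ are kept:

$$\mathrm{score}(A) \;=\; F \cdot \sum_{i=1}^{5} 2^{\,1-i}\, AB_i \cdot BP_i$$

The geometric weights make the best implicating gene dominate while
letting corroborating genes add diminishing support; with five equal
compounds the bracket sums to $1.9375$, which bounds the indirect score by
$1.9375\,F \cdot \max_i AB_i BP_i$. Implicating genes are gated by the
*full* Boolean query (not any single term), for consistency with the
direct mode; candidates are drawn corpus-wide because the implicating
gene need not be on the user's candidate list at all. $F = 0.05$ places
indirect scores on a scale comparable with direct scores (next section).

## Interlacing and the separation metric

Direct and indirect rankings are merged into one list by score (indirect
scores already carry $F$); a gene with both kinds of evidence keeps its
direct entry, and all ties anywhere break by ascending symbol so runs are
reproducible. How intermixed the two classes end up is measured by a
normalized adjacent-transposition distance: the number of adjacent swaps
needed to reach perfect separation (all direct first), divided by the
maximum $N_D \cdot N_I$ (the fully reversed arrangement). Equivalently it
is the fraction of (direct, indirect) pairs in inverted order, computed
as $\sum (r_n + N_D - n)$ over the indirect entries at merged positions
$n$ with within-class ranks $r_n$: each summand counts the direct entries
sitting below one indirect entry. The summation runs over indirect
entries only — extending it over all entries with within-class ranks
would not yield 0 for the perfectly separated list, so the swap-count
semantics (which reproduce the 0 and 1 extremes exactly) are the
implemented definition, verified exhaustively against a bubble-sort
distance oracle for all class patterns up to length 10.

`calibrateF()` turns the metric into a tuning procedure: over a set of
benchmark queries that yield both result classes, it scores a grid of
$F$ values and picks the one whose mean interlace score is nearest a
target, default 0.5 — the point where neither class systematically
dominates. Mean interlace is non-decreasing in $F$ (raising $F$ only
raises indirect scores), so the selection is well behaved; ties go to
the smaller $F$, preferring the more conservative weighting of
second-hand evidence.

## The synthetic benchmark corpus

`syntheticCorpus()` generates the corpora all tests run on, emulating a
spiked-probe benchmark. Background text is drawn i.i.d. from a
Zipf($s = 1.1$) vocabulary — reproducing the heavy document-frequency
skew that tf-idf assumes — kept disjoint from gene symbols and phenotype
terms, so every informative occurrence is planted, never accidental. Two
signals are planted per corpus:

* the **causal (probe) gene** receives each phenotype term
  $\mathrm{Poisson}(\lambda)$ times in Disorders, its highest-boost
  section;
* the **implicated gene** receives no phenotype terms at all, while each
  of 3 **implicating genes** receives the phenotype terms in Publications
  and the implicated gene's symbol in Pathways.

Defaults are 500 genes, vocabulary 2000, 6 sections of 100 background
tokens, 4 phenotype terms (multi-term OR queries of four to seven
symptoms are typical clinical usage), injection rate $\lambda = 3$, and
3 implicating genes. Placing the implicating genes' phenotype mentions in
a boost-1 section encodes the intended scenario — genes *related to* the
phenotype rather than primarily annotated with it — and a design-stage
power calculation shows why recovery is then reliable: the causal gene's
direct score is $4\,\mathrm{idf}\cdot X$ with $X \sim \mathrm{Poisson}(12)$
(four terms at rate 3, boost 4) against each implicating gene's
$1\cdot\mathrm{idf}\cdot Y$, $Y \sim \mathrm{Poisson}(12)$, and
$P(Y > 4X) \approx 2\times10^{-3}$ per competitor. The recovery suite
(50 seeded corpora at the full 500-gene scale) requires the probe gene at
direct rank 1 in ≥ 95% of runs and the implicated gene in the indirect
top 3 in ≥ 90%.

What the generator does *not* emulate — and therefore what passing these
tests does not show about real data: correlated medical vocabulary
(symptom terms co-occur in real annotations), uneven document lengths and
study-depth bias, alias collisions with English words, and dense
gene-gene mention networks in which indirect results compete. The
generator's role is to make planted ground truth recoverable and exact
counting verifiable, not to simulate a knowledgebase.

## Numerical and interface choices

* **Determinism.** A seed fully determines a generated corpus
  (bit-identical JSONL); identical inputs, config and corpus give
  byte-identical TSV and XLSX reports, and all rank ties break by symbol.
* **Degenerate inputs.** Empty corpora, unbalanced quotes/parentheses,
  dangling operators and all-negative queries (no positive term) are
  rejected with positions; an interlace score is undefined (error, not
  NaN) when either class is empty; `injectionRate = 0` plants nothing.
* **Symbolization.** Identifier matching is case-insensitive with
  original casing preserved. An alias owned by two genes, or equal to
  another gene's official symbol, is never auto-resolved: it is reported
  with ranked suggestions (exact alias owners first, then prefix matches,
  capped at 10). Duplicates after resolution collapse with a report. Gene
  lists beyond 4000 entries process with a warning.
* **Reports.** TSV files (one evidence row per implicating gene in the
  indirect table) and a four-worksheet XLSX workbook are written at full
  double precision with no cross-query rescaling, since scores from
  different queries are not comparable. The XLSX writer is
  self-contained (inline strings, uncompressed OOXML container), so
  export works with no spreadsheet dependency; output is verified in the
  suite with an independent XML parser.
* **Problem sizes.** The test suite exercises exhaustive oracles on
  corpora up to 20 genes, label sequences to length 10, and the recovery
  benchmark at 500 genes x 50 seeds — sizes at which brute-force
  verification is exact while the whole suite stays fast.

## Known limitations

Scores are corpus- and query-relative: they support ranking within one
run, not comparison across queries or corpora (no global or P-value
normalization is attempted). The engine is text-based: it can only find
what annotation text states, inherits annotation-depth bias, and treats
all mentions as positive evidence (a document saying a gene is *not*
involved in a phenotype still scores). Phrase matching is exact after
tokenization; there is no fuzzy matching or spelling correction.
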