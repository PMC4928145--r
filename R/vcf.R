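#' Extract a candidate gene list from an annotated VCF
#'
#' Reads the per-variant functional annotation field and collects gene
#' names in order of first appearance, deduplicated, with the number of
#' variants per gene retained in the `variantCounts` attribute. Variant
#' records are read only; no variant-level scoring or filtering is done.
#'
#' Supported annotation sources:
#' * `"snpeff-ANN"`: the `ANN` INFO field; the gene name is sub-field 4 of
#'   each `|`-separated entry, entries comma-separated (one or more per
#'   allele).
#' * `"vep-CSQ"`: the `CSQ` INFO field; the sub-field named `SYMBOL` (or
#'   `Gene` if `SYMBOL` is absent) located from the `Format:` part of the
#'   header description.
#' * `"info-key:<NAME>"`: a plain INFO key whose value is a gene name or a
#'   comma-separated list of gene names.
#'
#' @param vcfPath path to a VCF 4.x file (plain or bgzipped).
#' @param annotationSource one of the forms above; default `"snpeff-ANN"`.
#' @return character vector of gene names (first-appearance order) with
#'   attribute `variantCounts` (named integer: variants per gene).
#' @export
extractGeneList <- function(vcfPath, annotationSource = "snpeff-ANN") {
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  info <- vcf@fix[, "INFO"]
  meta <- vcf@meta
  availKeys <- unique(sub("^##INFO=<ID=([^,]+),.*$", "\\1",
                          grep("^##INFO=", meta, value = TRUE)))

  getField <- function(key) {
    pat <- paste0("(?:^|;)", key, "=([^;]*)")
    m <- regmatches(info, regexec(pat, info))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, character(1))
  }

  if (identical(annotationSource, "snpeff-ANN")) {
    if (!"ANN" %in% availKeys)
      stop("no ANN field in VCF header; available INFO keys: ",
           paste(availKeys, collapse = ", "))
    vals <- getField("ANN")
    perVariant <- lapply(vals, function(v) {
      if (is.na(v)) return(character(0))
      unique(vapply(strsplit(v, ",", fixed = TRUE)[[1L]], function(e) {
        f <- strsplit(e, "|", fixed = TRUE)[[1L]]
        if (length(f) >= 4L) f[4L] else NA_character_
      }, character(1), USE.NAMES = FALSE))
    })
  } else if (identical(annotationSource, "vep-CSQ")) {
    if (!"CSQ" %in% availKeys)
      stop("no CSQ field in VCF header; available INFO keys: ",
           paste(availKeys, collapse = ", "))
    descLine <- grep("^##INFO=<ID=CSQ,", meta, value = TRUE)[1L]
    fmt <- sub('.*Format: *([^">]+).*', "\\1", descLine)
    fields <- strsplit(fmt, "|", fixed = TRUE)[[1L]]
    pos <- match("SYMBOL", fields)
    if (is.na(pos)) pos <- match("Gene", fields)
    if (is.na(pos))
      stop("CSQ Format has neither SYMBOL nor Gene sub-field: ", fmt)
    vals <- getField("CSQ")
    perVariant <- lapply(vals, function(v) {
      if (is.na(v)) return(character(0))
      unique(vapply(strsplit(v, ",", fixed = TRUE)[[1L]], function(e) {
        f <- strsplit(e, "|", fixed = TRUE)[[1L]]
        if (length(f) >= pos) f[pos] else NA_character_
      }, character(1), USE.NAMES = FALSE))
    })
  } else if (startsWith(annotationSource, "info-key:")) {
    key <- sub("^info-key:", "", annotationSource)
    if (!key %in% availKeys)
      stop("no ", key, " field in VCF header; available INFO keys: ",
           paste(availKeys, collapse = ", "))
    vals <- getField(key)
    perVariant <- lapply(vals, function(v) {
      if (is.na(v)) return(character(0))
      unique(strsplit(v, ",", fixed = TRUE)[[1L]])
    })
  } else {
    stop("unknown annotation source: ", annotationSource)
  }

  perVariant <- lapply(perVariant, function(g) g[!is.na(g) & nzchar(g)])
  flat <- unlist(perVariant, use.names = FALSE)
  genes <- unique(flat)
  counts <- vapply(genes, function(g)
    sum(vapply(perVariant, function(v) g %in% v, logical(1))), integer(1))
  attr(genes, "variantCounts") <- counts
  genes
}
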