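#' @importFrom methods new validObject is slot
#' @importFrom stats rpois median setNames
#' @importFrom utils head tail
NULL

# Tokenizer used everywhere: case-fold, split on any non-alphanumeric run,
# keep digits, drop empties. No stemming -- rare medical terms must not be
# merged by a stemmer.
tokenize <- function(text) {
  if (length(text) == 0L || is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1L]]
  toks[nzchar(toks)]
}

# Tokenize with character offsets into the original text; needed for
# evidence snippets. Returns data.frame(token, start, end) (1-based,
# inclusive).
tokenizeOffsets <- function(text) {
  m <- gregexpr("[A-Za-z0-9]+", text)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(token = tolower(substring(text, m, m + len - 1L)),
             start = as.integer(m), end = as.integer(m + len - 1L),
             stringsAsFactors = FALSE)
}

# Count occurrences of a contiguous token sequence inside a token vector.
countPhrase <- function(tokens, phrase) {
  np <- length(phrase)
  nt <- length(tokens)
  if (np == 0L || nt < np) return(0L)
  if (np == 1L) return(sum(tokens == phrase))
  hit <- tokens[seq_len(nt - np + 1L)] == phrase[1L]
  for (k in seq_len(np - 1L)) {
    hit <- hit & tokens[seq_len(nt - np + 1L) + k] == phrase[k + 1L]
  }
  sum(hit)
}

# Zipf(s) probabilities over ranks 1..n.
zipfProbs <- function(n, s = 1.1) {
  p <- seq_len(n)^(-s)
  p / sum(p)
}

# Content hash of arbitrary character lines (used to key caches to a corpus).
contentHash <- function(lines) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(lines, f, useBytes = TRUE)
  unname(tools::md5sum(f))
}

# Render numbers for TSV output at full double precision.
formatNum <- function(x) {
  ifelse(is.na(x), "", sprintf("%.15g", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
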