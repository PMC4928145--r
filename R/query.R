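#' Parse a free-text Boolean phenotype query
#'
#' Grammar: quoted strings are contiguous-phrase terms; bare words are
#' single-token terms; operators `AND`, `OR`, `NOT` (case-insensitive) and
#' parentheses are honored with precedence `NOT > AND > OR`; adjacent terms
#' with no explicit operator are joined by `OR` (the natural reading for
#' lists of symptom synonyms). A hyphenated bare word tokenizes to several
#' tokens and is matched as a phrase. Queries must contain at least one
#' positive (non-negated) term.
#'
#' @param text query string, e.g. `'seizures OR "optic atrophy" OR apnea'`.
#' @return a query AST: nested lists with `kind` in TERM/AND/OR/NOT;
#'   TERM nodes carry `tokens` (character) and `raw` (original text);
#'   AND/OR carry `children`; NOT carries `child`.
#' @examples
#' ast <- parseQuery('"mental retardation" AND ataxia')
#' ast$kind
#' queryTerms(ast)
#' @export
parseQuery <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty query")
  toks <- .lexQuery(text)
  .checkParens(toks)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  ast <- .parseOr(st, text)
  if (st$pos <= length(st$toks)) {
    t <- st$toks[[st$pos]]
    stop(sprintf("unexpected '%s' at position %d", t$text, t$at))
  }
  if (.countPositiveTerms(ast) == 0L)
    stop("query must contain a positive term")
  ast
}

# Lexer: emits tokens (type in word/phrase/lparen/rparen/and/or/not) with
# 1-based character positions for error reporting.
.lexQuery <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { toks[[length(toks) + 1L]] <- list(type = "lparen", text = "(", at = i); i <- i + 1L; next }
    if (ch == ")") { toks[[length(toks) + 1L]] <- list(type = "rparen", text = ")", at = i); i <- i + 1L; next }
    if (ch == '"') {
      close <- regexpr('"', substr(text, i + 1L, n), fixed = TRUE)
      if (close == -1L) stop(sprintf("unbalanced quote at position %d", i))
      phrase <- substr(text, i + 1L, i + close - 1L)
      toks[[length(toks) + 1L]] <- list(type = "phrase", text = phrase, at = i)
      i <- i + close + 1L
      next
    }
    m <- regexpr("^[^\\s()\"]+", substr(text, i, n), perl = TRUE)
    word <- substr(text, i, i + attr(m, "match.length") - 1L)
    up <- toupper(word)
    type <- switch(up, AND = "and", OR = "or", NOT = "not", "word")
    toks[[length(toks) + 1L]] <- list(type = type, text = word, at = i)
    i <- i + nchar(word)
  }
  if (length(toks) == 0L) stop("empty query")
  toks
}

.checkParens <- function(toks) {
  stack <- integer(0)
  for (t in toks) {
    if (t$type == "lparen") stack <- c(stack, t$at)
    if (t$type == "rparen") {
      if (length(stack) == 0L)
        stop(sprintf("unbalanced parenthesis at position %d", t$at))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack))
    stop(sprintf("unbalanced parenthesis at position %d", stack[1L]))
  invisible(TRUE)
}

.peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL

.parseOr <- function(st, text) {
  children <- list(.parseAnd(st, text))
  repeat {
    t <- .peek(st)
    if (is.null(t)) break
    if (t$type == "or") {
      st$pos <- st$pos + 1L
      children[[length(children) + 1L]] <- .parseAnd(st, text)
    } else if (t$type %in% c("word", "phrase", "not", "lparen")) {
      # implicit operator between adjacent operands is OR
      children[[length(children) + 1L]] <- .parseAnd(st, text)
    } else break
  }
  if (length(children) == 1L) children[[1L]] else list(kind = "OR", children = children)
}

.parseAnd <- function(st, text) {
  children <- list(.parseNot(st, text))
  repeat {
    t <- .peek(st)
    if (!is.null(t) && t$type == "and") {
      st$pos <- st$pos + 1L
      children[[length(children) + 1L]] <- .parseNot(st, text)
    } else break
  }
  if (length(children) == 1L) children[[1L]] else list(kind = "AND", children = children)
}

.parseNot <- function(st, text) {
  t <- .peek(st)
  if (!is.null(t) && t$type == "not") {
    st$pos <- st$pos + 1L
    list(kind = "NOT", child = .parseNot(st, text))
  } else {
    .parsePrimary(st, text)
  }
}

.parsePrimary <- function(st, text) {
  t <- .peek(st)
  if (is.null(t)) {
    prev <- st$toks[[length(st$toks)]]
    stop(sprintf("dangling operator at position %d", prev$at))
  }
  if (t$type == "lparen") {
    st$pos <- st$pos + 1L
    inner <- .parseOr(st, text)
    t2 <- .peek(st)
    if (is.null(t2) || t2$type != "rparen")
      stop(sprintf("unbalanced parenthesis at position %d", t$at))
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (t$type %in% c("word", "phrase")) {
    st$pos <- st$pos + 1L
    tokens <- tokenize(t$text)
    if (length(tokens) == 0L)
      stop(sprintf("term with no indexable tokens at position %d", t$at))
    return(list(kind = "TERM", tokens = tokens, raw = t$text))
  }
  if (t$type %in% c("and", "or"))
    stop(sprintf("dangling operator '%s' at position %d", t$text, t$at))
  stop(sprintf("unexpected '%s' at position %d", t$text, t$at))
}

.countPositiveTerms <- function(node, negated = FALSE) {
  switch(node$kind,
    TERM = as.integer(!negated),
    NOT = .countPositiveTerms(node$child, !negated),
    sum(vapply(node$children, .countPositiveTerms, integer(1), negated = negated)))
}

#' Positive terms of a query, in reading order
#'
#' Returns the non-negated TERM nodes left to right, duplicates (same token
#' sequence) removed. These are the terms that contribute to scores; terms
#' under a `NOT` gate matching but never score.
#'
#' @param ast result of [parseQuery()].
#' @return list of TERM nodes.
#' @export
queryTerms <- function(ast) {
  acc <- list()
  walk <- function(node, negated) {
    if (node$kind == "TERM") {
      if (!negated) acc[[length(acc) + 1L]] <<- node
    } else if (node$kind == "NOT") {
      walk(node$child, !negated)
    } else {
      for (ch in node$children) walk(ch, negated)
    }
  }
  walk(ast, FALSE)
  keys <- vapply(acc, function(t) paste(t$tokens, collapse = "\r"), character(1))
  acc[!duplicated(keys)]
}

#' Validate a query without raising
#'
#' @param text query string.
#' @return list(ok = TRUE) or list(ok = FALSE, message = <why>); the message
#'   carries the character position where parsing failed when known.
#' @export
validateQuery <- function(text) {
  res <- tryCatch(list(ok = TRUE, ast = parseQuery(text)),
                  error = function(e) list(ok = FALSE, message = conditionMessage(e)))
  res
}

#' Evaluate which genes satisfy a Boolean query
#'
#' A TERM is satisfied by a gene when its total occurrence count anywhere in
#' the gene's document is at least one; `NOT x` is satisfied when `x` is
#' not. Evaluation is over whole documents -- per-section restriction is
#' deliberately not supported.
#'
#' @param ast query AST from [parseQuery()].
#' @param index an [InvertedIndex-class].
#' @param genes universe of genes to evaluate (default: all indexed genes).
#' @return character vector: the subset of `genes` satisfying the query,
#'   in `genes` order.
#' @export
evaluateBoolean <- function(ast, index, genes = geneSymbols(index)) {
  unknown <- setdiff(genes, index@genes)
  if (length(unknown))
    stop("genes not in index: ", paste(head(unknown, 5L), collapse = ", "))
  sat <- .evalNode(ast, index, genes)
  genes[sat]
}

# logical vector over `genes`
.evalNode <- function(node, index, genes) {
  switch(node$kind,
    TERM = .termGeneCounts(index, node$tokens)[genes] > 0,
    NOT = !.evalNode(node$child, index, genes),
    AND = Reduce(`&`, lapply(node$children, .evalNode, index = index, genes = genes)),
    OR = Reduce(`|`, lapply(node$children, .evalNode, index = index, genes = genes)),
    stop("unknown node kind: ", node$kind))
}
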