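# Query parsing: Boolean operators (AND/OR/NOT, also +/- prefixes), quoted
# phrases, term boosts (term^2), inclusive year ranges (year:[1990 TO 2005],
# year:[*-2005]), stop-word removal. The implicit operator between bare terms
# is OR: a document matching any positive element is a candidate, and the
# coordination factor rewards documents matching more of them.

#' Built-in query stop words
#'
#' The classic short English stop-word list used by information-retrieval
#' engines. Stop words are removed from queries only; they remain indexed.
#'
#' @return Character vector of stop words.
#' @export
entrank_stop_words <- function() {
  c("a", "an", "and", "are", "as", "at", "be", "but", "by", "for", "if",
    "in", "into", "is", "it", "no", "not", "of", "on", "or", "such", "that",
    "the", "their", "then", "there", "these", "they", "this", "to", "was",
    "will", "with")
}

query_leaf <- function(kind, tokens, boost = 1) {
  list(kind = kind, tokens = tokens, boost = boost)
}

leaf_key <- function(leaf) {
  paste(leaf$kind, paste(leaf$tokens, collapse = " "), sep = ":")
}

lex_query <- function(raw) {
  pat <- paste0(
    "\"[^\"]*\"(?:\\^[0-9.]+)?",              # quoted phrase (+boost)
    "|year:\\[[^\\]]*\\]",                     # year range
    "|\\(|\\)",                                # grouping
    "|[^\\s()]+"                               # bare term / operator
  )
  m <- gregexpr(pat, raw, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character())
  regmatches(raw, list(m))[[1]]
}

parse_year_range <- function(tok) {
  inner <- sub("^year:\\[", "", sub("\\]$", "", tok))
  parts <- stringr::str_split(
    stringr::str_squish(inner),
    stringr::regex("\\s+TO\\s+|\\s*[—–-]\\s*",
                   ignore_case = TRUE))[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) != 2L) {
    abort(paste0("Malformed year range: \"", tok, "\""))
  }
  bound <- function(p) {
    if (p == "*") return(NA_integer_)
    v <- suppressWarnings(as.integer(p))
    if (is.na(v)) abort(paste0("Malformed year range: \"", tok, "\""))
    v
  }
  lo <- bound(parts[1]); hi <- bound(parts[2])
  if (!is.na(lo) && !is.na(hi) && lo > hi) {
    abort(paste0("Year range lower bound exceeds upper bound: \"", tok,
                 "\""))
  }
  c(lo = lo, hi = hi)
}

split_boost <- function(tok) {
  m <- regmatches(tok, regexec("^(.*)\\^([0-9]*\\.?[0-9]+)$", tok))[[1]]
  if (length(m) == 3L && nzchar(m[2])) {
    list(body = m[2], boost = as.numeric(m[3]))
  } else {
    list(body = tok, boost = 1)
  }
}

#' Parse a free-text query
#'
#' Supports Boolean `AND`/`OR`/`NOT` (and Lucene-style `+`/`-` prefixes),
#' parenthesized groups, quoted phrases, per-element boosts (`imatinib^3`),
#' and an inclusive year filter `year:[1990 TO 2005]` (em/en dash or hyphen
#' also accepted; `*` opens an end). Terms are normalized with the index
#' tokenizer and stop words are dropped from term leaves (never from
#' phrases, boosts or the year filter). Bare terms combine with an implicit
#' OR for retrieval; ranking rewards documents matching more elements.
#'
#' @param raw Query string.
#' @param stop_words Character vector; defaults to [entrank_stop_words()].
#' @param type_filter Optional entity-type name used to filter results
#'   (e.g. `"drug"`, `"mutation"`).
#' @return An `entrank_query`: list with `clauses` (Boolean tree of leaves
#'   with occurrence flags), `positive` (the distinct positive term/phrase
#'   leaves; its length is |q| for the coordination factor), `year_filter`
#'   (NULL or `c(lo, hi)` with NA for open ends) and `type_filter`.
#' @examples
#' q <- parse_query("resistant to imatinib")
#' length(q$positive)  # 2: "to" is a stop word
#' @export
parse_query <- function(raw, stop_words = entrank_stop_words(),
                        type_filter = NULL) {
  if (length(raw) != 1L || is.na(raw) || !nzchar(stringr::str_squish(raw))) {
    abort("Query must be a non-empty string.", class = "entrank_empty_query")
  }
  toks <- lex_query(raw)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$pos <- 1L
  state$year <- NULL

  peek <- function() if (state$pos <= length(state$toks))
    state$toks[state$pos] else NA_character_
  advance <- function() state$pos <- state$pos + 1L

  parse_group <- function() {
    clauses <- list()
    occur_next <- "SHOULD"
    repeat {
      tok <- peek()
      if (is.na(tok) || tok == ")") break
      advance()
      up <- toupper(tok)
      if (up == "AND" || tok == "&&") {
        # promote the previous clause and the next one to MUST
        if (length(clauses) > 0L &&
            clauses[[length(clauses)]]$occur == "SHOULD") {
          clauses[[length(clauses)]]$occur <- "MUST"
        }
        occur_next <- "MUST"
        next
      }
      if (up == "OR" || tok == "||") { occur_next <- "SHOULD"; next }
      if (up == "NOT") { occur_next <- "MUST_NOT"; next }

      occur <- occur_next
      occur_next <- "SHOULD"
      body <- tok
      if (startsWith(body, "+")) { occur <- "MUST"; body <- substring(body, 2) }
      else if (startsWith(body, "-") && nchar(body) > 1L &&
               !grepl("^-?[0-9]", body)) {
        occur <- "MUST_NOT"; body <- substring(body, 2)
      }
      if (!nzchar(body)) {         # bare +/- prefix applies to what follows
        occur_next <- occur
        next
      }

      if (body == "(") {
        node <- parse_group()
        if (!is.na(peek()) && peek() == ")") advance()
        if (length(node$clauses) > 0L) {
          node$occur <- occur
          clauses[[length(clauses) + 1L]] <- node
        }
        next
      }
      if (grepl("^year:\\[", body)) {
        yr <- parse_year_range(body)
        state$year <- if (is.null(state$year)) yr else
          c(lo = max(state$year["lo"], yr["lo"], na.rm = TRUE),
            hi = min(state$year["hi"], yr["hi"], na.rm = TRUE))
        next
      }
      if (startsWith(body, "\"")) {
        sb <- split_boost(body)
        inner <- gsub("^\"|\"$", "", sb$body)
        ptoks <- tokenize(inner)[[1]]
        if (length(ptoks) == 0L) next
        kind <- if (length(ptoks) > 1L) "phrase" else "term"
        clauses[[length(clauses) + 1L]] <-
          list(leaf = query_leaf(kind, ptoks, sb$boost), occur = occur)
        next
      }
      sb <- split_boost(body)
      ttoks <- tokenize(sb$body)[[1]]
      ttoks <- setdiff(ttoks, stop_words)
      for (tt in ttoks) {
        clauses[[length(clauses) + 1L]] <-
          list(leaf = query_leaf("term", tt, sb$boost), occur = occur)
      }
    }
    list(kind = "group", clauses = clauses, occur = "SHOULD")
  }

  tree <- parse_group()

  positive <- collect_positive_leaves(tree)
  if (length(positive) == 0L) {
    abort("Query has no positive searchable terms (all stop words?).",
          class = "entrank_empty_query")
  }
  yf <- state$year
  if (!is.null(yf) && all(is.na(yf))) yf <- NULL

  structure(
    list(clauses = tree, positive = positive, year_filter = yf,
         type_filter = type_filter),
    class = "entrank_query"
  )
}

# distinct positive (non-negated) term/phrase leaves, in first-seen order
collect_positive_leaves <- function(node) {
  leaves <- list()
  walk <- function(nd) {
    if (identical(nd$occur, "MUST_NOT")) return(invisible())
    if (!is.null(nd$leaf)) {
      leaves[[length(leaves) + 1L]] <<- nd$leaf
    } else if (!is.null(nd$clauses)) {
      for (cl in nd$clauses) walk(cl)
    }
  }
  walk(node)
  keys <- vapply(leaves, leaf_key, character(1))
  leaves[!duplicated(keys)]
}

#' Serialize a parsed query canonically
#'
#' `parse_query(format_query(q))` reproduces `q` (round-trip).
#'
#' @param query An `entrank_query`.
#' @return A single query string.
#' @export
format_query <- function(query) {
  stopifnot(inherits(query, "entrank_query"))
  fmt_leaf <- function(leaf) {
    body <- if (leaf$kind == "phrase") {
      paste0("\"", paste(leaf$tokens, collapse = " "), "\"")
    } else leaf$tokens
    if (leaf$boost != 1) paste0(body, "^", format(leaf$boost)) else body
  }
  fmt_node <- function(nd) {
    prefix <- switch(nd$occur, MUST = "+", MUST_NOT = "-", "")
    body <- if (!is.null(nd$leaf)) {
      fmt_leaf(nd$leaf)
    } else {
      inner <- paste(vapply(nd$clauses, fmt_node, character(1)),
                     collapse = " ")
      paste0("(", inner, ")")
    }
    paste0(prefix, body)
  }
  parts <- vapply(query$clauses$clauses, fmt_node, character(1))
  out <- paste(parts, collapse = " ")
  if (!is.null(query$year_filter)) {
    lo <- query$year_filter[["lo"]]; hi <- query$year_filter[["hi"]]
    out <- paste0(out, " year:[", ifelse(is.na(lo), "*", lo), " TO ",
                  ifelse(is.na(hi), "*", hi), "]")
  }
  out
}

#' @export
print.entrank_query <- function(x, ...) {
  cat("<entrank_query> ", format_query(x), "\n", sep = "")
  cat("  |q| = ", length(x$positive), " positive element(s)", sep = "")
  if (!is.null(x$type_filter)) cat("; type filter: ", x$type_filter, sep = "")
  cat("\n")
  invisible(x)
}

#' Filter documents by publication-year range
#'
#' Keeps exactly the documents whose `pub_year` lies in the inclusive range;
#' when a filter is active, documents without a year are excluded.
#'
#' @param docs Corpus tibble with a `pub_year` column.
#' @param year_filter NULL (identity) or `c(lo, hi)`, NA for an open end.
#' @return The filtered tibble.
#' @export
apply_year_filter <- function(docs, year_filter) {
  if (is.null(year_filter)) return(docs)
  lo <- year_filter[["lo"]]; hi <- year_filter[["hi"]]
  keep <- !is.na(docs$pub_year) &
    (is.na(lo) | docs$pub_year >= lo) &
    (is.na(hi) | docs$pub_year <= hi)
  docs[keep, , drop = FALSE]
}
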