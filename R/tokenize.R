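# Shared tokenizer: tokens are maximal runs of alphanumerics with internal
# hyphens allowed ("BCR-ABL" is one token); boundaries are transitions between
# alphanumeric and non-alphanumeric characters. Index terms are lowercased.

.token_regex <- "[A-Za-z0-9]+(?:-[A-Za-z0-9]+)*"

#' Tokenize text into index terms
#'
#' Lowercases and splits on any character that is neither alphanumeric nor an
#' internal hyphen. Leading/trailing hyphens never survive because a token
#' must start and end on an alphanumeric. No stemming is applied.
#'
#' @param text Character vector.
#' @return For `tokenize()`, a list of character vectors (one per input
#'   string) of lowercased tokens.
#' @examples
#' tokenize("Consistent use of imatinib.")
#' @export
tokenize <- function(text) {
  m <- gregexpr(.token_regex, text, perl = TRUE)
  lapply(regmatches(text, m), tolower)
}

# Token spans for a single string: tibble(token, lower, start, end) with
# 0-based half-open character offsets.
token_spans <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(tibble(token = character(), lower = character(),
                  start = integer(), end = integer()))
  }
  m <- gregexpr(.token_regex, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble(token = character(), lower = character(),
                  start = integer(), end = integer()))
  }
  len <- attr(m, "match.length")
  tok <- substring(text, m, m + len - 1L)
  tibble(token = tok, lower = tolower(tok),
         start = as.integer(m - 1L), end = as.integer(m - 1L + len))
}
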