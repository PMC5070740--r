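# Dictionary tagging and mutation-pattern extraction. Matching is
# token-based: a surface matches when its token sequence equals a run of
# consecutive document tokens, so matches always start and end on word
# boundaries and "HER" can never fire inside "OTHER".

empty_mentions <- function() {
  tibble(concept_id = character(), start = integer(), end = integer(),
         surface = character())
}

#' Extract dictionary entity mentions from text
#'
#' Scans the text left to right; at every token position the longest
#' dictionary surface wins and overlapping shorter matches are suppressed.
#' Matching is case-insensitive except for short all-uppercase surfaces
#' (gene-symbol style, <= 4 characters), which must match exactly.
#'
#' @param text A single document string (empty text gives zero mentions).
#' @param dict An `entrank_dictionary` from [merge_records()].
#' @return A tibble of mentions ordered by `start`: `concept_id`, `start`,
#'   `end` (0-based half-open character offsets) and `surface` (the exact
#'   text slice).
#' @examples
#' recs <- tibble::tibble(
#'   source = "demo",
#'   surface = c("imatinib", "chronic myeloid leukemia"),
#'   entity_type = c("drug", "disease"), xrefs = c("", "")
#' )
#' d <- merge_records(recs)
#' extract_entities("imatinib treats chronic myeloid leukemia", d)
#' @export
extract_entities <- function(text, dict) {
  stopifnot(inherits(dict, "entrank_dictionary"))
  spans <- token_spans(text)
  n <- nrow(spans)
  if (n == 0L || nrow(dict$name_index) == 0L) return(empty_mentions())

  ni <- dict$name_index
  lookup <- new.env(parent = emptyenv(), size = max(16L, nrow(ni)))
  for (i in seq_len(nrow(ni))) {
    key <- ni$token_key[i]
    entry <- get0(key, envir = lookup)
    assign(key, c(entry, i), envir = lookup)
  }
  max_len <- max(ni$n_tokens)

  out <- vector("list", n)
  k <- 0L
  i <- 1L
  while (i <= n) {
    hit <- NULL
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      key <- paste(spans$lower[i:(i + len - 1L)], collapse = " ")
      idxs <- get0(key, envir = lookup)
      if (is.null(idxs)) next
      matched_tokens <- paste(spans$token[i:(i + len - 1L)], collapse = " ")
      for (j in idxs) {
        ok <- if (ni$case_sensitive[j]) {
          identical(matched_tokens, ni$surface[j])
        } else TRUE
        if (ok) {
          hit <- list(concept_id = ni$concept_id[j], len = len)
          break
        }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) {
      i <- i + 1L
    } else {
      s <- spans$start[i]
      e <- spans$end[i + hit$len - 1L]
      k <- k + 1L
      out[[k]] <- tibble(concept_id = hit$concept_id, start = s, end = e,
                         surface = substr(text, s + 1L, e))
      i <- i + hit$len
    }
  }
  if (k == 0L) return(empty_mentions())
  dplyr::bind_rows(out[seq_len(k)])
}

# protein point mutations (T315I) and simple HGVS-like coding changes
# (c.944C>T), each bounded by alphanumeric transitions
.mutation_patterns <- c(
  point = "(?<![A-Za-z0-9])[A-Z][0-9]+[A-Z](?![A-Za-z0-9])",
  coding = "(?<![A-Za-z0-9])c\\.[0-9]+[ACGT]>[ACGT](?![A-Za-z0-9])"
)

#' Extract mutation mentions from text
#'
#' A deliberately simple pattern set: protein point mutations of the form
#' capital letter, digits, capital letter (T315I, Y253H) and coding changes
#' c.<pos><ref>><alt>. Each distinct normalized surface becomes its own
#' mutation-group concept with id `MUT:<SURFACE>`. Overlaps resolve to the
#' longest leftmost match.
#'
#' @param text A single document string.
#' @return A mention tibble as in [extract_entities()].
#' @examples
#' extract_mutations("the T315I mutation confers resistance")
#' @export
extract_mutations <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text)) {
    return(empty_mentions())
  }
  hits <- lapply(.mutation_patterns, function(p) {
    m <- gregexpr(p, text, perl = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    len <- attr(m, "match.length")
    tibble(start = as.integer(m - 1L), end = as.integer(m - 1L + len))
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0L) return(empty_mentions())
  # longest leftmost, non-overlapping
  hits <- dplyr::arrange(hits, .data$start, dplyr::desc(.data$end))
  keep <- logical(nrow(hits))
  last_end <- -1L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- hits$end[i]
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits$surface <- substring(text, hits$start + 1L, hits$end)
  hits$concept_id <- paste0("MUT:", toupper(hits$surface))
  hits[, c("concept_id", "start", "end", "surface")]
}

#' Extract all mentions (dictionary entities plus mutations)
#'
#' Union of [extract_entities()] and [extract_mutations()]; when a mutation
#' pattern overlaps a dictionary match the dictionary match wins (mutations
#' fill the gaps).
#'
#' @inheritParams extract_entities
#' @return A mention tibble ordered by `start`.
#' @export
extract_all_mentions <- function(text, dict) {
  ents <- extract_entities(text, dict)
  muts <- extract_mutations(text)
  if (nrow(muts) > 0L && nrow(ents) > 0L) {
    overlaps <- vapply(seq_len(nrow(muts)), function(i) {
      any(muts$start[i] < ents$end & muts$end[i] > ents$start)
    }, logical(1))
    muts <- muts[!overlaps, , drop = FALSE]
  }
  dplyr::arrange(dplyr::bind_rows(ents, muts), .data$start)
}
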