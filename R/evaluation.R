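# Extraction and ranking quality metrics: precision / recall / F1 over
# mention counts, and precision@k over a ranked entity list.

#' Precision, recall and F1 from error counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, and F1 is their harmonic mean
#' `2PR/(P+R)`. A metric whose denominator is zero is reported as `NA`
#' (absent), never as zero; all-zero counts raise a condition since no
#' metric is defined.
#'
#' @param tp,fp,fn Non-negative integer counts, or a list/one-row data frame
#'   with those fields as `tp` (then `fp`, `fn` are ignored).
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`
#'   (fractions in \[0, 1\]).
#' @examples
#' prf1(tp = 8, fp = 2, fn = 4)
#' @export
prf1 <- function(tp, fp = NULL, fn = NULL) {
  if (is.list(tp)) {
    counts <- tp
    tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  }
  stopifnot(length(tp) == 1L, length(fp) == 1L, length(fn) == 1L)
  if (any(c(tp, fp, fn) < 0)) abort("Counts must be non-negative.")
  if (tp + fp + fn == 0) {
    abort("All counts are zero; precision and recall are undefined.",
          class = "entrank_undefined_metric")
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r)
  else NA_real_
  tibble(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1)
}

#' Match predicted mentions against gold mentions
#'
#' In `"strict"` mode a prediction is a true positive only when its document,
#' span and concept all agree with a gold mention; in `"concept"` mode (the
#' default, the natural criterion for dictionary extraction) agreement on
#' the document's set of distinct concepts is enough.
#'
#' @param gold,predicted Mention tibbles with columns `doc_id`,
#'   `concept_id`, `start`, `end`.
#' @param mode `"concept"` or `"strict"`.
#' @param doc_ids Optional character vector of known document ids; a mention
#'   referencing a document outside it is an error.
#' @return A one-row tibble of counts: `tp`, `fp`, `fn`.
#' @export
match_mentions <- function(gold, predicted, mode = c("concept", "strict"),
                           doc_ids = NULL) {
  mode <- match.arg(mode)
  gold <- as_tibble(gold); predicted <- as_tibble(predicted)
  if (!is.null(doc_ids)) {
    unknown <- setdiff(unique(c(gold$doc_id, predicted$doc_id)), doc_ids)
    if (length(unknown) > 0L) {
      abort(paste0("Mention(s) reference unknown document(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }
  key <- function(m) {
    if (mode == "strict") {
      paste(m$doc_id, m$start, m$end, m$concept_id, sep = "\r")
    } else {
      unique(paste(m$doc_id, m$concept_id, sep = "\r"))
    }
  }
  g <- key(gold); p <- key(predicted)
  tibble(tp = length(intersect(p, g)),
         fp = length(setdiff(p, g)),
         fn = length(setdiff(g, p)))
}

#' Precision at k
#'
#' Fraction of the top-k ranked names found in the relevance set; name
#' matching is case-insensitive after whitespace normalization.
#'
#' @param ranked Character vector of ranked concept names (best first), or
#'   an `entrank_ranking` (its `name` column is used).
#' @param relevant Non-empty character vector of relevant names.
#' @param k Cut-off (>= 1). If fewer than `k` items are available the
#'   precision is computed over the available items, with a warning.
#' @return A single fraction in \[0, 1\].
#' @examples
#' precision_at_k(c("imatinib", "dasatinib", "aspirin"),
#'                c("Imatinib", "Dasatinib"), k = 3)
#' @export
precision_at_k <- function(ranked, relevant, k = 10) {
  if (inherits(ranked, "entrank_ranking")) ranked <- ranked$name
  if (length(relevant) == 0L) abort("`relevant` must be non-empty.")
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    abort("`k` must be a positive integer.")
  }
  norm <- function(x) tolower(stringr::str_squish(x))
  if (length(ranked) < k) {
    warn(paste0("Only ", length(ranked), " ranked items available for k = ",
                k, "; computing over the available items."))
    k <- length(ranked)
  }
  top <- norm(ranked[seq_len(k)])
  sum(top %in% norm(relevant)) / k
}
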