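#' Entity types and priority groups
#'
#' Biomedical entity types fall into four priority groups: the gene group
#' (genes/proteins, drug targets, transcription factors, miRNAs), the chemical
#' group (chemical compounds, drugs, toxins), the disease group and the
#' pathway group. The gene group has the highest priority, followed by the
#' chemical, disease and pathway groups; a separate mutation group holds
#' pattern-derived variant concepts. When a concept ends up with types from
#' several groups, only the types of the highest-priority group are kept.
#'
#' @format `entity_type_groups` is a tibble with columns `entity_type` and
#'   `group`; `group_priority` is a named integer vector (1 = highest).
#' @name entity-groups
NULL

#' @rdname entity-groups
#' @export
entity_type_groups <- tibble::tibble(
  entity_type = c("gene/protein", "target", "transcription factor", "miRNA",
                  "chemical compound", "drug", "toxin",
                  "disease", "pathway", "mutation"),
  group = c(rep("gene_group", 4L), rep("chem_group", 3L),
            "disease_group", "pathway_group", "mutation_group")
)

#' @rdname entity-groups
#' @export
group_priority <- c(gene_group = 1L, chem_group = 2L, disease_group = 3L,
                    pathway_group = 4L, mutation_group = 5L)

type_to_group <- function(entity_type) {
  idx <- match(entity_type, entity_type_groups$entity_type)
  entity_type_groups$group[idx]
}

#' Assign the priority group for a set of entity types
#'
#' A concept can carry several types within one group (e.g. TP53 is both a
#' gene/protein and a transcription factor) but never across groups. When a
#' merged concept accumulates types from different groups, the
#' highest-priority group wins: gene before chemical before disease before
#' pathway.
#'
#' @param types Character vector of entity types (see [entity_type_groups]).
#' @return The winning group as a string.
#' @examples
#' assign_group(c("drug", "disease"))           # "chem_group"
#' assign_group(c("gene/protein"))              # "gene_group"
#' @export
assign_group <- function(types) {
  if (length(types) == 0L) abort("`types` must be non-empty.")
  bad <- setdiff(types, entity_type_groups$entity_type)
  if (length(bad) > 0L) {
    abort(paste0("Unknown entity type(s): ", paste(bad, collapse = ", ")))
  }
  groups <- unique(type_to_group(types))
  names(which.min(group_priority[groups]))
}

# Surfaces that are all-uppercase and short (<= 4 chars) behave like gene
# symbols and are matched case-sensitively to avoid colliding with common
# words.
is_case_sensitive_surface <- function(surface) {
  grepl("[A-Z]", surface) & !grepl("[a-z]", surface) & nchar(surface) <= 4L
}

fold_surface <- function(surface) {
  tolower(stringr::str_squish(surface))
}

#' Build an entity dictionary by merging multi-source records
#'
#' Records that share at least one cross-reference identifier are considered
#' synonyms and merged into one concept (transitively); records with no shared
#' xref but an identical case-folded surface within the same priority group
#' are also merged. Each concept keeps all surface names, all types of its
#' winning priority group (see [assign_group()]), and a deterministic
#' `concept_id` that does not depend on record order.
#'
#' @param records A data frame with columns `source`, `surface`,
#'   `entity_type`, and `xrefs` (either a list-column of character vectors or
#'   a character column of pipe-separated ids; empty string = no xrefs).
#' @param stop_surfaces Optional character vector of surfaces to exclude from
#'   the matching index (case-insensitive); stands in for a manual curation
#'   pass.
#' @return An object of class `entrank_dictionary`: a list with `concepts`
#'   (tibble: `concept_id`, `name`, `group`, `types`, `names`) and
#'   `name_index` (tibble mapping case-folded surfaces to concept ids;
#'   surfaces ambiguous across concepts are resolved to the concept of the
#'   highest-priority group, ties to the smallest `concept_id`).
#' @examples
#' recs <- tibble::tibble(
#'   source = "demo",
#'   surface = c("Gleevec", "imatinib"),
#'   entity_type = "drug",
#'   xrefs = c("D01441", "D01441")
#' )
#' merge_records(recs)
#' @export
merge_records <- function(records, stop_surfaces = character()) {
  records <- as_tibble(records)
  required <- c("source", "surface", "entity_type", "xrefs")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    abort(paste0("`records` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0L) abort("`records` must be non-empty.")

  records$surface <- stringr::str_squish(records$surface)
  empty <- !nzchar(records$surface) | is.na(records$surface)
  if (any(empty)) {
    abort(paste0("Record(s) with empty surface at row(s): ",
                 paste(which(empty), collapse = ", ")))
  }
  bad_type <- !(records$entity_type %in% entity_type_groups$entity_type)
  if (any(bad_type)) {
    i <- which(bad_type)[1]
    abort(paste0("Record ", i, " (surface \"", records$surface[i],
                 "\", source \"", records$source[i],
                 "\") has unknown entity type \"", records$entity_type[i],
                 "\"."))
  }
  if (!is.list(records$xrefs)) {
    records$xrefs <- strsplit(ifelse(is.na(records$xrefs), "",
                                     records$xrefs), "\\|")
  }
  records$xrefs <- lapply(records$xrefs, function(x) x[nzchar(x)])

  n <- nrow(records)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  # shared-xref merges (transitive closure via union-find)
  xref_long <- tibble(rec = rep(seq_len(n), lengths(records$xrefs)),
                      xref = unlist(records$xrefs))
  if (nrow(xref_long) > 0L) {
    for (grp in split(xref_long$rec, xref_long$xref)) {
      if (length(grp) > 1L) for (j in grp[-1]) union_(grp[1], j)
    }
  }
  # identical case-folded surface within the same group
  folded <- fold_surface(records$surface)
  rec_group <- type_to_group(records$entity_type)
  for (grp in split(seq_len(n), paste(folded, rec_group, sep = "\r"))) {
    if (length(grp) > 1L) for (j in grp[-1]) union_(grp[1], j)
  }

  roots <- vapply(seq_len(n), find, integer(1))
  concepts <- lapply(split(seq_len(n), roots), function(idx) {
    types <- unique(records$entity_type[idx])
    group <- assign_group(types)
    kept_types <- sort(types[type_to_group(types) == group])
    surfaces <- records$surface[idx]
    # one name per case-folded form; keep the lexicographically smallest
    fold <- fold_surface(surfaces)
    names_kept <- vapply(split(surfaces, fold),
                         function(s) sort(s)[1], character(1))
    names_kept <- unname(names_kept[order(names(names_kept))])
    list(group = group, types = kept_types, names = names_kept)
  })

  ord <- order(group_priority[vapply(concepts, `[[`, "", "group")],
               vapply(concepts, function(co) fold_surface(co$names[1]),
                      character(1)))
  concepts <- unname(concepts[ord])
  concept_tbl <- tibble(
    concept_id = sprintf("C%05d", seq_along(concepts)),
    name = vapply(concepts, function(co) co$names[1], character(1)),
    group = vapply(concepts, `[[`, "", "group"),
    types = lapply(concepts, `[[`, "types"),
    names = lapply(concepts, `[[`, "names")
  )

  build_dictionary(concept_tbl, stop_surfaces = stop_surfaces)
}

# Assemble the dictionary object (concepts tibble -> name index with
# ambiguity resolution and the case-sensitivity rule for short symbols).
build_dictionary <- function(concept_tbl, stop_surfaces = character()) {
  ni <- tidyr::unnest(
    dplyr::select(concept_tbl, "concept_id", "group", surface = "names"),
    "surface"
  )
  ni$folded <- fold_surface(ni$surface)
  ni$case_sensitive <- is_case_sensitive_surface(ni$surface)
  ni <- ni[!(ni$folded %in% fold_surface(stop_surfaces)), , drop = FALSE]
  # ambiguous surfaces: highest-priority group wins, then smallest concept_id
  ni <- dplyr::arrange(ni, .data$folded, group_priority[.data$group],
                       .data$concept_id)
  ni <- dplyr::distinct(ni, .data$folded, .keep_all = TRUE)
  ni$n_tokens <- lengths(tokenize(ni$folded))
  ni <- ni[ni$n_tokens > 0L, , drop = FALSE]
  ni$token_key <- vapply(tokenize(ni$folded),
                         paste, character(1), collapse = " ")

  structure(
    list(concepts = concept_tbl,
         name_index = as_tibble(dplyr::select(
           ni, "folded", "surface", "concept_id", "group",
           "case_sensitive", "n_tokens", "token_key"))),
    class = "entrank_dictionary"
  )
}

#' @export
print.entrank_dictionary <- function(x, ...) {
  cat("<entrank_dictionary> ", nrow(x$concepts), " concepts, ",
      nrow(x$name_index), " indexed surfaces\n", sep = "")
  print(dplyr::count(x$concepts, .data$group), ...)
  invisible(x)
}

#' Read entity source records from TSV
#'
#' Expects a UTF-8 tab-separated file with header columns `source`, `name`,
#' `type`, `xrefs` (pipe-separated identifiers; may be empty).
#'
#' @param path File path.
#' @return A tibble suitable for [merge_records()].
#' @export
read_source_records <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       na = character(), progress = FALSE)
  required <- c("source", "name", "type", "xrefs")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    abort(paste0("Source record file lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tibble(source = x$source, surface = x$name, entity_type = x$type,
         xrefs = x$xrefs)
}

#' Persist and restore a built dictionary
#'
#' One concept per line: `concept_id`, `group`, pipe-separated `types`,
#' pipe-separated `names`, tab-separated; round-trips exactly.
#'
#' @param dict An `entrank_dictionary`.
#' @param path File path.
#' @param stop_surfaces Passed through to the rebuild on read.
#' @return `read_dictionary()` returns the restored `entrank_dictionary`.
#' @export
write_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "entrank_dictionary"))
  out <- tibble(
    concept_id = dict$concepts$concept_id,
    group = dict$concepts$group,
    types = vapply(dict$concepts$types, paste, character(1), collapse = "|"),
    names = vapply(dict$concepts$names, paste, character(1), collapse = "|")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path, stop_surfaces = character()) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       na = character(), progress = FALSE)
  concept_tbl <- tibble(
    concept_id = x$concept_id,
    group = x$group,
    types = strsplit(x$types, "\\|"),
    names = strsplit(x$names, "\\|")
  )
  concept_tbl$name <- vapply(concept_tbl$names, `[`, character(1), 1)
  concept_tbl <- concept_tbl[, c("concept_id", "name", "group",
                                 "types", "names")]
  build_dictionary(concept_tbl, stop_surfaces = stop_surfaces)
}
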