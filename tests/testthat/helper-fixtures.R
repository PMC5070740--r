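# Small hand-built dictionary and corpus used across test files.

demo_records <- function() {
  tibble::tibble(
    source = "demo",
    surface = c("Gleevec", "imatinib", "chronic myeloid leukemia",
                "leukemia", "TP53", "dasatinib", "resistant protein"),
    entity_type = c("drug", "drug", "disease", "disease", "gene/protein",
                    "drug", "gene/protein"),
    xrefs = c("D01441", "D01441", "", "", "G7157", "D01254", "")
  )
}

demo_dictionary <- function() merge_records(demo_records())

cml_sentence <- function() {
  paste0("Consistent use of imatinib is critical for treatment success ",
         "in chronic myeloid leukemia.")
}

concept_of <- function(dict, surface) {
  ni <- dict$name_index
  ni$concept_id[ni$folded == tolower(surface)]
}

quiet_add <- function(index, docs) {
  suppressWarnings(add_documents(index, docs))
}
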