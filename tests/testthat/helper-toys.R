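# Small builders used across test files.

# documents tibble from a list of doc -> mentions, e.g.
# toy_docs(d1 = c(A = "drug", X = "disease"))
toy_docs <- function(...) {
  docs <- list(...)
  dplyr::bind_rows(purrr::imap(docs, function(mentions, id) {
    tibble::tibble(
      doc_id = id,
      concept_id = names(mentions),
      entity_type = unname(mentions)
    )
  }))
}

# one prescription row from component strings and an indication text
toy_rx <- function(rx_id, components, text) {
  tibble::tibble(
    rx_id = rx_id,
    indication_text = herbsub::normalize_text(text),
    source = NA_character_,
    components = list(herbsub::parse_component(components))
  )
}

toy_rx_db <- function(...) dplyr::bind_rows(...)

# a tiny lexicon from a named list concept -> synonyms
toy_lexicon <- function(synonyms) {
  dplyr::bind_rows(purrr::imap(synonyms, function(s, id) {
    tibble::tibble(concept_id = id, english_name = id, synonym = s)
  }))
}
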