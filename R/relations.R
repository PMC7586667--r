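#' Count abstract-level co-occurrence link weights
#'
#' The link weight of a pair of entities is the number of abstracts in which
#' both are mentioned. Only mixed-type pairs involving a disease are counted:
#' (drug, disease) and (herb, disease). Same-typed pairs (drug-drug,
#' disease-disease, herb-herb) and drug-herb pairs carry no weight. Each
#' document contributes exactly 1 to each of its qualifying unordered pairs,
#' no matter how often either entity is mentioned in the abstract.
#'
#' @param documents A documents tibble (see [validate_documents()]).
#' @return A tibble of class `link_weights` with columns `concept_a` (the
#'   drug or herb), `type_a` (`"drug"` or `"herb"`), `concept_b` (the
#'   disease) and `weight` (a positive integer count).
#' @examples
#' docs <- tibble::tribble(
#'   ~doc_id, ~concept_id, ~entity_type,
#'   "d1", "aspirin", "drug",
#'   "d1", "headache", "disease",
#'   "d1", "fever", "disease"
#' )
#' extract_pairs(docs)
#' @export
extract_pairs <- function(documents) {
  docs <- validate_documents(documents)
  dis <- filter(docs, .data$entity_type == "disease")
  oth <- filter(docs, .data$entity_type != "disease")
  pairs <- inner_join(oth, dis,
    by = "doc_id", suffix = c("", "_b"),
    relationship = "many-to-many"
  )
  pairs <- filter(pairs, .data$concept_id != .data$concept_id_b)
  links <- pairs |>
    count(
      concept_a = .data$concept_id, type_a = .data$entity_type,
      concept_b = .data$concept_id_b, name = "weight"
    ) |>
    arrange(.data$concept_a, .data$concept_b)
  class(links) <- c("link_weights", class(links))
  links
}

#' Symmetric link-weight lookup
#'
#' Order of the two concepts is irrelevant; pairs never observed have
#' weight 0.
#'
#' @param links A link-weight tibble with columns `concept_a`, `concept_b`,
#'   `weight`.
#' @param x,y The two concept ids.
#' @return A single nonnegative count.
#' @export
link_weight <- function(links, x, y) {
  hit <- (links$concept_a == x & links$concept_b == y) |
    (links$concept_a == y & links$concept_b == x)
  if (!any(hit)) return(0L)
  sum(links$weight[hit])
}

validate_dictionary <- function(dict, what = "dictionary") {
  dict <- as_tibble(dict)
  if (!all(c("drug", "concept") %in% names(dict))) {
    abort(sprintf("%s must have columns 'drug' and 'concept'", what))
  }
  if (nrow(dict) == 0) abort(sprintf("%s is empty", what))
  distinct(dict, .data$drug, .data$concept)
}

#' Split drug-disease links into side-effect and indication relations
#'
#' A (drug, disease) link is classified as a side-effect relation if the
#' disease appears in the drug's side-effect dictionary entry (SIDER-style),
#' and as an indication relation if it appears in the drug's indication
#' dictionary entry (TTD-style). A disease present in both dictionaries for
#' the same drug is kept in both relation sets; links matching neither are
#' dropped. Counts are copied verbatim from the link-weight table - nothing
#' is rescaled.
#'
#' @param links A link-weight tibble (from [extract_pairs()] or
#'   [read_link_weights()]).
#' @param se_dict,ind_dict Dictionaries as tibbles with columns `drug`,
#'   `concept` (see [read_dictionary()]).
#' @return A tibble with columns `drug`, `concept`, `relation`
#'   (`"side_effect"` or `"indication"`) and `weight`.
#' @export
classify_relations <- function(links, se_dict, ind_dict) {
  links <- as_tibble(links)
  se_dict <- validate_dictionary(se_dict, "side-effect dictionary")
  ind_dict <- validate_dictionary(ind_dict, "indication dictionary")
  match_dict <- function(dict, label) {
    fwd <- inner_join(links, dict, by = c(concept_a = "drug", concept_b = "concept")) |>
      transmute(drug = .data$concept_a, concept = .data$concept_b, weight = .data$weight)
    rev <- inner_join(links, dict, by = c(concept_b = "drug", concept_a = "concept")) |>
      transmute(drug = .data$concept_b, concept = .data$concept_a, weight = .data$weight)
    bind_rows(fwd, rev) |>
      distinct() |>
      mutate(relation = label)
  }
  out <- bind_rows(
    match_dict(se_dict, "side_effect"),
    match_dict(ind_dict, "indication")
  ) |>
    select("drug", "concept", "relation", "weight") |>
    arrange(.data$drug, .data$relation, .data$concept)
  out
}

#' Read and write link-weight tables and dictionaries
#'
#' Link-weight tables are three-column TSV (`concept_a`, `concept_b`,
#' `weight`); dictionaries are two-column TSV (`drug`, `concept`). Both with
#' a header row, UTF-8.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_link_weights <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    concept_a = readr::col_character(),
    concept_b = readr::col_character(),
    weight = readr::col_integer()
  ))
}

#' @rdname read_link_weights
#' @param links A link-weight tibble.
#' @export
write_link_weights <- function(links, path) {
  readr::write_tsv(as_tibble(links)[c("concept_a", "concept_b", "weight")], path)
  invisible(path)
}

#' @rdname read_link_weights
#' @export
read_dictionary <- function(path) {
  validate_dictionary(readr::read_tsv(path, col_types = readr::cols(
    drug = readr::col_character(),
    concept = readr::col_character()
  )))
}

#' @rdname read_link_weights
#' @param dict A dictionary tibble (`drug`, `concept`).
#' @export
write_dictionary <- function(dict, path) {
  readr::write_tsv(validate_dictionary(dict), path)
  invisible(path)
}
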