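#' Annotated abstracts as a long tibble
#'
#' An annotated-document set is represented as a tibble with one row per
#' entity mention: `doc_id` (abstract identifier), `concept_id` (normalized
#' entity id, e.g. a drug name or disease concept) and `entity_type`
#' (`"drug"`, `"disease"` or `"herb"`). Named-entity recognition and synonym
#' resolution are upstream of this package: mentions arrive pre-normalized.
#' Within one document a concept counts once; duplicated rows are collapsed,
#' so co-occurrence is at abstract granularity.
#'
#' @param documents A data frame with columns `doc_id`, `concept_id`,
#'   `entity_type`.
#' @return The validated, de-duplicated tibble.
#' @export
validate_documents <- function(documents) {
  documents <- as_tibble(documents)
  needed <- c("doc_id", "concept_id", "entity_type")
  missing <- setdiff(needed, names(documents))
  if (length(missing) > 0) {
    abort(paste0("documents must have columns: ", paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(documents$entity_type), c("drug", "disease", "herb"))
  if (length(bad) > 0) {
    offenders <- documents$doc_id[documents$entity_type %in% bad]
    abort(sprintf(
      "unknown entity_type %s (first offending doc_id: '%s')",
      paste(sQuote(bad), collapse = ", "), offenders[1]
    ))
  }
  distinct(documents, .data$doc_id, .data$concept_id, .data$entity_type)
}

#' Read annotated documents from a JSON-lines file
#'
#' One JSON object per line:
#' `{"doc_id": "d1", "mentions": [{"concept_id": "aspirin", "entity_type": "drug"}, ...]}`.
#' Files must be UTF-8.
#'
#' @param path Path to a JSON-lines file.
#' @return A documents tibble (see [validate_documents()]).
#' @export
read_documents <- function(path) {
  if (!file.exists(path)) abort(sprintf("document file not found: '%s'", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(str_trim(lines))]
  recs <- map(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyDataFrame = TRUE),
      error = function(e) {
        abort(sprintf("malformed document record at line %d: %s", i, conditionMessage(e)))
      }
    )
    doc_id <- rec$doc_id
    if (is.null(doc_id) || !nzchar(doc_id)) {
      abort(sprintf("document record at line %d has no doc_id", i))
    }
    m <- rec$mentions
    if (is.null(m) || NROW(m) == 0) {
      return(tibble(doc_id = character(), concept_id = character(), entity_type = character()))
    }
    if (!is.data.frame(m) || !all(c("concept_id", "entity_type") %in% names(m))) {
      abort(sprintf("malformed mentions for doc_id '%s'", doc_id))
    }
    tibble(
      doc_id = doc_id,
      concept_id = as.character(m$concept_id),
      entity_type = as.character(m$entity_type)
    )
  })
  validate_documents(bind_rows(recs))
}

#' Write annotated documents to a JSON-lines file
#'
#' @param documents A documents tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_documents <- function(documents, path) {
  documents <- validate_documents(documents)
  split_docs <- split(documents, factor(documents$doc_id, levels = unique(documents$doc_id)))
  lines <- map_chr(split_docs, function(d) {
    jsonlite::toJSON(
      list(
        doc_id = d$doc_id[1],
        mentions = data.frame(concept_id = d$concept_id, entity_type = d$entity_type)
      ),
      auto_unbox = TRUE
    )
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
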