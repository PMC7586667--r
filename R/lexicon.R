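#' Canonical Unicode normalization for Chinese text
#'
#' All Chinese text is brought to NFC (canonical composition) before any
#' matching, so visually identical strings compare equal.
#'
#' @param x Character vector.
#' @return NFC-normalized character vector.
#' @export
normalize_text <- function(x) {
  stringi::stri_trans_nfc(x)
}

#' Bilingual concept lexicons
#'
#' A lexicon maps an English disease/side-effect concept to one or more
#' Chinese synonym strings. Stored as UTF-8 TSV with a header row and one row
#' per synonym: `concept_id`, `english_name`, `synonym`. Every synonym must
#' be nonempty after Unicode normalization.
#'
#' @param lexicon A data frame with columns `concept_id`, `english_name`,
#'   `synonym`.
#' @return The validated lexicon tibble (synonyms NFC-normalized).
#' @export
validate_lexicon <- function(lexicon) {
  lexicon <- as_tibble(lexicon)
  if (!all(c("concept_id", "synonym") %in% names(lexicon))) {
    abort("lexicon must have columns 'concept_id' and 'synonym'")
  }
  if (!"english_name" %in% names(lexicon)) lexicon$english_name <- lexicon$concept_id
  if (nrow(lexicon) == 0) abort("lexicon is empty")
  lexicon$synonym <- normalize_text(lexicon$synonym)
  if (any(is.na(lexicon$synonym) | !nzchar(lexicon$synonym))) {
    abort("lexicon synonyms must be nonempty after Unicode normalization")
  }
  lexicon[c("concept_id", "english_name", "synonym")]
}

#' @rdname validate_lexicon
#' @param path File path.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) abort(sprintf("lexicon file not found: '%s'", path))
  validate_lexicon(readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character())))
}

#' @rdname validate_lexicon
#' @export
write_lexicon <- function(lexicon, path) {
  readr::write_tsv(validate_lexicon(lexicon), path)
  invisible(path)
}

#' Match a concept's synonyms against Chinese free text
#'
#' TRUE iff any synonym occurs as a contiguous substring of the text.
#' Matching is raw substring containment after NFC normalization - no word
#' segmentation, so a synonym like a two-character dizziness term matches
#' inside a longer compound. Comma variants and whitespace are left in
#' place; containment handles them.
#'
#' @param synonyms Character vector of synonyms for one concept.
#' @param text A single text string.
#' @return Logical scalar.
#' @export
match_concept <- function(synonyms, text) {
  if (length(text) != 1) abort("match_concept() takes a single text string")
  if (is.na(text) || !nzchar(text)) return(FALSE)
  syn <- normalize_text(synonyms)
  syn <- syn[!is.na(syn) & nzchar(syn)]
  if (length(syn) == 0) return(FALSE)
  any(stringi::stri_detect_fixed(normalize_text(text), syn))
}

#' Count side-effect concepts present in an indication text
#'
#' The number of distinct concepts in the lexicon with at least one synonym
#' occurring in the text. A concept counts once per text no matter how many
#' of its synonyms match.
#'
#' @param lexicon A concept lexicon (see [validate_lexicon()]), typically the
#'   side-effect lexicon of one drug.
#' @param text A single indication text.
#' @return An integer count.
#' @export
intersection_count <- function(lexicon, text) {
  lex <- validate_lexicon(lexicon)
  syn_by_concept <- split(lex$synonym, lex$concept_id)
  sum(map_lgl(syn_by_concept, match_concept, text = text))
}

#' @rdname intersection_count
#' @param texts Character vector of indication texts.
#' @return For `intersection_counts()`, an integer vector along `texts`.
#' @export
intersection_counts <- function(lexicon, texts) {
  lex <- validate_lexicon(lexicon)
  syn_by_concept <- split(lex$synonym, lex$concept_id)
  map_int(texts, function(txt) {
    sum(map_lgl(syn_by_concept, match_concept, text = txt))
  })
}
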