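herbsub_extdata <- function(file) {
  system.file("extdata", file, package = "herbsub", mustWork = TRUE)
}

#' Bundled depression case-study data
#'
#' Small published datasets shipped with the package for worked examples and
#' validation:
#'
#' * `depression_prescriptions()` - two classical prescriptions indicated
#'   for depression, with component doses in classical units and Chinese
#'   indication text (the mirtazapine / white peony root worked example).
#' * `mirtazapine_lexicon()` - the Chinese side-effect term lexicon of
#'   mirtazapine used in that example (concepts lacking a published Chinese
#'   term are omitted).
#' * `depression_synonyms()` - Chinese synonyms of the target indication,
#'   depression.
#' * `antidepressant_scores()` - averaged side-effect rates and indication
#'   scores for 12 antidepressants as derived from literature link weights.
#' * `antidepressant_profiles()` - free-text oral LD50 and half-life fields
#'   for the same 12 drugs, with the selected/unselected split.
#' * `toxicity_group_means()` - reported group means of oral LD50 (mg/kg)
#'   and half-life (hours) for selected vs unselected drugs over the full
#'   drug set.
#'
#' @return Tibbles in the package's standard shapes; `depression_case()`
#'   returns all of them in one named list.
#' @export
depression_prescriptions <- function() {
  read_prescriptions(herbsub_extdata("depression_prescriptions.tsv"))
}

#' @rdname depression_prescriptions
#' @export
mirtazapine_lexicon <- function() {
  read_lexicon(herbsub_extdata("mirtazapine_side_effects.tsv"))
}

#' @rdname depression_prescriptions
#' @export
depression_synonyms <- function() {
  normalize_text(c("抑郁", "抑郁症"))
}

#' @rdname depression_prescriptions
#' @export
antidepressant_scores <- function() {
  readr::read_tsv(herbsub_extdata("antidepressant_scores.tsv"),
    col_types = readr::cols(
      drug = readr::col_character(),
      rate_se = readr::col_double(),
      indication_score = readr::col_double()
    )
  )
}

#' @rdname depression_prescriptions
#' @export
antidepressant_profiles <- function() {
  readr::read_tsv(herbsub_extdata("antidepressant_profiles.tsv"),
    col_types = readr::cols(
      drug = readr::col_character(),
      ld50_text = readr::col_character(),
      half_life_text = readr::col_character(),
      selected = readr::col_logical()
    )
  )
}

#' @rdname depression_prescriptions
#' @export
toxicity_group_means <- function() {
  tibble(
    group = c("selected", "unselected"),
    mean_toxicity = c(1667.57, 2609.07),
    mean_half_life = c(10.87, 12.58)
  )
}

#' @rdname depression_prescriptions
#' @export
depression_case <- function() {
  list(
    prescriptions = depression_prescriptions(),
    se_lexicon = mirtazapine_lexicon(),
    indication_synonyms = depression_synonyms(),
    scores = antidepressant_scores(),
    profiles = antidepressant_profiles(),
    group_means = toxicity_group_means()
  )
}
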