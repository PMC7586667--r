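#' Normalized side-effect and indication scores
#'
#' For a drug d and a side effect s with link weight f_s, the side-effect
#' score is f_s divided by the mean link weight of s across all drugs linked
#' to s. Indication scores are computed the same way on the indication
#' relations. The cross-drug denominator deflates terms that are common to
#' many drugs (e.g. headache), so ubiquitous side effects do not inflate any
#' single drug's profile; by construction the mean score of each concept
#' across its linked drugs is exactly 1.
#'
#' @param relations A relation tibble from [classify_relations()] (columns
#'   `drug`, `concept`, `relation`, `weight`).
#' @return The same tibble with an added `score` column.
#' @export
score_relations <- function(relations) {
  relations <- as_tibble(relations)
  if (nrow(relations) == 0) {
    return(mutate(relations, score = numeric(0)))
  }
  relations |>
    group_by(.data$relation, .data$concept) |>
    mutate(score = .data$weight / mean(.data$weight)) |>
    ungroup()
}

#' @rdname score_relations
#' @param drug,side_effect,indication Single ids naming the pair to score.
#' @export
side_effect_score <- function(relations, drug, side_effect) {
  .pair_score(relations, drug, side_effect, "side_effect")
}

#' @rdname score_relations
#' @export
indication_score <- function(relations, drug, indication) {
  .pair_score(relations, drug, indication, "indication")
}

.pair_score <- function(relations, drug, concept, relation) {
  rel <- filter(as_tibble(relations), .data$relation == !!relation, .data$concept == !!concept)
  if (nrow(rel) == 0) {
    abort(sprintf("'%s' is not linked to any drug in the %s relations", concept, relation),
      class = "herbsub_undefined_score"
    )
  }
  f <- rel$weight[rel$drug == drug]
  if (length(f) == 0) {
    abort(sprintf("drug '%s' has no observed link to '%s'", drug, concept),
      class = "herbsub_undefined_score"
    )
  }
  sum(f) / mean(rel$weight)
}

#' Averaged side-effect rate of a drug
#'
#' The arithmetic mean of a drug's side-effect scores over its alpha distinct
#' observed side effects (those with nonzero link weight in the corpus, not
#' the dictionary's full list).
#'
#' @param scores Numeric vector of one drug's side-effect scores.
#' @return A single nonnegative number.
#' @export
rate_se <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) {
    abort("a drug needs at least one observed side effect to have a rate",
      class = "herbsub_undefined_rate"
    )
  }
  mean(scores)
}

#' Replaceable score
#'
#' The averaged side-effect rate divided by the indication score. A value
#' above 1 means the drug's side-effect literature outweighs its indication
#' literature, flagging it as a candidate for replacement by an alternative.
#'
#' @param rate Averaged side-effect rate(s).
#' @param ind_score Indication score(s); must be strictly positive.
#' @return `rate / ind_score`, at full floating precision.
#' @export
replaceable_score <- function(rate, ind_score) {
  if (any(!is.na(ind_score) & ind_score <= 0)) {
    abort("indication score must be > 0 to define a replaceable score",
      class = "herbsub_undefined_replaceable"
    )
  }
  rate / ind_score
}

#' Per-drug score cards
#'
#' Builds one row per (drug, indication) pair: the number of observed side
#' effects (`n_side_effects`, alpha), the averaged side-effect rate
#' (`rate_se`), the indication score, the replaceable score and a
#' `needs_alternative` flag (`replaceable > threshold`, strict). Drugs with
#' observed indications but no observed side effect cannot be rated and are
#' excluded (a message reports them).
#'
#' @param relations A relation tibble from [classify_relations()].
#' @param threshold Flagging threshold for the replaceable score; default 1.
#' @return A tibble of class `drug_ranking`, sorted by decreasing
#'   replaceable score with ties broken by drug id (code-point order).
#' @export
drug_scores <- function(relations, threshold = 1) {
  scored <- score_relations(relations)
  se <- scored |>
    filter(.data$relation == "side_effect") |>
    group_by(drug = .data$drug) |>
    summarise(n_side_effects = n(), rate_se = mean(.data$score), .groups = "drop")
  ind <- scored |>
    filter(.data$relation == "indication") |>
    transmute(drug = .data$drug, indication = .data$concept, indication_score = .data$score)
  unrated <- setdiff(unique(ind$drug), unique(se$drug))
  if (length(unrated) > 0) {
    inform(sprintf(
      "excluding %d drug(s) with no observed side effect: %s",
      length(unrated), paste(unrated, collapse = ", ")
    ))
  }
  cards <- inner_join(ind, se, by = "drug") |>
    select("drug", "n_side_effects", "rate_se", "indication", "indication_score")
  rank_replaceable(cards, threshold = threshold)
}

#' Rank a score table by replaceable score
#'
#' Takes a tibble that already carries `rate_se` and `indication_score`
#' columns per drug (for example a published score table, or the output half
#' of [drug_scores()]) and adds `replaceable` and `needs_alternative`.
#'
#' @param scores A tibble with columns `drug`, `rate_se`, `indication_score`
#'   (and optionally `indication`).
#' @inheritParams drug_scores
#' @return A `drug_ranking` tibble sorted by decreasing replaceable score.
#' @export
rank_replaceable <- function(scores, threshold = 1) {
  scores <- as_tibble(scores)
  if (!all(c("drug", "rate_se", "indication_score") %in% names(scores))) {
    abort("scores must have columns 'drug', 'rate_se' and 'indication_score'")
  }
  out <- scores |>
    mutate(
      replaceable = replaceable_score(.data$rate_se, .data$indication_score),
      needs_alternative = .data$replaceable > threshold
    ) |>
    arrange(desc(.data$replaceable), .data$drug)
  attr(out, "threshold") <- threshold
  class(out) <- c("drug_ranking", class(out))
  out
}

#' Select candidate drugs for replacement
#'
#' Keeps the drugs whose replaceable score for the target indication strictly
#' exceeds the threshold, sorted descending; ties broken by drug id. An empty
#' result is allowed.
#'
#' @param cards A `drug_ranking` tibble (from [drug_scores()] or
#'   [rank_replaceable()]).
#' @param indication Optional indication concept to restrict to.
#' @param threshold Strict lower bound on the replaceable score; default 1.
#' @return The selected rows, a tibble.
#' @export
select_candidates <- function(cards, indication = NULL, threshold = 1) {
  x <- as_tibble(cards)
  if (!is.null(indication)) {
    if (!"indication" %in% names(x)) abort("cards carry no 'indication' column")
    x <- filter(x, .data$indication == !!indication)
  }
  x |>
    filter(!is.na(.data$replaceable), .data$replaceable > threshold) |>
    arrange(desc(.data$replaceable), .data$drug)
}

#' Write a drug score card as TSV
#'
#' Columns: drug, rate_se, indication (if present), indication_score,
#' replaceable, needs_alternative.
#'
#' @param cards A `drug_ranking` tibble.
#' @param path Output path.
#' @export
write_drug_scores <- function(cards, path) {
  keep <- intersect(
    c("drug", "n_side_effects", "rate_se", "indication", "indication_score",
      "replaceable", "needs_alternative"),
    names(cards)
  )
  readr::write_tsv(as_tibble(cards)[keep], path)
  invisible(path)
}
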