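#' Tidiers for herbsub result objects
#'
#' `tidy()` returns the per-row results as a plain tibble; `glance()`
#' returns a one-row summary.
#'
#' @param x A `drug_ranking`, `substitutability`, `group_comparison` or
#'   `hitd_graph` object.
#' @param ... Unused.
#' @return A tibble.
#' @name herbsub-tidiers
NULL

#' @rdname herbsub-tidiers
#' @method tidy drug_ranking
#' @export
tidy.drug_ranking <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "drug_ranking")
  as_tibble(out)
}

#' @rdname herbsub-tidiers
#' @method glance drug_ranking
#' @export
glance.drug_ranking <- function(x, ...) {
  tibble(
    n_drugs = length(unique(x$drug)),
    n_flagged = sum(x$needs_alternative, na.rm = TRUE),
    threshold = attr(x, "threshold") %||% 1,
    max_replaceable = max(x$replaceable, na.rm = TRUE)
  )
}

#' @rdname herbsub-tidiers
#' @method tidy substitutability
#' @export
tidy.substitutability <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "substitutability")
  as_tibble(out)
}

#' @rdname herbsub-tidiers
#' @method glance substitutability
#' @export
glance.substitutability <- function(x, ...) {
  tibble(
    drug = attr(x, "drug") %||% NA_character_,
    n_herbs = nrow(x),
    n_direct = sum(x$mode == "direct"),
    n_indirect = sum(x$mode == "indirect"),
    top_herb = if (nrow(x) > 0) x$herb[which.max(x$score)] else NA_character_,
    top_score = if (nrow(x) > 0) max(x$score) else NA_real_
  )
}

#' @rdname herbsub-tidiers
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) {
  x$summary
}

#' @rdname herbsub-tidiers
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  s <- x$summary
  tibble(
    mean_toxicity_selected = s$mean_toxicity[s$group == "selected"],
    mean_toxicity_unselected = s$mean_toxicity[s$group == "unselected"],
    mean_half_life_selected = s$mean_half_life[s$group == "selected"],
    mean_half_life_unselected = s$mean_half_life[s$group == "unselected"],
    toxicity_ratio = x$toxicity_ratio
  )
}

#' @rdname herbsub-tidiers
#' @method tidy hitd_graph
#' @export
tidy.hitd_graph <- function(x, ...) {
  x$edges
}

#' @rdname herbsub-tidiers
#' @method glance hitd_graph
#' @export
glance.hitd_graph <- function(x, ...) {
  tibble(
    n_herbs = sum(x$nodes$type == "herb"),
    n_ingredients = sum(x$nodes$type == "ingredient"),
    n_targets = sum(x$nodes$type == "target"),
    n_diseases = sum(x$nodes$type == "disease"),
    n_edges = nrow(x$edges)
  )
}
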