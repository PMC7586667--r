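.num_re <- "[0-9]+(?:\\.[0-9]+)?"
# en dash, em dash, minus sign, hyphen, or "to"
.range_sep <- "\\s*(?:–|—|−|-|to)\\s*"
.hl_unit <- "(h(?:ours?|rs?)?|days?)"

#' Parse free-text toxicity and half-life fields
#'
#' Extracts a single number from DrugBank-style free text. Ranges
#' (`"2-4 h"`, en dash, em dash, minus or `"to"` as separators) take the
#' median (a + b) / 2; `"x +/- y"` forms take the central value x; a single
#' number with the expected unit is returned as is. Toxicity requires an
#' `mg/kg` unit (oral LD50 in rat); half-life accepts hours or days, days
#' are converted to hours (x24). Purely descriptive text - no number with
#' the expected unit - yields `NA`, which excludes the drug from downstream
#' means.
#'
#' @param text Character vector of free-text fields.
#' @param kind `"toxicity"` (mg/kg) or `"half_life"` (hours).
#' @return Numeric vector; `NA` where no value can be extracted.
#' @examples
#' parse_numeric_range("2–4 h", "half_life") # 3
#' parse_numeric_range("Oral LD50 rat: 780 mg/kg", "toxicity") # 780
#' parse_numeric_range("1–3 days", "half_life") # 48
#' @export
parse_numeric_range <- function(text, kind = c("toxicity", "half_life")) {
  kind <- match.arg(kind)
  fn <- if (kind == "toxicity") .parse_toxicity else .parse_half_life
  vapply(as.character(text), fn, numeric(1), USE.NAMES = FALSE)
}

.parse_toxicity <- function(txt) {
  if (is.na(txt)) return(NA_real_)
  mgkg <- "\\s*mg\\s*/\\s*kg"
  m <- str_match(txt, paste0("(", .num_re, ")", .range_sep, "(", .num_re, ")", mgkg))
  if (!is.na(m[1, 1])) return(mean(as.numeric(m[1, 2:3])))
  m <- str_match(txt, paste0("(", .num_re, ")", mgkg))
  if (!is.na(m[1, 1])) return(as.numeric(m[1, 2]))
  NA_real_
}

.parse_half_life <- function(txt) {
  if (is.na(txt)) return(NA_real_)
  to_hours <- function(value, unit) {
    if (str_starts(str_to_lower(unit), "d")) value * 24 else value
  }
  # central value of "x +/- y" (ASCII or unicode minus/plus-minus)
  m <- str_match(txt, paste0(
    "(", .num_re, ")\\s*(?:\\+\\s*/\\s*[-−–]|±)\\s*",
    .num_re, "\\s*", .hl_unit, "\\b"
  ))
  if (!is.na(m[1, 1])) return(to_hours(as.numeric(m[1, 2]), m[1, 3]))
  m <- str_match(txt, paste0("(", .num_re, ")", .range_sep, "(", .num_re, ")\\s*", .hl_unit, "\\b"))
  if (!is.na(m[1, 1])) return(to_hours(mean(as.numeric(m[1, 2:3])), m[1, 4]))
  m <- str_match(txt, paste0("(", .num_re, ")\\s*", .hl_unit, "\\b"))
  if (!is.na(m[1, 1])) return(to_hours(as.numeric(m[1, 2]), m[1, 3]))
  NA_real_
}

#' Parse numeric columns onto a drug profile table
#'
#' @param profiles A tibble with columns `drug`, `ld50_text`,
#'   `half_life_text`.
#' @return The tibble with added `ld50_mg_per_kg` and `half_life_hours`
#'   columns (NA where not parseable).
#' @export
parse_profiles <- function(profiles) {
  profiles <- as_tibble(profiles)
  if (!all(c("drug", "ld50_text", "half_life_text") %in% names(profiles))) {
    abort("profiles must have columns 'drug', 'ld50_text', 'half_life_text'")
  }
  profiles |>
    mutate(
      ld50_mg_per_kg = parse_numeric_range(.data$ld50_text, "toxicity"),
      half_life_hours = parse_numeric_range(.data$half_life_text, "half_life")
    )
}

#' Compare toxicity and half-life between selected and unselected drugs
#'
#' Arithmetic means over the parseable values only, per group, plus the
#' toxicity ratio (unselected mean LD50 / selected mean LD50). A ratio above
#' 1 means the drugs flagged for replacement are on average more toxic
#' (lower LD50) than the rest.
#'
#' @param selected,unselected Drug profile tibbles (`drug`, `ld50_text`,
#'   `half_life_text`).
#' @return An object of class `group_comparison`: a list with `summary` (a
#'   tibble of per-group means and counts) and `toxicity_ratio`.
#' @export
group_comparison <- function(selected, unselected) {
  one <- function(profiles, label) {
    p <- parse_profiles(profiles)
    tox <- p$ld50_mg_per_kg[!is.na(p$ld50_mg_per_kg)]
    hl <- p$half_life_hours[!is.na(p$half_life_hours)]
    if (length(tox) == 0 || length(hl) == 0) {
      abort(sprintf("group '%s' has no parseable toxicity or half-life value", label),
        class = "herbsub_insufficient_data"
      )
    }
    tibble(
      group = label, n = nrow(p),
      n_toxicity = length(tox), mean_toxicity = mean(tox),
      n_half_life = length(hl), mean_half_life = mean(hl)
    )
  }
  summary <- bind_rows(one(selected, "selected"), one(unselected, "unselected"))
  ratio <- summary$mean_toxicity[summary$group == "unselected"] /
    summary$mean_toxicity[summary$group == "selected"]
  structure(list(summary = summary, toxicity_ratio = ratio), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Toxicity / half-life comparison of selected vs unselected drugs\n")
  print(x$summary)
  cat(sprintf(
    "Unselected mean oral LD50 is %.2f times the selected mean (higher = selected drugs more toxic)\n",
    x$toxicity_ratio
  ))
  invisible(x)
}

#' Build a filtered herb-ingredient-target-disease graph
#'
#' Ingredients must pass the oral-bioavailability and drug-likeness
#' admission filters strictly (OB > 30, DL > 0.18 by default; equality is
#' excluded); failing ingredients are dropped with their incident edges.
#' Disease nodes are restricted to the focal drug's own side-effect and
#' indication concepts. Targets are kept only when reached by a retained
#' ingredient, and diseases only when reached by a retained target, so no
#' edge references a dropped node.
#'
#' @param herb_ingredients Tibble with columns `herb`, `ingredient`, `ob`
#'   (oral bioavailability, percent), `dl` (drug-likeness).
#' @param ingredient_targets Tibble with columns `ingredient`, `target`.
#' @param target_diseases Tibble with columns `target`, `disease`.
#' @param drug_diseases Character vector: the focal drug's side-effect and
#'   indication concepts.
#' @param ob_threshold,dl_threshold Strict admission thresholds; defaults 30
#'   and 0.18.
#' @return An object of class `hitd_graph`: a list with `nodes` (`node`,
#'   `type`, and `ob`/`dl` for ingredients) and `edges` (`from`, `to`,
#'   `from_type`, `to_type`).
#' @export
build_hitd_graph <- function(herb_ingredients, ingredient_targets, target_diseases,
                             drug_diseases, ob_threshold = 30, dl_threshold = 0.18) {
  herb_ingredients <- as_tibble(herb_ingredients)
  ingredient_targets <- as_tibble(ingredient_targets)
  target_diseases <- as_tibble(target_diseases)
  if (!all(c("herb", "ingredient", "ob", "dl") %in% names(herb_ingredients))) {
    abort("herb_ingredients needs columns herb, ingredient, ob, dl")
  }
  hi <- filter(
    herb_ingredients,
    .data$ob > ob_threshold, .data$dl > dl_threshold
  ) |>
    distinct(.data$herb, .data$ingredient, .data$ob, .data$dl)
  it <- ingredient_targets |>
    distinct(.data$ingredient, .data$target) |>
    semi_join(hi, by = "ingredient")
  td <- target_diseases |>
    distinct(.data$target, .data$disease) |>
    filter(.data$disease %in% drug_diseases) |>
    semi_join(it, by = "target")
  nodes <- bind_rows(
    tibble(node = unique(hi$herb), type = "herb"),
    hi |> distinct(.data$ingredient, .data$ob, .data$dl) |>
      transmute(node = .data$ingredient, type = "ingredient", ob = .data$ob, dl = .data$dl),
    tibble(node = unique(it$target), type = "target"),
    tibble(node = unique(td$disease), type = "disease")
  )
  edges <- bind_rows(
    transmute(hi, from = .data$herb, to = .data$ingredient,
              from_type = "herb", to_type = "ingredient"),
    transmute(it, from = .data$ingredient, to = .data$target,
              from_type = "ingredient", to_type = "target"),
    transmute(td, from = .data$target, to = .data$disease,
              from_type = "target", to_type = "disease")
  )
  structure(list(nodes = nodes, edges = edges), class = "hitd_graph")
}

#' @export
print.hitd_graph <- function(x, ...) {
  counts <- table(x$nodes$type)
  cat("herb-ingredient-target-disease graph:",
      paste(sprintf("%d %s", as.integer(counts), names(counts)), collapse = ", "),
      sprintf("| %d edges\n", nrow(x$edges)))
  invisible(x)
}

#' Export an HITD graph as a typed edge list
#'
#' TSV with columns `from`, `from_type`, `to`, `to_type`.
#'
#' @param graph An `hitd_graph` object.
#' @param path Output path.
#' @export
write_hitd_graph <- function(graph, path) {
  readr::write_tsv(graph$edges[c("from", "from_type", "to", "to_type")], path)
  invisible(path)
}

#' Common targets between a drug and herb ingredients
#'
#' For each of the drug's target proteins, the herb ingredients that also
#' hit it. Targets hit by no ingredient are omitted.
#'
#' @param drug_targets Character vector of the drug's target ids.
#' @param ingredient_targets Tibble with columns `ingredient`, `target`.
#' @return A tibble with columns `target`, `ingredient`, one row per pair.
#' @export
common_targets <- function(drug_targets, ingredient_targets) {
  ingredient_targets <- as_tibble(ingredient_targets)
  if (!all(c("ingredient", "target") %in% names(ingredient_targets))) {
    abort("ingredient_targets needs columns ingredient, target")
  }
  ingredient_targets |>
    filter(.data$target %in% drug_targets) |>
    distinct(.data$target, .data$ingredient) |>
    arrange(.data$target, .data$ingredient)
}
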