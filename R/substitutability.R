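rx_herb_sets <- function(prescriptions) {
  map(prescriptions$components, function(x) unique(x$herb))
}

#' Prescriptions that make a herb "direct" for an indication
#'
#' A herb is direct for a target indication when at least one prescription
#' contains the herb in its component list AND mentions an indication synonym
#' in its indication text. This returns those qualifying prescriptions.
#'
#' @param prescriptions A prescription tibble (see [read_prescriptions()]).
#' @param herb Herb name.
#' @param indication_synonyms Character vector of Chinese synonyms for the
#'   target indication.
#' @return The qualifying prescription rows (possibly zero).
#' @export
direct_prescriptions <- function(prescriptions, herb, indication_synonyms) {
  prescriptions <- validate_prescriptions(prescriptions)
  herb <- normalize_text(herb)
  has_herb <- map_lgl(rx_herb_sets(prescriptions), function(h) herb %in% h)
  has_ind <- map_lgl(prescriptions$indication_text, function(txt) {
    match_concept(indication_synonyms, txt)
  })
  prescriptions[has_herb & has_ind, ]
}

new_substitutability <- function(rows, drug = NA_character_) {
  rows <- as_tibble(rows)
  class(rows) <- c("substitutability", class(rows))
  attr(rows, "drug") <- drug
  rows
}

#' Direct substitutability of a herb for a drug
#'
#' Over the qualifying prescriptions (herb and target indication in the same
#' prescription): D is the unweighted mean of the herb's per-prescription
#' dosage proportions; N is the mean per-prescription count of the drug's
#' side-effect concepts found in the indication texts, plus 1 because the
#' target indication itself is also treated by every qualifying
#' prescription. The score is D x N.
#'
#' @param se_lexicon The drug's side-effect lexicon (Chinese synonyms).
#' @param herb Herb name.
#' @param rxs Qualifying prescriptions, e.g. from [direct_prescriptions()].
#' @param drug Optional drug id recorded on the result.
#' @return A one-row tibble of class `substitutability` with columns `drug`,
#'   `herb`, `mode`, `D`, `N`, `score`, `n_prescriptions`.
#' @export
direct_substitutability <- function(se_lexicon, herb, rxs, drug = NA_character_) {
  rxs <- validate_prescriptions(rxs)
  if (nrow(rxs) == 0) {
    abort(sprintf("herb '%s' has no prescription co-mentioning the target indication", herb),
      class = "herbsub_not_direct"
    )
  }
  herb <- normalize_text(herb)
  props <- map_dbl(seq_len(nrow(rxs)), function(i) dosage_proportion(rxs[i, ], herb))
  d_mean <- mean(props)
  n_mean <- mean(intersection_counts(se_lexicon, rxs$indication_text)) + 1
  new_substitutability(tibble(
    drug = drug, herb = herb, mode = "direct",
    D = d_mean, N = n_mean, score = d_mean * n_mean,
    n_prescriptions = nrow(rxs)
  ), drug = drug)
}

#' Propagated dosage proportion for an indirect herb
#'
#' For a herb never co-occurring with the target indication in a
#' prescription, the dosage proportion is propagated from the direct herbs:
#' for each direct herb h, F_c is the number of prescriptions containing both
#' the indirect herb and h, F_h the number containing the indirect herb, and
#' the contribution is (F_c / F_h) x D\[h\]. Contributions are accumulated
#' (summed) over all direct herbs. Presence is at prescription level: a herb
#' listed twice in one prescription counts once.
#'
#' @param herb_ind The indirect herb's name.
#' @param direct_D Named numeric vector (or tibble with columns `herb`, `D`)
#'   of direct-herb dosage proportions.
#' @param prescriptions The full prescription database.
#' @return A single nonnegative number (may exceed 1; it is an accumulated
#'   propagation score, not a fraction).
#' @export
indirect_dosage <- function(herb_ind, direct_D, prescriptions) {
  prescriptions <- validate_prescriptions(prescriptions)
  direct_D <- as_direct_D(direct_D)
  herb_ind <- normalize_text(herb_ind)
  sets <- rx_herb_sets(prescriptions)
  has_ind <- map_lgl(sets, function(h) herb_ind %in% h)
  f_h <- sum(has_ind)
  if (f_h == 0) {
    abort(sprintf("herb '%s' does not occur in the prescription database", herb_ind),
      class = "herbsub_unknown_herb"
    )
  }
  contribs <- map_dbl(names(direct_D), function(h) {
    f_c <- sum(has_ind & map_lgl(sets, function(s) h %in% s))
    (f_c / f_h) * direct_D[[h]]
  })
  sum(contribs)
}

as_direct_D <- function(direct_D) {
  if (is.data.frame(direct_D)) {
    if (!all(c("herb", "D") %in% names(direct_D))) {
      abort("direct_D must be a named numeric vector or a tibble with columns 'herb' and 'D'")
    }
    direct_D <- setNames(direct_D$D, direct_D$herb)
  }
  if (length(direct_D) == 0 || is.null(names(direct_D))) {
    abort("direct_D must be nonempty and named by herb")
  }
  names(direct_D) <- normalize_text(names(direct_D))
  direct_D
}

#' Indirect substitutability of a herb for a drug
#'
#' D comes from [indirect_dosage()]; N is the mean side-effect intersection
#' count over all prescriptions in the database containing the indirect herb
#' (no +1 term - the indication is, by definition of "indirect", never in
#' those prescriptions). The score is D x N.
#'
#' @inheritParams indirect_dosage
#' @inheritParams direct_substitutability
#' @return A one-row `substitutability` tibble with `mode = "indirect"`.
#' @export
indirect_substitutability <- function(se_lexicon, herb_ind, direct_D, prescriptions,
                                      drug = NA_character_) {
  prescriptions <- validate_prescriptions(prescriptions)
  herb_ind <- normalize_text(herb_ind)
  d_val <- indirect_dosage(herb_ind, direct_D, prescriptions)
  has_ind <- map_lgl(rx_herb_sets(prescriptions), function(h) herb_ind %in% h)
  containing <- prescriptions[has_ind, ]
  n_mean <- mean(intersection_counts(se_lexicon, containing$indication_text))
  new_substitutability(tibble(
    drug = drug, herb = herb_ind, mode = "indirect",
    D = d_val, N = n_mean, score = d_val * n_mean,
    n_prescriptions = nrow(containing)
  ), drug = drug)
}

#' Score every herb of a prescription database against one drug
#'
#' Each herb is scored on the direct path if it qualifies (herb and target
#' indication in at least one common prescription) and on the indirect path
#' otherwise; a herb qualifying as direct is never also scored indirectly.
#' If the database has no direct herb at all, indirect propagation has no
#' source and every indirect herb receives D = 0.
#'
#' @param prescriptions The prescription database.
#' @param se_lexicon The drug's side-effect lexicon.
#' @param indication_synonyms Chinese synonyms of the target indication.
#' @param herbs Herbs to score; defaults to every herb in the database.
#' @param drug Optional drug id recorded on the result.
#' @return A `substitutability` tibble, one row per herb.
#' @export
substitutability <- function(prescriptions, se_lexicon, indication_synonyms,
                             herbs = NULL, drug = NA_character_) {
  prescriptions <- validate_prescriptions(prescriptions)
  all_herbs <- sort(unique(c(character(0), unlist(rx_herb_sets(prescriptions)))),
    method = "radix"
  )
  herbs <- normalize_text(herbs %||% all_herbs)
  absent <- setdiff(herbs, all_herbs)
  if (length(absent) > 0) {
    inform(sprintf(
      "skipping %d herb(s) absent from the prescription database: %s",
      length(absent), paste(absent, collapse = ", ")
    ))
    herbs <- setdiff(herbs, absent)
  }
  if (length(herbs) == 0) {
    return(new_substitutability(tibble(
      drug = character(), herb = character(), mode = character(),
      D = numeric(), N = numeric(), score = numeric(), n_prescriptions = integer()
    ), drug = drug))
  }
  direct_rxs <- map(herbs, function(h) direct_prescriptions(prescriptions, h, indication_synonyms))
  is_direct <- map_int(direct_rxs, nrow) > 0
  direct_records <- map2(herbs[is_direct], direct_rxs[is_direct], function(h, rxs) {
    direct_substitutability(se_lexicon, h, rxs, drug = drug)
  })
  direct_tbl <- bind_rows(direct_records)
  indirect_records <- map(herbs[!is_direct], function(h) {
    if (nrow(direct_tbl) == 0) {
      # no direct herb anywhere: nothing to propagate from
      has_ind <- map_lgl(rx_herb_sets(prescriptions), function(s) h %in% s)
      containing <- prescriptions[has_ind, ]
      n_mean <- mean(intersection_counts(se_lexicon, containing$indication_text))
      return(tibble(
        drug = drug, herb = h, mode = "indirect",
        D = 0, N = n_mean, score = 0, n_prescriptions = nrow(containing)
      ))
    }
    indirect_substitutability(se_lexicon, h, setNames(direct_tbl$D, direct_tbl$herb),
      prescriptions,
      drug = drug
    )
  })
  new_substitutability(bind_rows(direct_tbl, bind_rows(indirect_records)), drug = drug)
}

#' Rank herbs by substitutability
#'
#' Descending by score, ties broken by herb name in code-point order,
#' truncated to the top k. Deterministic.
#'
#' @param records A `substitutability` tibble (all for one drug).
#' @param k Number of herbs to keep; default 10. If fewer records exist, all
#'   are returned.
#' @return The top rows with a `rank` column prepended.
#' @export
rank_alternatives <- function(records, k = 10) {
  out <- as_tibble(records) |>
    arrange(desc(.data$score), .data$herb) |>
    slice_head(n = k) |>
    mutate(rank = row_number(), .before = 1)
  new_substitutability(out, drug = attr(records, "drug"))
}

#' Write substitutability records as TSV
#'
#' Columns: drug, herb, mode, D, N, score, n_prescriptions (plus rank when
#' present).
#'
#' @param records A `substitutability` tibble.
#' @param path Output path.
#' @export
write_substitutability <- function(records, path) {
  keep <- intersect(
    c("rank", "drug", "herb", "mode", "D", "N", "score", "n_prescriptions"),
    names(records)
  )
  readr::write_tsv(as_tibble(records)[keep], path)
  invisible(path)
}
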