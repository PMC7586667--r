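#' Configuration for the synthetic study generator
#'
#' Bundles the study conditions for the seeded generators: corpus and
#' prescription-database sizes, the mean pair frequency, and the planted
#' structure used by the recovery tests - one drug whose side-effect links
#' run at a multiple of each side effect's cross-drug mean while its
#' indication link runs at a fraction of the indication mean, and one herb
#' receiving a boosted dosage share whose prescriptions get side-effect
#' terms seeded into their indication texts at an elevated rate.
#'
#' @param seed Integer seed; the same seed and config reproduce the data
#'   byte for byte.
#' @param n_drugs,n_side_effects,n_indications,n_docs,n_herbs,n_prescriptions
#'   Problem sizes (all >= 1).
#' @param base_link_rate Mean link weight aimed at for an ordinary
#'   drug-concept pair.
#' @param planted_drug List with `se_multiplier` and `ind_multiplier`
#'   (both > 0) applied to the first drug's link rates.
#' @param planted_herb List with `dose_boost` (> 0; the first herb's dose is
#'   this multiple of the mean component dose of its prescription) and
#'   `seed_rate` (probability, per side-effect concept, of seeding a synonym
#'   into the indication text of a prescription containing the planted
#'   herb).
#' @param base_seed_rate Seeding probability for prescriptions without the
#'   planted herb.
#' @param indication_rate Probability that a prescription's indication text
#'   mentions the target indication.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_drugs = 10, n_side_effects = 8, n_indications = 4,
                         n_docs = 600, n_herbs = 20, n_prescriptions = 40,
                         base_link_rate = 10,
                         planted_drug = list(se_multiplier = 3, ind_multiplier = 0.5),
                         planted_herb = list(dose_boost = 2, seed_rate = 0.6),
                         base_seed_rate = 0.1, indication_rate = 0.6) {
  counts <- c(
    n_drugs = n_drugs, n_side_effects = n_side_effects,
    n_indications = n_indications, n_docs = n_docs,
    n_herbs = n_herbs, n_prescriptions = n_prescriptions
  )
  if (any(!is.finite(counts)) || any(counts < 1)) {
    abort("all synthetic counts must be >= 1")
  }
  mult <- c(
    planted_drug$se_multiplier, planted_drug$ind_multiplier,
    planted_herb$dose_boost
  )
  if (length(mult) != 3 || any(!is.finite(mult)) || any(mult <= 0)) {
    abort("planted multipliers must all be > 0")
  }
  rates <- c(planted_herb$seed_rate, base_seed_rate, indication_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    abort("seeding and indication rates must lie in [0, 1]")
  }
  if (!is.finite(seed)) abort("seed must be a finite integer")
  structure(
    list(
      seed = as.integer(seed),
      n_drugs = as.integer(n_drugs), n_side_effects = as.integer(n_side_effects),
      n_indications = as.integer(n_indications), n_docs = as.integer(n_docs),
      n_herbs = as.integer(n_herbs), n_prescriptions = as.integer(n_prescriptions),
      base_link_rate = base_link_rate,
      planted_drug = planted_drug, planted_herb = planted_herb,
      base_seed_rate = base_seed_rate, indication_rate = indication_rate
    ),
    class = "synth_config"
  )
}

#' Generate a synthetic annotated-abstract corpus
#'
#' Each document mentions one drug plus a subset of that drug's dictionary
#' concepts, drawn independently with inclusion probabilities calibrated so
#' the expected link weight of an ordinary pair is `base_link_rate`; the
#' planted drug's side-effect and indication probabilities are scaled by its
#' multipliers. Alongside the documents the generator returns the true
#' link-weight table, tallied by a plain nested loop over the documents so
#' it can serve as an independent oracle for [extract_pairs()].
#'
#' @param cfg A [synth_config()].
#' @return A list with `documents`, `se_dict`, `ind_dict`, `truth` (tibble
#'   `concept_a`, `concept_b`, `weight`) and `planted_drug`.
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  drugs <- sprintf("DRUG%02d", seq_len(cfg$n_drugs))
  ses <- sprintf("SE%02d", seq_len(cfg$n_side_effects))
  inds <- sprintf("IND%02d", seq_len(cfg$n_indications))
  planted <- drugs[1]

  # dictionaries: each drug covers ~60% of side effects (>= 1), every drug
  # shares the first (target) indication so the candidate ranking has
  # competitors, plus occasional extra indications
  se_dict <- bind_rows(map(drugs, function(d) {
    mine <- ses[runif(length(ses)) < 0.6]
    if (length(mine) == 0) mine <- sample(ses, 1)
    tibble(drug = d, concept = mine)
  }))
  # ensure every side effect is linked to at least two drugs, so cross-drug
  # averaging is always defined on more than a single observation
  for (s in ses) {
    holders <- se_dict$drug[se_dict$concept == s]
    if (length(holders) < 2) {
      extra <- sample(setdiff(drugs, holders), 2 - length(holders))
      se_dict <- bind_rows(se_dict, tibble(drug = extra, concept = s))
    }
  }
  se_dict <- arrange(se_dict, .data$drug, .data$concept)
  ind_dict <- bind_rows(map(drugs, function(d) {
    extra <- inds[-1][runif(cfg$n_indications - 1) < 0.25]
    tibble(drug = d, concept = c(inds[1], extra))
  })) |> arrange(.data$drug, .data$concept)

  docs_per_drug <- cfg$n_docs / cfg$n_drugs
  p_of <- function(mult) min(0.95, mult * cfg$base_link_rate / docs_per_drug)
  doc_drug <- sample(drugs, cfg$n_docs, replace = TRUE)
  documents <- bind_rows(map(seq_len(cfg$n_docs), function(i) {
    d <- doc_drug[i]
    my_se <- se_dict$concept[se_dict$drug == d]
    my_ind <- ind_dict$concept[ind_dict$drug == d]
    p_se <- p_of(if (d == planted) cfg$planted_drug$se_multiplier else 1)
    p_ind <- p_of(if (d == planted) cfg$planted_drug$ind_multiplier else 1)
    dis <- c(
      my_se[runif(length(my_se)) < p_se],
      my_ind[runif(length(my_ind)) < p_ind]
    )
    tibble(
      doc_id = sprintf("doc%04d", i),
      concept_id = c(d, dis),
      entity_type = c("drug", rep("disease", length(dis)))
    )
  }))

  # independent truth tally: plain loop + table(), no joins
  keys <- character(0)
  for (i in seq_len(cfg$n_docs)) {
    rows <- documents[documents$doc_id == sprintf("doc%04d", i), ]
    dz <- unique(rows$concept_id[rows$entity_type == "disease"])
    dr <- unique(rows$concept_id[rows$entity_type == "drug"])
    for (a in dr) for (b in dz) keys <- c(keys, paste(a, b, sep = "\t"))
  }
  tab <- table(keys)
  parts <- str_split(names(tab), "\t", simplify = TRUE)
  truth <- tibble(
    concept_a = if (length(tab)) parts[, 1] else character(),
    concept_b = if (length(tab)) parts[, 2] else character(),
    weight = as.integer(tab)
  ) |> arrange(.data$concept_a, .data$concept_b)

  list(
    documents = documents, se_dict = se_dict, ind_dict = ind_dict,
    truth = truth, planted_drug = planted
  )
}

# deterministic pool of two-character CJK words, all distinct
cjk_words <- function(n, used = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    w <- map_chr(seq_len(n - length(out)), function(i) {
      intToUtf8(sample(0x4e00:0x9fa5, 2, replace = TRUE))
    })
    out <- unique(c(out, setdiff(w, used)))
  }
  out[seq_len(n)]
}

#' Generate a synthetic bilingual lexicon
#'
#' Concepts get 1-3 synonyms of two characters drawn from the CJK unified
#' range, globally distinct, to exercise Unicode handling end to end.
#'
#' @param n_concepts Number of concepts.
#' @param seed Integer seed.
#' @param prefix Concept-id prefix.
#' @return A lexicon tibble (`concept_id`, `english_name`, `synonym`).
#' @export
generate_lexicon <- function(n_concepts, seed = 1L, prefix = "SE") {
  set.seed(seed)
  n_syn <- sample(1:3, n_concepts, replace = TRUE)
  words <- cjk_words(sum(n_syn))
  idx <- rep(seq_len(n_concepts), n_syn)
  validate_lexicon(tibble(
    concept_id = sprintf("%s%02d", prefix, idx),
    english_name = sprintf("%s_concept_%02d", str_to_lower(prefix), idx),
    synonym = words
  ))
}

#' Generate a synthetic prescription database with planted structure
#'
#' Prescriptions draw 4-8 ordinary herbs with doses over the classical units
#' (liang/qian/fen). The planted herb (first of the herb pool) joins each
#' prescription with probability 0.9 and its dose is `dose_boost` times the
#' mean component dose of that prescription (expressed in qian, fractional
#' quantities allowed), so its dosage proportion is the boost multiple of an
#' average component by construction. Indication texts are comma-joined
#' synonym strings: the target indication appears with probability
#' `indication_rate`, and each side-effect concept contributes a synonym
#' with probability `seed_rate` in prescriptions containing the planted herb
#' (`base_seed_rate` otherwise), plus neutral filler words.
#'
#' @param cfg A [synth_config()].
#' @param se_lexicon Side-effect lexicon whose synonyms are seeded into the
#'   texts (e.g. from [generate_lexicon()]).
#' @param indication_synonyms Chinese synonyms of the target indication;
#'   defaults to a generated pair of terms.
#' @return A list with `prescriptions`, `herbs`, `planted_herb` and
#'   `indication_synonyms`.
#' @export
generate_prescriptions <- function(cfg, se_lexicon, indication_synonyms = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  se_lexicon <- validate_lexicon(se_lexicon)
  set.seed(cfg$seed)
  reserved <- se_lexicon$synonym
  if (is.null(indication_synonyms)) {
    pool <- cjk_words(2, used = reserved)
    indication_synonyms <- pool
  }
  indication_synonyms <- normalize_text(indication_synonyms)
  reserved <- c(reserved, indication_synonyms)
  herbs <- cjk_words(cfg$n_herbs, used = reserved)
  reserved <- c(reserved, herbs)
  fillers <- cjk_words(6, used = reserved)
  planted <- herbs[1]
  boost <- cfg$planted_herb$dose_boost
  syn_by_concept <- split(se_lexicon$synonym, se_lexicon$concept_id)

  rows <- map(seq_len(cfg$n_prescriptions), function(i) {
    k <- sample(4:8, 1)
    others <- sample(herbs[-1], k)
    unit <- sample(names(.fen_per_unit), k, replace = TRUE, prob = c(0.05, 0.70, 0.25))
    quantity <- ifelse(unit == names(.fen_per_unit)[1], 1, sample(1:9, k, replace = TRUE))
    comp <- tibble(
      herb = others, quantity = as.numeric(quantity), unit = unit,
      dose_fen = normalize_dose(as.numeric(quantity), unit)
    )
    has_planted <- runif(1) < 0.9
    if (has_planted) {
      dose <- boost * mean(comp$dose_fen)
      q <- round(dose / 10, 1) # express in qian, one decimal
      comp <- bind_rows(comp, tibble(
        herb = planted, quantity = q, unit = names(.fen_per_unit)[2],
        dose_fen = normalize_dose(q, names(.fen_per_unit)[2])
      ))
    }
    rate <- if (has_planted) cfg$planted_herb$seed_rate else cfg$base_seed_rate
    seeded <- map_chr(
      syn_by_concept[runif(length(syn_by_concept)) < rate],
      function(s) s[sample.int(length(s), 1)]
    )
    parts <- c(
      if (runif(1) < cfg$indication_rate) sample(indication_synonyms, 1),
      unname(seeded),
      sample(fillers, 2)
    )
    tibble(
      rx_id = sprintf("rx%03d", i),
      indication_text = paste(sample(parts), collapse = "，"),
      source = "synthetic",
      components = list(comp)
    )
  })
  list(
    prescriptions = validate_prescriptions(bind_rows(rows)),
    herbs = herbs, planted_herb = planted,
    indication_synonyms = indication_synonyms
  )
}

#' Write a complete synthetic bundle to disk
#'
#' Writes documents (JSON lines), both dictionaries, the prescription
#' database, the side-effect lexicon, the indication synonyms and a manifest
#' recording the seed and a hash of the configuration. All files are UTF-8
#' and round-trip through the package readers.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_synthetic_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  corpus <- generate_corpus(cfg)
  lex <- generate_lexicon(cfg$n_side_effects, seed = cfg$seed, prefix = "SE")
  rx <- generate_prescriptions(cfg, lex)
  write_documents(corpus$documents, file.path(dir, "documents.jsonl"))
  write_dictionary(corpus$se_dict, file.path(dir, "se_dict.tsv"))
  write_dictionary(corpus$ind_dict, file.path(dir, "ind_dict.tsv"))
  write_link_weights(corpus$truth, file.path(dir, "true_link_weights.tsv"))
  write_prescriptions(rx$prescriptions, file.path(dir, "prescriptions.tsv"))
  write_lexicon(lex, file.path(dir, "se_lexicon.tsv"))
  writeLines(rx$indication_synonyms, file.path(dir, "indication_synonyms.txt"),
    useBytes = TRUE
  )
  jsonlite::write_json(
    list(seed = cfg$seed, config_hash = rlang::hash(unclass(cfg))),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}
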