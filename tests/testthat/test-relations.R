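test_that("a single document contributes one count per mixed-type pair", {
  docs <- toy_docs(d1 = c(A = "drug", X = "disease", Y = "disease"))
  links <- extract_pairs(docs)
  expect_equal(nrow(links), 2)
  expect_equal(link_weight(links, "A", "X"), 1L)
  expect_equal(link_weight(links, "A", "Y"), 1L)
  expect_equal(link_weight(links, "X", "A"), 1L) # symmetric lookup
  expect_equal(link_weight(links, "X", "Y"), 0L) # same-typed pair not counted
})

test_that("counts accumulate across documents and same-typed pairs never count", {
  docs <- toy_docs(
    d1 = c(A = "drug", X = "disease"),
    d2 = c(A = "drug", X = "disease"),
    d3 = c(A = "drug", B = "drug", H = "herb", X = "disease")
  )
  links <- extract_pairs(docs)
  expect_equal(link_weight(links, "A", "X"), 3L)
  expect_equal(link_weight(links, "B", "X"), 1L)
  expect_equal(link_weight(links, "H", "X"), 1L) # herb-disease counts
  expect_equal(link_weight(links, "A", "B"), 0L) # drug-drug does not
  expect_equal(link_weight(links, "A", "H"), 0L) # drug-herb does not
})

test_that("mention order and duplicated mentions do not change any count", {
  docs <- toy_docs(
    d1 = c(A = "drug", X = "disease", Y = "disease"),
    d2 = c(B = "drug", X = "disease")
  )
  shuffled <- docs[rev(seq_len(nrow(docs))), ]
  duplicated <- dplyr::bind_rows(docs, docs[1, ])
  expect_equal(extract_pairs(shuffled), extract_pairs(docs))
  expect_equal(extract_pairs(duplicated), extract_pairs(docs))
})

test_that("malformed documents are rejected with informative errors", {
  expect_error(
    validate_documents(tibble::tibble(doc_id = "d1", concept_id = "A", entity_type = "gene")),
    "unknown entity_type"
  )
  expect_error(validate_documents(tibble::tibble(doc_id = "d1")), "must have columns")
})

test_that("extract_pairs matches the generator's loop-tallied truth on a planted corpus", {
  cfg <- synth_config(seed = 42, n_docs = 50, n_drugs = 5, n_side_effects = 4, n_indications = 2)
  corpus <- generate_corpus(cfg)
  links <- extract_pairs(corpus$documents)
  got <- dplyr::arrange(
    tibble::tibble(
      concept_a = links$concept_a, concept_b = links$concept_b,
      weight = links$weight
    ),
    concept_a, concept_b
  )
  expect_equal(got, corpus$truth)
})

test_that("classification copies counts by dictionary membership, keeping dual members in both", {
  links <- extract_pairs(toy_docs(
    d1 = c(A = "drug", headache = "disease", insomnia = "disease"),
    d2 = c(A = "drug", headache = "disease", fever = "disease"),
    d3 = c(A = "drug", headache = "disease", insomnia = "disease"),
    d4 = c(A = "drug", headache = "disease"),
    d5 = c(A = "drug", headache = "disease"),
    d6 = c(A = "drug", insomnia = "disease")
  ))
  se_dict <- tibble::tibble(drug = "A", concept = c("headache", "insomnia"))
  ind_dict <- tibble::tibble(drug = "A", concept = "insomnia")
  rel <- classify_relations(links, se_dict, ind_dict)
  se <- dplyr::filter(rel, relation == "side_effect")
  ind <- dplyr::filter(rel, relation == "indication")
  expect_equal(se$weight[se$concept == "headache"], 5L)
  expect_false("headache" %in% ind$concept)
  # insomnia is in both dictionaries: present in both tables, same count
  expect_equal(se$weight[se$concept == "insomnia"], 3L)
  expect_equal(ind$weight[ind$concept == "insomnia"], 3L)
  # fever matches neither dictionary and is dropped
  expect_false("fever" %in% rel$concept)
})

test_that("classification conserves link weights on a synthetic table", {
  cfg <- synth_config(seed = 7, n_docs = 120, n_drugs = 10)
  corpus <- generate_corpus(cfg)
  links <- extract_pairs(corpus$documents)
  rel <- classify_relations(links, corpus$se_dict, corpus$ind_dict)
  # every output count equals the input link weight for its pair
  for (i in seq_len(nrow(rel))) {
    expect_identical(rel$weight[i], link_weight(links, rel$drug[i], rel$concept[i]))
  }
  # brute-force conservation: matched (deduplicated) plus dropped = total
  in_se <- purrr::map2_lgl(links$concept_a, links$concept_b, function(a, b) {
    any(corpus$se_dict$drug == a & corpus$se_dict$concept == b)
  })
  in_ind <- purrr::map2_lgl(links$concept_a, links$concept_b, function(a, b) {
    any(corpus$ind_dict$drug == a & corpus$ind_dict$concept == b)
  })
  expect_equal(sum(rel$weight), sum(links$weight[in_se]) + sum(links$weight[in_ind]))
  expect_equal(
    sum(links$weight) - sum(links$weight[in_se | in_ind]),
    sum(links$weight[!in_se & !in_ind])
  )
})

test_that("documents and link weights round-trip through their file formats", {
  docs <- toy_docs(
    d1 = c(A = "drug", X = "disease"),
    d2 = c(H = "herb", X = "disease", Y = "disease")
  )
  doc_path <- withr::local_tempfile(fileext = ".jsonl")
  write_documents(docs, doc_path)
  expect_equal(read_documents(doc_path), validate_documents(docs))

  links <- extract_pairs(docs)
  lw_path <- withr::local_tempfile(fileext = ".tsv")
  write_link_weights(links, lw_path)
  back <- read_link_weights(lw_path)
  expect_equal(back$weight, links$weight)
  expect_equal(back$concept_a, links$concept_a)
})

test_that("malformed JSON-lines input names the offending record", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"doc_id":"d1","mentions":[{"concept_id":"A","entity_type":"drug"}]}', "{oops"), path)
  expect_error(read_documents(path), "line 2")
})
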