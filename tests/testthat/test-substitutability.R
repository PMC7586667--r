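se_lex <- function() toy_lexicon(list(dizzy = c("头昏", "头眩"), dry = "口燥", upset = "烦躁"))

test_that("the mirtazapine / white peony worked example reproduces", {
  rxs <- depression_prescriptions()
  lex <- mirtazapine_lexicon()
  direct <- direct_prescriptions(rxs, "白芍", depression_synonyms())
  expect_equal(nrow(direct), 2) # both prescriptions mention depression
  rec <- direct_substitutability(lex, "白芍", direct, drug = "mirtazapine")
  expect_equal(rec$N, 4) # mean(3, 3) + 1
  expect_equal(rec$D, mean(c(0.12, 10 / 116)))
  expect_equal(rec$score, 0.412, tolerance = 0.002)
  expect_equal(rec$score, rec$D * rec$N, tolerance = 1e-12)
})

test_that("a direct herb with no side-effect overlap still gets N = 1", {
  rx <- toy_rx("r1", c("白芍2钱", "甘草1钱"), "治抑郁")
  rec <- direct_substitutability(se_lex(), "白芍", rx)
  expect_equal(rec$N, 1) # 0 intersections + 1 for the indication itself
  expect_equal(rec$score, 20 / 30 * 1)
  expect_error(direct_substitutability(se_lex(), "白芍", rx[0, ]), class = "herbsub_not_direct")
})

test_that("direct scores equal brute-force means on seeded prescriptions", {
  lex <- generate_lexicon(6, seed = 31)
  db <- generate_prescriptions(synth_config(seed = 31, n_prescriptions = 5), lex)
  rxs <- db$prescriptions
  herb <- db$planted_herb
  direct <- direct_prescriptions(rxs, herb, db$indication_synonyms)
  if (nrow(direct) > 0) {
    rec <- direct_substitutability(lex, herb, direct)
    # independent recomputation: explicit loops, no package helpers
    props <- ns <- numeric(0)
    for (i in seq_len(nrow(direct))) {
      comp <- direct$components[[i]]
      props <- c(props, sum(comp$dose_fen[comp$herb == herb]) / sum(comp$dose_fen))
      hit <- 0
      for (cid in unique(lex$concept_id)) {
        syns <- lex$synonym[lex$concept_id == cid]
        if (any(vapply(syns, grepl, logical(1), x = direct$indication_text[i], fixed = TRUE))) {
          hit <- hit + 1
        }
      }
      ns <- c(ns, hit)
    }
    expect_equal(rec$D, mean(props))
    expect_equal(rec$N, mean(ns) + 1)
    expect_equal(rec$score, mean(props) * (mean(ns) + 1))
  }
})

test_that("indirect dosage propagates co-occurrence ratios and sums over direct herbs", {
  # ind co-occurs with every direct herb in all its prescriptions
  db1 <- toy_rx_db(
    toy_rx("r1", c("直一1钱", "直二1钱", "旁参2钱"), "抑郁"),
    toy_rx("r2", c("直一1钱", "直二1钱", "旁参1钱"), "安神")
  )
  D <- c("直一" = 0.3, "直二" = 0.2)
  expect_equal(indirect_dosage("旁参", D, db1), 0.5) # all ratios 1 -> sum of D

  # never co-occurring indirect herb scores zero
  db2 <- toy_rx_db(
    toy_rx("r1", "直一1钱", "抑郁"),
    toy_rx("r2", "旁参1钱", "安神")
  )
  expect_equal(indirect_dosage("旁参", c("直一" = 0.4), db2), 0)
  expect_error(indirect_dosage("不在", D, db1), class = "herbsub_unknown_herb")

  # hand-computed mixed case: 3 direct herbs, F_h = 2
  db3 <- toy_rx_db(
    toy_rx("r1", c("旁参1钱", "直一1钱", "直二1钱"), "甲"),
    toy_rx("r2", c("旁参1钱", "直一1钱"), "乙"),
    toy_rx("r3", c("直三1钱",  "直二1钱"), "丙")
  )
  D3 <- c("直一" = 0.5, "直二" = 0.25, "直三" = 0.1)
  # F_c: 直一 = 2, 直二 = 1, 直三 = 0; F_h = 2
  expect_equal(indirect_dosage("旁参", D3, db3), (2 / 2) * 0.5 + (1 / 2) * 0.25 + 0)
})

test_that("indirect substitutability averages N over containing prescriptions, no +1", {
  lex <- se_lex()
  db <- toy_rx_db(
    toy_rx("r1", c("直一2钱", "旁参2钱"), "抑郁, 头昏"), # direct herb's rx
    toy_rx("r2", "旁参1钱", "头昏, 口燥"), # N_n = 2
    toy_rx("r3", "旁参1钱", "安神") # N_n = 0
  )
  direct <- direct_substitutability(lex, "直一", direct_prescriptions(db, "直一", "抑郁"))
  rec <- indirect_substitutability(lex, "旁参", c("直一" = direct$D), db)
  expect_equal(rec$mode, "indirect")
  # N averages over ALL prescriptions containing the indirect herb: (1+2+0)/3
  expect_equal(rec$N, 1)
  expect_equal(rec$score, rec$D * rec$N)
  # single-prescription arithmetic: D = 0.1, N_n = 2 -> score 0.2
  db4 <- toy_rx_db(
    toy_rx("p1", c("直一9钱", "旁参1钱"), "头昏, 口燥"),
    toy_rx("p2", "直一1钱", "抑郁")
  )
  rec4 <- indirect_substitutability(lex, "旁参", c("直一" = 0.1), db4)
  expect_equal(rec4$D, (1 / 1) * 0.1)
  expect_equal(rec4$N, 2)
  expect_equal(rec4$score, 0.2)
})

test_that("direct herbs take precedence and are never scored indirectly", {
  lex <- se_lex()
  db <- toy_rx_db(
    toy_rx("r1", c("白芍2钱", "甘草1钱"), "抑郁, 烦躁"),
    toy_rx("r2", c("甘草1钱", "旁参1钱"), "安神")
  )
  recs <- substitutability(db, lex, "抑郁")
  expect_equal(sort(recs$herb[recs$mode == "direct"]), sort(c("白芍", "甘草")))
  expect_equal(recs$herb[recs$mode == "indirect"], "旁参")
  expect_equal(sum(recs$herb == "甘草"), 1)
  # direct N >= 1 always; indirect has no +1 floor
  expect_true(all(recs$N[recs$mode == "direct"] >= 1))
})

test_that("raising the target herb's dose or seeding a synonym never lowers the direct score", {
  lex <- se_lex()
  base_rx <- toy_rx("r1", c("白芍2钱", "甘草1钱"), "抑郁")
  base <- direct_substitutability(lex, "白芍", base_rx)
  heavier <- direct_substitutability(lex, "白芍", toy_rx("r1", c("白芍4钱", "甘草1钱"), "抑郁"))
  expect_gte(heavier$score, base$score)
  seeded <- direct_substitutability(lex, "白芍", toy_rx("r1", c("白芍2钱", "甘草1钱"), "抑郁, 头昏"))
  expect_gte(seeded$score, base$score)
})

test_that("ranking is a deterministic sorted truncation with code-point ties", {
  recs <- tibble::tibble(
    drug = "x", herb = c("乙", "甲", "丙"), mode = "direct",
    D = 0.1, N = c(2, 2, 5), score = c(0.2, 0.2, 0.5), n_prescriptions = 1L
  )
  ranked <- rank_alternatives(recs, k = 10)
  expect_equal(ranked$herb[1], "丙")
  # tie between 乙 (U+4E59) and 甲 (U+7532): code-point order
  expect_equal(ranked$herb[2:3], c("乙", "甲"))
  expect_equal(ranked$rank, 1:3)
  top2 <- rank_alternatives(recs, k = 2)
  expect_equal(nrow(top2), 2)
  expect_setequal(rank_alternatives(recs, k = 99)$herb, recs$herb)
})

test_that("full-database scoring agrees with an independent per-herb loop", {
  lex <- generate_lexicon(5, seed = 77)
  db <- generate_prescriptions(synth_config(seed = 77, n_prescriptions = 12), lex)
  recs <- substitutability(db$prescriptions, lex, db$indication_synonyms)
  expect_setequal(
    recs$herb,
    unique(unlist(purrr::map(db$prescriptions$components, ~ unique(.x$herb))))
  )
  for (h in sample(recs$herb, 4)) {
    row <- recs[recs$herb == h, ]
    direct <- direct_prescriptions(db$prescriptions, h, db$indication_synonyms)
    if (nrow(direct) > 0) {
      expect_equal(row$mode, "direct")
      expect_equal(row$score, direct_substitutability(lex, h, direct)$score)
    } else {
      expect_equal(row$mode, "indirect")
    }
  }
})
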