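# herbsub

Literature-based discovery of traditional-Chinese-medicine (TCM) alternatives
for western drugs with prominent side effects.

Adverse drug reactions are a leading cause of death, and TCM herbs are
increasingly used alongside western drugs as complementary treatment. For a
given therapeutic area, `herbsub` answers two questions from tabular inputs a
text-mining pipeline already produces:

1. **Which drugs most need an alternative?** From annotated abstracts it
   counts *link weights* — the number of abstracts in which a drug co-occurs
   with a disease concept — splits them into side-effect vs indication
   relations using SIDER-like and TTD-like dictionaries, and ranks drugs by a
   *replaceable score*.
2. **Which herbs could substitute for a flagged drug?** From a classical
   prescription database (CTPD-like) it scores each herb's *substitutability*
   for the drug by combining its dosage proportion in relevant prescriptions
   with how many of the drug's side effects the prescriptions' Chinese
   indication texts address.

It is aimed at drug-safety and TCM informatics researchers; entity
recognition, translation and database retrieval are upstream — this package
owns the scoring, ranking, unit handling and evaluation.

## The model

For drug *d* and side effect *s* with link weight *f\_s*,

```
side-effect score(d, s) = f_s / mean(f_s' over all drugs linked to s)
indication score(d, i)  = f_i / mean(f_i' over all drugs linked to i)
```

The cross-drug denominators damp literature bias: a side effect common to
many drugs (headache, say) cannot inflate any one drug's profile, and by
construction each concept's scores average to exactly 1 across its drugs.
With `Rate_se` the mean of a drug's side-effect scores over its α observed
side effects,

```
replaceable(d, i) = Rate_se(d) / indication score(d, i)
```

and drugs with `replaceable > 1` are flagged as candidates for replacement.
Flagged candidates are validated against oral LD50 (rat, mg/kg) and
elimination half-life parsed from free-text drug profiles.

For a herb *h*, doses are normalized to the smallest classical mass unit
(1 两 liang = 10 钱 qian = 100 分 fen). If *h* appears in at least one
prescription whose indication text mentions the target indication (a
*direct* herb),

```
substitutability(d, h) = D × N,
D = mean per-prescription dosage proportion of h,
N = mean per-prescription count of d's side-effect concepts found in the
    indication text, + 1 (the target indication itself is treated too)
```

Herbs never co-occurring with the indication (*indirect*) get D propagated
through co-occurrence ratios with direct herbs, `D = Σ_h (F_c/F_h) × D[h]`,
and N averaged over their own prescriptions without the +1. The top herbs
are finally checked structurally: herb → ingredient → target → disease
graphs keep only ingredients with oral bioavailability > 30 % and
drug-likeness > 0.18 (strict), and diseases restricted to the focal drug's
own side effects and indications.

## Worked example

The package bundles the published worked example: two classical
prescriptions indicated for depression and the side-effect lexicon of
mirtazapine. White peony root (白芍) appears in both prescriptions with
dosage proportions 3/25 = 0.12 and 10/116 ≈ 0.086; each indication text
mentions three of mirtazapine's side effects.

```r
library(herbsub)
rxs <- depression_prescriptions()
lex <- mirtazapine_lexicon()
rec <- direct_substitutability(
  lex, "白芍",
  direct_prescriptions(rxs, "白芍", depression_synonyms()),
  drug = "mirtazapine"
)
tidy(rec)
#> # A tibble: 1 × 7
#>   drug        herb  mode       D     N score n_prescriptions
#>   <chr>       <chr> <chr>  <dbl> <dbl> <dbl>           <int>
#> 1 mirtazapine 白芍  direct 0.103     4 0.412               2
```

D = mean(0.12, 0.086) ≈ 0.103 and N = mean(3, 3) + 1 = 4 give a
substitutability of 0.412. On the drug side, the bundled score table for 12
antidepressants ranks and flags them:

```r
cards <- rank_replaceable(antidepressant_scores())
head(tidy(cards), 4)
#> # A tibble: 4 × 5
#>   drug        rate_se indication_score replaceable needs_alternative
#>   <chr>         <dbl>            <dbl>       <dbl> <lgl>
#> 1 Nefazodone    0.333           0.0795        4.19 TRUE
#> 2 Milnacipran   0.623           0.159         3.92 TRUE
#> 3 Mianserin     0.346           0.119         2.90 TRUE
#> 4 Trazodone     0.816           0.318         2.57 TRUE
glance(cards)
#> # A tibble: 1 × 4
#>   n_drugs n_flagged threshold max_replaceable
#>     <int>     <int>     <dbl>           <dbl>
#> 1      12         7         1            4.19
```

Seven of the twelve antidepressants exceed the threshold; nefazodone ranks
first (its side-effect literature outweighs its indication literature more
than four-fold), matching its poor toxicity/half-life profile.

`autoplot()` works on rankings, substitutability tables and filtered
herb–ingredient–target–disease graphs; `tidy()`/`glance()` follow broom
conventions. A command-line wrapper (`exec/herbsub`) exposes the pipeline as
`score-drugs`, `rank-herbs`, `evaluate`, `hitd-graph` and `simulate`
subcommands.

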