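# hlenrich

Which protein-level functions carry information about how fast the body
clears a drug? `hlenrich` is an R package for analysts who have (a) a table
of drugs with known biological half-lives, (b) a protein–chemical
interaction network in the STITCH `protein_chemical.links` dialect, and
(c) GO-term / KEGG-pathway protein annotations in GMT format, and who want
to know which annotation terms are informative about the drugs' half-life
categories.

## The method

Drugs are binned into five half-life categories (&lt;1 h, 1–4 h, 4–12 h,
12–24 h, ≥24 h). Each drug *d* gets a protein set *P(d)* from the
interaction network, and its association with an annotation term *t*
(protein set *P(t)*, |*P(t)*| = *M*, universe size *N*) is the
hypergeometric upper-tail score

    S(d, t) = −log10  Σ_{k=m}^{min(n,M)}  C(M,k) · C(N−M, n−k) / C(N,n)

with *n* = |*P(d)*| and *m* = |*P(d)* ∩ *P(t)*|. The drug × term score
matrix is the feature encoding. Every term is then ranked by the plug-in
mutual information I(x, y) = Σ p(x,y) log[ p(x,y) / (p(x) p(y)) ] between
its discretized score column and the category labels — the Max-Relevance
(MaxRel) half of the mRMR criterion — and terms above an MI threshold
(defaults: 0.03 GO, 0.013 KEGG, inclusive) are summarised as "level
values": the mean enrichment score per half-life category, the cells of
the exported heat-map matrices.

A planted-signal synthetic generator (`generate_dataset()`) produces
complete datasets in which known terms are overrepresented in known
categories, so the whole pipeline — parsing, encoding, ranking, profiling —
is testable end to end without any downloads.

## Worked example

```r
library(hlenrich)

ds <- generate_dataset(syn_config(seed = 1))        # 300 drugs, 200 terms, 10 planted
em <- encode_drugs(ds$interactions, ds$annotations) # 300 x 200 score matrix
labels <- ds$drugs$category[match(rownames(em$scores), ds$drugs$drug_id)]
ranked <- maxrel_rank(em, labels)
head(ranked, 5)
#>    rank term_id name     mi
#> 1     1 T0134   T0134 0.452
#> 2     2 T0136   T0136 0.413
#> 3     3 T0001   T0001 0.368
#> 4     4 T0112   T0112 0.368
#> 5     5 T0045   T0045 0.355

recovery_report(ranked, ds$planted, k = c(10, 15))
#>       k recall
#> 1    10    0.9
#> 2    15    1
```

The MI column is in bits; the top-ranked terms here are planted ones
(`ds$planted` holds the ground truth), and all 10 planted terms sit inside
the top 15 of 200 — the generator's signal is fully recovered. Level
profiles for the leaders show *which* category drives each term:

```r
level_values(em, labels, selected_terms = head(ranked$term_id, 3))
#>   term_id category_1 category_2 category_3 category_4 category_5
#> 1 T0134       0         15.5         0.117      0          0
#> 2 T0136       0.0889     0.536       0          0          0
#> 3 T0001      15.2        0.0215      0          0.188      0.132
```

T0134 is planted for category 2 and T0001 for category 1; their level
values spike exactly there (a level value of 15 means the mean per-drug
tail probability in that category is ~10⁻¹⁵). `autoplot()` on a
`level_matrix` draws the heat map; on a `maxrel_ranking` it draws MI
against rank.

File-based runs go through `run_pipeline(pipeline_config(...))` (or the
wrapper script `inst/cli/halflife_enrich.R` with subcommands
`run` / `encode` / `rank` / `select` / `levels` / `simulate`), which writes
per namespace the enrichment matrix, full MaxRel ranking, selected terms
and level-value matrix, plus a JSON manifest with input checksums,
parameters and drug-attrition counts.

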