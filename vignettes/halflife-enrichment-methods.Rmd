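---
title: "Methods: gene-set enrichment profiles and mutual-information ranking for drug half-life"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-set enrichment profiles and mutual-information ranking for drug half-life}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlenrich)
```

## The problem and the model

A drug's biological half-life — the time for the body to eliminate half of a
dose — is binned here into five categories: under 1 h, 1–4 h, 4–12 h,
12–24 h, and 24 h or more. The question the pipeline addresses is which
protein-level functional annotations (GO terms, KEGG pathways) carry
information about those categories.

The encoding works through protein sets. Each drug $d$ is linked, via a
protein–chemical interaction network in the STITCH `protein_chemical.links`
dialect, to a protein set $P(d)$. Each annotation term $t$ annotates a
protein set $P(t)$ of size $M$ inside a background universe of $N$ proteins.
The association between drug and term is scored by the hypergeometric
upper-tail probability of their overlap $m = |P(d) \cap P(t)|$ given the
drug's set size $n = |P(d)|$:

$$
S(d, t) \;=\; -\log_{10} \sum_{k=m}^{\min(n, M)}
\frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}} .
$$

The sum's upper limit is written as $\min(n, M)$; terms beyond $M$ vanish
anyway because $\binom{M}{k} = 0$ for $k > M$, so this is value-preserving
and avoids evaluating undefined coefficients. A score of 0 corresponds to
$m = 0$ (the tail is then exactly 1); larger scores indicate stronger
association. The scores of one drug over all terms form its feature vector,
and drugs whose protein set is empty are excluded from the matrix and
reported.

Each term is then ranked by the *relevance* half of the
minimum-redundancy–maximum-relevance (mRMR) criterion: the plug-in mutual
information

$$
I(x, y) \;=\; \sum_{x,y} p(x,y)\,\log\frac{p(x,y)}{p(x)\,p(y)}
$$

between the term's discretized score column $y$ and the category labels
$x$, estimated from the empirical contingency table. Terms are sorted by
descending MI (the MaxRel list); a threshold on MI selects the informative
terms, and each selected term is profiled by its *level values* — the mean
enrichment score over the drugs of each category — which are the cells of
the exported heat-map matrices.

## Tunable parameters

- **`min_score`** (STITCH combined score, integer 0–1000; default 0).
  The upstream study states no confidence cutoff, so the default keeps every
  interaction; raising it reruns the analysis on higher-confidence links.
- **`merge_stereo`** (default `TRUE`). STITCH carries both a stereo-merged
  (`CIDm`) and a stereo-specific (`CIDs`) flavor of each PubChem compound.
  By default both flavors of one numeric CID collapse to a single drug;
  disabling keeps them apart with a flavor suffix.
- **`universe_size`** ($N$; default: the union of all annotation members).
  "The total number of human proteins" admits no single census, so $N$ is
  an explicit, recorded input rather than a guess. Reproducibility beats
  precision here: the ranking is monotone-stable under moderate changes of
  $N$ because all cells of a column shift together.
- **`sigma`** (discretization width; default 1). Continuous scores are cut
  into three states at mean $\pm \sigma \cdot s$, with $s$ the *population*
  standard deviation of the column — the convention of the widely used mRMR
  implementation. A constant column is entirely `mid` and carries zero MI.
- **`mi_base`** (default 2, bits). The MI definition leaves the base open;
  the base rescales all MI values by a constant and therefore never changes
  the ranking, only the threshold scale.
- **MI thresholds** (defaults 0.03 for GO, 0.013 for KEGG, *inclusive*).
  The published selections contain entries printed exactly at the
  threshold, so the comparison is $\ge$.
- **`top_k`** (default off). The full ranking is always computed;
  truncation (the original analysis kept the first 500 GO features) is an
  output option only.

Ties in MI are broken by ascending `term_id`, which together with the fixed
iteration orders makes every ranking a deterministic function of its
inputs: identical inputs give byte-identical output files.

## Numerical choices

The hypergeometric tail is evaluated in log space through
`phyper(..., log.p = TRUE)` (log-gamma based), so deep tails lose no
precision to underflow in $P$-space; scores are capped at 300 because
$-\log_{10}$ of the smallest positive double is about 308. Output TSVs
print doubles with 17 significant digits and are re-read through the
correctly rounded C `strtod`, so write-then-read reproduces every value
bit-exactly. The plug-in MI sum skips zero-probability cells (their limit
contribution is 0) and clamps the result at 0 against rounding noise.
Drug proteins absent from the annotated universe count in $n$ but can never
appear in $m$: they are draws without success potential, consistent with
the two-set overlap picture.

## What the synthetic generator emulates

`generate_dataset()` produces a self-contained dataset so every stage is
testable without downloads: drugs with half-lives sampled inside their
category's bin, category counts drawn from the published 56:231:154:61:63
proportions (multinomial by default, exact largest-remainder counts on
request), a 2000-protein universe, 200 flat annotation terms of 10–80
proteins, and drug protein sets of 5–40 proteins. Ten planted terms are
assigned round-robin to the five categories; for each drug of a planted
term's target category, $\lceil \rho \cdot |P(t)| \rceil$ proteins of the
term (default $\rho = 0.8$) are forced into the drug's set. When several
planted terms target the same category, the drug's set capacity is split
evenly among them before that cap is applied — otherwise the first term
processed would exhaust small sets and systematically starve the rest,
making half the planted signal unrecoverable by construction. The effect is
planted at the protein-set level, not the score level, so recovery
exercises the whole composition: set overlap, hypergeometric scoring,
discretization, and MI ranking.

What the generator does *not* emulate: STITCH's confidence-score
distribution (all synthetic links share one score), the GO DAG (terms are
flat, independent sets, whereas real GO terms nest and overlap
hierarchically), term-size and set-size distributions of real annotation
releases, and the correlated pharmacology of real drugs. Passing the
planted-recovery benchmark therefore shows the machinery is correct and
sensitive under clean conditions; it does not certify effect sizes on real
2016-era STITCH/GO/KEGG inputs, whose published MI magnitudes depend on
those specific releases and are not numeric reproduction targets.

## Design decisions on genuinely open points

- **Bin boundaries.** The category descriptions ("less than 1 h", "between
  1 and 4 h", ...) leave boundary membership open; bins are
  lower-closed/upper-open, giving a deterministic partition of $(0,
  \infty)$ with no gaps or overlaps.
- **Stereo flavors and score cutoff.** Both are unstated upstream; both are
  configuration, defaulting to the most inclusive behavior (merge, keep
  all).
- **Discretization and MI base.** The downloaded mRMR binary's exact
  settings are unrecoverable; the defaults follow its documented
  convention (three states at mean $\pm 1$ population SD, bits) and both
  are configurable.
- **Level values for absent categories.** A category with no drugs has no
  mean; it is an error to request one rather than silently reported as 0,
  because 0 is a meaningful score.

## Problem sizes used by the test suite

The packaged checks run the generator at its defaults (300 drugs, 2000
proteins, 200 terms) for the recovery benchmark over five seeds, with
smaller instances (60–150 drugs) for parser, pipeline and property tests,
and a 670-drug table for full-scale parsing. A full default-size run —
generation, encoding (300 × 200 hypergeometric tests), ranking and
profiling — takes well under a minute on one core.

## A small end-to-end example

```{r example, message = FALSE}
ds <- generate_dataset(syn_config(n_drugs = 120, n_proteins = 800,
                                  n_terms = 80, seed = 1))
em <- encode_drugs(ds$interactions, ds$annotations)
labels <- ds$drugs$category[match(rownames(em$scores), ds$drugs$drug_id)]
ranked <- maxrel_rank(em, labels)
recovery_report(ranked, ds$planted, k = c(10, 15, 20))
level_values(em, labels, selected_terms = head(ranked$term_id, 5))
```

## Known limitations

- Identifier mapping between chemical vocabularies (drug names, PubChem
  CIDs) is out of scope; inputs must arrive pre-mapped, and attrition from
  unmapped drugs is recorded in the run manifest rather than repaired.
- Only the Max-Relevance ranking is implemented; the redundancy-aware mRMR
  list (and any classifier built on the selected features) is deliberately
  absent.
- The plug-in MI estimator is positively biased at small sample sizes
  (roughly $(|x|-1)(|y|-1)/(2 N \ln 2)$ bits); rankings are comparable
  within one dataset, but MI values should not be compared across datasets
  of different size. The permuted-label null in the test suite quantifies
  this floor.
- Raw per-cell tail probabilities are used as a feature encoding, not as
  significance calls; no multiple-testing correction is applied or
  appropriate.
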