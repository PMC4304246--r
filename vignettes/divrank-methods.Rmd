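---
title: "Methods: diversity-biased learning-to-rank for passage retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity-biased learning-to-rank for passage retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divrank)
```

## The model

`divrank` ranks passages — maximal spans of consecutive text between
paragraph boundaries within one document — for biomedical topics whose
information need decomposes into *aspects* (genes, diseases, mutations,
...). Two linear models share one scoring form `S_Λ(p, Q) = Λ · fv(p, Q)`:

* the **general model (gLTR)** uses eight content-based features
  (`general_feature_names()`): TF-IDF, Okapi BM25, DFR BM25, InL2, DLH13,
  Dirichlet KL language model, Hiemstra's language model, and query-term
  proximity;
* the **diversity-biased model (dLTR)** appends seven features
  (`diversity_feature_names()`) computed from the ranking that gLTR induces
  and from per-passage aspect annotations.

The final ranking uses `α · gLTR + (1 − α) · dLTR` on per-query
min–max-normalized scores.

## Pinned feature formulations

The framework names its constituent retrieval models but their exact
dialects vary across systems, so this package pins one formulation per
feature and unit-tests each against hand-worked values on a three-passage
micro-corpus. With `tf` the term frequency in the passage, `df`/`cf`
document and collection frequency, `N` passages, `len` the passage length,
`avgdl` the mean passage length and `total` the token count of the
collection:

| Feature | Per matched query term (summed with query multiplicity) |
|---|---|
| TFIDF | `tf · log((N+1)/(df+1))` |
| BM25 | `log((N−df+0.5)/(df+0.5)) · tf(k1+1) / (tf + k1(1−b+b·len/avgdl))` |
| DFR_BM25 | `(k1+1)·tfn/(k1+tfn) · log2((N−df+0.5)/(df+0.5))` |
| InL2 | `tfn/(tfn+1) · log2((N+1)/(df+0.5))` |
| DLH13 | `(tf·log2((tf·avgdl/len)·(N/cf)) + 0.5·log2(2π·tf·(1−tf/len))) / (tf+0.5)` |
| DirKL | `log((tf + μ·cf/total)/(len + μ))` (all query terms, matched or not) |
| HiemstraLM | `log(1 + λ·tf·total/((1−λ)·cf·len))` |
| ProxQT | sum over ordered pairs of distinct matched terms of `1/mindist²` |

`tfn = tf · log2(1 + c·avgdl/len)` is DFR length normalization 2. Defaults
(`feature_params()`) are the field-standard `k1 = 1.2`, `b = 0.75`,
`c = 1`, `μ = 2000` tokens, `λ = 0.15`, unlimited proximity window; all are
configurable, and DLH13 deliberately accepts no tuning parameter.

Three numerical guards keep scores finite without disturbing order: an
out-of-vocabulary query term under DirKL uses the background floor
`1/(2·total)`; DLH13 clamps `1 − tf/len` at `1e-10` for the degenerate
single-term passage; Hiemstra terms with `cf = 0` contribute nothing.
A caveat the test suite makes explicit: classical BM25 idf becomes negative
once `df > N/2`, where BM25 is genuinely *not* monotone in `tf`; the
monotonicity property is asserted in the ordinary `df ≤ N/2` regime.

ProxQT is specified in the literature only by the intuition that co-occurring
query terms near each other signal relevance; the inverse-square
minimum-distance pair accumulation used here satisfies the required strict
monotonicity in pair distance and is directly testable against a brute-force
oracle.

## Diversity features ("once for all")

Walking the initial ranking at rank `i` with `Seen(i)` the aspects of ranks
`< i` and `A_rel` the query's relevant aspect set:

* `RelAsp`/`NonRelAsp` split the passage's aspects by membership in `A_rel`;
* `NewRelAsp`/`OldRelAsp` split the relevant ones by novelty against
  `Seen(i)` (their sum is `RelAsp` — an identity the tests enforce on
  thousands of random instances);
* `NewAspPsg` is the fraction of prior passages that themselves introduced
  an unseen aspect (any aspect, read literally), 0 at rank 1;
* `PctRelAsp` counts relevant-aspect occurrences among all aspect
  occurrences before rank `i` *with multiplicity*, while `PctUniqRelAsp` is
  `|Seen ∩ A_rel| / |Seen|` over *unique* aspects — the two ratios would
  otherwise be redundant. Both are 0 when nothing precedes.

Features are computed once from the gLTR ranking and never regenerated
during training; the alternative (regenerating features as the model is
re-learned) is substantially more expensive and is not implemented.

Where `A_rel` comes from is genuinely open at inference time. The package
uses a provider abstraction: during training `A_rel` defaults to the
query's gold aspects; at inference, with no provider, every observed aspect
is treated as relevant, so only the novelty structure of the list carries
signal and no ground truth leaks into prediction. `gold_aspect_provider()`
supplies the query's own aspect set at both ends ("topics detected on the
query"); on synthetic data it is close to oracular (it lifted Aspect MAP by
an order of magnitude more than the no-provider default in our runs), which
is why the package's benchmark does not use it.

## Training: coordinate ascent on a retrieval metric

`train_coordinate_ascent()` maximizes a rank-based metric directly: each
coordinate in turn is replaced by every value of a signed geometric grid
(`default_weight_grid()`, 17 values spanning ±[0.01, 4]), the best strictly
improving replacement is accepted, and sweeps repeat until the relative
improvement drops below `tol = 1e-4` or 25 sweeps. Restarts (the best
single-feature model first, then seeded random grid points) guard against
local optima; the best vector visited anywhere is returned, L1-normalized
(scale cannot change a ranking, so normalization is cosmetic).

Two design choices differ from the obvious transcription and are
deliberate:

* **weights stay on the grid during the search** and are normalized only at
  the end. Normalizing after every accepted step would move coordinates off
  the grid and void the package's strongest trainer guarantee — that on
  small problems (≤3 features, ≤5 grid points) the final objective equals
  exhaustive search over every grid combination, which the tests verify;
* an off-grid **refinement pass is opt-in** (`refine = TRUE`) for the same
  reason.

The trainer metrics are `"map"` (binary AP over passage grades),
`"document_map"` and `"aspect_map"`, all evaluated by fast kernels that the
test suite cross-checks against the general run/qrels evaluation module.
The general model trains on Document MAP (also the model-selection metric
in the cross-validation harness). The diversity model trains on aspect-level
AP: that is the quantity its features exist to improve, and a saturated
relevance metric (common on easy splits) would otherwise leave coordinate
ascent with no accepted moves and a degenerate model. `train_greedy()`
implements greedy feature introduction — each round, the best single
feature addition is kept only if it improves the objective after coordinate
ascent — as a model-building alternative; plain coordinate ascent over all
features reaches the same training objective on our benchmarks at a
fraction of the cost, so the harnesses default to it.

Ties in every ranking are broken by ascending passage id, a stable
documented rule that makes rankings, runs and the whole pipeline
reproducible byte for byte under a fixed seed.

## Evaluation dialect

The four metrics are pinned operationally (exact parity with the official
TREC Genomics scoring scripts is out of scope):

* **Document MAP** — collapse the run to first document occurrences;
  textbook AP, a document being relevant iff it carries any positively
  graded gold span (verified against an independent AP oracle on hundreds
  of random instances);
* **Passage MAP** — walking ranked passages, a hit contributes its newly
  retrieved gold characters at precision (cumulative gold characters) /
  (cumulative retrieved characters), normalized by total gold characters;
* **Passage2 MAP** — passages exploded to characters in rank order; a
  character is a hit iff inside a gold span and not previously retrieved;
  AP over the character stream;
* **Aspect MAP** — a passage is an aspect-hit iff relevant and introducing
  ≥1 unseen gold aspect; `k` new aspects give `k` credits at precision
  (aspect-hit passages so far)/rank, normalized by the gold aspect count.
  The per-aspect credit convention is an interpretation; it makes a
  passage covering all aspects at rank 1 score exactly 1.

Character spans are 0-based half-open throughout; two spans overlap iff
they share ≥1 character, and relevance transfer from gold spans to
extracted passages takes the maximum grade and the union of aspects over
overlapping positively graded spans. Unjudged material is non-relevant.

## The synthetic collection generator

`generate_corpus()` emulates the statistical structure the framework
assumes, not biomedical language: each topic owns a gold aspect set; each
aspect owns a disjoint 5-term vocabulary cluster; queries sample two terms
per gold cluster; relevant passages draw tokens from their assigned
aspects' clusters with background noise; non-relevant passages are
background text with a weaker "distractor" admixture of the topic's
cluster terms (half the relevant share), so lexical separation is
imperfect, as in real collections. The `redundancy` parameter is the
probability that a relevant passage repeats an already-used aspect instead
of introducing a new one — at 0, every relevant passage brings a new
aspect until the gold set is exhausted; at 1, one aspect is repeated
throughout. Passages are packed five to a document with paragraph breaks
between them so extraction and overlap-based relevance transfer are
exercised end to end, and all outputs re-serialize deterministically per
seed.

Default conditions — 20 topics, 4 aspects/topic, 30 candidate passages of
30 tokens per topic, vocabulary 600, relevance rate 0.3, noise rate 0.6 —
were chosen to give the general model realistic headroom (Document MAP
≈ 0.97, Aspect MAP ≈ 0.8 in the package's benchmark) rather than a
saturated task on which every trainer move would be rejected. The
package's benchmark (`diversity_benchmark()`, also what
`scripts/acceptance.R` runs: 10 replicate collections at redundancy 0.6,
2-fold cross-validation, α tuned per fold on the training half by Document
MAP over the 0.1…0.9 grid) shows the combined model improving mean Aspect
MAP over gLTR by about 5% with tuned α centring on the 0.6–0.8 band.

What passing on this generator does *not* show: robustness to real
biomedical vocabulary statistics (Zipfian tails, synonymy), to noisy topic
detection in the annotations, or to the span-reconciliation quirks of
official judgment files. The generator's aspects are clean, disjoint and
consistently annotated; results on it validate the machinery and the
qualitative behaviour of the diversity features, not absolute performance
on any real collection.

## Known limitations

* The metric dialect is one defensible reading of the TREC Genomics
  write-ups; in particular the Passage MAP precision bookkeeping differs
  across descriptions, and no bit-parity with `trec_eval`-family scripts is
  claimed.
* Tokenization is whitespace/punctuation splitting with an optional light
  suffix stemmer — deliberately simple and deterministic, not a full
  Porter implementation.
* Coordinate ascent guarantees the ascent property and grid-oracle
  equivalence, not any particular step trajectory; different grids give
  different (all valid) optima on non-smooth metric surfaces.
* The diversity features depend on the quality of the initial ranking; a
  poor general model degrades them (the "once for all" trade-off).
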