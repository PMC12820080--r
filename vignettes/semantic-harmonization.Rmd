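---
title: "Semantic harmonization of symptom rating scales: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic harmonization of symptom rating scales: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semharmony)
library(dplyr)
```

## The problem

Formal thought disorder (FTD) — disruption of the structure and flow of
thought as expressed in speech — is rated with at least seven partly
overlapping instruments (TLC, TALD, CLANG, SAPS-SANS, PANSS, TLI, BIT).
The same term can denote different phenomena in different scales, and
different terms the same phenomenon, which blocks pooling of item-level
data across studies. `semharmony` harmonizes scales by the *meaning of
their item descriptions*: items are embedded as dense vectors, compared by
cosine similarity, clustered across scales, and the resulting semantic
groups are checked against expert judgment and against item correlations
in participant data.

Scale texts are copyrighted and not bundled. Users supply their own item
bank (CSV/JSON); everything here runs on the package's synthetic corpora,
which have known ground truth.

## Pipeline and model

1. **Preprocessing** (`preprocess_text()`): lowercasing, whitespace
   collapsing, and removal of *illustrative* parenthetical groups — those
   opening with "e.g." or "i.e." (extra prefixes configurable). Only these
   groups are removed because other parentheticals typically carry synonyms
   ("(Word salad, Jargon Aphasia)") that are part of the item's meaning.
   Word counts are taken on the raw description (whitespace tokens), so
   length statistics describe the source texts, not the cleaned ones.

2. **Embedding** (`embed_texts()`): a pluggable backend contract. The
   reference backend is the published 768-dimensional sentence-transformer
   `all-mpnet-base-v2` (pinned by id and revision); it is *not* bundled,
   and its absence is a hard error — never a silent fallback. The default
   offline backend, `mock_backend()`, hashes tokens into 4096 vocabulary
   slots, projects the slot-count vector through a seed-determined Gaussian
   matrix (d = 256 by default, minimum 8), and L2-normalizes. Texts sharing
   more tokens have higher expected cosine, which is all the downstream
   machinery needs; the mock is bitwise reproducible across sessions.

3. **Similarity** (`item_similarity_matrix()`, `scale_centroid_matrix()`):
   cosine similarity, with three normalizations. The default `clip01`
   truncates negatives to zero: cosines between natural-language item
   embeddings are almost always positive, so observed values are unchanged
   while the advertised [0, 1] range holds. `affine01` ((cos + 1)/2) is
   offered where strict monotonicity matters, `raw_cosine` for raw values.
   Whether one clips, rescales, or simply observes nonnegative cosines is a
   package design choice, not an inference about any published analysis.
   At scale level, off-diagonal cells compare scale centroids (mean item
   embedding); the diagonal is the scale's within-scale consistency — the
   mean pairwise similarity over its items' unordered pairs, `NA` for
   single-item scales.

4. **Backbone sparsification** (`sparsify_to_backbone()`): one scale (TLC
   by convention; it is widely used, mid-sized, and present in the clinical
   data) anchors the network. Every non-backbone item keeps exactly one
   edge — to its most similar backbone item. By default every backbone item
   also keeps one edge to its most similar *other* backbone item
   (`include_intra_backbone = TRUE`). Without some intra-backbone linkage
   each connected component would contain exactly one backbone item and the
   backbone scale could never form multi-item groups; the top-1 rule is the
   minimal-degree way to connect it and is configurable. Similarity ties
   break toward the earliest backbone item in bank order and are flagged.

5. **Clustering** (`cluster_graph()`): default `components` — connected
   components of the undirected edge set. It is parameter-free and
   deterministic, and on the sparse backbone topology the number of
   clusters is emergent, never forced. `greedy_modularity` (weighted greedy
   modularity maximization) is offered for denser graphs. Labels are
   renumbered by descending cluster size, ties by smallest member id, so
   output labels are stable.

6. **Expert agreement** (`fleiss_kappa()`, `category_kappa()`): multi-rater
   Fleiss' kappa over an items x categories count matrix, overall and per
   category, with asymptotic normal confidence intervals. The standard
   error is the classic large-sample null-variance form (Fleiss/Nee/Landis)
   and, per category, `sqrt(2 / (N m (m-1)))`; other published variants
   exist, and the CI should be read as precision under the null-style
   approximation. The machine clustering can be folded in as one more
   rater. Because cluster ids are arbitrary while expert categories are
   meaningful, `map_machine_to_categories()` first aligns the label spaces
   by majority vote within each cluster (ties warn and resolve
   deterministically). `disagreement_ranking()` gives the complementary
   per-item human-vs-machine view used to surface the most contested items.

7. **Clinical alignment** (`clinical_alignment()`): items on which no
   participant scored above zero are excluded (and constant nonzero columns,
   separately flagged, since correlations are undefined there); excluded
   items also leave the candidate pool. Each backbone item is then paired
   with the partner-scale item of maximal *signed* Pearson correlation
   (Spearman optional). Signed, not absolute: the question is which
   phenomena co-occur, and an absolute rule would pair opposites. The
   co-cluster count is tested with an exact one-sided binomial tail
   (`exact_binomial_upper_tail()`, accumulated in log space), against a
   flat 1/K chance level by default; a cluster-size-weighted null
   (`sum of squared cluster shares`) is available because flat chance
   ignores unequal cluster sizes. Patients and controls are pooled by
   default, with a group filter flag.

## The synthetic-data generator

`generator_config()` fixes the study conditions: 7 scales with 103 items
(30/20/17/13/11/8/4), 4 latent themes, mixing weight `w = 0.8`, 6 expert
raters at fidelity 0.9, latent loading `lambda = 0.8`, noise
`sigma = 0.5`, ordinal scores 0–4, and 98 participants (49 patients, 49
controls). Design choices worth knowing:

* **Item texts.** Each theme owns a disjoint core vocabulary (30 tokens);
  a shared filler vocabulary (80 tokens) supplies the rest. An item of
  length `L` draws `ceiling(w * L)` core tokens; `w` therefore controls
  between-theme separation monotonically (`w = 0` makes themes
  unrecoverable, `w = 1` removes all sharing). Lengths are drawn uniformly
  from 6–150 tokens: real instruments range from terse labels to
  paragraph-length definitions, and this heterogeneity matters
  structurally — long, vocabulary-rich items act as semantic prototypes
  that anchor each theme's neighborhood, keeping the top-1 backbone graph
  connected within themes. With constant-length texts, within-theme
  similarities are exchangeable and the top-1 digraph fragments into
  mutual-nearest pairs.

* **Expert error model.** A rater labels an item with its true theme with
  probability `a`, else uniformly over all k categories *including* the
  truth, so the effective per-rating accuracy is `a + (1 - a)/k`. This is
  the exact process Monte-Carlo oracles in the tests simulate.

* **Ratings.** Each participant draws one standard-normal severity per
  theme (shared across scales); an item's raw score is
  `lambda * severity + sigma * noise`, discretized at equal-probability
  cut points of the marginal Normal(0, sqrt(lambda^2 + sigma^2)) — a
  simplicity-over-realism choice (real symptom scores are right-skewed).
  Zero-inflation is applied after discretization (so planted all-zero
  columns are exact), with a higher rate for controls (0.30 vs 0.15),
  which reproduces the qualitative patient > control severity contrast.

* **Determinism.** All generator stages derive their RNG streams from one
  seed via stage-name hashing, through a private RNG that never touches the
  caller's `.Random.seed`; identical config + seed gives byte-identical
  CSV output.

What passing synthetic tests does *not* show: the generator's bag-of-tokens
texts have no syntax, no antonymy, and no cross-theme polysemy, so it
cannot expose the known failure mode of text embeddings where opposite
severity poles ("too slow" vs "too fast") embed as near-identical. Results
on real scales depend on the reference model and must be validated with it
(see `inst/integration/reference_model_check.R`).

## Numerical choices and degenerate inputs

* Cosines are symmetrized and clamped to [-1, 1] before normalization;
  zero-norm vectors raise an error naming the item.
* Argmax ties (construct classification, backbone edges, correlate
  pairing) resolve to the earliest candidate in input order and carry an
  explicit flag, because a silent arbitrary choice would be irreproducible.
* `exact_binomial_upper_tail()` accumulates the tail in log space
  (log-sum-exp), exact to ~1e-15 relative against big-integer rational
  arithmetic for all k <= n <= 30 in the test suite.
* `fleiss_kappa()` is undefined when all mass falls in a single category
  (expected agreement 1) and errors; `category_kappa()` likewise for
  marginal proportions of 0 or 1.
* A 2x2 chi-square with a zero row or column margin is an error, not 0.
* Single-item scales get `NA` within-scale consistency rather than a
  fabricated 1.

## Worked example (all numbers computed here)

```{r example}
cfg <- generator_config(seed = 1)
gen <- generate_item_bank(cfg)
length_statistics(gen$bank)

backend <- mock_backend(seed = 1, dimension = 256)
emb <- embed_items(gen$bank, backend)
sim <- item_similarity_matrix(emb)
graph <- sparsify_to_backbone(sim, gen$bank, backbone_scale = "TLC")
clusters <- cluster_graph(graph)
table(clusters$cluster)
adjusted_rand_index(
  clusters$cluster,
  gen$truth$theme[match(clusters$item_id, gen$truth$item_id)])

experts <- generate_expert_assignments(gen$truth, fidelity = 0.9,
                                       n_raters = 6, seed = 1)
am <- build_assignment_matrix(experts, machine = clusters)
agreement_table(am)

items <- left_join(gen$truth, as_tibble(gen$bank)[, c("item_id", "scale_id")],
                   by = "item_id")
ratings <- generate_participant_ratings(
  items[items$scale_id %in% c("TLC", "CLANG"), ], cfg)
clinical_alignment(ratings$TLC, ratings$CLANG, clusters, chance = 0.25)
```

## Problem sizes used in the test suite

The suite validates cluster recovery over 20 generator seeds (median
adjusted Rand index), expert agreement against a 10,000-replicate
Monte-Carlo expectation at N = 103 items and m = 7 raters, and end-to-end
clinical alignment over 100 replicates of 200 participants each; formula
oracles run on 1,000 random agreement matrices and 200 random graph
fixtures. These sizes give Monte-Carlo error well inside the asserted
tolerances while keeping a full run to a few minutes.

## Known limitations

* The mock backend measures token overlap, not meaning; it validates the
  pipeline, never a linguistic claim.
* Connected components are brittle to single spurious edges on dense
  graphs; prefer `greedy_modularity` if you lower the sparsification.
* The asymptotic kappa CIs use a null-style variance; for small N a
  bootstrap would be preferable.
* The flat 1/K chance level of the co-cluster test ignores unequal
  cluster sizes; the weighted null is the conservative alternative.
* With more clusters than expert categories, majority mapping can merge
  clusters, which deflates machine-included agreement relative to a
  one-to-one matching.
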