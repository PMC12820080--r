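#!/usr/bin/env Rscript

# OPTIONAL integration check -- requires the reference sentence-transformer.
#
# This script is NOT part of the test suite: it needs the all-mpnet-base-v2
# model (downloaded via the Python `sentence-transformers` package and
# reached from R through `reticulate`), neither of which ships with this
# package. Run it manually in an environment that has both:
#
#   Rscript inst/integration/reference_model_check.R
#
# It verifies the published reference-model behaviours that the offline
# suite cannot touch:
#   * the antonym pair "responses are too slow" / "responses are too fast"
#     embeds with cosine similarity 0.931 (+/- 0.005) -- the known
#     limitation that text embeddings conflate opposite severity poles;
#   * if you supply your own TALD item bank (path as first argument, CSV
#     with scale_id,item_index,label,description) plus a reference
#     classification CSV (item_id,construct_id; second argument), the
#     positive/negative construct classification and its accuracy /
#     chi-square against the factor-derived grouping are reported.

library(semharmony)

if (!requireNamespace("reticulate", quietly = TRUE)) {
  stop("reticulate is required to bridge to sentence-transformers")
}
st <- reticulate::import("sentence_transformers")
model <- st$SentenceTransformer("all-mpnet-base-v2")

backend <- reference_backend(embed_fn = function(texts) {
  m <- model$encode(as.list(texts))
  matrix(as.numeric(m), nrow = length(texts), byrow = FALSE,
         dimnames = list(NULL, NULL))
})

emb <- embed_texts(c("responses are too slow", "responses are too fast"),
                   backend)
cosine <- sum(emb[1, ] * emb[2, ]) / sqrt(sum(emb[1, ]^2) * sum(emb[2, ]^2))
cat(sprintf("antonym cosine: %.4f (published reference: 0.931 +/- 0.005)\n",
            cosine))
stopifnot(abs(cosine - 0.931) <= 0.005)

args <- commandArgs(trailingOnly = TRUE)
if (length(args) >= 2) {
  bank <- load_item_bank(args[1])
  reference <- readr::read_csv(args[2], show_col_types = FALSE)
  constructs <- construct_descriptions(
    positive_FTD = paste(
      "Positive FTD is best represented by derailment and loosening of",
      "associations, an increased amount of produced speech (e.g.,",
      "logorrhoea, pressured speech), the use of new words (neologisms),",
      "and stilted speech phenomena (manneristic speech)"),
    negative_FTD = paste(
      "Negative FTD has been conceptualised as a quantitative deficit in",
      "speech and thought production (e.g., poverty of speech, slowed",
      "thinking, and blocking)"))
  asg <- classify_by_construct(bank, constructs, backend)
  print(asg)
  cmp <- compare_to_reference(asg, reference)
  print(cmp)
} else {
  cat("no item bank supplied; skipping the construct-classification check\n")
}
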