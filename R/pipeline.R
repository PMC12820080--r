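#' Adjusted Rand index between two partitions
#'
#' Chance-corrected overlap between two labelings of the same items; 1 for
#' identical partitions (up to relabeling), about 0 for independent ones.
#' Used throughout to score recovery of generator ground truth.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}

#' Pipeline configuration
#'
#' Collects every tunable of the semantic-harmonization pipeline with
#' documented defaults: the embedding backend, cosine normalization,
#' backbone scale, clustering method, correlation method, chance-level
#' rule, confidence level, preprocessing flags, and the master seed from
#' which all stage seeds are derived. The configuration round-trips through
#' JSON unchanged (backends are stored by id and rebuilt).
#'
#' @param backend An `embedding_backend` (default `mock_backend()` with
#'   `seed`; reference-model runs are opt-in by passing
#'   [reference_backend()] explicitly).
#' @param normalization Cosine normalization mode.
#' @param backbone_scale Backbone scale id (default `"TLC"`).
#' @param cluster_method `"components"` or `"greedy_modularity"`.
#' @param include_intra_backbone Keep top-1 backbone-to-backbone edges.
#' @param correlation `"pearson"` or `"spearman"`.
#' @param chance Chance-level rule for [cocluster_test()].
#' @param level Confidence level for agreement statistics.
#' @param strip_illustrative,lowercase Text preprocessing flags.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(backend = NULL,
                            normalization = "clip01",
                            backbone_scale = "TLC",
                            cluster_method = "components",
                            include_intra_backbone = TRUE,
                            correlation = "pearson",
                            chance = "flat",
                            level = 0.95,
                            strip_illustrative = TRUE,
                            lowercase = TRUE,
                            seed = 1L) {
  backend <- backend %||% mock_backend(seed = derive_seed(seed, "embedding"))
  structure(
    list(backend = backend, normalization = normalization,
         backbone_scale = backbone_scale, cluster_method = cluster_method,
         include_intra_backbone = include_intra_backbone,
         correlation = correlation, chance = chance, level = level,
         strip_illustrative = strip_illustrative, lowercase = lowercase,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_snapshot <- function(config) {
  list(backend_id = config$backend$backend_id,
       backend_dimension = config$backend$dimension,
       normalization = config$normalization,
       backbone_scale = config$backbone_scale,
       cluster_method = config$cluster_method,
       include_intra_backbone = config$include_intra_backbone,
       correlation = config$correlation,
       chance = config$chance, level = config$level,
       strip_illustrative = config$strip_illustrative,
       lowercase = config$lowercase, seed = config$seed)
}

#' Run the full semantic-harmonization pipeline
#'
#' Orchestrates the stages on in-memory inputs and writes every stage
#' output plus a run manifest under `output_dir`:
#'
#' 1. embed item texts, build the item similarity matrix
#'    (`item_similarity.tsv`) and the scale-centroid matrix
#'    (`scale_similarity.tsv`);
#' 2. sparsify onto the backbone scale and cluster (`edges.tsv`,
#'    `network.graphml`, `clusters.tsv`);
#' 3. if `expert_table` is given: pooled Fleiss' kappa (overall and per
#'    category, machine folded in as an extra rater) and the human–machine
#'    ranking (`agreement.json`, `disagreement_ranking.tsv`);
#' 4. if two ratings matrices are given: degenerate-item exclusion,
#'    strongest-correlate pairing and the co-cluster binomial test
#'    (`alignment.json`, `pairs.tsv`);
#' 5. if `constructs` (and optionally `reference`) are given:
#'    construct-polarity classification (`polarity.tsv`,
#'    `polarity_summary.json`).
#'
#' `manifest.json` records the package version, the configuration
#' snapshot, input digests, and the MD5 digest of every output; with the
#' mock backend, re-running an identical configuration reproduces
#' byte-identical outputs.
#'
#' @param bank An `item_bank`.
#' @param output_dir Directory for stage outputs (created if needed; inputs
#'   are never mutated).
#' @param config A [pipeline_config()].
#' @param expert_table Optional long expert table (`item_id`, `rater_id`,
#'   `category`).
#' @param ratings Optional named list of exactly two `ratings_matrix`
#'   tibbles; the one whose name equals `config$backbone_scale` is the
#'   backbone side.
#' @param constructs,reference Optional construct descriptions and
#'   reference classification for the polarity stage.
#' @return Invisibly, a list with the stage results (`similarity`,
#'   `scale_similarity`, `graph`, `clusters`, and when computed
#'   `agreement`, `alignment`, `polarity`) and `manifest`.
#' @export
run_pipeline <- function(bank, output_dir, config = pipeline_config(),
                         expert_table = NULL, ratings = NULL,
                         constructs = NULL, reference = NULL) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  outputs <- character()

  emb <- embed_items(bank, config$backend)
  sim <- item_similarity_matrix(emb, normalization = config$normalization)
  results$similarity <- sim
  outputs["item_similarity"] <- file.path(output_dir, "item_similarity.tsv")
  write_similarity_tsv(sim, outputs["item_similarity"])

  results$scale_similarity <- scale_centroid_matrix(emb, bank,
                                                    normalization = config$normalization)
  outputs["scale_similarity"] <- file.path(output_dir, "scale_similarity.tsv")
  write_similarity_tsv(results$scale_similarity, outputs["scale_similarity"])

  graph <- sparsify_to_backbone(sim, bank, config$backbone_scale,
                                include_intra_backbone = config$include_intra_backbone)
  clusters <- cluster_graph(graph, method = config$cluster_method,
                            seed = config$seed)
  results$graph <- graph
  results$clusters <- clusters
  outputs["edges"] <- file.path(output_dir, "edges.tsv")
  export_graph(graph, clusters, outputs["edges"], format = "edge_tsv")
  outputs["graphml"] <- file.path(output_dir, "network.graphml")
  export_graph(graph, clusters, outputs["graphml"], format = "graphml")
  outputs["clusters"] <- file.path(output_dir, "clusters.tsv")
  write_cluster_tsv(clusters, outputs["clusters"])

  if (!is.null(expert_table)) {
    am <- build_assignment_matrix(expert_table, machine = clusters)
    overall <- fleiss_kappa(am, level = config$level)
    per_cat <- category_kappa(am, level = config$level)
    ranking <- disagreement_ranking(expert_table, clusters)
    results$agreement <- agreement_table(am, level = config$level)
    results$disagreement <- ranking
    outputs["agreement"] <- file.path(output_dir, "agreement.json")
    jsonlite::write_json(
      list(overall = as.list(as_tibble(overall)),
           per_category = as_tibble(per_cat)),
      outputs["agreement"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs["disagreement"] <- file.path(output_dir, "disagreement_ranking.tsv")
    readr::write_tsv(ranking, outputs["disagreement"], progress = FALSE)
  }

  if (!is.null(ratings)) {
    if (length(ratings) != 2L || is.null(names(ratings))) {
      abort("`ratings` must be a named list of exactly two ratings matrices")
    }
    if (!config$backbone_scale %in% names(ratings)) {
      abort(sprintf("no ratings matrix named after backbone scale '%s'",
                    config$backbone_scale))
    }
    backbone_r <- ratings[[config$backbone_scale]]
    partner_r <- ratings[[setdiff(names(ratings), config$backbone_scale)[1]]]
    alignment <- clinical_alignment(backbone_r, partner_r, clusters,
                                    method = config$correlation,
                                    chance = config$chance)
    results$alignment <- alignment
    outputs["alignment"] <- file.path(output_dir, "alignment.json")
    jsonlite::write_json(
      c(as.list(glance(alignment)), list(excluded = alignment$excluded)),
      outputs["alignment"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs["pairs"] <- file.path(output_dir, "pairs.tsv")
    readr::write_tsv(alignment$pairs, outputs["pairs"], progress = FALSE)
  }

  if (!is.null(constructs)) {
    assignments <- classify_by_construct(bank, constructs, config$backend,
                                         normalization = config$normalization)
    results$polarity <- assignments
    outputs["polarity"] <- file.path(output_dir, "polarity.tsv")
    readr::write_tsv(as_tibble(assignments), outputs["polarity"], progress = FALSE)
    if (!is.null(reference)) {
      comparison <- compare_to_reference(assignments, reference)
      results$polarity_comparison <- comparison
      outputs["polarity_summary"] <- file.path(output_dir, "polarity_summary.json")
      jsonlite::write_json(
        c(as.list(glance(comparison)),
          list(contingency = unclass(comparison$contingency))),
        outputs["polarity_summary"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }

  manifest <- list(
    tool = sprintf("semharmony %s", as.character(utils::packageVersion("semharmony"))),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = config_snapshot(config),
    outputs = lapply(stats::setNames(nm = names(outputs)), function(k) {
      list(path = basename(outputs[[k]]),
           md5 = unname(tools::md5sum(outputs[[k]])))
    })
  )
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
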