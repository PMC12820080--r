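random_fixture <- function(seed, n_scales = 3, max_items = 4) {
  # random bank + random symmetric similarity matrix over its items
  set.seed(seed)
  rows <- purrr::map_dfr(seq_len(n_scales), function(s) {
    n <- sample.int(max_items, 1)
    data.frame(scale_id = LETTERS[s], item_index = as.character(seq_len(n)),
               label = "x", description = "some item words")
  })
  bank <- as_item_bank(rows)
  n <- nrow(bank)
  m <- matrix(runif(n * n), n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  sim <- structure(list(ids = bank$item_id,
                        values = `dimnames<-`(m, list(bank$item_id, bank$item_id)),
                        normalization = "clip01", level = "item"),
                   class = "similarity_matrix")
  list(bank = bank, sim = sim)
}

test_that("single-backbone-item banks give a star graph", {
  fx <- random_fixture(1, n_scales = 2)
  bank <- as_item_bank(data.frame(
    scale_id = c("B", "X", "X", "X"), item_index = c("1", "1", "2", "3"),
    label = "x", description = "words here"))
  emb <- matrix(rnorm(4 * 8), 4, dimnames = list(bank$item_id, NULL))
  sim <- item_similarity_matrix(emb)
  g <- sparsify_to_backbone(sim, bank, "B")
  expect_equal(nrow(g$edges), 3L)  # one backbone item: no intra edges possible
  expect_true(all(g$edges$target == "B-1"))
})

test_that("edges equal a brute-force per-item argmax over backbone columns", {
  for (seed in 1:60) {
    fx <- random_fixture(seed)
    backbone <- fx$bank$scale_id[1]
    for (intra in c(TRUE, FALSE)) {
      g <- sparsify_to_backbone(fx$sim, fx$bank, backbone,
                                include_intra_backbone = intra)
      bb <- fx$bank$item_id[fx$bank$scale_id == backbone]
      others <- setdiff(fx$bank$item_id, bb)
      # edge-count law
      expect_equal(nrow(g$edges),
                   length(others) + if (intra && length(bb) > 1) length(bb) else 0L)
      for (id in others) {
        w <- fx$sim$values[id, bb]
        expected <- bb[which.max(w)]   # earliest max in bank order
        e <- g$edges[g$edges$source == id, ]
        expect_equal(e$target, expected)
        expect_equal(e$weight, max(w))
      }
      if (intra && length(bb) > 1) {
        for (id in bb) {
          cand <- setdiff(bb, id)
          w <- fx$sim$values[id, cand]
          e <- g$edges[g$edges$source == id, ]
          expect_equal(e$target, cand[which.max(w)])
        }
      }
    }
  }
})

test_that("similarity ties break to the earliest backbone item and are flagged", {
  bank <- as_item_bank(data.frame(
    scale_id = c("B", "B", "X"), item_index = c("1", "2", "1"),
    label = "x", description = "words"))
  m <- matrix(c(1, 0.2, 0.7,
                0.2, 1, 0.7,
                0.7, 0.7, 1), 3, byrow = TRUE,
              dimnames = list(bank$item_id, bank$item_id))
  sim <- structure(list(ids = bank$item_id, values = m,
                        normalization = "clip01", level = "item"),
                   class = "similarity_matrix")
  g <- sparsify_to_backbone(sim, bank, "B", include_intra_backbone = FALSE)
  expect_equal(g$edges$target, "B-1")
  expect_true(g$edges$tie)
  expect_error(sparsify_to_backbone(sim, bank, "NOPE"), "not present")
})

test_that("component clustering equals an independent flood-fill oracle", {
  for (seed in 1:40) {
    fx <- random_fixture(seed, n_scales = 4)
    g <- sparsify_to_backbone(fx$sim, fx$bank, fx$bank$scale_id[1])
    cl <- cluster_graph(g, method = "components")
    oracle <- oracle_components(fx$bank$item_id, g$edges)
    # same partition up to labels
    expect_equal(adjusted_rand_index(cl$cluster, oracle[cl$item_id]), 1)
    # labels contiguous from 1, ordered by size then smallest member
    sizes <- table(cl$cluster)
    expect_equal(sort(unique(cl$cluster)), seq_along(sizes))
    expect_true(all(diff(as.integer(sizes)) <= 0))
  }
})

test_that("two disjoint stars give two clusters; edgeless graphs give singletons", {
  bank <- as_item_bank(data.frame(
    scale_id = c("B", "B", "X", "X", "X", "X"),
    item_index = as.character(1:6), label = "x", description = "w"))
  m <- diag(6) * 0 + 0.01
  # X-3, X-4 strongly tied to B-1; X-5, X-6 to B-2; backbone items dissimilar
  m[3, 1] <- m[1, 3] <- m[4, 1] <- m[1, 4] <- 0.9
  m[5, 2] <- m[2, 5] <- m[6, 2] <- m[2, 6] <- 0.9
  diag(m) <- 1
  dimnames(m) <- list(bank$item_id, bank$item_id)
  sim <- structure(list(ids = bank$item_id, values = m,
                        normalization = "clip01", level = "item"),
                   class = "similarity_matrix")
  g <- sparsify_to_backbone(sim, bank, "B", include_intra_backbone = FALSE)
  cl <- cluster_graph(g)
  expect_equal(attr(cl, "n_clusters"), 2L)
  lab <- stats::setNames(cl$cluster, cl$item_id)
  expect_equal(lab[["B-1"]], lab[["X-3"]])
  expect_equal(lab[["B-2"]], lab[["X-5"]])
  expect_false(lab[["B-1"]] == lab[["B-2"]])

  # no edges at all: every node its own cluster
  g0 <- g
  g0$edges <- g$edges[0, ]
  cl0 <- cluster_graph(g0)
  expect_equal(attr(cl0, "n_clusters"), 6L)
  expect_error(cluster_graph(g, method = "nope"))
})

test_that("greedy modularity is deterministic and respects obvious structure", {
  fx <- random_fixture(3, n_scales = 4)
  g <- sparsify_to_backbone(fx$sim, fx$bank, fx$bank$scale_id[1])
  c1 <- cluster_graph(g, method = "greedy_modularity", seed = 5)
  c2 <- cluster_graph(g, method = "greedy_modularity", seed = 5)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_true(all(c1$cluster >= 1))
})

test_that("adding a constant to all similarities leaves edges and clusters unchanged", {
  fx <- random_fixture(11, n_scales = 4)
  g1 <- sparsify_to_backbone(fx$sim, fx$bank, fx$bank$scale_id[1])
  shifted <- fx$sim
  shifted$values <- fx$sim$values + 0.25
  g2 <- sparsify_to_backbone(shifted, fx$bank, fx$bank$scale_id[1])
  expect_equal(g2$edges[, c("source", "target")], g1$edges[, c("source", "target")])
  expect_equal(cluster_graph(g2)$cluster, cluster_graph(g1)$cluster)
})

test_that("every cluster contains a backbone item when intra-backbone edges are on", {
  for (seed in 1:10) {
    fx <- random_fixture(seed, n_scales = 4)
    g <- sparsify_to_backbone(fx$sim, fx$bank, fx$bank$scale_id[1],
                              include_intra_backbone = TRUE)
    cl <- cluster_graph(g)
    backbone_ids <- fx$bank$item_id[fx$bank$scale_id == fx$bank$scale_id[1]]
    with_backbone <- unique(cl$cluster[cl$item_id %in% backbone_ids])
    expect_setequal(unique(cl$cluster), with_backbone)
  }
})

test_that("graph exports round-trip (edge TSV) and parse as GraphML", {
  fx <- random_fixture(17, n_scales = 3)
  g <- sparsify_to_backbone(fx$sim, fx$bank, fx$bank$scale_id[1])
  cl <- cluster_graph(g)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_graph(g, cl, tsv, format = "edge_tsv")
  back <- read_edge_tsv(tsv)
  expect_equal(nrow(back), nrow(g$edges))
  key <- function(df) sort(paste(df$source, df$target, signif(df$weight, 12)))
  expect_equal(key(back), key(g$edges))

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, cl, gml, format = "graphml")
  doc <- xml2::read_xml(gml)             # well-formed XML
  expect_equal(xml2::xml_name(doc), "graphml")
  nodes <- xml2::xml_find_all(doc, ".//*[local-name() = 'node']")
  edges <- xml2::xml_find_all(doc, ".//*[local-name() = 'edge']")
  expect_equal(length(nodes), nrow(fx$bank))
  expect_equal(length(edges), nrow(g$edges))
  # independent re-parse through igraph preserves attributes
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::vertex_attr(g2, "cluster"),
                  cl$cluster[match(igraph::vertex_attr(g2, "name"), cl$item_id)])

  # a two-node, one-edge graph exports exactly one data row
  mini_bank <- as_item_bank(data.frame(scale_id = c("B", "X"),
                                       item_index = "1", label = "x",
                                       description = "w"))
  mm <- matrix(c(1, .5, .5, 1), 2, dimnames = list(mini_bank$item_id, mini_bank$item_id))
  mini_sim <- structure(list(ids = mini_bank$item_id, values = mm,
                             normalization = "clip01", level = "item"),
                        class = "similarity_matrix")
  mg <- sparsify_to_backbone(mini_sim, mini_bank, "B")
  mtsv <- withr::local_tempfile(fileext = ".tsv")
  export_graph(mg, cluster_graph(mg), mtsv, format = "edge_tsv")
  expect_equal(length(readLines(mtsv)), 2L)  # header + one edge

  expect_error(export_graph(g, cl[-1, ], tsv), "cover")
})
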