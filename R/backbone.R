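#' Sparsify an item-similarity network onto a backbone scale
#'
#' Cross-scale item similarity matrices are dense and hard to read; the
#' backbone construction keeps, for every item outside a designated
#' backbone scale, only its single strongest similarity link into the
#' backbone. With `include_intra_backbone = TRUE` (the default) every
#' backbone item additionally keeps one edge to its most similar *other*
#' backbone item, so the backbone itself can form multi-item groups rather
#' than one component per backbone item. Similarity ties are broken toward
#' the earliest backbone item in bank order and flagged.
#'
#' @param sim An item-level `similarity_matrix` covering every bank item.
#' @param bank The `item_bank` the matrix was built from.
#' @param backbone_scale `scale_id` of the backbone instrument.
#' @param include_intra_backbone Add top-1 backbone-to-backbone edges.
#' @return A `backbone_graph` object: `nodes` tibble (`item_id`,
#'   `scale_id`, `label`, `is_backbone`), `edges` tibble (`source`,
#'   `target`, `weight`, `tie`), plus `backbone_scale` and
#'   `include_intra_backbone`.
#' @export
sparsify_to_backbone <- function(sim, bank, backbone_scale,
                                 include_intra_backbone = TRUE) {
  assert_flag(include_intra_backbone, "include_intra_backbone")
  if (!inherits(sim, "similarity_matrix")) abort("`sim` must be a similarity_matrix")
  if (!setequal(sim$ids, bank$item_id) || length(sim$ids) != nrow(bank)) {
    abort("similarity matrix ids do not match bank item_ids")
  }
  if (!backbone_scale %in% bank$scale_id) {
    abort(sprintf("backbone scale '%s' not present in bank", backbone_scale))
  }
  vals <- sim$values[bank$item_id, bank$item_id, drop = FALSE]
  backbone_ids <- bank$item_id[bank$scale_id == backbone_scale]
  other_ids <- bank$item_id[bank$scale_id != backbone_scale]

  top1_edge <- function(source_id, candidates) {
    w <- vals[source_id, candidates]
    best <- max(w)
    hits <- candidates[w == best]
    tibble(source = source_id, target = hits[1], weight = best,
           tie = length(hits) > 1L)
  }

  edges <- purrr::map_dfr(other_ids, top1_edge, candidates = backbone_ids)
  if (include_intra_backbone && length(backbone_ids) >= 2) {
    intra <- purrr::map_dfr(backbone_ids, function(id) {
      top1_edge(id, setdiff(backbone_ids, id))
    })
    edges <- dplyr::bind_rows(edges, intra)
  }
  nodes <- tibble(item_id = bank$item_id, scale_id = bank$scale_id,
                  label = bank$label,
                  is_backbone = bank$scale_id == backbone_scale)
  structure(
    list(nodes = nodes, edges = edges, backbone_scale = backbone_scale,
         include_intra_backbone = include_intra_backbone),
    class = "backbone_graph"
  )
}

#' @export
print.backbone_graph <- function(x, ...) {
  cat(sprintf("<backbone_graph: %d nodes, %d edges, backbone = %s%s>\n",
              nrow(x$nodes), nrow(x$edges), x$backbone_scale,
              if (x$include_intra_backbone) " (+intra-backbone top-1)" else ""))
  invisible(x)
}

as_igraph <- function(graph, clusters = NULL) {
  vertices <- as.data.frame(graph$nodes[, c("item_id", "scale_id", "label")])
  if (!is.null(clusters)) {
    vertices$cluster <- clusters$cluster[match(vertices$item_id, clusters$item_id)]
  }
  igraph::graph_from_data_frame(
    as.data.frame(graph$edges[, c("source", "target", "weight")]),
    directed = FALSE, vertices = vertices)
}

#' Extract semantic clusters from a backbone graph
#'
#' Two deterministic methods are offered. `"components"` (default) takes the
#' connected components of the undirected edge set — parameter-free, and
#' natural for the sparse backbone topology where the number of groups is
#' emergent, never forced. `"greedy_modularity"` runs greedy modularity
#' maximization on the weighted undirected graph. Cluster labels are
#' renumbered 1..K by descending cluster size, ties by smallest member
#' `item_id`.
#'
#' @param graph A `backbone_graph`.
#' @param method `"components"` or `"greedy_modularity"`.
#' @param seed Integer seed (fixed before community detection so the result
#'   is reproducible; both methods are deterministic in practice).
#' @return A `cluster_assignment` tibble (`item_id`, `cluster`) with
#'   attributes `n_clusters` and `method`.
#' @export
cluster_graph <- function(graph, method = c("components", "greedy_modularity"),
                          seed = 1L) {
  method <- match.arg(method)
  if (nrow(graph$nodes) == 0) abort("graph has no nodes")
  g <- as_igraph(graph)
  membership <- with_private_seed(derive_seed(seed, "cluster_graph"), {
    switch(method,
      components = igraph::components(g)$membership,
      greedy_modularity = igraph::membership(igraph::cluster_fast_greedy(
        igraph::simplify(g, edge.attr.comb = list(weight = "max"))))
    )
  })
  ids <- igraph::V(g)$name
  raw <- as.integer(membership)

  # relabel: descending size, ties by smallest member id
  sizes <- table(raw)
  first_member <- vapply(names(sizes), function(lab) {
    min(ids[raw == as.integer(lab)])
  }, character(1))
  ord <- order(-as.integer(sizes), first_member)
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- tibble(item_id = ids, cluster = unname(relabel[as.character(raw)]))
  out <- out[match(graph$nodes$item_id, out$item_id), ]
  structure(out, n_clusters = length(sizes), method = method,
            class = c("cluster_assignment", class(tibble())))
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("# Cluster assignment: %d items in %d cluster(s) [%s]\n",
              nrow(x), attr(x, "n_clusters"), attr(x, "method")))
  NextMethod()
}

#' Export a backbone graph (with clusters) to disk
#'
#' `"edge_tsv"` writes `source<TAB>target<TAB>weight` and round-trips
#' losslessly via [read_edge_tsv()]; `"graphml"` writes GraphML with node
#' attributes `scale_id`, `label`, `cluster` for inspection in network
#' tools.
#'
#' @param graph A `backbone_graph`.
#' @param clusters A `cluster_assignment` covering the graph's nodes.
#' @param path Output file path.
#' @param format `"edge_tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, clusters, path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  missing <- setdiff(graph$nodes$item_id, clusters$item_id)
  if (length(missing) > 0) {
    abort(sprintf("cluster assignment does not cover node(s): %s",
                  paste(missing, collapse = ", ")))
  }
  switch(format,
    edge_tsv = readr::write_tsv(graph$edges[, c("source", "target", "weight")],
                                path, progress = FALSE),
    graphml = igraph::write_graph(as_igraph(graph, clusters), path,
                                  format = "graphml")
  )
  invisible(path)
}

#' @rdname export_graph
#' @export
read_edge_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    source = readr::col_character(), target = readr::col_character(),
    weight = readr::col_double()), progress = FALSE)
}

#' Write / read a cluster assignment TSV (`item_id<TAB>cluster`)
#'
#' @param clusters A `cluster_assignment`.
#' @param path TSV file path.
#' @return `path` invisibly / a `cluster_assignment` tibble.
#' @export
write_cluster_tsv <- function(clusters, path) {
  readr::write_tsv(as_tibble(clusters), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_cluster_tsv
#' @export
read_cluster_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    item_id = readr::col_character(), cluster = readr::col_integer()),
    progress = FALSE)
  structure(out, n_clusters = length(unique(out$cluster)), method = "file",
            class = c("cluster_assignment", class(tibble())))
}

#' Plot a clustered backbone network
#'
#' Force-directed layout of the sparsified network, points colored by
#' cluster and shaped by backbone membership.
#'
#' @param object A `backbone_graph`.
#' @param clusters A `cluster_assignment` for its nodes.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.backbone_graph <- function(object, clusters, seed = 1L, ...) {
  g <- as_igraph(object, clusters)
  xy <- with_private_seed(derive_seed(seed, "graph_layout"),
                          igraph::layout_with_fr(g))
  nodes <- tibble(item_id = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
                  cluster = factor(igraph::V(g)$cluster),
                  is_backbone = object$nodes$is_backbone[
                    match(igraph::V(g)$name, object$nodes$item_id)])
  ed <- object$edges %>%
    dplyr::left_join(nodes[, c("item_id", "x", "y")], by = c(source = "item_id")) %>%
    dplyr::left_join(nodes[, c("item_id", "x", "y")], by = c(target = "item_id"),
                     suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to, yend = .data$y_to),
      color = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$cluster,
                   shape = .data$is_backbone), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 17, `FALSE` = 16),
                                name = "backbone") +
    ggplot2::labs(title = "Backbone-sparsified semantic network",
                  color = "cluster") +
    ggplot2::theme_void()
}
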