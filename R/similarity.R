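new_similarity_matrix <- function(values, ids, normalization, level) {
  dimnames(values) <- list(ids, ids)
  structure(
    list(ids = ids, values = values, normalization = normalization, level = level),
    class = "similarity_matrix"
  )
}

# cosine of all row pairs; errors on zero-norm rows, naming the offender
cosine_all_pairs <- function(mat, ids) {
  norms <- sqrt(rowSums(mat^2))
  zero <- which(norms == 0)
  if (length(zero) > 0) {
    abort(sprintf("zero-norm embedding vector for: %s",
                  paste(ids[zero], collapse = ", ")))
  }
  unit <- mat / norms
  cs <- tcrossprod(unit)
  # enforce exact symmetry and clamp numerical overshoot beyond [-1, 1]
  cs <- (cs + t(cs)) / 2
  pmin(pmax(cs, -1), 1)
}

apply_normalization <- function(cs, normalization) {
  switch(normalization,
    raw_cosine = cs,
    clip01 = pmax(cs, 0),
    affine01 = (cs + 1) / 2,
    abort(sprintf("unknown normalization '%s'", normalization))
  )
}

#' Item-level semantic similarity matrix
#'
#' Pairwise cosine similarity between item embeddings, optionally mapped to
#' the unit interval. `clip01` (the default) truncates negative cosines to 0
#' — on natural-language item descriptions cosines are almost always
#' positive, so observed values are unchanged while the stated \[0, 1\]
#' range holds; `affine01` applies the strictly monotone map
#' \eqn{(\cos + 1)/2}; `raw_cosine` leaves values in \[-1, 1\].
#'
#' @param emb Embedding matrix from [embed_texts()] / [embed_items()].
#' @param normalization `"clip01"`, `"raw_cosine"`, or `"affine01"`.
#' @return A `similarity_matrix` object: fields `ids`, `values` (square
#'   symmetric matrix), `normalization`, `level = "item"`.
#' @export
item_similarity_matrix <- function(emb, normalization = c("clip01", "raw_cosine", "affine01")) {
  normalization <- match.arg(normalization)
  if (!is.matrix(emb) || nrow(emb) < 1) abort("embedding matrix must have >= 1 row")
  ids <- rownames(emb) %||% sprintf("item%d", seq_len(nrow(emb)))
  cs <- apply_normalization(cosine_all_pairs(emb, ids), normalization)
  new_similarity_matrix(cs, ids, normalization, level = "item")
}

#' Scale-level centroid similarity matrix
#'
#' Summarizes cross-instrument semantic overlap. Off-diagonal cells hold the
#' cosine similarity between scale centroids (the mean embedding of each
#' scale's items); the diagonal holds each scale's *within-scale semantic
#' consistency* — the mean pairwise item similarity over all unordered item
#' pairs inside the scale (self-pairs excluded), so it is generally below 1.
#' A scale with a single item has an undefined consistency and gets `NA` on
#' the diagonal. The chosen `normalization` map is applied to every cosine
#' (centroid-pair and item-pair) before averaging.
#'
#' @param emb Embedding matrix with rownames matching `bank$item_id`.
#' @param bank The `item_bank` the embeddings came from.
#' @inheritParams item_similarity_matrix
#' @return A `similarity_matrix` with `level = "scale"`, ids in order of
#'   first appearance of each scale in the bank.
#' @export
scale_centroid_matrix <- function(emb, bank, normalization = c("clip01", "raw_cosine", "affine01")) {
  normalization <- match.arg(normalization)
  if (!setequal(rownames(emb), bank$item_id) || nrow(emb) != nrow(bank)) {
    abort("embedding rownames must match bank item_ids exactly")
  }
  emb <- emb[bank$item_id, , drop = FALSE]
  scales <- unique(bank$scale_id)
  groups <- split(seq_len(nrow(bank)), factor(bank$scale_id, levels = scales))
  if (any(lengths(groups) == 0)) abort("every scale must have >= 1 item")

  centroids <- do.call(rbind, lapply(groups, function(ix) {
    colMeans(emb[ix, , drop = FALSE])
  }))
  rownames(centroids) <- scales
  vals <- apply_normalization(cosine_all_pairs(centroids, scales), normalization)

  item_cos <- apply_normalization(cosine_all_pairs(emb, bank$item_id), normalization)
  diag_vals <- vapply(groups, function(ix) {
    if (length(ix) < 2) return(NA_real_)
    sub <- item_cos[ix, ix, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  diag(vals) <- diag_vals
  new_similarity_matrix(vals, scales, normalization, level = "scale")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix: %d x %d %ss, normalization = %s>\n",
              length(x$ids), length(x$ids), x$level, x$normalization))
  n <- min(6L, length(x$ids))
  print(round(x$values[seq_len(n), seq_len(n), drop = FALSE], 3))
  if (length(x$ids) > n) cat(sprintf("... %d more rows/cols\n", length(x$ids) - n))
  invisible(x)
}

#' Tidy a similarity matrix into long form
#'
#' @param x A `similarity_matrix`.
#' @param upper_only Keep only unordered pairs (i < j), dropping the
#'   diagonal; default `FALSE` returns the full square.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `similarity`.
#' @export
tidy.similarity_matrix <- function(x, upper_only = FALSE, ...) {
  long <- tibble(
    from = rep(x$ids, times = length(x$ids)),
    to = rep(x$ids, each = length(x$ids)),
    similarity = as.vector(x$values)
  )
  if (upper_only) {
    i <- rep(seq_along(x$ids), times = length(x$ids))
    j <- rep(seq_along(x$ids), each = length(x$ids))
    long <- long[i < j, ]
  }
  long
}

#' Heatmap of a similarity matrix
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  long <- tidy(object)
  long$from <- factor(long$from, levels = object$ids)
  long$to <- factor(long$to, levels = rev(object$ids))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$from, y = .data$to,
                                     fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = if (object$normalization == "raw_cosine") c(-1, 1) else c(0, 1),
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity",
                  title = sprintf("%s-level semantic similarity", object$level)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Write / read a similarity matrix as TSV
#'
#' TSV layout: first column `id`, remaining columns one per identifier.
#'
#' @param sim A `similarity_matrix`.
#' @param path TSV file path.
#' @return `write_similarity_tsv()` returns `path` invisibly;
#'   `read_similarity_tsv()` returns a `similarity_matrix`.
#' @param normalization,level Metadata restored on read (not stored in the
#'   TSV itself).
#' @export
write_similarity_tsv <- function(sim, path) {
  df <- as.data.frame(sim$values)
  df <- cbind(id = sim$ids, df)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path, normalization = "clip01", level = "item") {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(df$id)
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(vals), ids)) abort("similarity TSV is not square with matching ids")
  storage.mode(vals) <- "double"
  new_similarity_matrix(vals, ids, normalization, level)
}
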