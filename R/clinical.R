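#' Ratings-matrix tibble
#'
#' Participant ratings for one scale are kept as a tibble with columns
#' `participant_id`, optional `group` (`"patient"` / `"control"`), and one
#' ordinal-score column per item (named by `item_id`). [as_ratings_matrix()]
#' validates the shape: nonnegative integer scores, no missing cells
#' (missingness must be resolved upstream).
#'
#' @param df Data frame in the layout above.
#' @return A validated `ratings_matrix` tibble.
#' @export
as_ratings_matrix <- function(df) {
  if (!"participant_id" %in% names(df)) {
    abort("ratings matrix needs a participant_id column")
  }
  meta <- intersect(c("participant_id", "group"), names(df))
  item_cols <- setdiff(names(df), meta)
  if (length(item_cols) == 0) abort("ratings matrix has no item columns")
  scores <- as.matrix(df[, item_cols, drop = FALSE])
  if (any(is.na(scores))) abort("ratings contain missing cells; resolve missingness upstream")
  if (any(scores < 0) || any(scores != round(scores))) {
    abort("scores must be nonnegative integers")
  }
  out <- as_tibble(df)
  class(out) <- c("ratings_matrix", class(tibble()))
  out
}

ratings_item_cols <- function(ratings) {
  setdiff(names(ratings), c("participant_id", "group"))
}

#' Read a ratings CSV (`participant_id,group,<item_id columns...>`)
#'
#' @param path CSV file path.
#' @return A `ratings_matrix` tibble.
#' @export
load_ratings_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("ratings file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_ratings_matrix(df)
}

#' Drop items that cannot enter a correlation analysis
#'
#' Items on which no participant scored above zero carry no signal and are
#' removed (as in clinical practice some rare symptoms are simply never
#' observed in a sample); any remaining constant (zero-variance but
#' nonzero) columns are removed too, flagged separately, since a
#' correlation with them is undefined.
#'
#' @param ratings A `ratings_matrix` tibble.
#' @return A list: `ratings` (filtered), `excluded` — a tibble `item_id`,
#'   `reason` (`"all_zero"` or `"constant"`).
#' @export
exclude_degenerate_items <- function(ratings) {
  items <- ratings_item_cols(ratings)
  scores <- as.matrix(ratings[, items, drop = FALSE])
  all_zero <- items[colSums(scores != 0) == 0]
  constant <- setdiff(items[apply(scores, 2, function(x) length(unique(x)) == 1L)],
                      all_zero)
  excluded <- dplyr::bind_rows(
    tibble(item_id = all_zero, reason = "all_zero"),
    tibble(item_id = constant, reason = "constant")
  )
  keep <- setdiff(items, excluded$item_id)
  if (length(keep) == 0) abort("all items are degenerate; nothing left to analyse")
  out <- ratings[, c(intersect(c("participant_id", "group"), names(ratings)), keep)]
  class(out) <- class(ratings)
  list(ratings = out, excluded = excluded)
}

#' Pair backbone items with their strongest cross-scale correlate
#'
#' For every item of the backbone scale, finds the partner-scale item with
#' the maximal (signed, not absolute — the aim is phenomena that co-occur)
#' correlation across participants. Both matrices must carry the same
#' participants in the same order and should already be filtered with
#' [exclude_degenerate_items()]. Ties go to the earliest partner column and
#' are flagged.
#'
#' @param backbone_ratings,partner_ratings `ratings_matrix` tibbles for the
#'   two instruments.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A tibble: `backbone_item`, `partner_item`, `correlation`, `tie`.
#' @export
top_correlate_pairing <- function(backbone_ratings, partner_ratings,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(as.character(backbone_ratings$participant_id),
                 as.character(partner_ratings$participant_id))) {
    abort("participant ids/order differ between the two ratings matrices")
  }
  b_items <- ratings_item_cols(backbone_ratings)
  p_items <- ratings_item_cols(partner_ratings)
  B <- as.matrix(backbone_ratings[, b_items, drop = FALSE])
  P <- as.matrix(partner_ratings[, p_items, drop = FALSE])
  R <- stats::cor(B, P, method = method)
  purrr::map_dfr(seq_along(b_items), function(i) {
    r <- R[i, ]
    best <- max(r)
    hits <- p_items[r == best]
    tibble(backbone_item = b_items[i], partner_item = hits[1],
           correlation = best, tie = length(hits) > 1L)
  })
}

#' Exact one-sided binomial upper-tail probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim \mathrm{Binomial}(n, p_0)}, accumulated
#' stably in log space term by term.
#'
#' @param k Number of successes observed (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Null success probability, in (0, 1).
#' @return The upper-tail probability, a scalar in (0, 1].
#' @export
#' @examples
#' exact_binomial_upper_tail(11, 17, 0.25)
exact_binomial_upper_tail <- function(k, n, p0) {
  if (length(k) != 1L || length(n) != 1L || k != round(k) || n != round(n)) {
    abort("k and n must be single integers")
  }
  if (n < 0 || k < 0 || k > n) abort("need 0 <= k <= n")
  assert_prob(p0, "p0", open = TRUE)
  if (k == 0) return(1)
  j <- k:n
  log_terms <- lchoose(n, j) + j * log(p0) + (n - j) * log1p(-p0)
  # log-sum-exp over the tail terms
  mx <- max(log_terms)
  min(1, exp(mx + log(sum(exp(log_terms - mx)))))
}

#' Test whether correlational pairs co-occur in semantic clusters
#'
#' Given cross-scale item pairs (from [top_correlate_pairing()]) and a
#' semantic `cluster_assignment`, counts the pairs whose two items share a
#' cluster label and tests that count against chance with an exact
#' one-sided binomial test, \eqn{P(X \ge n_{cocluster})},
#' \eqn{X \sim \mathrm{Binomial}(n_{pairs}, p_0)}. The default chance level
#' is the flat \eqn{1/K} for K clusters (25\% for four);
#' `chance = "weighted"` instead uses \eqn{\sum_c w_c^2} with \eqn{w_c} the
#' cluster share of items, a null that accounts for unequal cluster sizes.
#'
#' @param pairs Tibble with columns `backbone_item`, `partner_item` (and
#'   optionally `correlation`).
#' @param clusters A `cluster_assignment` covering every paired item.
#' @param chance `"flat"`, `"weighted"`, or a numeric chance level in
#'   (0, 1).
#' @return An `alignment_result`: `pairs` (with `cocluster` flag columns),
#'   `n_pairs`, `n_cocluster`, `chance_level`, `p_value`. Use [glance()]
#'   for a one-row tibble.
#' @export
cocluster_test <- function(pairs, clusters, chance = "flat") {
  lab <- stats::setNames(clusters$cluster, clusters$item_id)
  used <- unique(c(pairs$backbone_item, pairs$partner_item))
  missing <- setdiff(used, names(lab))
  if (length(missing) > 0) {
    abort(sprintf("item(s) missing from clustering: %s",
                  paste(missing, collapse = ", ")))
  }
  k_clusters <- length(unique(clusters$cluster))
  chance_level <- if (is.numeric(chance)) {
    assert_prob(chance, "chance", open = TRUE)
    chance
  } else if (identical(chance, "flat")) {
    1 / k_clusters
  } else if (identical(chance, "weighted")) {
    w <- table(clusters$cluster) / nrow(clusters)
    sum(w^2)
  } else {
    abort("`chance` must be 'flat', 'weighted', or a number in (0, 1)")
  }
  annotated <- pairs %>%
    dplyr::mutate(
      backbone_cluster = unname(lab[.data$backbone_item]),
      partner_cluster = unname(lab[.data$partner_item]),
      cocluster = .data$backbone_cluster == .data$partner_cluster
    )
  n_pairs <- nrow(annotated)
  n_cocluster <- sum(annotated$cocluster)
  structure(
    list(pairs = annotated, n_pairs = n_pairs, n_cocluster = n_cocluster,
         chance_level = chance_level,
         p_value = exact_binomial_upper_tail(n_cocluster, n_pairs, chance_level)),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "Co-clustering of strongest cross-scale correlates: %d of %d pairs (%.1f%%)\n",
    x$n_cocluster, x$n_pairs, 100 * x$n_cocluster / max(1, x$n_pairs)))
  cat(sprintf("Chance level %.3f; exact binomial P(X >= %d) = %.4g\n",
              x$chance_level, x$n_cocluster, x$p_value))
  invisible(x)
}

#' @export
glance.alignment_result <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, n_cocluster = x$n_cocluster,
         proportion = x$n_cocluster / max(1, x$n_pairs),
         chance_level = x$chance_level, p_value = x$p_value)
}

#' @export
tidy.alignment_result <- function(x, ...) {
  x$pairs
}

#' Run the clinical-alignment stage end to end
#'
#' Filters degenerate items from both ratings matrices, pairs each backbone
#' item with its strongest partner correlate, and runs the co-cluster
#' binomial test. Excluded items are removed from pairing candidacy as well
#' as from the backbone side.
#'
#' @inheritParams top_correlate_pairing
#' @inheritParams cocluster_test
#' @param group Optional group filter (`"patient"` / `"control"`); default
#'   pools all participants.
#' @return An `alignment_result` with an extra `excluded` field listing the
#'   dropped items of both scales.
#' @export
clinical_alignment <- function(backbone_ratings, partner_ratings, clusters,
                               method = c("pearson", "spearman"),
                               chance = "flat", group = NULL) {
  method <- match.arg(method)
  if (!is.null(group)) {
    if (!"group" %in% names(backbone_ratings)) abort("no group column to filter on")
    keep <- backbone_ratings$group == group
    backbone_ratings <- backbone_ratings[keep, ]
    partner_ratings <- partner_ratings[keep, ]
  }
  fb <- exclude_degenerate_items(backbone_ratings)
  fp <- exclude_degenerate_items(partner_ratings)
  pairs <- top_correlate_pairing(fb$ratings, fp$ratings, method = method)
  out <- cocluster_test(pairs, clusters, chance = chance)
  out$excluded <- dplyr::bind_rows(fb$excluded, fp$excluded)
  out
}
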