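#' Map machine cluster labels onto an expert category set
#'
#' Cluster ids are arbitrary (numbered by cluster size), while expert
#' categories are meaningful labels; before the machine clustering can be
#' folded into an agreement analysis the two label spaces must be aligned.
#' Each cluster is mapped to the expert category most frequently assigned
#' to its items (majority mapping; ties broken toward the
#' lexicographically first category and flagged by a warning). Distinct
#' clusters may map to the same category when there are more clusters than
#' categories.
#'
#' @param machine A `cluster_assignment`.
#' @param expert_table Long tibble (`item_id`, `rater_id`, `category`).
#' @return A tibble `item_id`, `category` with the machine's mapped labels.
#' @export
map_machine_to_categories <- function(machine, expert_table) {
  tab <- tibble(item_id = as.character(expert_table$item_id),
                category = as.character(expert_table$category))
  mapping <- vapply(sort(unique(machine$cluster)), function(cl) {
    ids <- machine$item_id[machine$cluster == cl]
    votes <- sort(table(tab$category[tab$item_id %in% ids]), decreasing = TRUE)
    if (length(votes) == 0) return(as.character(cl))
    if (length(votes) > 1 && votes[1] == votes[2]) {
      warn(sprintf("cluster %s maps ambiguously; choosing category '%s'",
                   cl, names(votes)[1]))
    }
    names(votes)[1]
  }, character(1))
  names(mapping) <- as.character(sort(unique(machine$cluster)))
  tibble(item_id = as.character(machine$item_id),
         category = unname(mapping[as.character(machine$cluster)]))
}

#' Build an item-by-category assignment count matrix
#'
#' Tallies how many raters placed each item in each category — the input to
#' multi-rater Fleiss' kappa. The machine clustering can be folded in as an
#' additional pseudo-rater, giving the pooled human+machine agreement view;
#' the per-item human-versus-machine view is provided separately by
#' [disagreement_ranking()].
#'
#' @param expert_table Long tibble with columns `item_id`, `rater_id`,
#'   `category` — one row per (item, rater). Every rater must rate every
#'   item exactly once.
#' @param machine Optional `cluster_assignment`; its labels are coerced to
#'   character and folded in as rater `".machine"`.
#' @return An `assignment_matrix` object: `counts` (N x k integer matrix,
#'   rows = items, columns = categories), `items`, `raters`, `categories`,
#'   `n_raters`.
#' @export
build_assignment_matrix <- function(expert_table, machine = NULL) {
  required <- c("item_id", "rater_id", "category")
  missing <- setdiff(required, names(expert_table))
  if (length(missing) > 0) {
    abort(sprintf("expert table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  tab <- tibble(item_id = as.character(expert_table$item_id),
                rater_id = as.character(expert_table$rater_id),
                category = as.character(expert_table$category))
  if (any(is.na(tab$category) | !nzchar(tab$category))) {
    bad <- tab[is.na(tab$category) | !nzchar(tab$category), ]
    abort(sprintf("missing rating for item %s by rater %s",
                  bad$item_id[1], bad$rater_id[1]))
  }
  if (!is.null(machine)) {
    mapped <- map_machine_to_categories(machine, tab)
    tab <- dplyr::bind_rows(tab, tibble(
      item_id = mapped$item_id,
      rater_id = ".machine",
      category = mapped$category))
  }
  items <- unique(tab$item_id)
  raters <- unique(tab$rater_id)
  # every rater must rate every item exactly once
  cell_n <- table(factor(tab$item_id, levels = items),
                  factor(tab$rater_id, levels = raters))
  if (any(cell_n != 1L)) {
    miss <- which(cell_n != 1L, arr.ind = TRUE)[1, ]
    abort(sprintf("item %s has %d rating(s) from rater %s (expected exactly 1)",
                  items[miss[1]], cell_n[miss[1], miss[2]], raters[miss[2]]))
  }
  categories <- sort(unique(tab$category))
  counts <- unclass(as.matrix(table(factor(tab$item_id, levels = items),
                                    factor(tab$category, levels = categories))))
  names(dimnames(counts)) <- NULL
  if (length(categories) < 2) abort("at least 2 categories are required")
  if (length(raters) < 2) abort("at least 2 raters are required")
  structure(
    list(counts = counts, items = items, raters = raters,
         categories = categories, n_raters = length(raters)),
    class = "assignment_matrix"
  )
}

#' Construct an assignment matrix directly from counts
#'
#' For worked examples and simulation: rows are items, columns categories,
#' each row summing to the common number of raters.
#'
#' @param counts Integer matrix N x k, row sums all equal.
#' @param items,categories Optional identifiers.
#' @return An `assignment_matrix`.
#' @export
as_assignment_matrix <- function(counts, items = NULL, categories = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be nonnegative integers")
  }
  m <- unique(rowSums(counts))
  if (length(m) != 1L) abort("every row must sum to the same number of raters")
  if (m < 2) abort("at least 2 raters are required")
  if (ncol(counts) < 2) abort("at least 2 categories are required")
  items <- items %||% rownames(counts) %||% sprintf("item%d", seq_len(nrow(counts)))
  categories <- categories %||% colnames(counts) %||% as.character(seq_len(ncol(counts)))
  dimnames(counts) <- NULL
  structure(
    list(counts = counts, items = items,
         raters = sprintf("rater%d", seq_len(m)),
         categories = as.character(categories), n_raters = as.integer(m)),
    class = "assignment_matrix"
  )
}

#' @export
print.assignment_matrix <- function(x, ...) {
  cat(sprintf("<assignment_matrix: %d items x %d categories, %d raters>\n",
              nrow(x$counts), ncol(x$counts), x$n_raters))
  invisible(x)
}

new_agreement_result <- function(scope, kappa, se, level, n_items, n_raters,
                                 n_categories) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble(scope = scope, kappa = kappa, se = se,
         ci_low = kappa - z * se, ci_high = kappa + z * se,
         level = level, n_items = n_items, n_raters = n_raters,
         n_categories = n_categories) %>%
    structure(class = c("agreement_result", class(tibble())))
}

#' Fleiss' kappa for multi-rater nominal agreement
#'
#' Chance-corrected agreement among `m` raters assigning `N` items to `k`
#' nominal categories. With \eqn{n_{ij}} raters placing item *i* in
#' category *j*:
#' \deqn{P_i = \frac{\sum_j n_{ij}^2 - m}{m(m-1)}, \quad
#'       \bar P = \frac{1}{N}\sum_i P_i, \quad
#'       p_j = \frac{\sum_i n_{ij}}{Nm}, \quad
#'       \bar P_e = \sum_j p_j^2, \quad
#'       \kappa = \frac{\bar P - \bar P_e}{1 - \bar P_e}.}
#' The standard error is the classic large-sample null-variance form
#' (Fleiss, Nee & Landis), and the confidence interval is the asymptotic
#' normal interval \eqn{\kappa \pm z \cdot SE}.
#'
#' @param matrix An `assignment_matrix`.
#' @param level Confidence level (default 0.95).
#' @return An `agreement_result` tibble (one row, `scope = "overall"`):
#'   `kappa`, `se`, `ci_low`, `ci_high`, `level`, `n_items`, `n_raters`,
#'   `n_categories`.
#' @export
fleiss_kappa <- function(matrix, level = 0.95) {
  assert_prob(level, "level", open = TRUE)
  n <- matrix$counts
  m <- matrix$n_raters
  N <- nrow(n)
  P_i <- (rowSums(n^2) - m) / (m * (m - 1))
  P_bar <- mean(P_i)
  p_j <- colSums(n) / (N * m)
  P_e <- sum(p_j^2)
  if (1 - P_e < .Machine$double.eps) {
    abort("kappa undefined: all ratings fall in a single category (expected agreement = 1)")
  }
  kappa <- (P_bar - P_e) / (1 - P_e)
  q_j <- 1 - p_j
  spq <- sum(p_j * q_j)
  se <- sqrt(2 / (N * m * (m - 1))) *
    sqrt(spq^2 - sum(p_j * q_j * (q_j - p_j))) / spq
  new_agreement_result("overall", kappa, se, level, N, m, ncol(n))
}

#' Per-category Fleiss' kappa
#'
#' Decomposes multi-rater agreement by category:
#' \deqn{\kappa_j = 1 - \frac{\sum_i n_{ij}(m - n_{ij})}{N m (m-1) p_j (1-p_j)}}
#' with the large-sample null standard error
#' \eqn{\sqrt{2 / (N m (m-1))}}. A category used by every rating or by none
#' (\eqn{p_j \in \{0, 1\}}) has undefined kappa.
#'
#' @param matrix An `assignment_matrix`.
#' @param category A category label (or `NULL` for all categories).
#' @param level Confidence level.
#' @return An `agreement_result` tibble, one row per requested category.
#' @export
category_kappa <- function(matrix, category = NULL, level = 0.95) {
  assert_prob(level, "level", open = TRUE)
  cats <- category %||% matrix$categories
  unknown <- setdiff(as.character(cats), matrix$categories)
  if (length(unknown) > 0) {
    abort(sprintf("unknown category: %s", paste(unknown, collapse = ", ")))
  }
  n <- matrix$counts
  m <- matrix$n_raters
  N <- nrow(n)
  rows <- lapply(as.character(cats), function(cat) {
    j <- match(cat, matrix$categories)
    p_j <- sum(n[, j]) / (N * m)
    if (p_j <= 0 || p_j >= 1) {
      abort(sprintf("kappa undefined for category '%s': marginal proportion is %g", cat, p_j))
    }
    kappa_j <- 1 - sum(n[, j] * (m - n[, j])) / (N * m * (m - 1) * p_j * (1 - p_j))
    se_j <- sqrt(2 / (N * m * (m - 1)))
    new_agreement_result(cat, kappa_j, se_j, level, N, m, ncol(n))
  })
  dplyr::bind_rows(rows) %>%
    structure(class = c("agreement_result", class(tibble())))
}

#' Overall plus per-category agreement in one table
#'
#' Convenience wrapper computing [fleiss_kappa()] and [category_kappa()]
#' for every category, stacked into a single `agreement_result` tibble
#' (the layout of a typical agreement summary table).
#'
#' @inheritParams fleiss_kappa
#' @return An `agreement_result` tibble: one `"overall"` row followed by
#'   one row per category.
#' @export
agreement_table <- function(matrix, level = 0.95) {
  out <- dplyr::bind_rows(fleiss_kappa(matrix, level = level),
                          category_kappa(matrix, level = level))
  structure(out, class = c("agreement_result", class(tibble())))
}

#' @export
glance.agreement_result <- function(x, ...) {
  as_tibble(x)[, c("scope", "kappa", "se", "ci_low", "ci_high")]
}

#' Forest-style plot of agreement results
#'
#' @param object An `agreement_result` (rows from [fleiss_kappa()] and/or
#'   [category_kappa()], e.g. bound with `dplyr::bind_rows()`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_result <- function(object, ...) {
  df <- as_tibble(object)
  df$scope <- factor(df$scope, levels = rev(unique(df$scope)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kappa, y = .data$scope)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey50") +
    ggplot2::labs(x = "Fleiss' kappa (asymptotic CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Rank items by human-machine agreement
#'
#' For each item, the share of (human) raters whose category matches the
#' machine cluster label; sorted descending, ties broken by `item_id`. The
#' head of the ranking lists the most consensually machine-classified
#' items, the tail the most contested ones.
#'
#' @param expert_table Long tibble (`item_id`, `rater_id`, `category`) of
#'   human ratings only.
#' @param machine A `cluster_assignment` covering every rated item; its
#'   cluster ids are aligned to the expert category set with
#'   [map_machine_to_categories()] first.
#' @return A tibble: `item_id`, `machine_category`, `n_agree`, `n_raters`,
#'   `fraction_agree`, ordered best-to-worst.
#' @export
disagreement_ranking <- function(expert_table, machine) {
  mapped <- map_machine_to_categories(machine, expert_table)
  mach <- stats::setNames(mapped$category, mapped$item_id)
  items <- unique(as.character(expert_table$item_id))
  missing <- setdiff(items, names(mach))
  if (length(missing) > 0) {
    abort(sprintf("machine clustering does not cover item(s): %s",
                  paste(missing, collapse = ", ")))
  }
  expert_table %>%
    dplyr::mutate(item_id = as.character(.data$item_id),
                  category = as.character(.data$category)) %>%
    dplyr::group_by(.data$item_id) %>%
    dplyr::summarise(
      machine_category = mach[[unique(.data$item_id)]],
      n_agree = sum(.data$category == mach[[unique(.data$item_id)]]),
      n_raters = dplyr::n(),
      .groups = "drop"
    ) %>%
    dplyr::mutate(fraction_agree = .data$n_agree / .data$n_raters) %>%
    dplyr::arrange(dplyr::desc(.data$fraction_agree), .data$item_id)
}
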