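#' Classify items against construct descriptions
#'
#' Assigns each item to the construct whose description it is semantically
#' closest to — the validation step that splits, for example, the items of
#' an exhaustive formal-thought-disorder scale into the classical positive
#' (excess, disordered production) and negative (impoverished production)
#' poles. Item `clean_text` and raw construct paragraphs are embedded with
#' the same backend; each item takes the argmax-similarity construct. Exact
#' ties go to the construct listed first and are flagged.
#'
#' @param bank An `item_bank` tibble (or a subset of its rows).
#' @param constructs A tibble from [construct_descriptions()] with at least
#'   two rows.
#' @param backend An `embedding_backend`.
#' @param normalization Cosine normalization (see
#'   [item_similarity_matrix()]); the argmax is invariant to the choice for
#'   the monotone maps offered.
#' @return A `polarity_assignment` tibble: `item_id`, one `sim_<construct>`
#'   column per construct, `assigned`, `margin` (top minus runner-up
#'   similarity, >= 0), `tie`.
#' @export
classify_by_construct <- function(bank, constructs, backend,
                                  normalization = c("clip01", "raw_cosine", "affine01")) {
  normalization <- match.arg(normalization)
  if (!is.data.frame(constructs) || nrow(constructs) < 2) {
    abort("at least 2 construct descriptions are required")
  }
  if (anyDuplicated(constructs$construct_id)) {
    abort("construct_id values must be pairwise distinct")
  }
  item_emb <- embed_items(bank, backend)
  cons_emb <- embed_texts(constructs$text, backend, ids = constructs$construct_id)

  all_emb <- rbind(item_emb, cons_emb)
  cs <- cosine_all_pairs(all_emb, rownames(all_emb))
  sims <- apply_normalization(
    cs[bank$item_id, constructs$construct_id, drop = FALSE], normalization)

  pick <- apply(sims, 1L, which.max)       # ties resolve to the first listed
  top <- sims[cbind(seq_len(nrow(sims)), pick)]
  runner <- vapply(seq_len(nrow(sims)), function(i) {
    max(sims[i, -pick[i]])
  }, numeric(1))
  tie <- vapply(seq_len(nrow(sims)), function(i) {
    sum(sims[i, ] == top[i]) > 1L
  }, logical(1))

  out <- tibble(item_id = bank$item_id)
  for (j in seq_len(ncol(sims))) {
    out[[paste0("sim_", constructs$construct_id[j])]] <- unname(sims[, j])
  }
  out$assigned <- constructs$construct_id[pick]
  out$margin <- unname(top - runner)
  out$tie <- tie
  class(out) <- c("polarity_assignment", class(tibble()))
  out
}

#' Pearson chi-square test for a 2x2 contingency table
#'
#' Closed-form Pearson statistic
#' \eqn{\chi^2 = N(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))} with 1 degree of
#' freedom; with Yates continuity correction, \eqn{|ad-bc|} is replaced by
#' \eqn{\max(0, |ad-bc| - N/2)} before squaring. A zero row or column margin
#' leaves the statistic undefined and is an error.
#'
#' @param tbl A 2x2 numeric matrix (or object coercible to one) of
#'   nonnegative counts.
#' @param continuity_correction Apply the Yates correction (default off).
#' @return A one-row tibble: `statistic`, `df` (always 1), `p_value`.
#' @export
#' @examples
#' chi2_2x2(matrix(c(10, 5, 3, 12), 2, byrow = TRUE))
chi2_2x2 <- function(tbl, continuity_correction = FALSE) {
  assert_flag(continuity_correction, "continuity_correction")
  tbl <- as.matrix(tbl)
  if (!all(dim(tbl) == c(2L, 2L))) abort("`tbl` must be a 2x2 table")
  if (any(is.na(tbl)) || any(tbl < 0)) abort("cell counts must be nonnegative")
  a <- tbl[1, 1]; b <- tbl[1, 2]; c <- tbl[2, 1]; d <- tbl[2, 2]
  N <- a + b + c + d
  if (N < 1) abort("table total must be >= 1")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) abort("chi-square statistic undefined: zero row or column margin")
  delta <- abs(a * d - b * c)
  if (continuity_correction) delta <- max(0, delta - N / 2)
  chi2 <- N * delta^2 / prod(margins)
  tibble(statistic = chi2, df = 1L,
         p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Compare machine construct assignments with a reference classification
#'
#' Cross-tabulates the similarity-based assignments against an external
#' reference (e.g. a published factor-analytic item grouping), reporting
#' raw accuracy and the Pearson chi-square association for the 2x2 case.
#'
#' @param assignments A `polarity_assignment` tibble from
#'   [classify_by_construct()].
#' @param reference Named character vector or two-column data frame
#'   (`item_id`, `construct_id`) giving the reference construct of every
#'   assigned item.
#' @param continuity_correction Passed to [chi2_2x2()] (2-construct case).
#' @return A `polarity_comparison` object with fields `n_items`, `n_match`,
#'   `accuracy`, `contingency` (machine x reference count matrix), and —
#'   when both classifications are binary — `statistic`, `df`, `p_value`.
#'   Use [glance()] for a one-row tibble summary.
#' @export
compare_to_reference <- function(assignments, reference,
                                 continuity_correction = FALSE) {
  if (is.data.frame(reference)) {
    ref <- stats::setNames(as.character(reference$construct_id),
                           as.character(reference$item_id))
  } else {
    ref <- reference
  }
  missing <- setdiff(assignments$item_id, names(ref))
  if (length(missing) > 0) {
    abort(sprintf("item(s) missing from reference classification: %s",
                  paste(missing, collapse = ", ")))
  }
  machine <- assignments$assigned
  refv <- unname(ref[assignments$item_id])
  n_items <- length(machine)
  n_match <- sum(machine == refv)
  levels_all <- union(unique(machine), unique(refv))
  contingency <- table(factor(machine, levels = levels_all),
                       factor(refv, levels = levels_all))
  contingency <- unclass(as.matrix(contingency))
  names(dimnames(contingency)) <- c("machine", "reference")

  out <- list(n_items = n_items, n_match = n_match,
              accuracy = n_match / n_items, contingency = contingency,
              statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
  if (length(levels_all) == 2L) {
    ch <- chi2_2x2(contingency, continuity_correction = continuity_correction)
    out$statistic <- ch$statistic
    out$df <- ch$df
    out$p_value <- ch$p_value
  }
  structure(out, class = "polarity_comparison")
}

#' @export
print.polarity_comparison <- function(x, ...) {
  cat(sprintf("Machine vs reference classification: %d/%d matched (accuracy %.1f%%)\n",
              x$n_match, x$n_items, 100 * x$accuracy))
  if (!is.na(x$statistic)) {
    cat(sprintf("Association: chi-square(%d, N = %d) = %.3f, p = %.4g\n",
                x$df, x$n_items, x$statistic, x$p_value))
  }
  print(x$contingency)
  invisible(x)
}

#' @export
glance.polarity_comparison <- function(x, ...) {
  tibble(n_items = x$n_items, n_match = x$n_match, accuracy = x$accuracy,
         statistic = x$statistic, df = x$df, p_value = x$p_value)
}

#' @export
tidy.polarity_comparison <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$contingency), responseName = "n"))
}
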