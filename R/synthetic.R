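#' Configuration for the synthetic-data generator
#'
#' The generator emulates the study design end to end with known ground
#' truth: an item bank of themed symptom descriptions across several
#' scales, noisy expert category assignments, and ordinal participant
#' ratings driven by a per-theme latent severity. Defaults mirror the
#' studied corpus: 7 scales with 103 items total, 4 semantic themes, 6
#' expert raters, ordinal scores 0–4, and a patient/control split of a
#' 98-participant sample with heavier zero-inflation for controls (so
#' patients score higher on average).
#'
#' @param n_themes Number of latent semantic themes (clusters).
#' @param scales Tibble `scale_id`, `n_items` — items per scale; themes are
#'   assigned round-robin within each scale so every scale spans themes.
#' @param w Mixing weight in \[0, 1\]: the share of each item text drawn
#'   from its theme's core vocabulary (the rest is shared filler). Controls
#'   between-theme separation monotonically; `w = 0` makes themes
#'   unrecoverable.
#' @param text_length Tokens per item description: either a single length
#'   or a range `c(min, max)` from which each item's length is drawn
#'   uniformly. The default wide range mirrors the strong length
#'   heterogeneity of real instruments, where one scale's items are terse
#'   labels and another's are paragraph-length definitions; the resulting
#'   "prototypical" long items anchor the within-theme similarity
#'   structure the way detailed definitions do in real corpora.
#' @param core_vocab_size,filler_vocab_size Vocabulary sizes (core
#'   vocabularies are pairwise disjoint across themes).
#' @param expert_fidelity Probability a rater assigns an item its true
#'   theme; otherwise the rater picks uniformly among all `n_themes`
#'   categories (including the truth), so the effective correct probability
#'   is `a + (1 - a)/k`.
#' @param n_raters Number of simulated expert raters.
#' @param lambda Loading of item scores on the participant's per-theme
#'   latent severity (standard normal).
#' @param sigma Item-level Gaussian noise standard deviation.
#' @param ordinal_levels Number of score levels (scores run `0 ..
#'   ordinal_levels - 1`); discretization uses equal-probability cut points
#'   of the marginal latent distribution.
#' @param zero_inflation Named numeric `c(patient = , control = )`: the
#'   probability a score is forced to 0 after discretization, per group.
#' @param n_participants Total participants (split evenly
#'   patient/control).
#' @param planted_zero_items Character vector of `item_id`s whose ratings
#'   are forced to all-zero (for testing degenerate-item exclusion).
#' @param seed Master seed; all generator outputs are fully determined by
#'   the configuration plus this seed.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_themes = 4L,
                             scales = default_scales(),
                             w = 0.8,
                             text_length = c(6L, 150L),
                             core_vocab_size = 30L,
                             filler_vocab_size = 80L,
                             expert_fidelity = 0.9,
                             n_raters = 6L,
                             lambda = 0.8,
                             sigma = 0.5,
                             ordinal_levels = 5L,
                             zero_inflation = c(patient = 0.15, control = 0.30),
                             n_participants = 98L,
                             planted_zero_items = character(),
                             seed = 1L) {
  assert_prob(w, "w")
  assert_prob(expert_fidelity, "expert_fidelity")
  assert_prob(unname(zero_inflation["patient"]), "zero_inflation['patient']")
  assert_prob(unname(zero_inflation["control"]), "zero_inflation['control']")
  if (length(text_length) == 1L) text_length <- rep(text_length, 2L)
  if (length(text_length) != 2L || any(text_length < 1) ||
      text_length[1] > text_length[2]) {
    abort("`text_length` must be a positive length or a c(min, max) range")
  }
  stopifnot(n_themes >= 2, n_raters >= 2,
            ordinal_levels >= 2, n_participants >= 4, sigma >= 0, lambda >= 0)
  if (!is.data.frame(scales) || !all(c("scale_id", "n_items") %in% names(scales))) {
    abort("`scales` must be a data frame with columns scale_id, n_items")
  }
  structure(
    list(n_themes = as.integer(n_themes), scales = as_tibble(scales),
         w = w, text_length = as.integer(text_length),
         core_vocab_size = as.integer(core_vocab_size),
         filler_vocab_size = as.integer(filler_vocab_size),
         expert_fidelity = expert_fidelity, n_raters = as.integer(n_raters),
         lambda = lambda, sigma = sigma,
         ordinal_levels = as.integer(ordinal_levels),
         zero_inflation = zero_inflation,
         n_participants = as.integer(n_participants),
         planted_zero_items = planted_zero_items,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' @rdname generator_config
#' @export
default_scales <- function() {
  tibble(
    scale_id = c("TALD", "TLC", "CLANG", "SAPS-SANS", "BIT", "TLI", "PANSS"),
    n_items = c(30L, 20L, 17L, 13L, 11L, 8L, 4L)
  )
}

theme_core_vocab <- function(theme, size) {
  sprintf("theme%d_term%02d", theme, seq_len(size))
}

#' Generate a synthetic item bank with known theme structure
#'
#' Each item's description is `L` tokens (`L` drawn uniformly from the
#' configured `text_length` range): `ceiling(w * L)` sampled (with
#' replacement) from its theme's core vocabulary and the rest from a
#' filler vocabulary shared across themes. Core vocabularies are pairwise
#' disjoint, so `w` directly controls how separable the themes are to any
#' bag-of-tokens embedding, and the length spread produces prototypical
#' long items that anchor each theme.
#'
#' @param config A [generator_config()].
#' @return A list: `bank` (an `item_bank`) and `truth` (tibble `item_id`,
#'   `theme`).
#' @export
generate_item_bank <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$core_vocab_size < 1 || config$filler_vocab_size < 1) {
    abort("vocabularies must be nonempty")
  }
  filler <- sprintf("filler_term%02d", seq_len(config$filler_vocab_size))

  rows <- with_private_seed(derive_seed(config$seed, "item_bank"), {
    purrr::pmap_dfr(config$scales, function(scale_id, n_items) {
      purrr::map_dfr(seq_len(n_items), function(i) {
        theme <- ((i - 1L) %% config$n_themes) + 1L
        core <- theme_core_vocab(theme, config$core_vocab_size)
        L <- sample(seq(config$text_length[1], config$text_length[2]), 1L)
        n_core <- ceiling(config$w * L)
        n_fill <- L - n_core
        tokens <- c(
          if (n_core > 0) sample(core, n_core, replace = TRUE),
          if (n_fill > 0) sample(filler, n_fill, replace = TRUE)
        )
        tibble(scale_id = scale_id, item_index = as.character(i),
               label = sprintf("Synthetic symptom %s-%d", scale_id, i),
               description = paste(sample(tokens), collapse = " "),
               theme = theme)
      })
    })
  })
  bank <- as_item_bank(rows[, c("scale_id", "item_index", "label", "description")])
  truth <- tibble(item_id = bank$item_id, theme = rows$theme)
  list(bank = bank, truth = truth)
}

#' Generate noisy expert assignments from a ground-truth partition
#'
#' Each rater labels each item with its true theme with probability
#' `fidelity`; otherwise the label is uniform over all `k` categories
#' (including the truth), so the effective per-rating accuracy is
#' `fidelity + (1 - fidelity)/k`.
#'
#' @param truth Tibble `item_id`, `theme`.
#' @param fidelity Per-rating fidelity `a` in \[0, 1\].
#' @param n_raters Number of raters.
#' @param k Number of categories (defaults to the number of distinct true
#'   themes).
#' @param seed Integer seed.
#' @return A long tibble `item_id`, `rater_id`, `category` (categories are
#'   `"1" .. "k"`).
#' @export
generate_expert_assignments <- function(truth, fidelity, n_raters,
                                        k = length(unique(truth$theme)),
                                        seed = 1L) {
  assert_prob(fidelity, "fidelity")
  N <- nrow(truth)
  with_private_seed(derive_seed(seed, "expert_assignments"), {
    grid <- tidyr::expand_grid(rater_id = sprintf("rater%d", seq_len(n_raters)),
                               item_id = truth$item_id)
    grid$true_theme <- truth$theme[match(grid$item_id, truth$item_id)]
    faithful <- stats::runif(nrow(grid)) < fidelity
    random_cat <- sample.int(k, nrow(grid), replace = TRUE)
    grid$category <- as.character(ifelse(faithful, grid$true_theme, random_cat))
    grid[, c("item_id", "rater_id", "category")]
  })
}

#' Generate ordinal participant ratings from a latent-theme factor model
#'
#' Every participant draws one standard-normal severity per theme, shared
#' across scales; each item's raw score is `lambda * severity(theme) +
#' sigma * noise`, discretized to `0 .. ordinal_levels - 1` at
#' equal-probability cut points of the marginal
#' Normal(0, sqrt(lambda^2 + sigma^2)) distribution. After discretization,
#' each cell is independently zeroed with the group's zero-inflation
#' probability (higher for controls, so patient totals exceed control
#' totals on average), and any `planted_zero_items` are forced to all-zero
#' exactly.
#'
#' @param items Tibble `item_id`, `scale_id`, `theme` for the scales to
#'   rate (e.g. the generator `truth` joined to the bank, subset to two
#'   scales).
#' @param config A [generator_config()].
#' @param seed Integer seed (defaults to the config seed).
#' @return A named list of `ratings_matrix` tibbles, one per scale in
#'   `items`.
#' @export
generate_participant_ratings <- function(items, config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!all(c("item_id", "scale_id", "theme") %in% names(items))) {
    abort("`items` needs columns item_id, scale_id, theme")
  }
  n <- config$n_participants
  n_pat <- n %/% 2L
  group <- c(rep("patient", n_pat), rep("control", n - n_pat))
  marg_sd <- sqrt(config$lambda^2 + config$sigma^2)
  cuts <- stats::qnorm(seq_len(config$ordinal_levels - 1L) / config$ordinal_levels,
                       sd = marg_sd)

  with_private_seed(derive_seed(seed, "participant_ratings"), {
    severity <- matrix(stats::rnorm(n * config$n_themes), nrow = n)
    scales <- unique(items$scale_id)
    out <- lapply(scales, function(sc) {
      sub <- items[items$scale_id == sc, ]
      raw <- config$lambda * severity[, sub$theme, drop = FALSE] +
        config$sigma * matrix(stats::rnorm(n * nrow(sub)), nrow = n)
      score <- matrix(findInterval(raw, cuts), nrow = n)
      pi0 <- config$zero_inflation[group]
      zero_mask <- matrix(stats::runif(n * nrow(sub)), nrow = n) < pi0
      score[zero_mask] <- 0L
      score[, sub$item_id %in% config$planted_zero_items] <- 0L
      df <- as_tibble(as.data.frame(score))
      names(df) <- sub$item_id
      as_ratings_matrix(dplyr::bind_cols(
        tibble(participant_id = sprintf("p%03d", seq_len(n)), group = group), df))
    })
    stats::setNames(out, scales)
  })
}

#' Generate and write a complete synthetic dataset
#'
#' Emits, under `dir`, the exact file dialects the analysis stages consume:
#' `item_bank.csv`, `truth.tsv`, `constructs.json` (two synthetic construct
#' descriptions built from the theme vocabularies), `experts.csv` (long
#' `item_id,rater_id,category`), and one ratings CSV per requested scale.
#' Identical config + seed produce byte-identical files.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @param ratings_scales Which two scales get participant ratings (default
#'   the two largest).
#' @return Invisibly, a named list of the written paths plus the in-memory
#'   objects (`bank`, `truth`, `experts`, `ratings`).
#' @export
generate_dataset <- function(config, dir,
                             ratings_scales = config$scales$scale_id[
                               order(-config$scales$n_items)][1:2]) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_item_bank(config)
  experts <- generate_expert_assignments(
    gen$truth, config$expert_fidelity, config$n_raters,
    k = config$n_themes, seed = config$seed)
  items <- dplyr::left_join(gen$truth,
                            as_tibble(gen$bank)[, c("item_id", "scale_id")],
                            by = "item_id")
  ratings <- generate_participant_ratings(
    items[items$scale_id %in% ratings_scales, ], config)

  paths <- list(
    bank = file.path(dir, "item_bank.csv"),
    truth = file.path(dir, "truth.tsv"),
    experts = file.path(dir, "experts.csv"),
    ratings = stats::setNames(
      file.path(dir, sprintf("ratings_%s.csv", names(ratings))), names(ratings))
  )
  write_item_bank(gen$bank, paths$bank)
  readr::write_tsv(gen$truth, paths$truth, progress = FALSE)
  readr::write_csv(experts, paths$experts, progress = FALSE)
  for (sc in names(ratings)) {
    readr::write_csv(ratings[[sc]], paths$ratings[[sc]], progress = FALSE)
  }
  invisible(c(paths, list(bank = gen$bank, truth = gen$truth,
                          experts = experts, ratings = ratings)))
}
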