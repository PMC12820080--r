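test_that("generator outputs are fully determined by config + seed", {
  cfg <- generator_config(seed = 5)
  g1 <- generate_item_bank(cfg)
  g2 <- generate_item_bank(cfg)
  expect_identical(as.data.frame(g1$bank), as.data.frame(g2$bank))
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_item_bank(generator_config(seed = 6))
  expect_false(identical(g1$bank$description, g3$bank$description))

  e1 <- generate_expert_assignments(g1$truth, 0.9, 6, seed = 5)
  e2 <- generate_expert_assignments(g1$truth, 0.9, 6, seed = 5)
  expect_identical(e1, e2)

  items <- dplyr::left_join(g1$truth,
                            tibble::as_tibble(g1$bank)[, c("item_id", "scale_id")],
                            by = "item_id")
  two <- items[items$scale_id %in% c("TLC", "CLANG"), ]
  r1 <- generate_participant_ratings(two, cfg)
  r2 <- generate_participant_ratings(two, cfg)
  expect_identical(r1, r2)
})

test_that("default bank matches the studied corpus dimensions", {
  gen <- generate_item_bank(generator_config(seed = 1))
  expect_equal(nrow(gen$bank), 103L)
  expect_equal(length(attr(gen$bank, "scales")), 7L)
  expect_equal(sort(unique(gen$truth$theme)), 1:4)
  counts <- table(gen$bank$scale_id)
  expect_equal(unname(counts[["TALD"]]), 30L)
  expect_equal(unname(counts[["TLC"]]), 20L)
})

test_that("w = 1 items of different themes share no core tokens; w = 0 hides themes", {
  cfg1 <- generator_config(w = 1, seed = 3)
  gen1 <- generate_item_bank(cfg1)
  toks <- strsplit(gen1$bank$description, " ")
  themes <- gen1$truth$theme
  for (t1 in 1:3) for (t2 in (t1 + 1):4) {
    a <- unlist(toks[themes == t1])
    b <- unlist(toks[themes == t2])
    expect_equal(length(intersect(a, b)), 0L)
  }

  # w = 0: theme structure unrecoverable, ARI near 0 across seeds
  aris <- vapply(1:12, function(s) {
    cfg0 <- generator_config(w = 0, seed = s)
    gen0 <- generate_item_bank(cfg0)
    emb <- embed_items(gen0$bank, mock_backend(seed = s, dimension = 128))
    g <- sparsify_to_backbone(item_similarity_matrix(emb), gen0$bank, "TLC")
    cl <- cluster_graph(g)
    adjusted_rand_index(cl$cluster,
                        gen0$truth$theme[match(cl$item_id, gen0$truth$item_id)])
  }, numeric(1))
  expect_lt(median(aris), 0.2)
})

test_that("expert assignments at the fidelity extremes behave as designed", {
  gen <- generate_item_bank(generator_config(seed = 2))
  perfect <- generate_expert_assignments(gen$truth, 1, 6, seed = 2)
  am <- build_assignment_matrix(perfect)
  expect_equal(fleiss_kappa(am)$kappa, 1)
  truth_cat <- as.character(gen$truth$theme[match(perfect$item_id, gen$truth$item_id)])
  expect_equal(perfect$category, truth_cat)

  # a = 0: labels independent of truth, kappa near zero
  noise <- generate_expert_assignments(gen$truth, 0, 8, seed = 2)
  am0 <- build_assignment_matrix(noise)
  expect_lt(abs(fleiss_kappa(am0)$kappa), 0.05)
})

test_that("ratings follow the latent-theme factor model", {
  gen <- generate_item_bank(generator_config(seed = 4))
  items <- dplyr::left_join(gen$truth,
                            tibble::as_tibble(gen$bank)[, c("item_id", "scale_id")],
                            by = "item_id")
  two <- items[items$scale_id %in% c("TLC", "CLANG"), ]

  # sigma = 0, no zero-inflation: same-theme items perfectly rank-correlated
  cfg0 <- generator_config(seed = 4, sigma = 0,
                           zero_inflation = c(patient = 0, control = 0),
                           n_participants = 200)
  r0 <- generate_participant_ratings(two, cfg0)
  tlc <- r0$TLC
  tlc_items <- setdiff(names(tlc), c("participant_id", "group"))
  th <- two$theme[match(tlc_items, two$item_id)]
  same <- which(th == th[1])
  expect_equal(stats::cor(tlc[[tlc_items[same[1]]]], tlc[[tlc_items[same[2]]]],
                          method = "spearman"), 1, tolerance = 1e-12)

  # planted all-zero item is excluded exactly
  cfgz <- generator_config(seed = 4, planted_zero_items = "TLC-3")
  rz <- generate_participant_ratings(two, cfgz)
  out <- exclude_degenerate_items(rz$TLC)
  expect_true("TLC-3" %in% out$excluded$item_id[out$excluded$reason == "all_zero"])

  # scores live on the configured ordinal range
  scores <- as.matrix(rz$TLC[, setdiff(names(rz$TLC), c("participant_id", "group"))])
  expect_true(all(scores >= 0 & scores <= 4))
})

test_that("within-theme correlation matches a large-sample oracle run", {
  gen <- generate_item_bank(generator_config(seed = 6))
  items <- dplyr::left_join(gen$truth,
                            tibble::as_tibble(gen$bank)[, c("item_id", "scale_id")],
                            by = "item_id")
  two <- items[items$scale_id %in% c("TLC", "CLANG"), ]
  mean_within <- function(r, items_df) {
    cols <- setdiff(names(r), c("participant_id", "group"))
    th <- items_df$theme[match(cols, items_df$item_id)]
    R <- stats::cor(as.matrix(r[, cols]))
    vals <- c()
    for (t in unique(th)) {
      sub <- R[th == t, th == t, drop = FALSE]
      if (nrow(sub) > 1) vals <- c(vals, sub[upper.tri(sub)])
    }
    mean(vals)
  }
  cfg_small <- generator_config(seed = 6, n_participants = 500,
                                zero_inflation = c(patient = 0.15, control = 0.30))
  cfg_big <- generator_config(seed = 601, n_participants = 20000,
                              zero_inflation = c(patient = 0.15, control = 0.30))
  r_small <- generate_participant_ratings(two, cfg_small)
  r_big <- generate_participant_ratings(two, cfg_big)
  expect_equal(mean_within(r_small$TLC, two), mean_within(r_big$TLC, two),
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("patients outscore controls under heavier control zero-inflation", {
  gen <- generate_item_bank(generator_config(seed = 8))
  items <- dplyr::left_join(gen$truth,
                            tibble::as_tibble(gen$bank)[, c("item_id", "scale_id")],
                            by = "item_id")
  two <- items[items$scale_id %in% c("TLC", "CLANG"), ]
  r <- generate_participant_ratings(two, generator_config(seed = 8, n_participants = 400))
  tot <- rowSums(as.matrix(r$TLC[, setdiff(names(r$TLC), c("participant_id", "group"))]))
  expect_gt(mean(tot[r$TLC$group == "patient"]), mean(tot[r$TLC$group == "control"]))
})

test_that("co-cluster strength is monotone in the latent loading and text separation", {
  # lambda grid at fixed w
  prop_at <- function(lambda, w, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- generator_config(seed = s, lambda = lambda, w = w,
                              n_participants = 150)
      gen <- generate_item_bank(cfg)
      items <- dplyr::left_join(gen$truth,
                                tibble::as_tibble(gen$bank)[, c("item_id", "scale_id")],
                                by = "item_id")
      two <- items[items$scale_id %in% c("TLC", "CLANG"), ]
      r <- generate_participant_ratings(two, cfg)
      truth_cl <- structure(
        tibble::tibble(item_id = gen$truth$item_id,
                       cluster = as.integer(gen$truth$theme)),
        class = c("cluster_assignment", class(tibble::tibble())))
      res <- clinical_alignment(r$TLC, r$CLANG, truth_cl, chance = 0.25)
      res$n_cocluster / res$n_pairs
    }, numeric(1)))
  }
  seeds <- 1:8
  p_low <- prop_at(0.1, 0.8, seeds)
  p_mid <- prop_at(0.4, 0.8, seeds)
  p_high <- prop_at(0.8, 0.8, seeds)
  # nondecreasing along the grid, allowing one small noise inversion
  expect_true(sum(c(p_mid < p_low - 0.05, p_high < p_mid - 0.05)) <= 1)
  expect_gt(p_high, p_low)
})

test_that("generate_dataset writes byte-identical files for identical configs", {
  cfg <- generator_config(seed = 9, n_participants = 40)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  out1 <- generate_dataset(cfg, d1)
  out2 <- generate_dataset(cfg, d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", n = 1e6),
                     readBin(file.path(d2, f), "raw", n = 1e6), info = f)
  }
  # emitted dialects load through the package readers
  bank <- load_item_bank(file.path(d1, "item_bank.csv"))
  expect_equal(nrow(bank), 103L)
  experts <- readr::read_csv(file.path(d1, "experts.csv"), show_col_types = FALSE,
                             col_types = readr::cols(.default = "c"))
  am <- build_assignment_matrix(experts)
  expect_equal(am$n_raters, 6L)
  r <- load_ratings_matrix(file.path(d1, sprintf("ratings_%s.csv", "TALD")))
  expect_equal(nrow(r), 40L)
})
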