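# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph) so they can arbitrate correctness.

# --- tiny base-1e7 big-integer arithmetic (nonnegative), little-endian ----
BIG_BASE <- 1e7

big_from_num <- function(x) {
  stopifnot(x >= 0, x == round(x))
  d <- numeric(0)
  repeat {
    d <- c(d, x %% BIG_BASE)
    x <- x %/% BIG_BASE
    if (x == 0) break
  }
  d
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% BIG_BASE
    s[i] <- s[i] %% BIG_BASE
  }
  while (carry > 0) {
    s <- c(s, carry %% BIG_BASE)
    carry <- carry %/% BIG_BASE
  }
  s
}

# multiply by a small integer (s * BIG_BASE must stay exactly representable)
big_mul_small <- function(a, s) {
  stopifnot(s >= 0, s == round(s), s < 2^26)
  p <- a * s
  carry <- 0
  for (i in seq_along(p)) {
    p[i] <- p[i] + carry
    carry <- p[i] %/% BIG_BASE
    p[i] <- p[i] %% BIG_BASE
  }
  while (carry > 0) {
    p <- c(p, carry %% BIG_BASE)
    carry <- carry %/% BIG_BASE
  }
  p
}

big_to_num <- function(a) sum(a * BIG_BASE^(seq_along(a) - 1))

# exact-rational binomial upper tail P(X >= k), X ~ Bin(n, pa/pb),
# evaluated with big-integer numerator/denominator then converted to double
oracle_binom_tail <- function(k, n, pa, pb) {
  if (k == 0) return(1)
  num <- big_from_num(0)
  for (j in k:n) {
    term <- big_from_num(round(choose(n, j)))
    if (j > 0) for (r in seq_len(j)) term <- big_mul_small(term, pa)
    if (n - j > 0) for (r in seq_len(n - j)) term <- big_mul_small(term, pb - pa)
    num <- big_add(num, term)
  }
  den <- big_from_num(1)
  for (r in seq_len(n)) den <- big_mul_small(den, pb)
  big_to_num(num) / big_to_num(den)
}

# --- flood-fill connected components on an undirected edge list ----------
oracle_components <- function(nodes, edges) {
  comp <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  nbr <- lapply(stats::setNames(nm = nodes), function(v) {
    unique(c(edges$target[edges$source == v], edges$source[edges$target == v]))
  })
  label <- 0L
  for (v in nodes) {
    if (!is.na(comp[[v]])) next
    label <- label + 1L
    queue <- v
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[[u]])) next
      comp[[u]] <- label
      queue <- c(queue, nbr[[u]][is.na(comp[nbr[[u]]])])
    }
  }
  comp
}

# --- independently coded Fleiss kappa (pair-agreement formulation) -------
oracle_fleiss <- function(counts) {
  m <- sum(counts[1, ])
  pairs_agree <- apply(counts, 1, function(r) sum(r * (r - 1) / 2))
  P_i <- pairs_agree / (m * (m - 1) / 2)
  p_j <- colMeans(counts / m)
  (mean(P_i) - sum(p_j^2)) / (1 - sum(p_j^2))
}

oracle_category_kappa <- function(counts, j) {
  m <- sum(counts[1, ])
  N <- nrow(counts)
  x <- counts[, j]
  p <- mean(x) / m
  1 - mean(x * (m - x)) / (m * (m - 1) * p * (1 - p))
}

# random assignment-count matrix with every row summing to m
random_counts <- function(N, m, k) {
  t(vapply(seq_len(N), function(i) {
    tabulate(sample.int(k, m, replace = TRUE), nbins = k)
  }, integer(k)))
}

# small deterministic item-bank fixture
tiny_bank <- function() {
  as_item_bank(data.frame(
    scale_id = c("TLC", "TLC", "CLANG", "CLANG", "TALD"),
    item_index = c("1", "2", "1", "2", "1"),
    label = c("Poverty of speech", "Derailment", "Neologisms",
              "Pressure of speech", "Blocking"),
    description = c(
      "Restriction in the amount of spontaneous speech",
      "Ideas slip off the track onto another obliquely related topic",
      "New word formations unknown to the common language",
      "An increase in the amount of spontaneous speech",
      "Interruption of a train of speech before completion")
  ))
}
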