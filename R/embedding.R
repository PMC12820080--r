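#' Embedding backends
#'
#' Text is mapped to dense vectors by a pluggable backend. Two backends are
#' provided:
#'
#' * `mock_backend()` — a deterministic, offline bag-of-tokens random
#'   projection. Tokens are hashed into a fixed vocabulary slot space, the
#'   slot-count vector is multiplied by a Gaussian projection matrix
#'   generated from `seed` alone, and the result is L2-normalized. Texts
#'   sharing more tokens have higher expected cosine similarity, so the
#'   semantic-similarity pipeline is fully exercisable without any model.
#' * `reference_backend()` — the published 768-dimensional
#'   sentence-transformer (`all-mpnet-base-v2` by default). The model is not
#'   bundled; calling [embed_texts()] with this backend raises an explicit
#'   backend-unavailable error unless an `embed_fn` wired to a local model
#'   runtime is supplied. There is never a silent fallback to the mock.
#'
#' @param seed Integer seed; together with `dimension` it fully determines
#'   every mock vector (bitwise reproducible across sessions).
#' @param dimension Embedding dimension (mock default 256; minimum 8).
#' @param n_slots Size of the hashed vocabulary slot space (mock).
#' @param model_id,revision Reference model identifier and pinned revision.
#' @param embed_fn Optional function `(character) -> numeric matrix` that
#'   performs the actual reference-model inference.
#' @return An object of class `embedding_backend` with fields `backend_id`,
#'   `dimension`, `deterministic`.
#' @export
#' @examples
#' b <- mock_backend(seed = 1, dimension = 64)
#' emb <- embed_texts(c("poverty of speech", "pressured speech"), b)
#' dim(emb)
mock_backend <- function(seed = 1L, dimension = 256L, n_slots = 4096L) {
  dimension <- as.integer(dimension)
  if (is.na(dimension) || dimension < 8L) abort("mock backend dimension must be >= 8")
  seed <- as.integer(seed)
  structure(
    list(
      backend_id = sprintf("mock-d%d-s%d", dimension, seed),
      dimension = dimension,
      deterministic = TRUE,
      seed = seed,
      n_slots = as.integer(n_slots)
    ),
    class = "embedding_backend"
  )
}

#' @rdname mock_backend
#' @export
reference_backend <- function(model_id = "all-mpnet-base-v2",
                              revision = "main", embed_fn = NULL) {
  structure(
    list(
      backend_id = sprintf("st:%s@%s", model_id, revision),
      dimension = 768L,
      deterministic = TRUE,
      model_id = model_id,
      revision = revision,
      embed_fn = embed_fn
    ),
    class = "embedding_backend"
  )
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat(sprintf("<embedding_backend %s, d = %d>\n", x$backend_id, x$dimension))
  invisible(x)
}

# cache of mock projection matrices keyed by backend_id (8 MB at d=256)
.mock_cache <- new.env(parent = emptyenv())

mock_projection <- function(backend) {
  key <- backend$backend_id
  if (!is.null(.mock_cache[[key]])) return(.mock_cache[[key]])
  P <- with_private_seed(backend$seed, {
    matrix(stats::rnorm(backend$dimension * backend$n_slots),
           nrow = backend$dimension, ncol = backend$n_slots)
  })
  .mock_cache[[key]] <- P
  P
}

# deterministic polynomial rolling hash of a token into 1..n_slots
hash_token <- function(token, n_slots) {
  h <- 0
  for (cp in utf8ToInt(token)) h <- (h * 131 + cp) %% 1000003
  as.integer(h %% n_slots) + 1L
}

#' Embed a single text with the mock backend
#'
#' Exposed primarily for testing the backend contract; most callers use
#' [embed_texts()]. The vector is the L2-normalized projection of the
#' text's hashed token-count vector through a seed-determined Gaussian
#' matrix.
#'
#' @param text A single nonempty string.
#' @param seed Integer seed for the projection matrix.
#' @param dimension Embedding dimension (>= 8).
#' @return A numeric vector of length `dimension` with unit L2 norm.
#' @export
mock_embed <- function(text, seed = 1L, dimension = 256L) {
  backend <- mock_backend(seed = seed, dimension = dimension)
  as.vector(embed_texts(text, backend)[1, ])
}

embed_mock_texts <- function(texts, backend) {
  P <- mock_projection(backend)
  vecs <- vapply(texts, function(txt) {
    tokens <- strsplit(trimws(txt), "\\s+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    slots <- vapply(tokens, hash_token, integer(1), n_slots = backend$n_slots)
    counts <- table(slots)
    v <- P[, as.integer(names(counts)), drop = FALSE] %*% as.numeric(counts)
    nrm <- sqrt(sum(v^2))
    if (nrm == 0) abort("mock embedding collapsed to the zero vector")
    as.numeric(v) / nrm
  }, numeric(backend$dimension))
  t(vecs)
}

#' Embed a collection of texts
#'
#' @param texts Character vector of nonempty cleaned texts.
#' @param backend An `embedding_backend` (see [mock_backend()]).
#' @param ids Optional row identifiers (defaults to names of `texts` or
#'   positional ids).
#' @return A numeric matrix, one row per text in input order, with
#'   `rownames` set to `ids` and attribute `backend_id`. Calling twice with
#'   identical inputs yields identical matrices (bitwise for the mock
#'   backend).
#' @export
embed_texts <- function(texts, backend, ids = NULL) {
  if (!inherits(backend, "embedding_backend")) abort("`backend` must be an embedding_backend")
  texts <- as.character(texts)
  if (length(texts) == 0) abort("no texts to embed")
  bad <- which(is.na(texts) | !nzchar(trimws(texts)))
  if (length(bad) > 0) {
    abort(sprintf("empty text at position(s): %s", paste(bad, collapse = ", ")))
  }
  ids <- ids %||% names(texts) %||% sprintf("text%d", seq_along(texts))
  mat <- if (startsWith(backend$backend_id, "mock-")) {
    embed_mock_texts(texts, backend)
  } else if (!is.null(backend$embed_fn)) {
    m <- backend$embed_fn(texts)
    if (!is.matrix(m) || nrow(m) != length(texts) || ncol(m) != backend$dimension) {
      abort(sprintf("backend embed_fn must return a %d x %d numeric matrix",
                    length(texts), backend$dimension))
    }
    m
  } else {
    abort(sprintf(paste0(
      "embedding backend '%s' is unavailable: the reference ",
      "sentence-transformer model is not bundled. Supply embed_fn= wired to ",
      "a local model runtime, or use mock_backend() explicitly."),
      backend$backend_id))
  }
  if (any(!is.finite(mat))) abort("backend produced non-finite embedding values")
  rownames(mat) <- ids
  attr(mat, "backend_id") <- backend$backend_id
  mat
}

#' Embed every item of a bank
#'
#' Convenience wrapper: embeds `clean_text` with rows named by `item_id`.
#'
#' @param bank An `item_bank` tibble.
#' @param backend An `embedding_backend`.
#' @return Embedding matrix (items x dimension), rows in bank order.
#' @export
embed_items <- function(bank, backend) {
  embed_texts(bank$clean_text, backend, ids = bank$item_id)
}
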