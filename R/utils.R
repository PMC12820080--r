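#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# run code with a private, fully specified RNG so results are reproducible
# across sessions and the caller's RNG stream is untouched
with_private_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# derive a stage-specific seed from a master seed and a stage name; keeps
# every stage independently reproducible from one configured seed
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% 1048573
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE", name))
  }
  invisible(x)
}

assert_prob <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    if (open) (x > 0 && x < 1) else (x >= 0 && x <= 1)
  if (!ok) abort(sprintf("`%s` must be a probability in %s", name,
                         if (open) "(0, 1)" else "[0, 1]"))
  invisible(x)
}
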