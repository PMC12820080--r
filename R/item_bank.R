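#' Load a bank of rating-scale items
#'
#' Reads a corpus of rating-scale items ("item bank") from CSV or JSON and
#' returns a tibble, one row per item, in input order. A globally unique
#' `item_id` is synthesized as `"<scale_id>-<item_index>"` (e.g. `"TLC-10"`,
#' `"PANSS-N7"`). Descriptions are preprocessed with [preprocess_text()] into
#' a `clean_text` column, and `word_count` holds the whitespace-token count
#' of the raw description (computed before any preprocessing).
#'
#' The scale texts of the common formal-thought-disorder instruments are
#' copyrighted and are not bundled; users supply their own item bank (or use
#' [generate_item_bank()] for synthetic corpora with known ground truth).
#'
#' @param path Path to a CSV file (header
#'   `scale_id,item_index,label,description`, RFC-4180) or a JSON array of
#'   objects with the same keys.
#' @param format `"auto"` (by file extension), `"csv"`, or `"json"`.
#' @param strip_illustrative,lowercase Preprocessing flags passed to
#'   [preprocess_text()].
#' @param embed_label If `TRUE`, `clean_text` is built from
#'   `label: description` rather than the description alone. Default embeds
#'   the description only.
#' @return A tibble of class `item_bank` with columns `scale_id`,
#'   `item_index`, `item_id`, `label`, `description`, `clean_text`,
#'   `word_count`, and a `scales` attribute listing scale ids in order of
#'   first appearance.
#' @seealso [as_item_bank()], [write_item_bank()], [length_statistics()]
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("scale_id,item_index,label,description",
#'              "TLC,1,Poverty of speech,Restriction in the amount of speech",
#'              "TLC,2,Poverty of content,Speech conveying little information"),
#'            path)
#' bank <- load_item_bank(path)
#' bank$item_id
load_item_bank <- function(path, format = c("auto", "csv", "json"),
                           strip_illustrative = TRUE, lowercase = TRUE,
                           embed_label = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("item bank file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- switch(format,
    csv = {
      out <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE, show_col_types = FALSE)
      as_tibble(out)
    },
    json = {
      recs <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      if (length(recs) == 0) tibble() else as_tibble(recs)
    }
  )
  if (nrow(df) == 0) abort(sprintf("item bank is empty: %s", path))
  as_item_bank(df, strip_illustrative = strip_illustrative,
               lowercase = lowercase, embed_label = embed_label)
}

#' Validate a data frame as an item bank
#'
#' Checks the schema (`scale_id`, `item_index`, `label`, `description`),
#' synthesizes `item_id`, enforces its uniqueness, and computes `clean_text`
#' and `word_count`. Row order is preserved.
#'
#' @param df A data frame with columns `scale_id`, `item_index`, `label`,
#'   `description`. `item_index` may be numeric or character (PANSS-style
#'   labels such as `"N7"` are kept as strings).
#' @inheritParams load_item_bank
#' @return An `item_bank` tibble (see [load_item_bank()]).
#' @export
as_item_bank <- function(df, strip_illustrative = TRUE, lowercase = TRUE,
                         embed_label = FALSE) {
  required <- c("scale_id", "item_index", "label", "description")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("item bank is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) abort("item bank has no items")
  assert_flag(embed_label, "embed_label")
  bank <- tibble(
    scale_id = as.character(df$scale_id),
    item_index = as.character(df$item_index),
    item_id = paste(as.character(df$scale_id), as.character(df$item_index), sep = "-"),
    label = as.character(df$label),
    description = as.character(df$description)
  )
  dup <- unique(bank$item_id[duplicated(bank$item_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate item_id(s) in bank: %s", paste(dup, collapse = ", ")))
  }
  base_text <- if (embed_label) {
    paste(bank$label, bank$description, sep = ": ")
  } else {
    bank$description
  }
  bank$clean_text <- preprocess_text(base_text,
                                     strip_illustrative = strip_illustrative,
                                     lowercase = lowercase)
  bank$word_count <- count_words(bank$description)
  empty <- bank$item_id[!nzchar(bank$clean_text)]
  if (length(empty) > 0) {
    abort(sprintf("item(s) with empty description after preprocessing: %s",
                  paste(empty, collapse = ", ")))
  }
  structure(bank,
            scales = unique(bank$scale_id),
            class = c("item_bank", class(tibble())))
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("# Item bank: %d items across %d scale(s) (%s)\n",
              nrow(x), length(attr(x, "scales")),
              paste(attr(x, "scales"), collapse = ", ")))
  NextMethod()
}

#' Write an item bank back to CSV or JSON
#'
#' Writes the four raw columns (`scale_id`, `item_index`, `label`,
#' `description`); loading the written file reproduces an identical bank.
#'
#' @param bank An `item_bank` tibble.
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"csv"`, or `"json"`.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  raw <- bank[, c("scale_id", "item_index", "label", "description")]
  switch(format,
    csv = readr::write_csv(raw, path, progress = FALSE),
    json = jsonlite::write_json(raw, path, dataframe = "rows", auto_unbox = TRUE,
                                pretty = TRUE)
  )
  invisible(path)
}

#' Preprocess item description text
#'
#' Normalizes free-text symptom descriptions for embedding: optionally
#' removes illustrative parenthetical examples, optionally lowercases, and
#' collapses whitespace. A parenthetical group is treated as illustrative
#' when its content begins with `"e.g."` or `"i.e."` (case-insensitive,
#' optional whitespace); other parentheticals — often meaningful synonyms
#' such as "(Word salad, Jargon Aphasia)" — are retained.
#'
#' The function is vectorized and idempotent: applying it twice equals
#' applying it once.
#'
#' @param raw Character vector of raw texts (may contain empty strings).
#' @param strip_illustrative Remove `e.g.`/`i.e.` parenthetical groups.
#' @param lowercase Convert to lowercase.
#' @param extra_prefixes Additional content prefixes (plain strings) that
#'   mark a parenthetical group as illustrative, e.g. `"for example"`.
#' @return Character vector of cleaned texts.
#' @export
#' @examples
#' preprocess_text(paste("Restricted thinking (e.g., a depressive patient",
#'                       "who is preoccupied with his indigestion)"))
#' preprocess_text("Incoherence (Word salad)")
preprocess_text <- function(raw, strip_illustrative = TRUE, lowercase = TRUE,
                            extra_prefixes = character()) {
  assert_flag(strip_illustrative, "strip_illustrative")
  assert_flag(lowercase, "lowercase")
  if (length(raw) == 0) return(character())
  out <- as.character(raw)
  out[is.na(out)] <- ""
  if (strip_illustrative) {
    prefixes <- c("e\\.g\\.", "i\\.e\\.",
                  vapply(extra_prefixes, function(p) {
                    gsub("([][{}()*+?.\\^$|\\\\])", "\\\\\\1", p)
                  }, character(1)))
    pat <- sprintf("\\(\\s*(%s)[^()]*\\)", paste(prefixes, collapse = "|"))
    # repeat so nested/adjacent groups exposed by a removal are also caught
    repeat {
      nxt <- gsub(pat, " ", out, ignore.case = TRUE, perl = TRUE)
      if (identical(nxt, out)) break
      out <- nxt
    }
  }
  if (lowercase) out <- tolower(out)
  out <- gsub("\\s+", " ", out)
  trimws(out)
}

# whitespace-token count on the raw text; empty or blank strings count 0
count_words <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  vapply(strsplit(trimws(x), "\\s+"), function(t) sum(nzchar(t)), integer(1))
}

#' Per-scale description length statistics
#'
#' Word counts of item descriptions differ strongly between instruments
#' (some scales use terse labels, others paragraph-length definitions with
#' examples); this summary quantifies that heterogeneity. Counts are
#' whitespace tokens of the raw (unpreprocessed) description.
#'
#' @param bank An `item_bank` tibble.
#' @return A tibble with one row per scale: `scale_id`, `n_items`,
#'   `mean_words`, `max_words`.
#' @export
length_statistics <- function(bank) {
  if (!is.data.frame(bank) || nrow(bank) == 0) abort("item bank is empty")
  bank %>%
    as_tibble() %>%
    dplyr::group_by(.data$scale_id) %>%
    dplyr::summarise(
      n_items = dplyr::n(),
      mean_words = mean(.data$word_count),
      max_words = as.integer(max(.data$word_count)),
      .groups = "drop"
    ) %>%
    dplyr::arrange(match(.data$scale_id, unique(bank$scale_id)))
}

#' Construct-description tibble
#'
#' Builds the small table of construct descriptions (e.g. the classical
#' positive and negative formal-thought-disorder definitions) used for
#' similarity-based item classification. Construct texts are consumed
#' exactly as written — illustrative-parenthetical stripping applies to
#' scale items, not to construct paragraphs.
#'
#' @param ... Named character arguments, `construct_id = text`, or a single
#'   named character vector / list.
#' @return A tibble with columns `construct_id`, `text`.
#' @export
#' @examples
#' construct_descriptions(
#'   positive_FTD = "derailment, pressured speech, neologisms",
#'   negative_FTD = "poverty of speech, slowed thinking, blocking"
#' )
construct_descriptions <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) &&
      (is.list(args[[1]]) || length(args[[1]]) > 1L)) {
    args <- as.list(args[[1]])
  }
  if (length(args) == 0 || is.null(names(args)) || any(!nzchar(names(args)))) {
    abort("construct descriptions must be named: construct_id = text")
  }
  txt <- vapply(args, as.character, character(1))
  if (any(!nzchar(txt))) abort("construct description text must be nonempty")
  if (anyDuplicated(names(args))) abort("construct_id values must be distinct")
  tibble(construct_id = names(args), text = unname(txt))
}

#' Read construct descriptions from JSON
#'
#' @param path JSON file: an object mapping `construct_id` to text.
#' @return A tibble with columns `construct_id`, `text`.
#' @export
load_construct_descriptions <- function(path) {
  if (!file.exists(path)) abort(sprintf("construct file not found: %s", path))
  obj <- jsonlite::fromJSON(path)
  construct_descriptions(obj)
}
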