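#' Build a corpus of bibliographic records
#'
#' A corpus is the total population of potentially eligible articles
#' retrieved by a systematic review search strategy: one record per
#' article, each with a title, an (optionally empty) abstract and
#' bibliographic metadata. Record identifiers are unique within a corpus.
#'
#' If `record_id` is missing it is assigned deterministically: the DOI
#' when present, otherwise a content hash of the whitespace-normalized,
#' casefolded title; hash collisions (e.g. injected byte-identical
#' duplicates) get a sequential `-2`, `-3`, ... suffix so identifiers stay
#' unique while remaining stable across re-imports.
#'
#' @param records a data frame with columns `title` and `abstract`
#'   (character); optional columns `record_id`, `authors` (list of
#'   character vectors or `"; "`-separated strings), `year`, `journal`,
#'   `doi`, `source_file`.
#' @param source_file label recorded on every record lacking one.
#' @return an object of class `corpus`: a tibble of records with the full
#'   column set, in input order.
#' @export
new_corpus <- function(records, source_file = NA_character_) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"title" %in% names(records)) {
    stop_data("corpus records must have a 'title' column")
  }
  n <- nrow(records)
  title <- as.character(records$title)
  abstract <- as.character(records$abstract %||% rep("", n))
  abstract[is.na(abstract)] <- ""

  placeholder <- is.na(title) | !nzchar(trimws(title))
  if (any(placeholder)) {
    warning(sprintf("%d record(s) have an empty title; retained with a placeholder",
                    sum(placeholder)), call. = FALSE)
    title[placeholder] <- sprintf("(untitled record %d)", which(placeholder))
  }

  authors <- records$authors %||% replicate(n, character(0), simplify = FALSE)
  if (is.character(authors)) {
    authors <- lapply(authors, function(a) {
      if (is.na(a) || !nzchar(a)) character(0) else trimws(strsplit(a, ";", fixed = TRUE)[[1]])
    })
  }
  doi <- as.character(records$doi %||% rep(NA_character_, n))
  doi[!is.na(doi) & !nzchar(trimws(doi))] <- NA_character_

  record_id <- as.character(records$record_id %||% rep(NA_character_, n))
  need_id <- is.na(record_id)
  if (any(need_id)) {
    auto <- ifelse(!is.na(doi), doi, paste0("h", content_hash(normalize_text(title))))
    record_id[need_id] <- auto[need_id]
  }
  record_id <- make_unique_ids(record_id)

  out <- tibble::tibble(
    record_id = record_id,
    title = title,
    abstract = abstract,
    authors = authors,
    year = suppressWarnings(as.integer(records$year %||% rep(NA_integer_, n))),
    journal = as.character(records$journal %||% rep(NA_character_, n)),
    doi = doi,
    source_file = as.character(records$source_file %||% rep(source_file, n)),
    title_placeholder = placeholder
  )
  class(out) <- c("corpus", class(out))
  out
}

make_unique_ids <- function(ids) {
  if (!anyDuplicated(ids)) return(ids)
  stats::ave(ids, ids, FUN = function(g) {
    if (length(g) == 1) g else c(g[1], paste0(g[-1], "-", seq_along(g[-1]) + 1L))
  })
}

#' Number of records in a corpus
#' @param corpus a [new_corpus()] object.
#' @return integer count N.
#' @export
n_total <- function(corpus) nrow(corpus)

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d record(s)\n", nrow(x)))
  NextMethod()
}

#' Fingerprint of a corpus
#'
#' Hash over record ids, titles and abstracts, used to tie vector models
#' and screening sessions to the collection they were built from.
#'
#' @param corpus a corpus.
#' @return 16-character hex string.
#' @export
corpus_fingerprint <- function(corpus) {
  content_hash(paste(
    paste(corpus$record_id, collapse = "\x1f"),
    paste(corpus$title, collapse = "\x1f"),
    paste(corpus$abstract, collapse = "\x1f"),
    sep = "\x1e"
  ))
}
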