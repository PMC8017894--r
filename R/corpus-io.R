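#' Read a reference collection from RIS or CSV
#'
#' Parses a bibliographic export into a [new_corpus()] object, one record
#' per entry, preserving file order. RIS entries use the standard tags
#' (`TY`/`TI`/`AB`/`AU`/`PY`/`DO`/`ER`, with `T1`/`N2`/`JO`/`JF`/`T2`
#' accepted as common synonyms); continuation lines are folded into the
#' preceding tag. CSV files must carry a header row; the `title` and
#' `abstract` columns are required (names remappable via `csv_columns`).
#'
#' @param path path to the file.
#' @param format `"ris"` or `"csv"`.
#' @param csv_columns named list mapping the canonical names `title`,
#'   `abstract` and optionally `record_id`, `authors`, `year`, `journal`,
#'   `doi` onto the file's column names. Authors in CSV are `"; "`-separated.
#' @return a `corpus`; records with an empty title are retained with a
#'   placeholder title and flagged (with a warning).
#' @export
read_records <- function(path, format = c("ris", "csv"), csv_columns = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_data("cannot read '%s': file does not exist", path)
  switch(format,
    ris = read_ris(path),
    csv = read_records_csv(path, csv_columns)
  )
}

read_ris <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  entries <- list()
  fields <- list()
  tag <- NULL
  flush_entry <- function() {
    if (length(fields) == 0) return()
    entries[[length(entries) + 1L]] <<- fields
    fields <<- list()
  }
  for (line in lines) {
    m <- regmatches(line, regexec("^([A-Z][A-Z0-9])  - ?(.*)$", line))[[1]]
    if (length(m) == 3) {
      tag <- m[2]
      val <- m[3]
      if (tag == "ER") {
        flush_entry()
        tag <- NULL
      } else {
        fields[[length(fields) + 1L]] <- c(tag, val)
      }
    } else if (!is.null(tag) && nzchar(trimws(line))) {
      # continuation of the previous tag's value
      i <- length(fields)
      if (i > 0) fields[[i]][2] <- paste(fields[[i]][2], trimws(line))
    }
  }
  flush_entry()

  get1 <- function(e, tags) {
    for (f in e) if (f[1] %in% tags) return(f[2])
    NA_character_
  }
  getall <- function(e, tags) {
    out <- vapply(Filter(function(f) f[1] %in% tags, e), `[`, "", 2)
    as.character(out)
  }
  recs <- lapply(entries, function(e) {
    list(
      title = get1(e, c("TI", "T1")) %||% NA_character_,
      abstract = get1(e, c("AB", "N2")),
      authors = list(getall(e, c("AU", "A1"))),
      year = get1(e, c("PY", "Y1")),
      journal = get1(e, c("JO", "JF", "T2")),
      doi = get1(e, "DO")
    )
  })
  df <- do.call(rbind, lapply(recs, function(r) {
    tibble::tibble(title = r$title, abstract = r$abstract %||% "",
                   authors = r$authors, year = sub("[/-].*$", "", r$year %||% NA_character_),
                   journal = r$journal, doi = r$doi)
  }))
  if (is.null(df)) {
    df <- tibble::tibble(title = character(0), abstract = character(0),
                         authors = list(), year = character(0),
                         journal = character(0), doi = character(0))
  }
  df$abstract[is.na(df$abstract)] <- ""
  new_corpus(df, source_file = path)
}

read_records_csv <- function(path, csv_columns = list()) {
  cols <- utils::modifyList(
    list(title = "title", abstract = "abstract", record_id = "record_id",
         authors = "authors", year = "year", journal = "journal", doi = "doi"),
    csv_columns
  )
  header <- strsplit(readLines(path, n = 1L, encoding = "UTF-8", warn = FALSE), ",")[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  if (anyDuplicated(header)) {
    stop_data("duplicated column header(s) in '%s': %s", path,
              paste(unique(header[duplicated(header)]), collapse = ", "))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  for (req in c("title", "abstract")) {
    if (!cols[[req]] %in% names(df)) {
      stop_data("required column '%s' is missing from '%s'", cols[[req]], path)
    }
  }
  pick <- function(key) if (cols[[key]] %in% names(df)) df[[cols[[key]]]] else NULL
  records <- tibble::tibble(title = pick("title"), abstract = pick("abstract"))
  for (key in c("record_id", "authors", "year", "journal", "doi")) {
    val <- pick(key)
    if (!is.null(val)) records[[key]] <- val
  }
  new_corpus(records, source_file = path)
}

#' Write a corpus to CSV
#'
#' Fixed schema: `record_id`, `title`, `abstract`, `authors`
#' (`"; "`-separated), `year`, `journal`, `doi`, `source_file`. A corpus
#' written with this function round-trips through
#' `read_records(format = "csv")`.
#'
#' @param corpus a corpus.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  out <- data.frame(
    record_id = corpus$record_id,
    title = corpus$title,
    abstract = corpus$abstract,
    authors = vapply(corpus$authors, paste, "", collapse = "; "),
    year = corpus$year,
    journal = corpus$journal,
    doi = corpus$doi,
    source_file = corpus$source_file,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Remove exact-match duplicate records
#'
#' Duplicate detection is deliberately conservative: two records are
#' duplicates only when their `(title, abstract)` pair matches. In
#' `"strict"` mode (the default) the match is byte-exact, so records that
#' differ by stray whitespace, punctuation or casing are all retained —
#' trading a few residual duplicates for zero risk of dropping distinct
#' records. `"normalized"` mode is an explicit opt-in that first applies
#' Unicode NFC normalization, casefolding and whitespace collapsing, which
#' approximates what a careful manual de-duplication additionally catches.
#' The first occurrence is kept; output order is preserved; removed
#' records are listed in the report so they can be cross-checked.
#'
#' @param corpus a corpus.
#' @param mode `"strict"` (byte-exact) or `"normalized"`.
#' @return a list with elements `corpus` (de-duplicated) and `report`, a
#'   `duplicate_report`: `groups` (tibble of `kept`, `removed` list-column),
#'   `n_removed`, `mode`.
#' @export
deduplicate <- function(corpus, mode = c("strict", "normalized")) {
  mode <- match.arg(mode)
  key <- if (mode == "strict") {
    paste(corpus$title, corpus$abstract, sep = "\x1f")
  } else {
    paste(normalize_text(corpus$title), normalize_text(corpus$abstract), sep = "\x1f")
  }
  dup <- duplicated(key)
  kept_for <- corpus$record_id[match(key, key)]  # id of first occurrence per key

  groups <- tibble::tibble(kept = character(0), removed = list())
  if (any(dup)) {
    removed_by_kept <- split(corpus$record_id[dup], kept_for[dup])
    groups <- tibble::tibble(
      kept = names(removed_by_kept),
      removed = unname(removed_by_kept)
    )
  }
  report <- structure(
    list(groups = groups, n_removed = sum(dup), mode = mode),
    class = "duplicate_report"
  )
  out <- corpus[!dup, , drop = FALSE]
  class(out) <- class(corpus)
  list(corpus = out, report = report)
}

#' @export
print.duplicate_report <- function(x, ...) {
  cat(sprintf("<duplicate_report> mode=%s, %d record(s) removed in %d group(s)\n",
              x$mode, x$n_removed, nrow(x$groups)))
  invisible(x)
}

#' Export screening results to CSV
#'
#' Writes one of three fixed-schema CSVs, rows sorted by `record_id` so
#' repeated exports diff cleanly:
#' * `"decisions"` — one row per decided record: `record_id`, `title`,
#'   one `decision_<reviewer>` column per reviewer, `flagged`, and the
#'   round in which the record was presented;
#' * `"conflicts"` — the subset of rows with non-unanimous decisions
#'   (requires at least two reviewers);
#' * `"dedup"` — the removed/kept pairs from the de-duplication attached
#'   to the session.
#'
#' @param session a [init_session()] screening session.
#' @param path output CSV path.
#' @param what `"decisions"`, `"conflicts"` or `"dedup"`.
#' @return `path`, invisibly.
#' @export
export_results <- function(session, path, what = c("decisions", "conflicts", "dedup")) {
  if (length(what) != 1 || !what %in% c("decisions", "conflicts", "dedup")) {
    stop_usage("unknown export kind '%s' (expected decisions, conflicts or dedup)",
               paste(what, collapse = ","))
  }
  out <- switch(what,
    decisions = decisions_table(session),
    conflicts = {
      cs <- find_conflicts(session)
      tab <- decisions_table(session)
      tab[tab$record_id %in% cs$conflicts$record_id, , drop = FALSE]
    },
    dedup = {
      drep <- session$dedup_report
      if (is.null(drep)) stop_usage("session has no de-duplication report attached")
      kept <- rep(drep$groups$kept, lengths(drep$groups$removed))
      df <- data.frame(removed_id = unlist(drep$groups$removed) %||% character(0),
                       kept_id = kept %||% character(0),
                       stringsAsFactors = FALSE)
      df[order(df$removed_id), , drop = FALSE]
    }
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

decisions_table <- function(session) {
  d <- session$decisions
  reviewers <- sort(unique(d$reviewer))
  ids <- sort(unique(d$record_id))
  tab <- data.frame(record_id = ids, stringsAsFactors = FALSE)
  tab$title <- session$corpus$title[match(ids, session$corpus$record_id)]
  for (r in reviewers) {
    dr <- d[d$reviewer == r, ]
    tab[[paste0("decision_", r)]] <- dr$decision[match(ids, dr$record_id)]
  }
  tab$flagged <- ids %in% session$flags
  tab$round_presented <- session$presented$round[match(ids, session$presented$record_id)]
  tab
}
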