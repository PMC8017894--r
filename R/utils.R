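# Error helpers: usage errors (caller misuse, CLI exit 1), data errors
# (bad input files / unknown ids, CLI exit 2), contract errors (violated
# numeric preconditions).

stop_usage <- function(msg, ...) {
  stop(structure(
    class = c("screenloop_usage_error", "screenloop_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_data <- function(msg, ...) {
  stop(structure(
    class = c("screenloop_data_error", "screenloop_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_contract <- function(msg, ...) {
  stop(structure(
    class = c("screenloop_contract_error", "screenloop_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed review statistics use
#' conventional half-away-from-zero rounding, so all rendered percentages
#' and currency amounts go through this helper.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Content hash of character strings
#'
#' 64-bit FNV-1a hash rendered as 16 hex characters; used for stable
#' record identifiers and corpus fingerprints.
#'
#' @param x character vector.
#' @return character vector of 16-character hex digests.
#' @export
content_hash <- function(x) {
  fnv1a64(enc2utf8(as.character(x)))
}

# Collapse whitespace, trim, NFC-normalize and casefold: the "normalized"
# text form used for duplicate detection and id hashing.
normalize_text <- function(x) {
  x <- stringi::stri_trans_nfc(as.character(x))
  x <- stringi::stri_trans_tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Run code with a private, restored RNG state so generators are
# deterministic under their own seed without disturbing the caller's stream.
with_private_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
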