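#' Percentage of the corpus not reviewed
#'
#' The headline workload statistic: of `n_total` retrieved articles, the
#' share left unreviewed once screening stopped, rendered as an integer
#' percentage (half away from zero).
#'
#' @param n_total total articles retrieved (N > 0).
#' @param n_reviewed articles screened (0..N).
#' @return integer percent.
#' @export
percent_not_reviewed <- function(n_total, n_reviewed) {
  if (n_total <= 0) stop_contract("n_total must be positive")
  if (n_reviewed < 0 || n_reviewed > n_total) {
    stop_contract("n_reviewed must lie in [0, n_total]")
  }
  as.integer(round_half_up((n_total - n_reviewed) / n_total * 100))
}

#' Work saved over sampling at recall level R
#'
#' `WSS@R = (N - n_screened_at_R)/N - (1 - R)`: the screening effort saved
#' relative to random ordering while still retrieving fraction `R` of the
#' eligible articles. `WSS@95` is the conventional benchmark; `WSS@100`
#' reflects the systematic-review requirement of finding every eligible
#' paper. May be negative (ranking worse than random).
#'
#' @param R recall level in `(0, 1]`.
#' @param n_total corpus size N.
#' @param n_screened_at_R articles screened when recall R was reached
#'   (taken from a [recall_trajectory()], not inferred here).
#' @return a `wss_report`: list with `recall_level`, `n_total`,
#'   `n_screened_at_R`, `wss` (fraction) and `wss_percent` (integer
#'   rendering, half away from zero).
#' @export
wss_at <- function(R, n_total, n_screened_at_R) {
  if (R <= 0 || R > 1) stop_contract("R must lie in (0, 1]")
  if (n_screened_at_R < 0 || n_screened_at_R > n_total) {
    stop_contract("n_screened_at_R must lie in [0, n_total]")
  }
  wss <- (n_total - n_screened_at_R) / n_total - (1 - R)
  structure(
    list(recall_level = R, n_total = n_total, n_screened_at_R = n_screened_at_R,
         wss = wss, wss_percent = as.integer(round_half_up(wss * 100))),
    class = "wss_report"
  )
}

#' @export
print.wss_report <- function(x, ...) {
  cat(sprintf("<wss_report> WSS@%g = %.4f (%d%%), N = %d, screened = %d\n",
              x$recall_level * 100, x$wss, x$wss_percent, x$n_total,
              x$n_screened_at_R))
  invisible(x)
}

#' Rounds of screening needed for a reviewed count
#'
#' @param n_reviewed articles screened.
#' @param round_size articles per round (default 50).
#' @return `ceiling(n_reviewed / round_size)`.
#' @export
rounds_required <- function(n_reviewed, round_size = 50) {
  if (n_reviewed < 0 || round_size < 1) {
    stop_contract("n_reviewed must be >= 0 and round_size >= 1")
  }
  as.integer(ceiling(n_reviewed / round_size))
}

#' Cumulative recall curve over a presentation log
#'
#' Steps through the ordered log of screened records and counts how many
#' members of `final_set` (the articles included in the published review)
#' have been found after each screening decision. Non-decreasing; reaches
#' `|final_set|` when the log is exhaustive.
#'
#' @param presented_ids ordered character vector of screened record ids.
#' @param final_set character vector of target record ids.
#' @param n_found_at_start finals already known before screening began
#'   (e.g. final articles used as seeds), added to every step.
#' @return tibble with `n_screened` and `n_found`; attribute `n_final`
#'   holds the target count.
#' @export
recall_trajectory <- function(presented_ids, final_set, n_found_at_start = 0L) {
  found <- cumsum(presented_ids %in% final_set) + n_found_at_start
  out <- tibble::tibble(n_screened = seq_along(presented_ids), n_found = found)
  attr(out, "n_final") <- length(final_set) + n_found_at_start
  attr(out, "n_start") <- as.integer(n_found_at_start)
  out
}

#' Articles screened when a recall fraction is reached
#'
#' @param trajectory a [recall_trajectory()].
#' @param R recall fraction in `(0, 1]` of the trajectory's final count.
#' @return smallest `n_screened` at which `ceiling(R * n_final)` finals
#'   were found; 0 if already satisfied at the start, `NA` if never.
#' @export
screened_at_recall <- function(trajectory, R) {
  if (R <= 0 || R > 1) stop_contract("R must lie in (0, 1]")
  n_final <- attr(trajectory, "n_final")
  target <- ceiling(R * n_final)
  if (target <= (attr(trajectory, "n_start") %||% 0L)) return(0L)
  hit <- which(trajectory$n_found >= target)
  if (length(hit) == 0) return(NA_integer_)
  trajectory$n_screened[hit[1]]
}

#' Screened fraction of the corpus
#'
#' @param n_screened articles screened.
#' @param n_total corpus size (N > 0).
#' @return percent with 2 decimals (half away from zero).
#' @export
screened_fraction <- function(n_screened, n_total) {
  if (n_total <= 0) stop_contract("n_total must be positive")
  if (n_screened < 0 || n_screened > n_total) {
    stop_contract("n_screened must lie in [0, n_total]")
  }
  round_half_up(n_screened / n_total * 100, 2)
}

#' Time and cost savings of tool-assisted screening
#'
#' Converts screening hours under the manual and tool-assisted process
#' into full-time-equivalent days and monetary cost. Currency is rounded
#' to whole units and days to 2 decimals, the precision such figures are
#' conventionally reported at.
#'
#' @param hours_manual,hours_tool screening hours under each process.
#' @param rate hourly cost (currency/hour).
#' @param fte_hours_per_day hours in one full-time-equivalent day
#'   (default 7.5).
#' @return a `savings_report` list: `hours_manual`, `hours_tool`, `rate`,
#'   `fte_hours_per_day`, `cost_manual`, `cost_tool`, `cost_saving`,
#'   `fte_days_manual`, `fte_days_tool`, `fte_days_saved`.
#' @export
workload_savings <- function(hours_manual, hours_tool, rate,
                             fte_hours_per_day = 7.5) {
  if (any(c(hours_manual, hours_tool, rate) < 0) || fte_hours_per_day <= 0) {
    stop_contract("hours and rate must be non-negative, fte_hours_per_day positive")
  }
  cost_manual <- round_half_up(hours_manual * rate)
  cost_tool <- round_half_up(hours_tool * rate)
  structure(
    list(
      hours_manual = hours_manual, hours_tool = hours_tool, rate = rate,
      fte_hours_per_day = fte_hours_per_day,
      cost_manual = cost_manual, cost_tool = cost_tool,
      cost_saving = cost_manual - cost_tool,
      fte_days_manual = round_half_up(hours_manual / fte_hours_per_day, 2),
      fte_days_tool = round_half_up(hours_tool / fte_hours_per_day, 2),
      fte_days_saved = round_half_up((hours_manual - hours_tool) / fte_hours_per_day, 2)
    ),
    class = "savings_report"
  )
}

#' @export
print.savings_report <- function(x, ...) {
  cat(sprintf(
    "<savings_report> %g h -> %g h: cost %g -> %g (saving %g); %.2f -> %.2f FTE days (saved %.2f)\n",
    x$hours_manual, x$hours_tool, x$cost_manual, x$cost_tool, x$cost_saving,
    x$fte_days_manual, x$fte_days_tool, x$fte_days_saved))
  invisible(x)
}

#' Screening throughput
#'
#' @param n_screened articles screened.
#' @param hours total screening hours (> 0).
#' @param fte_hours_per_day hours per FTE day (default 7.5).
#' @param days_elapsed optional calendar days, for a per-calendar-day rate.
#' @return list with `per_hour`, `per_fte_day` and `per_day` (NA when
#'   `days_elapsed` is missing), each rendered to 1 decimal.
#' @export
screening_rate <- function(n_screened, hours, fte_hours_per_day = 7.5,
                           days_elapsed = NULL) {
  if (hours <= 0) stop_contract("hours must be positive")
  if (n_screened < 0) stop_contract("n_screened must be non-negative")
  list(
    per_hour = round_half_up(n_screened / hours, 1),
    per_fte_day = round_half_up(n_screened / (hours / fte_hours_per_day), 1),
    per_day = if (is.null(days_elapsed)) NA_real_ else
      round_half_up(n_screened / days_elapsed, 1)
  )
}
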