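#' Weekly airborne pollen index
#'
#' Sums daily pollen concentrations into consecutive fixed 7-day
#' windows.  The anchor defaults to the Monday on or before the first
#' observation; weeks run from the anchor to the last observed date.
#' Days missing from a window contribute 0 and the window is flagged
#' incomplete.
#'
#' @param series A `pollen_series` (or data.frame `date`, `count`).
#' @param week_anchor Optional date starting the first week.
#' @return An object of class `"weekly_pollen_index"`: a data.frame with
#'   `week_start`, `index` (pollen day/m3 summed over the week),
#'   `days_observed` and `complete`.
#' @export
weekly_pollen_index <- function(series, week_anchor = NULL) {
  series <- as_pollen_series(series)
  if (nrow(series) == 0) stop("empty pollen series", call. = FALSE)
  if (is.null(week_anchor)) {
    first <- min(series$date)
    # weekday: 0 = Monday
    wd <- (as.integer(format(first, "%u")) - 1L)
    week_anchor <- first - wd
  } else {
    week_anchor <- as.Date(week_anchor)
    if (week_anchor > min(series$date)) {
      stop("`week_anchor` must be on or before the first observation",
           call. = FALSE)
    }
  }
  week_idx <- as.integer(floor(as.numeric(series$date - week_anchor) / 7))
  n_weeks <- max(week_idx) + 1L
  index <- numeric(n_weeks)
  days <- integer(n_weeks)
  agg_i <- tapply(series$count, week_idx, sum)
  agg_n <- tapply(series$count, week_idx, length)
  slot <- as.integer(names(agg_i)) + 1L
  index[slot] <- as.numeric(agg_i)
  days[slot] <- as.integer(agg_n)
  out <- data.frame(week_start = week_anchor + 7 * (seq_len(n_weeks) - 1L),
                    index = index, days_observed = days,
                    complete = days == 7L)
  class(out) <- c("weekly_pollen_index", "data.frame")
  out
}

#' Peak pollen week
#'
#' The week with the highest pollen index; ties are broken by the
#' earliest week and reported.
#'
#' @param weekly A [weekly_pollen_index()] result.
#' @return List with `week_start`, `index` and logical `tie`.
#' @export
peak_week <- function(weekly) {
  stopifnot(inherits(weekly, "weekly_pollen_index"), nrow(weekly) >= 1)
  top <- max(weekly$index)
  at <- which(weekly$index == top)
  list(week_start = weekly$week_start[at[1]], index = top,
       tie = length(at) > 1)
}

#' Join full-flowering map area with the weekly pollen curve
#'
#' For each mapped date, pairs the full-flowering area fraction with
#' the pollen index of the week containing that date, enabling the
#' qualitative comparison of which areas contribute most to the pollen
#' curve.  Dates outside the pollen-series span are kept but flagged.
#'
#' @param masks Either a named list of [classify_full_flowering()]
#'   masks (names are ISO dates) or a data.frame with columns `date`
#'   and `area_fraction`.
#' @param weekly A [weekly_pollen_index()] result.
#' @return A data.frame `date`, `area_fraction`, `week_start`,
#'   `pollen_index`, `in_span`.
#' @export
flowering_pollen_table <- function(masks, weekly) {
  stopifnot(inherits(weekly, "weekly_pollen_index"))
  if (is.data.frame(masks)) {
    tab <- data.frame(date = as.Date(masks$date),
                      area_fraction = as.numeric(masks$area_fraction))
  } else {
    if (length(masks) == 0) {
      return(data.frame(date = as.Date(character(0)),
                        area_fraction = numeric(0),
                        week_start = as.Date(character(0)),
                        pollen_index = numeric(0), in_span = logical(0)))
    }
    stopifnot(!is.null(names(masks)))
    tab <- data.frame(
      date = as.Date(names(masks)),
      area_fraction = vapply(masks, function(m) m$area_fraction,
                             numeric(1)))
  }
  anchor <- weekly$week_start[1]
  span_end <- weekly$week_start[nrow(weekly)] + 6
  idx <- as.integer(floor(as.numeric(tab$date - anchor) / 7)) + 1L
  in_span <- idx >= 1 & idx <= nrow(weekly) & tab$date <= span_end
  out <- data.frame(
    date = tab$date, area_fraction = tab$area_fraction,
    week_start = as.Date(ifelse(in_span, weekly$week_start[idx], NA),
                         origin = "1970-01-01"),
    pollen_index = ifelse(in_span, weekly$index[idx], NA_real_),
    in_span = in_span)
  rownames(out) <- NULL
  out
}
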