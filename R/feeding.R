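# Feeder event-log feature extraction: per animal-day summaries, pen-relative
# normalization, and per-phase aggregation.

#' Study origin date
#'
#' Study day 1 corresponds to 2022-06-01 (UTC); timestamps are converted to
#' study days against this origin when no explicit `day` column is present.
#' @return a Date.
#' @export
study_origin_date <- function() as.Date("2022-05-31")

slot_metric_cols <- function(nms) grep("^slot[1-6]_", nms, value = TRUE)

#' Per animal-day feeding summaries
#'
#' Aggregates raw feeder sessions into daily metrics: total intake (g),
#' number of visits, total and median session duration (s), feed rate
#' (g/s), and time spent in six 4-hour slots, in seconds and as a
#' percentage of the day's feeding time. Slots are anchored at
#' `slot_anchor_hour` (default 02:00), so slot 3 is exactly the
#' 10:00-13:59 window. Sessions spanning a slot boundary are split
#' pro-rata by time; a session is attributed to the calendar day it starts.
#' Rows with negative duration or intake are rejected with a warning.
#'
#' @param events data.frame with animal_id, start_time (POSIXct), duration_s,
#'   intake_g (see [generate_feeding_events()]).
#' @param slot_anchor_hour first slot boundary hour (default 2).
#' @return data.frame, one row per animal-day: animal_id, day, intake_g,
#'   n_visits, total_duration_s, median_session_s, feed_rate_g_per_s,
#'   slot1_s..slot6_s, slot1_pct..slot6_pct.
#' @export
daily_summaries <- function(events, slot_anchor_hour = 2L) {
  assert_has_cols(events, c("animal_id", "start_time", "duration_s",
                            "intake_g"))
  bad <- events$duration_s <= 0 | events$intake_g < 0
  if (any(bad)) {
    warning(sum(bad), " event(s) with non-positive duration or negative ",
            "intake rejected")
    events <- events[!bad, , drop = FALSE]
  }
  if (!nrow(events)) stop_config("no valid feeding events")
  dt <- data.table::as.data.table(events)
  if (!"day" %in% names(dt)) {
    dt$day <- as.integer(as.Date(dt$start_time, tz = "UTC") -
                           study_origin_date())
  }
  # seconds since midnight of the attributed day
  t0 <- as.numeric(dt$start_time) -
    as.numeric(as.POSIXct(as.Date(dt$start_time, tz = "UTC"), tz = "UTC"))
  t1 <- t0 + dt$duration_s
  a <- slot_anchor_hour * 3600
  W <- 4 * 3600
  k0 <- floor((t0 - a) / W)
  k1 <- floor((t1 - a - 1e-9) / W)
  n_pieces <- pmax(k1 - k0, 0) + 1L

  idx <- rep.int(seq_len(nrow(dt)), n_pieces)
  joff <- sequence(n_pieces) - 1L
  kk <- k0[idx] + joff
  piece_start <- pmax(t0[idx], a + kk * W)
  piece_end <- pmin(t1[idx], a + (kk + 1) * W)
  slot <- (kk %% 6) + 1L
  pieces <- data.table::data.table(
    animal_id = dt$animal_id[idx], day = dt$day[idx],
    slot = slot, secs = piece_end - piece_start)
  slot_tab <- data.table::dcast(
    pieces, animal_id + day ~ slot, value.var = "secs",
    fun.aggregate = sum, fill = 0)
  for (s in 1:6) {
    nm <- as.character(s)
    if (!nm %in% names(slot_tab)) slot_tab[[nm]] <- 0
  }
  data.table::setnames(slot_tab, as.character(1:6), paste0("slot", 1:6, "_s"))

  duration_s <- intake_g <- NULL  # data.table NSE
  daily <- dt[, list(
    intake_g = sum(intake_g),
    n_visits = .N,
    total_duration_s = sum(duration_s),
    median_session_s = as.numeric(median(duration_s))
  ), by = c("animal_id", "day")]
  daily <- merge(daily, slot_tab, by = c("animal_id", "day"))
  daily$feed_rate_g_per_s <- daily$intake_g / daily$total_duration_s
  for (s in 1:6) {
    daily[[paste0("slot", s, "_pct")]] <-
      100 * daily[[paste0("slot", s, "_s")]] / daily$total_duration_s
  }
  data.table::setDF(daily)
  daily[order(daily$animal_id, daily$day), ]
}

normalized_metrics <- function(daily) {
  c("intake_g", "n_visits", "total_duration_s", "median_session_s",
    "feed_rate_g_per_s", grep("_pct$", names(daily), value = TRUE))
}

#' Pen-relative normalization of daily metrics
#'
#' Each metric value is divided by the median of that metric across all
#' animals of the same pen on the same day, giving age- and
#' environment-independent relative measures (relative value 1 = pen
#' median). Pen membership is evaluated per day, so normalization is aware
#' of mixing events. A pen-day median of 0 yields NA (flagged missing, not
#' infinite).
#'
#' @param daily a [daily_summaries()] result.
#' @param roster either a `cohort` (pen membership resolved per day via the
#'   mixing plan) or a data.frame with animal_id and pen_id (static pens).
#' @return `daily` with a `pen_id` column and `rel_<metric>` columns.
#' @export
normalize_by_pen <- function(daily, roster) {
  dt <- data.table::as.data.table(daily)
  if (inherits(roster, "cohort")) {
    pens <- data.table::rbindlist(lapply(
      sort(unique(dt$day)),
      function(d) cbind(pen_assignment(roster, d), day = d)))
    dt <- merge(dt, pens, by = c("animal_id", "day"), all.x = TRUE)
  } else {
    assert_has_cols(roster, c("animal_id", "pen_id"))
    dt$pen_id <- roster$pen_id[match(dt$animal_id, roster$animal_id)]
  }
  if (anyNA(dt$pen_id)) {
    stop_config("animals without pen membership: ",
                paste(unique(dt$animal_id[is.na(dt$pen_id)]), collapse = ", "))
  }
  for (m in normalized_metrics(dt)) {
    med <- stats::ave(dt[[m]], dt$pen_id, dt$day, FUN = midpoint_median)
    rel <- dt[[m]] / med
    rel[!is.finite(rel)] <- NA_real_
    dt[[paste0("rel_", m)]] <- rel
  }
  data.table::setDF(dt)
  dt
}

#' Aggregate daily metrics per animal and phase
#'
#' For every animal and experimental phase, the median over days of each
#' daily metric is taken, except time-slot metrics which use the mean over
#' days. The daily median session duration is aggregated as the median of
#' daily medians. Both absolute and relative (`rel_`) columns are
#' aggregated. Animals with no data in a phase are simply absent from that
#' phase's rows (explicit missing).
#'
#' @param daily a [daily_summaries()] (optionally [normalize_by_pen()])
#'   result.
#' @param config a [cohort_config()], or an integer vector of mixing days
#'   defining the phase boundaries.
#' @return data.frame, one row per animal-phase, with `n_days` and the
#'   aggregated metrics.
#' @export
phase_aggregate <- function(daily, config) {
  mix_days <- if (inherits(config, "cohort_config")) config$mix_days else
    as.integer(config)
  dt <- data.table::as.data.table(daily)
  dt$phase <- findInterval(dt$day, mix_days) + 1L
  metrics <- setdiff(names(dt)[vapply(dt, is.numeric, TRUE)],
                     c("day", "phase"))
  slotty <- grepl("^(rel_)?slot[1-6]_", metrics)
  agg <- dt[, {
    vals <- lapply(seq_along(metrics), function(i) {
      v <- .SD[[metrics[i]]]
      if (slotty[i]) mean(v, na.rm = TRUE)
      else as.numeric(median(v, na.rm = TRUE))
    })
    names(vals) <- metrics
    c(list(n_days = .N), vals)
  }, by = c("animal_id", "phase"), .SDcols = metrics]
  data.table::setDF(agg)
  agg[order(agg$animal_id, agg$phase), ]
}
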