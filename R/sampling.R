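#' Scan-sampling scheme
#'
#' @param interval_s Interval between scans, seconds.
#' @param window_s Length of the observation window ending at each scan
#'   time, seconds (0 = truly instantaneous).  Must be shorter than the
#'   interval.
#' @param mode `"instantaneous"`: an animal's state is read off at the scan
#'   instant.  `"window_majority"`: the animal is counted if visible for at
#'   least half of the window, and scored with the behavior occupying the
#'   largest share of the window (ties broken by the behavior active at the
#'   scan instant).
#' @param offset_s Shift applied to all scan times; by default scans sit at
#'   the end of each interval (`k * interval_s`).
#' @return A list of class `"sampling_scheme"`.
#' @export
sampling_scheme <- function(interval_s, window_s = 0,
                            mode = c("instantaneous", "window_majority"),
                            offset_s = 0) {
  assert_number(interval_s, "interval_s", lower = 1e-9)
  assert_number(window_s, "window_s", lower = 0)
  if (window_s >= interval_s) stop_scanopt("`window_s` must be < `interval_s`")
  mode <- match.arg(mode)
  structure(list(interval_s = interval_s, window_s = window_s, mode = mode,
                 offset_s = offset_s),
            class = "sampling_scheme")
}

#' Scan times for a session
#'
#' End-of-interval convention: scans at `k * interval_s` for
#' `k = 1, ..., floor(duration_s / interval_s)`, e.g. 12 scans for a 2-h
#' session at a 10-min interval.  An `offset_s` shifts the grid while
#' keeping times inside `(0, duration_s]`.
#'
#' @param duration_s Session length, seconds.
#' @param interval_s Sampling interval, seconds.
#' @param offset_s Grid shift, seconds.
#' @return Numeric vector of scan times (possibly empty, with a warning,
#'   when the interval exceeds the session length).
#' @examples
#' length(scan_times(7200, 600))  # 12
#' length(scan_times(7200, 300))  # 24
#' @export
scan_times <- function(duration_s, interval_s, offset_s = 0) {
  assert_number(duration_s, "duration_s", lower = 1e-9)
  assert_number(interval_s, "interval_s", lower = 1e-9)
  k <- seq_len(max(0, floor((duration_s - offset_s) / interval_s + 1e-9)))
  times <- offset_s + k * interval_s
  times <- times[times > 0 & times <= duration_s + 1e-9]
  if (!length(times)) {
    warning("interval longer than session: no scans", call. = FALSE)
  }
  times
}

#' Scan-sample a continuous timeline
#'
#' Applies a [sampling_scheme()] to a [session_timeline()], producing the
#' per-scan behavior counts of visible animals that a human observer
#' scanning the pen would record.  With a positive window the window is
#' truncated at session start for the first scan.
#'
#' @param timeline A [session_timeline()].
#' @param scheme A [sampling_scheme()] (or a bare interval in seconds).
#' @param ethogram Optional [ethogram()] fixing the behavior column set (so
#'   behaviors never seen still appear with zero counts); defaults to the
#'   behaviors present in the timeline.
#' @return A [scan_table()].
#' @export
scan_sample <- function(timeline, scheme, ethogram = NULL) {
  stopifnot(inherits(timeline, "session_timeline"))
  if (is.numeric(scheme)) scheme <- sampling_scheme(scheme)
  stopifnot(inherits(scheme, "sampling_scheme"))
  behaviors <- if (is.null(ethogram)) {
    sort(unique(timeline$bouts$behavior))
  } else {
    ethogram$behavior
  }
  times <- scan_times(timeline$duration_s, scheme$interval_s, scheme$offset_s)
  counts <- matrix(0L, length(times), length(behaviors),
                   dimnames = list(NULL, behaviors))
  visible_n <- integer(length(times))
  w <- scheme$window_s
  use_window <- scheme$mode == "window_majority" && w > 0

  for (a in timeline$animals) {
    b <- timeline$bouts[timeline$bouts$animal_id == a, ]
    v <- timeline$visibility[timeline$visibility$animal_id == a, ]
    b <- b[order(b$start_s), ]; v <- v[order(v$start_s), ]
    beh_at <- b$behavior[findInterval(times, b$start_s)]
    vis_at <- v$visible[findInterval(times, v$start_s)]
    for (j in seq_along(times)) {
      t <- times[j]
      if (use_window) {
        lo <- max(0, t - w)
        span <- t - lo
        ov_v <- pmax(0, pmin(v$end_s, t) - pmax(v$start_s, lo))
        if (sum(ov_v[v$visible]) < span / 2) next
        ov_b <- pmax(0, pmin(b$end_s, t) - pmax(b$start_s, lo))
        tot_b <- tapply(ov_b, b$behavior, sum)
        best <- names(tot_b)[tot_b > max(tot_b) - 1e-9]
        beh <- if (length(best) > 1 && beh_at[j] %in% best) beh_at[j] else best[1]
      } else {
        if (!vis_at[j]) next
        beh <- beh_at[j]
      }
      visible_n[j] <- visible_n[j] + 1L
      counts[j, beh] <- counts[j, beh] + 1L
    }
  }
  scans <- dplyr::bind_cols(
    tibble::tibble(time_s = times, visible_count = visible_n),
    tibble::as_tibble(counts)
  )
  scan_table(timeline$session_id, scheme$interval_s, scans,
             window_s = w, group = timeline$group,
             replicate = timeline$replicate, day = timeline$day)
}

#' Occurrence from a scan table
#'
#' The occurrence of a behavior under scan sampling is the mean, over scans,
#' of the percentage of visible animals engaged in it.  Scans at which no
#' animal was visible contribute an undefined 0/0 proportion and are dropped
#' from the mean (with a message).
#'
#' @param table A [scan_table()].
#' @param method Method label attached to the records; defaults to the
#'   interval's label (e.g. `"10min"`).
#' @return A tibble of occurrence records: `session_id`, `group`,
#'   `replicate`, `day`, `method`, `behavior`, `value` (percent, 0-100).
#' @export
occurrence_from_scans <- function(table,
                                  method = interval_label(table$interval_s)) {
  stopifnot(inherits(table, "scan_table"))
  sc <- table$scans
  if (!nrow(sc)) stop_scanopt("scan table has no scans")
  keep <- sc$visible_count > 0
  if (!any(keep)) stop_scanopt("no scan has a visible animal")
  if (any(!keep)) {
    message(sum(!keep), " scan(s) with zero visible animals dropped")
  }
  sc <- sc[keep, ]
  prop <- 100 * as.matrix(sc[table$behaviors]) / sc$visible_count
  tibble::tibble(
    session_id = table$session_id, group = table$group,
    replicate = table$replicate, day = table$day, method = method,
    behavior = table$behaviors, value = unname(colMeans(prop))
  )
}

#' Occurrence from continuous recording
#'
#' The continuous (gold-standard) occurrence of a behavior is the percentage
#' of visible animal-time spent in it: 100 x visible animal-seconds in the
#' behavior / total visible animal-seconds.  Values over all behaviors sum
#' to 100.
#'
#' @param timeline A [session_timeline()].
#' @param ethogram Optional [ethogram()] fixing the behavior set (behaviors
#'   never performed get value 0).
#' @return A tibble of occurrence records with `method = "continuous"`.
#' @export
occurrence_continuous <- function(timeline, ethogram = NULL) {
  stopifnot(inherits(timeline, "session_timeline"))
  behaviors <- if (is.null(ethogram)) {
    sort(unique(timeline$bouts$behavior))
  } else {
    ethogram$behavior
  }
  secs <- setNames(numeric(length(behaviors)), behaviors)
  total <- 0
  b_idx <- split(seq_len(nrow(timeline$bouts)), timeline$bouts$animal_id)
  v_idx <- split(seq_len(nrow(timeline$visibility)),
                 timeline$visibility$animal_id)
  for (a in timeline$animals) {
    b <- timeline$bouts[b_idx[[a]], ]
    v <- timeline$visibility[v_idx[[a]], ]
    b <- b[order(b$start_s), ]; v <- v[order(v$start_s), ]
    # refine into segments constant in both behavior and visibility
    breaks <- sort(unique(c(b$start_s, b$end_s, v$start_s, v$end_s)))
    st <- breaks[-length(breaks)]
    dur <- breaks[-1] - st
    beh <- b$behavior[findInterval(st, b$start_s)]
    vis <- v$visible[findInterval(st, v$start_s)]
    if (any(vis)) {
      agg <- tapply(dur[vis], beh[vis], sum)
      secs[names(agg)] <- secs[names(agg)] + agg
      total <- total + sum(dur[vis])
    }
  }
  if (total <= 0) stop_scanopt("session has no visible animal-time")
  tibble::tibble(
    session_id = timeline$session_id, group = timeline$group,
    replicate = timeline$replicate, day = timeline$day,
    method = "continuous", behavior = behaviors,
    value = unname(100 * secs / total)
  )
}
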