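#' Construct a scan table
#'
#' A scan table holds, for one session sampled at one interval, the number of
#' visible animals engaged in each behavior at every scan.  Each visible
#' animal is assigned exactly one behavior, so per scan the behavior counts
#' sum to `visible_count`.
#'
#' @param session_id Session identifier.
#' @param interval_s Sampling interval in seconds.
#' @param scans Tibble with columns `time_s`, `visible_count` and one
#'   non-negative integer column per behavior.  Scan times must be strictly
#'   increasing.  May have zero rows.
#' @param window_s Observation-window length in seconds (0 = instantaneous).
#' @param group,replicate,day Session metadata carried from the timeline.
#' @return A list of class `"scan_table"`.
#' @seealso [scan_sample()], [read_scan_table()]
#' @export
scan_table <- function(session_id, interval_s, scans, window_s = 0,
                       group = "A", replicate = "1", day = 1L) {
  assert_number(interval_s, "interval_s", lower = 1e-9)
  assert_number(window_s, "window_s", lower = 0)
  scans <- tibble::as_tibble(scans)
  if (!all(c("time_s", "visible_count") %in% names(scans))) {
    stop_scanopt("`scans` needs columns time_s, visible_count")
  }
  behaviors <- setdiff(names(scans), c("time_s", "visible_count"))
  if (nrow(scans)) {
    if (is.unsorted(scans$time_s, strictly = TRUE)) {
      stop_scanopt("scan times must be strictly increasing")
    }
    counts <- as.matrix(scans[behaviors])
    if (length(behaviors) && any(counts < 0)) {
      stop_scanopt("behavior counts must be non-negative")
    }
    tot <- if (length(behaviors)) rowSums(counts) else rep(0, nrow(scans))
    off <- which(tot != scans$visible_count)
    if (length(off)) {
      stop_scanopt(sprintf(
        "scan at t=%g: behavior counts sum to %g but visible_count is %g",
        scans$time_s[off[1]], tot[off[1]], scans$visible_count[off[1]]))
    }
  }
  structure(
    list(session_id = as.character(session_id), interval_s = interval_s,
         window_s = window_s, group = as.character(group),
         replicate = as.character(replicate), day = as.integer(day),
         behaviors = behaviors, scans = scans),
    class = "scan_table"
  )
}

#' @export
print.scan_table <- function(x, ...) {
  cat(sprintf("<scan_table> %s  interval=%s  %d scans, %d behaviors\n",
              x$session_id, interval_label(x$interval_s), nrow(x$scans),
              length(x$behaviors)))
  invisible(x)
}

#' Write / read a scan table as CSV
#'
#' One row per scan; metadata (`session_id`, `interval_s`, `window_s`,
#' `group`, `replicate`, `day`) repeated per row so the file is
#' self-contained.  `read_scan_table(write_scan_table(x, p))` reproduces `x`.
#'
#' @param table A [scan_table()].
#' @param path CSV path.
#' @return `write_scan_table()` returns `path` invisibly;
#'   `read_scan_table()` returns a [scan_table()].
#' @export
write_scan_table <- function(table, path) {
  stopifnot(inherits(table, "scan_table"))
  meta <- tibble::tibble(
    session_id = table$session_id, interval_s = table$interval_s,
    window_s = table$window_s, group = table$group,
    replicate = table$replicate, day = table$day
  )
  df <- if (nrow(table$scans)) {
    dplyr::bind_cols(meta[rep(1, nrow(table$scans)), ], table$scans)
  } else { # keep header (and hence behavior set) for empty tables
    dplyr::bind_cols(meta[0, ], table$scans)
  }
  utils::write.csv(df, path, row.names = FALSE)
  if (!nrow(df)) { # write.csv drops nothing, but record metadata in a comment
    lines <- readLines(path)
    writeLines(c(sprintf("#scanopt %s,%g,%g,%s,%s,%d", table$session_id,
                         table$interval_s, table$window_s, table$group,
                         table$replicate, table$day), lines), path)
  }
  invisible(path)
}

#' @rdname write_scan_table
#' @export
read_scan_table <- function(path) {
  first <- readLines(path, n = 1)
  meta0 <- NULL
  if (startsWith(first, "#scanopt ")) {
    meta0 <- strsplit(sub("^#scanopt ", "", first), ",")[[1]]
  }
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  meta_cols <- c("session_id", "interval_s", "window_s", "group",
                 "replicate", "day")
  if (nrow(df)) {
    scan_table(df$session_id[1], df$interval_s[1],
               df[setdiff(names(df), meta_cols)], window_s = df$window_s[1],
               group = df$group[1], replicate = df$replicate[1],
               day = df$day[1])
  } else {
    if (is.null(meta0)) stop_scanopt("empty scan-table CSV lacks metadata header")
    scans <- tibble::as_tibble(df[setdiff(names(df), meta_cols)])
    scan_table(meta0[1], as.numeric(meta0[2]), scans,
               window_s = as.numeric(meta0[3]), group = meta0[4],
               replicate = meta0[5], day = as.integer(meta0[6]))
  }
}
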