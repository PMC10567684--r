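#' Construct a continuous-session timeline
#'
#' A `session_timeline` is the continuous (gold-standard) record of one
#' observation session: for every animal, behavior bouts that tile the whole
#' session, plus visibility intervals saying when the animal could actually
#' be seen.  Time is in seconds from session start; intervals are half-open
#' `[start_s, end_s)` so the tiling is unambiguous.
#'
#' @param session_id Session identifier.
#' @param duration_s Session length in seconds.
#' @param bouts Tibble/data frame with columns `animal_id`, `behavior`,
#'   `start_s`, `end_s`.  Per animal the bouts must tile `[0, duration_s]`
#'   with no gaps or overlaps.  Adjacent bouts of the same behavior are
#'   merged.
#' @param visibility Tibble with columns `animal_id`, `start_s`, `end_s`,
#'   `visible` (logical), tiling `[0, duration_s]` per animal.  Default:
#'   every animal visible throughout.
#' @param group,replicate Group (e.g. genotype) and replicate (e.g. pen)
#'   labels carried through to downstream analyses.
#' @param day Integer sampling-day covariate.
#' @param ethogram Optional [ethogram()]; when supplied, bout behaviors are
#'   resolved through its alias table and checked for membership.
#'
#' @return A list of class `"session_timeline"` with elements `session_id`,
#'   `group`, `replicate`, `day`, `duration_s`, `animals`, `bouts`,
#'   `visibility`.
#' @seealso [read_timeline()], [simulate_flock()]
#' @export
session_timeline <- function(session_id, duration_s, bouts, visibility = NULL,
                             group = "A", replicate = "1", day = 1L,
                             ethogram = NULL) {
  assert_number(duration_s, "duration_s", lower = 1e-9)
  bouts <- tibble::as_tibble(bouts)
  need <- c("animal_id", "behavior", "start_s", "end_s")
  if (!all(need %in% names(bouts))) {
    stop_scanopt("`bouts` needs columns ", paste(need, collapse = ", "))
  }
  bouts$animal_id <- as.character(bouts$animal_id)
  bouts$behavior <- as.character(bouts$behavior)
  if (!is.null(ethogram)) {
    bouts$behavior <- resolve_behavior_names(bouts$behavior, ethogram)
  }
  animals <- sort(unique(bouts$animal_id))
  if (is.null(visibility)) {
    visibility <- tibble::tibble(animal_id = animals, start_s = 0,
                                 end_s = duration_s, visible = TRUE)
  }
  visibility <- tibble::as_tibble(visibility)
  visibility$animal_id <- as.character(visibility$animal_id)
  visibility$visible <- as.logical(visibility$visible)

  bouts <- merge_adjacent(bouts, "behavior")
  visibility <- merge_adjacent(visibility, "visible")
  check_tiling(bouts, duration_s, what = "bout")
  check_tiling(visibility, duration_s, what = "visibility interval")

  structure(
    list(session_id = as.character(session_id), group = as.character(group),
         replicate = as.character(replicate), day = as.integer(day),
         duration_s = duration_s, animals = animals,
         bouts = bouts, visibility = visibility),
    class = "session_timeline"
  )
}

#' @export
print.session_timeline <- function(x, ...) {
  cat(sprintf(
    "<session_timeline> %s  group=%s rep=%s day=%d  %gs, %d animals, %d bouts\n",
    x$session_id, x$group, x$replicate, x$day, x$duration_s,
    length(x$animals), nrow(x$bouts)))
  invisible(x)
}

# merge rows whose `key` value repeats across adjacent intervals of one animal
merge_adjacent <- function(seg, key) {
  o <- order(seg$animal_id, seg$start_s)
  seg <- seg[o, ]
  n <- nrow(seg)
  if (n == 0) return(seg[c("animal_id", key, "start_s", "end_s")])
  kv <- seg[[key]]
  new_run <- c(TRUE, seg$animal_id[-1] != seg$animal_id[-n] |
                 kv[-1] != kv[-n] |
                 abs(seg$start_s[-1] - seg$end_s[-n]) > 1e-9)
  run <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1] - 1L, n)
  out <- tibble::tibble(
    animal_id = seg$animal_id[first],
    start_s = seg$start_s[first],
    end_s = seg$end_s[last]
  )
  out[[key]] <- kv[first]
  out[c("animal_id", key, "start_s", "end_s")]
}

# per-animal half-open tiling of [0, duration]: no overlap, no gap
check_tiling <- function(seg, duration_s, what = "bout") {
  if (any(seg$start_s >= seg$end_s)) {
    bad <- seg[seg$start_s >= seg$end_s, ][1, ]
    stop_scanopt(sprintf("empty or inverted %s for animal %s at t=%g",
                         what, bad$animal_id, bad$start_s))
  }
  if (any(seg$start_s < -1e-9) || any(seg$end_s > duration_s + 1e-9)) {
    stop_scanopt(sprintf("%ss must lie within [0, %g]", what, duration_s))
  }
  o <- order(seg$animal_id, seg$start_s)
  seg <- seg[o, ]
  n <- nrow(seg)
  new_animal <- c(TRUE, seg$animal_id[-1] != seg$animal_id[-n])
  last_of_animal <- c(new_animal[-1], TRUE)
  bad <- which(new_animal & abs(seg$start_s) > 1e-9)
  if (length(bad)) {
    stop_scanopt(sprintf("gap before first %s for animal %s (t=0)", what,
                         seg$animal_id[bad[1]]))
  }
  bad <- which(last_of_animal & abs(seg$end_s - duration_s) > 1e-9)
  if (length(bad)) {
    stop_scanopt(sprintf("%ss for animal %s end at t=%g, not duration %g",
                         what, seg$animal_id[bad[1]], seg$end_s[bad[1]],
                         duration_s))
  }
  if (n > 1) {
    d <- seg$start_s[-1] - seg$end_s[-n]
    within <- !new_animal[-1]
    if (any(within & d < -1e-9)) {
      i <- which(within & d < -1e-9)[1]
      stop_scanopt(sprintf("overlapping %ss for animal %s at t=%g",
                           what, seg$animal_id[i + 1], seg$start_s[i + 1]))
    }
    if (any(within & d > 1e-9)) {
      i <- which(within & d > 1e-9)[1]
      stop_scanopt(sprintf("gap between %ss for animal %s at t=%g",
                           what, seg$animal_id[i], seg$end_s[i]))
    }
  }
  invisible(seg)
}

#' Read a continuous timeline from CSV
#'
#' The CSV holds one row per segment during which both behavior and
#' visibility are constant: columns `session_id`, `animal_id`, `behavior`,
#' `start_s`, `end_s`, `visible` (0/1), plus optional per-session metadata
#' columns `group`, `replicate`, `day` and `duration_s` (constant within the
#' file).  Adjacent same-behavior segments are merged back into bouts and
#' adjacent same-visibility segments into visibility intervals.
#'
#' @param path CSV file path (comma-separated, `.` decimal, header required).
#' @param ethogram Optional [ethogram()] used to resolve behavior-name
#'   aliases and reject unknown behaviors.
#' @return A [session_timeline()].
#' @seealso [write_timeline()]
#' @export
read_timeline <- function(path, ethogram = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("session_id", "animal_id", "behavior", "start_s", "end_s", "visible")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_scanopt("timeline CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  if (length(unique(df$session_id)) != 1) {
    stop_scanopt("timeline CSV must contain exactly one session")
  }
  meta <- function(col, default) {
    if (col %in% names(df)) unique(df[[col]])[1] else default
  }
  duration <- if ("duration_s" %in% names(df)) unique(df$duration_s)[1] else max(df$end_s)
  session_timeline(
    session_id = df$session_id[1],
    duration_s = duration,
    bouts = df[c("animal_id", "behavior", "start_s", "end_s")],
    visibility = tibble::tibble(animal_id = as.character(df$animal_id),
                                start_s = df$start_s, end_s = df$end_s,
                                visible = df$visible != 0),
    group = meta("group", "A"), replicate = meta("replicate", "1"),
    day = meta("day", 1L), ethogram = ethogram
  )
}

#' Write a continuous timeline to CSV
#'
#' Inverse of [read_timeline()]: refines bouts and visibility intervals into
#' segments constant in both, one row each.
#'
#' @param timeline A [session_timeline()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeline <- function(timeline, path) {
  segs <- lapply(timeline$animals, function(a) {
    b <- timeline$bouts[timeline$bouts$animal_id == a, ]
    v <- timeline$visibility[timeline$visibility$animal_id == a, ]
    b <- b[order(b$start_s), ]; v <- v[order(v$start_s), ]
    breaks <- sort(unique(c(b$start_s, b$end_s, v$start_s, v$end_s)))
    st <- head(breaks, -1); en <- breaks[-1]
    tibble::tibble(
      session_id = timeline$session_id, animal_id = a,
      behavior = b$behavior[findInterval(st, b$start_s)],
      start_s = st, end_s = en,
      visible = as.integer(v$visible[findInterval(st, v$start_s)]),
      group = timeline$group, replicate = timeline$replicate,
      day = timeline$day, duration_s = timeline$duration_s
    )
  })
  utils::write.csv(dplyr::bind_rows(segs), path, row.names = FALSE)
  invisible(path)
}
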