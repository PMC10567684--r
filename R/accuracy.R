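# match two occurrence-record tibbles on (session, behavior)
match_records <- function(a, b, suffixes = c("_a", "_b")) {
  key <- c("session_id", "behavior")
  for (df in list(a, b)) {
    if (!all(c(key, "value") %in% names(df))) {
      stop_scanopt("occurrence records need columns session_id, behavior, value")
    }
  }
  j <- dplyr::inner_join(
    dplyr::select(a, dplyr::all_of(c(key, "value"))),
    dplyr::select(b, dplyr::all_of(c(key, "value"))),
    by = key, suffix = suffixes
  )
  j
}

#' Agreement metrics of a candidate method against continuous recording
#'
#' Pools matched (session, behavior) occurrence pairs and reports the
#' R-squared of the ordinary least-squares regression of the continuous
#' (gold-standard) values on the candidate values, the mean absolute error
#' and the root mean square error, all in percentage points.
#'
#' @param candidate Occurrence records for the candidate sampling method.
#' @param truth Occurrence records from continuous recording.
#' @return A list with `r2`, `mae`, `rmse` and `n` (matched pairs).
#' @seealso [select_reference()]
#' @export
reference_metrics <- function(candidate, truth) {
  j <- match_records(candidate, truth, c("_cand", "_true"))
  if (nrow(j) < 3) stop_scanopt("need at least 3 matched (session, behavior) pairs")
  err <- j$value_cand - j$value_true
  fit <- lm(value_true ~ value_cand, data = j)
  ss_tot <- sum((j$value_true - mean(j$value_true))^2)
  list(
    r2 = if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_,
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    n = nrow(j)
  )
}

#' Choose the reference sampling interval
#'
#' The reference ("best estimate of the true occurrences") is the candidate
#' winning a majority of the three criteria: highest R-squared, lowest MAE,
#' lowest RMSE.  Ties are resolved toward the shortest interval (with a
#' message), which is also the feasibility-minded choice.
#'
#' @param metrics A tibble/data frame with columns `method`, `r2`, `mae`,
#'   `rmse` and optionally `interval_s` (used for tie-breaking).
#' @return The chosen method label (character scalar).
#' @export
select_reference <- function(metrics) {
  metrics <- tibble::as_tibble(metrics)
  if (nrow(metrics) < 1) stop_scanopt("no candidate methods")
  if (nrow(metrics) == 1) return(metrics$method[1])
  wins <- integer(nrow(metrics))
  best <- function(x, maximize) which(abs(x - if (maximize) max(x) else min(x)) < 1e-12)
  for (w in list(best(metrics$r2, TRUE), best(metrics$mae, FALSE),
                 best(metrics$rmse, FALSE))) {
    wins[w] <- wins[w] + 1L
  }
  top <- which(wins == max(wins))
  if (length(top) > 1) {
    if ("interval_s" %in% names(metrics)) {
      top <- top[which.min(metrics$interval_s[top])]
    } else {
      top <- top[1]
    }
    message("reference selection tied; choosing shortest interval: ",
            metrics$method[top])
  }
  metrics$method[top]
}

#' Bin behaviors into occurrence categories
#'
#' Behaviors are classed by their mean occurrence under the reference
#' method: low (at or below `low_max` percent of visible animals per scan),
#' medium (above `low_max`, at or below `medium_max`) and high (above
#' `medium_max`).  Behaviors flagged `excluded_from_binning` in the
#' ethogram (e.g. a catch-all bucket) are skipped.
#'
#' @param occurrences Occurrence records for the reference method (one or
#'   more sessions per behavior; values are averaged per behavior).
#' @param ethogram Optional [ethogram()] supplying exclusion flags.
#' @param low_max,medium_max Category boundaries in percent; defaults 0.49
#'   and 3.50.
#' @return Tibble with `behavior`, `mean_value`, `category` (ordered factor
#'   low < medium < high).
#' @export
bin_behaviors <- function(occurrences, ethogram = NULL,
                          low_max = 0.49, medium_max = 3.50) {
  if (low_max <= 0 || medium_max <= low_max) {
    stop_scanopt("need 0 < low_max < medium_max")
  }
  means <- occurrences |>
    dplyr::group_by(.data$behavior) |>
    dplyr::summarise(mean_value = mean(.data$value), .groups = "drop")
  if (!is.null(ethogram)) {
    excl <- ethogram$behavior[ethogram$excluded_from_binning]
    means <- means[!means$behavior %in% excl, ]
  }
  means$category <- factor(
    ifelse(means$mean_value <= low_max, "low",
           ifelse(means$mean_value <= medium_max, "medium", "high")),
    levels = c("low", "medium", "high"), ordered = TRUE
  )
  means
}

#' Signed error scores of a test method against a reference
#'
#' Per matched (session, behavior) pair, `error = test - reference` in
#' percentage points, so a negative error means the test method (typically
#' the longer interval) underestimates the occurrence.
#'
#' @param test,reference Occurrence records.
#' @return Tibble with `session_id`, `behavior`, `method` (test label, if
#'   present), `error`.
#' @export
error_scores <- function(test, reference) {
  j <- match_records(test, reference, c("_test", "_ref"))
  unmatched <- dplyr::anti_join(test, j, by = c("session_id", "behavior"))
  if (nrow(unmatched)) {
    stop_scanopt(sprintf("unmatched record: session %s, behavior %s",
                         unmatched$session_id[1], unmatched$behavior[1]))
  }
  tibble::tibble(
    session_id = j$session_id, behavior = j$behavior,
    method = if ("method" %in% names(test)) test$method[1] else "test",
    error = j$value_test - j$value_ref
  )
}

#' Summarize error scores by occurrence category
#'
#' Mean signed error with a t-based confidence interval per occurrence
#' category (and per test method when several are present); a category
#' whose interval excludes zero indicates systematic over- or
#' under-estimation.
#'
#' @param errors Output of [error_scores()] (possibly several methods
#'   row-bound).
#' @param categories Output of [bin_behaviors()].
#' @param alpha Significance level; the CI has level `1 - alpha`.
#' @return Tibble with `method`, `category`, `n`, `mean_error`, `ci_low`,
#'   `ci_high`, `significant`.
#' @export
summarize_errors <- function(errors, categories, alpha = 0.05) {
  assert_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  j <- dplyr::inner_join(errors, categories[c("behavior", "category")],
                         by = "behavior")
  dropped <- setdiff(unique(errors$behavior), unique(j$behavior))
  if (length(dropped)) {
    warning("behavior(s) without category omitted: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  out <- j |>
    dplyr::group_by(.data$method, .data$category) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_error = mean(.data$error),
      se = sd(.data$error) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  small <- out$n < 2
  if (any(small)) {
    warning("category with fewer than 2 errors omitted", call. = FALSE)
    out <- out[!small, ]
  }
  tcrit <- qt(1 - alpha / 2, out$n - 1)
  out$ci_low <- out$mean_error - tcrit * out$se
  out$ci_high <- out$mean_error + tcrit * out$se
  out$significant <- out$ci_low > 0 | out$ci_high < 0
  dplyr::select(out, -"se")
}

#' Compare two paired error distributions (Wilcoxon signed-rank)
#'
#' Two-sided related-samples Wilcoxon signed-rank test on paired error
#' scores, e.g. the errors of two long intervals against the same
#' reference.  Zero differences are discarded (signed-rank convention); the
#' p-value is exact when 25 or fewer non-zero untied pairs remain, else a
#' normal approximation with continuity correction is used.
#'
#' @param errors_a,errors_b Paired numeric vectors of equal length.
#' @return List with `statistic` (V), `p_value`, `n_used`, `exact`.
#' @export
compare_error_distributions <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b)) {
    stop_scanopt("error vectors must be paired (equal length)")
  }
  d <- errors_a - errors_b
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero", call. = FALSE)
    return(list(statistic = NA_real_, p_value = 1, n_used = 0L, exact = TRUE))
  }
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    wilcox.test(d, mu = 0, exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_used = length(d), exact = exact)
}

#' Bland-Altman limits of agreement from bias and SD
#'
#' The 95% limits of agreement are the bias plus/minus `multiplier` (by
#' convention 1.96) standard deviations of the paired differences.
#'
#' @param bias Mean difference between the two methods.
#' @param sd_diff Standard deviation of the differences.
#' @param multiplier Width multiplier; 1.96 for 95% limits.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' loa_limits(-0.0003, 2.558)
#' @export
loa_limits <- function(bias, sd_diff, multiplier = 1.96) {
  c(lower = bias - multiplier * sd_diff, upper = bias + multiplier * sd_diff)
}

#' Bland-Altman comparison of two sampling methods
#'
#' Computes per-pair differences between matched occurrence records, the
#' bias (mean difference), the SD of the differences and the 95% limits of
#' agreement.  In `"raw"` mode the difference is `a - b` in percentage
#' points.  In `"percent"` mode the difference is expressed relative to the
#' reference method `a` (the best estimate of the true value):
#' `100 * (a - b) / a`, so a positive bias means `b` underestimates; pairs
#' with a zero reference value are undefined, dropped, and counted in
#' `n_dropped`.  The x-axis coordinate is the pair mean `(a + b) / 2` in
#' both modes.
#'
#' @param a Occurrence records of the reference method.
#' @param b Occurrence records of the comparison method.
#' @param mode `"raw"` or `"percent"`.
#' @param multiplier Limits-of-agreement width multiplier (1.96).
#' @return A list of class `"bland_altman"`: `method_pair`, `mode`,
#'   `points` (tibble `session_id`, `behavior`, `mean`, `diff`), `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n`, `n_dropped`.
#' @examples
#' a <- tibble::tibble(session_id = "s1", behavior = c("x", "y"),
#'                     method = "10min", value = c(2, 4))
#' b <- tibble::tibble(session_id = "s1", behavior = c("x", "y"),
#'                     method = "15min", value = c(1, 5))
#' ba <- bland_altman(a, b, mode = "percent")
#' ba$bias  # +12.5
#' @export
bland_altman <- function(a, b, mode = c("raw", "percent"),
                         multiplier = 1.96) {
  mode <- match.arg(mode)
  j <- match_records(a, b)
  n_dropped <- 0L
  if (mode == "percent") {
    zero <- j$value_a == 0
    n_dropped <- sum(zero)
    j <- j[!zero, ]
  }
  if (nrow(j) < 3) stop_scanopt("fewer than 3 usable pairs")
  diff <- if (mode == "raw") {
    j$value_a - j$value_b
  } else {
    100 * (j$value_a - j$value_b) / j$value_a
  }
  bias <- mean(diff)
  sd_diff <- sd(diff)
  loa <- loa_limits(bias, sd_diff, multiplier)
  out <- list(
    method_pair = c(if ("method" %in% names(a)) a$method[1] else "a",
                    if ("method" %in% names(b)) b$method[1] else "b"),
    mode = mode,
    points = tibble::tibble(session_id = j$session_id, behavior = j$behavior,
                            mean = (j$value_a + j$value_b) / 2, diff = diff),
    bias = bias, sd_diff = sd_diff,
    loa_low = unname(loa["lower"]), loa_high = unname(loa["upper"]),
    n = nrow(j), n_dropped = n_dropped
  )
  class(out) <- "bland_altman"
  out
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> %s vs %s (%s): bias %.4g, SD %.4g, LoA [%.4g, %.4g], n=%d%s\n",
    x$method_pair[1], x$method_pair[2], x$mode, x$bias, x$sd_diff,
    x$loa_low, x$loa_high, x$n,
    if (x$n_dropped) sprintf(" (%d zero-reference pairs dropped)", x$n_dropped)
    else ""))
  invisible(x)
}
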