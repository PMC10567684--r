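#' Study configuration for the full workflow
#'
#' Bundles the tunable choices of the multistep workflow: candidate
#' intervals, observation-window convention, occurrence-category
#' thresholds, ICC flavor, Tweedie variance power and significance level.
#'
#' @param intervals_s Candidate sampling intervals in seconds (default 10,
#'   15 and 30 minutes).
#' @param window_s Observation-window length passed to [sampling_scheme()].
#' @param mode Scan mode, `"instantaneous"` or `"window_majority"`.
#' @param reference_method Fix the reference method label instead of
#'   selecting it from the data (`NULL` = select via [select_reference()]).
#' @param low_max,medium_max Occurrence-category boundaries (percent).
#' @param icc_definition,icc_type Flavor of [icc()] used for the
#'   among-methods agreement stage.
#' @param tweedie_power Variance power for [fit_tweedie_glm()].
#' @param alpha Significance level.
#' @param validity_behaviors Behaviors for the validity stage (`NULL` =
#'   pick one per occurrence category).
#' @param seed Seed recorded in the report provenance.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(intervals_s = c(600, 900, 1800), window_s = 0,
                         mode = "instantaneous", reference_method = NULL,
                         low_max = 0.49, medium_max = 3.50,
                         icc_definition = "average",
                         icc_type = "absolute_agreement",
                         tweedie_power = 1.5, alpha = 0.05,
                         validity_behaviors = NULL, seed = NULL) {
  if (length(intervals_s) < 1 || any(intervals_s <= 0)) {
    stop_scanopt("`intervals_s` must be positive")
  }
  if (low_max <= 0 || medium_max <= low_max) {
    stop_scanopt("need 0 < low_max < medium_max")
  }
  assert_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  structure(
    list(intervals_s = sort(unique(intervals_s)), window_s = window_s,
         mode = mode, reference_method = reference_method,
         low_max = low_max, medium_max = medium_max,
         icc_definition = icc_definition, icc_type = icc_type,
         tweedie_power = tweedie_power, alpha = alpha,
         validity_behaviors = validity_behaviors, seed = seed),
    class = "study_config"
  )
}

stage_fail <- function(bundle, name, reason) {
  bundle$stages[[name]] <- list(status = "failed", reason = reason)
  bundle
}
stage_skip <- function(bundle, name, reason) {
  bundle$stages[[name]] <- list(status = "skipped", reason = reason)
  bundle
}
stage_ok <- function(bundle, name) {
  bundle$stages[[name]] <- list(status = "ok", reason = NULL)
  bundle
}

#' Run the full interval-selection workflow
#'
#' Executes the multistep methodology on a set of continuous timelines:
#' continuous occurrences, scan tables at every candidate interval,
#' reference-interval selection (R-squared / MAE / RMSE), occurrence-category
#' binning, among-methods agreement (ICC per behavior), accuracy (per-
#' behavior method comparisons, signed error scores by category, Bland-
#' Altman in raw and percent mode) and, when the sessions span at least two
#' groups, validity (Tweedie-GLM group effects per method and pairwise
#' effect-size comparisons against the reference).  A stage that fails or
#' lacks its inputs is marked in `$stages` with a reason, and dependent
#' stages are skipped.
#'
#' @param timelines A list of [session_timeline()]s (or a single one).
#' @param config A [study_config()].
#' @param ethogram Optional [ethogram()]; default is a plain ethogram over
#'   the behaviors present in the timelines.
#' @return A list of class `"scan_report"` with elements `occurrences`
#'   (all methods, long tibble), `reference_selection`, `categories`,
#'   `agreement`, `methods_comparison`, `accuracy`, `validity`, `stages`,
#'   `provenance`.
#' @export
run_pipeline <- function(timelines, config = study_config(),
                         ethogram = NULL) {
  if (inherits(timelines, "session_timeline")) timelines <- list(timelines)
  if (!length(timelines)) stop_scanopt("need at least one timeline")
  stopifnot(inherits(config, "study_config"))
  if (is.null(ethogram)) {
    ethogram <- ethogram(sort(unique(unlist(
      lapply(timelines, function(tl) tl$bouts$behavior)))))
  }
  bundle <- list(stages = list())
  class(bundle) <- "scan_report"
  methods <- interval_label(config$intervals_s)

  # -- continuous (gold standard) occurrences ------------------------------
  occ_cont <- tryCatch({
    dplyr::bind_rows(lapply(timelines, occurrence_continuous,
                            ethogram = ethogram))
  }, error = function(e) e)
  if (inherits(occ_cont, "error")) {
    return(stage_fail(bundle, "continuous", conditionMessage(occ_cont)))
  }
  bundle <- stage_ok(bundle, "continuous")

  # -- scan sampling at each candidate interval ----------------------------
  occ_scan <- tryCatch({
    dplyr::bind_rows(lapply(seq_along(config$intervals_s), function(i) {
      scheme <- sampling_scheme(config$intervals_s[i], config$window_s,
                                config$mode)
      dplyr::bind_rows(lapply(timelines, function(tl) {
        occurrence_from_scans(scan_sample(tl, scheme, ethogram))
      }))
    }))
  }, error = function(e) e)
  if (inherits(occ_scan, "error")) {
    return(stage_fail(bundle, "sampling", conditionMessage(occ_scan)))
  }
  bundle <- stage_ok(bundle, "sampling")
  bundle$occurrences <- dplyr::bind_rows(occ_cont, occ_scan)

  # -- reference selection -------------------------------------------------
  metrics <- dplyr::bind_rows(lapply(seq_along(methods), function(i) {
    m <- reference_metrics(occ_scan[occ_scan$method == methods[i], ], occ_cont)
    tibble::tibble(method = methods[i], interval_s = config$intervals_s[i],
                   r2 = m$r2, mae = m$mae, rmse = m$rmse, n = m$n)
  }))
  reference <- config$reference_method %||% select_reference(metrics)
  bundle$reference_selection <- list(metrics = metrics, chosen = reference)
  bundle <- stage_ok(bundle, "reference_selection")

  occ_ref <- occ_scan[occ_scan$method == reference, ]

  # -- occurrence-category binning (on the reference method) ---------------
  bundle$categories <- bin_behaviors(occ_ref, ethogram,
                                     config$low_max, config$medium_max)
  bundle <- stage_ok(bundle, "binning")

  if (length(methods) < 2) {
    bundle <- stage_skip(bundle, "agreement", "fewer than 2 intervals")
    bundle <- stage_skip(bundle, "methods_comparison", "fewer than 2 intervals")
    bundle <- stage_skip(bundle, "accuracy", "fewer than 2 intervals")
  } else {
    wide <- occ_scan |>
      dplyr::select("session_id", "method", "behavior", "value") |>
      tidyr::pivot_wider(names_from = "method", values_from = "value")

    # -- agreement among methods (ICC per behavior) ------------------------
    agreement <- dplyr::bind_rows(lapply(ethogram$behavior, function(b) {
      w <- wide[wide$behavior == b, methods]
      res <- icc(as.matrix(w), config$icc_definition, config$icc_type)
      tibble::tibble(behavior = b, icc = res$icc, ci_low = res$ci_low,
                     ci_high = res$ci_high, f_stat = res$f_stat,
                     p_value = res$p_value, label = res$label,
                     undefined_reason = res$undefined_reason %||% NA_character_)
    }))
    bundle$agreement <- agreement
    bundle <- stage_ok(bundle, "agreement")

    # -- per-behavior method comparison (Friedman + post hoc letters) ------
    comp <- dplyr::bind_rows(lapply(ethogram$behavior, function(b) {
      w <- as.matrix(wide[wide$behavior == b, methods])
      fr <- friedman_test(w)
      ph <- pairwise_posthoc(w, alpha = config$alpha)
      tibble::tibble(behavior = b, method = methods,
                     mean = colMeans(w), sd = apply(w, 2, sd),
                     letter = unname(ph$letters),
                     friedman_chi2 = fr$statistic, friedman_p = fr$p_value)
    }))
    bundle$methods_comparison <- comp
    bundle <- stage_ok(bundle, "methods_comparison")

    # -- accuracy: error scores + Bland-Altman -----------------------------
    acc <- tryCatch({
      tests <- setdiff(methods, reference)
      errors <- dplyr::bind_rows(lapply(tests, function(mth) {
        error_scores(occ_scan[occ_scan$method == mth, ], occ_ref)
      }))
      err_summary <- summarize_errors(errors, bundle$categories, config$alpha)
      err_tests <- if (length(tests) >= 2) {
        prs <- utils::combn(tests, 2)
        dplyr::bind_rows(lapply(seq_len(ncol(prs)), function(j) {
          ea <- errors[errors$method == prs[1, j], ]
          eb <- errors[errors$method == prs[2, j], ]
          jj <- dplyr::inner_join(ea, eb, by = c("session_id", "behavior"),
                                  suffix = c("_a", "_b"))
          wt <- compare_error_distributions(jj$error_a, jj$error_b)
          tibble::tibble(method_a = prs[1, j], method_b = prs[2, j],
                         statistic = wt$statistic, p_value = wt$p_value,
                         n = wt$n_used)
        }))
      } else NULL
      ba <- list()
      for (mth in tests) {
        for (mode in c("raw", "percent")) {
          ba[[paste(reference, mth, mode, sep = "_")]] <-
            bland_altman(occ_ref, occ_scan[occ_scan$method == mth, ], mode)
        }
      }
      list(errors = errors, error_summary = err_summary,
           error_tests = err_tests, bland_altman = ba)
    }, error = function(e) e)
    if (inherits(acc, "error")) {
      bundle <- stage_fail(bundle, "accuracy", conditionMessage(acc))
    } else {
      bundle$accuracy <- acc
      bundle <- stage_ok(bundle, "accuracy")
    }
  }

  # -- validity: group effects per method, compared across methods ---------
  groups <- unique(vapply(timelines, function(tl) tl$group, character(1)))
  if (length(groups) < 2) {
    bundle <- stage_skip(bundle, "validity", "fewer than 2 groups")
  } else {
    val <- tryCatch({
      beh_val <- config$validity_behaviors %||% {
        ct <- bundle$categories
        unlist(lapply(split(ct, ct$category), function(d) {
          if (nrow(d)) d$behavior[which.max(d$mean_value)] else NULL
        }))
      }
      fits <- list(); comps <- NULL
      for (b in beh_val) {
        for (mth in methods) {
          d <- bundle$occurrences[bundle$occurrences$behavior == b &
                                    bundle$occurrences$method == mth, ]
          d$group <- factor(d$group)
          key <- paste(b, mth, sep = "|")
          fits[[key]] <- tryCatch(
            fit_tweedie_glm(value ~ group + day, d,
                            power = config$tweedie_power),
            error = function(e) conditionMessage(e))
        }
        ref_fit <- fits[[paste(b, reference, sep = "|")]]
        if (!inherits(ref_fit, "tweedie_glm")) next
        g_terms <- grep("^group", ref_fit$terms$term, value = TRUE)
        for (mth in setdiff(methods, reference)) {
          f2 <- fits[[paste(b, mth, sep = "|")]]
          if (!inherits(f2, "tweedie_glm")) next
          for (tm in g_terms) {
            cc <- compare_glm_terms(ref_fit, f2, tm)
            comps <- dplyr::bind_rows(comps, tibble::tibble(
              behavior = b, term = tm, method_a = reference, method_b = mth,
              z = cc$z, p_value = cc$p_value))
          }
        }
      }
      list(behaviors = beh_val, fits = fits, comparisons = comps)
    }, error = function(e) e)
    if (inherits(val, "error")) {
      bundle <- stage_fail(bundle, "validity", conditionMessage(val))
    } else {
      bundle$validity <- val
      bundle <- stage_ok(bundle, "validity")
    }
  }

  bundle$provenance <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    n_sessions = length(timelines),
    package_version = as.character(utils::packageVersion("scanopt"))
  )
  bundle
}

#' @export
print.scan_report <- function(x, ...) {
  cat("<scan_report>\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-20s %s%s\n", nm, st$status,
                if (!is.null(st$reason)) paste0(" (", st$reason, ")") else ""))
  }
  if (!is.null(x$reference_selection)) {
    cat("  reference method:", x$reference_selection$chosen, "\n")
  }
  invisible(x)
}

#' Export a workflow report to files
#'
#' Writes the report bundle as a JSON summary plus flat CSV tables:
#' reference-selection metrics, per-behavior agreement, the per-behavior
#' method comparison (means, SDs, letters, Friedman p), the error summary
#' by category, one CSV of Bland-Altman points per method pair and mode,
#' the validity coefficient tables and effect-size comparisons.  Re-export
#' to the same directory is idempotent.
#'
#' @param bundle A `"scan_report"` from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
export_report <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "scan_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_scanopt("cannot create directory: ", out_dir)
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  if (!is.null(bundle$reference_selection)) {
    put(dplyr::rename(bundle$reference_selection$metrics,
                      interval = "method"), "reference_selection.csv")
  }
  if (!is.null(bundle$categories)) put(bundle$categories, "categories.csv")
  if (!is.null(bundle$agreement)) put(bundle$agreement, "agreement.csv")
  if (!is.null(bundle$methods_comparison)) {
    put(bundle$methods_comparison, "methods_comparison.csv")
  }
  if (!is.null(bundle$accuracy)) {
    put(bundle$accuracy$error_summary, "error_summary.csv")
    if (!is.null(bundle$accuracy$error_tests)) {
      put(bundle$accuracy$error_tests, "error_tests.csv")
    }
    for (nm in names(bundle$accuracy$bland_altman)) {
      put(bundle$accuracy$bland_altman[[nm]]$points,
          paste0("bland_altman_", nm, ".csv"))
    }
  }
  if (!is.null(bundle$validity)) {
    tabs <- lapply(names(bundle$validity$fits), function(key) {
      f <- bundle$validity$fits[[key]]
      if (!inherits(f, "tweedie_glm")) return(NULL)
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      dplyr::mutate(f$terms, behavior = parts[1], method = parts[2],
                    .before = 1)
    })
    put(dplyr::bind_rows(tabs), "validity_glm.csv")
    if (!is.null(bundle$validity$comparisons)) {
      put(bundle$validity$comparisons, "effect_comparisons.csv")
    }
  }
  summary <- list(
    stages = bundle$stages,
    reference = bundle$reference_selection$chosen,
    bland_altman = lapply(bundle$accuracy$bland_altman, function(ba) {
      list(mode = ba$mode, bias = ba$bias, sd_diff = ba$sd_diff,
           loa_low = ba$loa_low, loa_high = ba$loa_high, n = ba$n,
           n_dropped = ba$n_dropped)
    }),
    provenance = bundle$provenance
  )
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files <- c(files, p)
  invisible(files)
}
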