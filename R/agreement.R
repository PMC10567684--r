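#' Two-way ANOVA mean squares for a ratings matrix
#'
#' Standard two-way crossed decomposition without replication, the basis of
#' the two-way intraclass correlation coefficients: rows are subjects
#' (e.g. behavior-by-session cells or individual scans), columns are raters
#' or sampling methods.
#'
#' @param m Numeric matrix, `n >= 2` subjects by `k >= 2` raters, no missing
#'   cells.
#' @return List with `ms_rows`, `ms_cols`, `ms_error` and the matching
#'   degrees of freedom `df_rows`, `df_cols`, `df_error`.
#' @export
two_way_anova <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop_scanopt("ratings matrix must have no missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop_scanopt("need at least 2 subjects and 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(ms_rows = ss_rows / (n - 1), ms_cols = ss_cols / (k - 1),
       ms_error = max(0, ss_err) / ((n - 1) * (k - 1)),
       df_rows = n - 1, df_cols = k - 1, df_error = (n - 1) * (k - 1))
}

#' Intraclass correlation coefficient (two-way model)
#'
#' Shrout-Fleiss two-way ICCs with exact F-based 95% confidence bounds and
#' the F-test of the subject effect.  `type = "consistency"` ignores
#' systematic rater offsets (ICC(3,1)/ICC(3,k)); `type =
#' "absolute_agreement"` penalizes them (ICC(2,1)/ICC(2,k)).  `definition =
#' "single"` rates a single measurement, `"average"` the mean across the
#' `k` raters (Spearman-Brown scaled).
#'
#' When the between-subject mean square is (numerically) zero -- e.g. a
#' behavior never expressed by any subject under any method -- the ICC is
#' undefined and reported as such rather than forced to a number.
#'
#' @param m Numeric ratings matrix (subjects x raters).
#' @param definition `"single"` or `"average"`.
#' @param type `"absolute_agreement"` (default) or `"consistency"`.
#' @param conf_level Confidence level for the interval.
#' @return A list of class `"icc_result"`: `icc`, `ci_low`, `ci_high`,
#'   `f_stat`, `df1`, `df2`, `p_value`, `definition`, `type`, `label`
#'   (via [interpret_icc()]), `n`, `k`, and `undefined_reason` (string or
#'   `NULL`).
#' @examples
#' m <- cbind(a = c(1, 3, 5, 7), b = c(2, 3, 6, 6))
#' icc(m, "single", "consistency")
#' @export
icc <- function(m, definition = c("single", "average"),
                type = c("absolute_agreement", "consistency"),
                conf_level = 0.95) {
  definition <- match.arg(definition)
  type <- match.arg(type)
  m <- as.matrix(m)
  an <- two_way_anova(m)
  n <- nrow(m); k <- ncol(m)
  msr <- an$ms_rows; msc <- an$ms_cols; mse <- an$ms_error
  alpha <- 1 - conf_level

  scale <- max(msr, msc, mse)
  if (scale <= 0 || msr / scale < 1e-12) {
    out <- list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                f_stat = NA_real_, df1 = an$df_rows, df2 = an$df_error,
                p_value = NA_real_, definition = definition, type = type,
                label = NA_character_, n = n, k = k,
                undefined_reason = "zero variance")
    class(out) <- "icc_result"
    return(out)
  }

  point <- switch(
    paste(type, definition),
    "consistency single" = (msr - mse) / (msr + (k - 1) * mse),
    "consistency average" = (msr - mse) / msr,
    "absolute_agreement single" =
      (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    "absolute_agreement average" =
      (msr - mse) / (msr + (msc - mse) / n)
  )

  f_stat <- if (mse > 0) msr / mse else Inf
  p_value <- pf(f_stat, an$df_rows, an$df_error, lower.tail = FALSE)

  if (type == "consistency") {
    fl <- f_stat / qf(1 - alpha / 2, an$df_rows, an$df_error)
    fu <- f_stat * qf(1 - alpha / 2, an$df_error, an$df_rows)
    if (definition == "single") {
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    } else {
      ci <- c(1 - 1 / fl, 1 - 1 / fu)
    }
  } else {
    # Satterthwaite bounds for ICC(2,1), Spearman-Brown scaled for average
    icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    if (mse <= 0 && abs(msc - mse) <= 0) {
      ci <- c(1, 1)
    } else {
      a <- k * icc1 / (n * (1 - icc1))
      b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f_low <- qf(1 - alpha / 2, n - 1, v)
      f_up <- qf(1 - alpha / 2, v, n - 1)
      lo <- n * (msr - f_low * mse) /
        (f_low * (k * msc + (k * n - k - n) * mse) + n * msr)
      hi <- n * (f_up * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_up * msr)
      ci <- c(lo, hi)
    }
    if (definition == "average") {
      sb <- function(x) k * x / (1 + (k - 1) * x)
      ci <- sb(ci)
    }
  }
  ci <- pmin(1, pmax(-1, sort(ci)))

  out <- list(icc = point, ci_low = ci[1], ci_high = ci[2],
              f_stat = f_stat, df1 = an$df_rows, df2 = an$df_error,
              p_value = p_value, definition = definition, type = type,
              label = interpret_icc(point), n = n, k = k,
              undefined_reason = NULL)
  class(out) <- "icc_result"
  out
}

#' @export
print.icc_result <- function(x, ...) {
  if (!is.null(x$undefined_reason)) {
    cat(sprintf("<icc> undefined (%s)  [%s, %s]\n", x$undefined_reason,
                x$definition, x$type))
  } else {
    cat(sprintf(
      "<icc> %.3f (95%% CI %.3f-%.3f), %s  [%s, %s]  F(%d,%d)=%.3g, p=%.3g\n",
      x$icc, x$ci_low, x$ci_high, x$label, x$definition, x$type,
      x$df1, x$df2, x$f_stat, x$p_value))
  }
  invisible(x)
}

#' Qualitative interpretation of an ICC value
#'
#' Conventional cut-points: poor below 0.40, fair from 0.40, good from 0.60,
#' excellent from 0.75 (lower bound inclusive in the upper class).
#'
#' @param value Numeric ICC value(s).
#' @return Character vector: `"poor"`, `"fair"`, `"good"` or `"excellent"`.
#' @examples
#' interpret_icc(c(0.39, 0.40, 0.60, 0.75, 0.97))
#' @export
interpret_icc <- function(value) {
  out <- rep(NA_character_, length(value))
  out[!is.na(value) & value < 0.40] <- "poor"
  out[!is.na(value) & value >= 0.40 & value < 0.60] <- "fair"
  out[!is.na(value) & value >= 0.60 & value < 0.75] <- "good"
  out[!is.na(value) & value >= 0.75] <- "excellent"
  out
}
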