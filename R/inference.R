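# all k! permutations of 1:k, one per row
all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# exact permutation distribution of the Friedman statistic: dynamic program
# over blocks on the vector of column rank sums (requires untied ranks)
friedman_exact_p <- function(n, k, stat_obs) {
  perms <- all_permutations(k)
  states <- matrix(0L, 1, k)
  counts <- 1
  for (i in seq_len(n)) {
    grown <- do.call(rbind, lapply(seq_len(nrow(perms)), function(p) {
      sweep(states, 2, perms[p, ], "+")
    }))
    cnt <- rep(counts, times = nrow(perms))
    key <- apply(grown, 1, paste, collapse = ",")
    agg <- rowsum(cnt, key)
    states <- do.call(rbind, lapply(strsplit(rownames(agg), ","), as.integer))
    counts <- agg[, 1]
  }
  stat <- 12 / (n * k * (k + 1)) * rowSums(states^2) - 3 * n * (k + 1)
  sum(counts[stat >= stat_obs - 1e-9]) / sum(counts)
}

#' Friedman test across sampling methods
#'
#' Related-samples Friedman rank test for whether a within-session quantity
#' (e.g. the occurrence of one behavior) differs across methods.  Rows are
#' complete blocks (sessions), columns are the methods.  The statistic uses
#' average ranks for ties with the tie-corrected denominator.  The p-value
#' is computed by exact enumeration of all within-block rank permutations
#' (a dynamic program over blocks) when there are no ties and the problem
#' is small, otherwise from the chi-squared approximation.
#'
#' @param m Numeric matrix, blocks x methods, no missing values.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact p-value;
#'   default `NULL` picks exact for untied data with at most 12 blocks and
#'   5 methods.
#' @return List with `statistic` (chi-squared), `df`, `p_value`, `method`
#'   (`"exact"` or `"asymptotic"`), `n_blocks`, `k`.
#' @export
friedman_test <- function(m, exact = NULL) {
  m <- as.matrix(m)
  if (anyNA(m)) stop_scanopt("incomplete block: Friedman test needs no missing values")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop_scanopt("need at least 2 blocks and 2 methods")
  r <- t(apply(m, 1, rank))
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  if (A - C <= 1e-12) {
    return(list(statistic = 0, df = k - 1, p_value = 1,
                method = "degenerate", n_blocks = n, k = k))
  }
  stat <- (k - 1) * sum((colSums(r) - n * (k + 1) / 2)^2) / (A - C)
  ties <- any(apply(m, 1, function(x) anyDuplicated(x) > 0))
  if (is.null(exact)) exact <- !ties && n <= 12 && k <= 5
  if (exact && ties) {
    warning("ties present: falling back to asymptotic p-value", call. = FALSE)
    exact <- FALSE
  }
  p <- if (exact) {
    friedman_exact_p(n, k, stat)
  } else {
    pchisq(stat, k - 1, lower.tail = FALSE)
  }
  list(statistic = stat, df = k - 1, p_value = p,
       method = if (exact) "exact" else "asymptotic", n_blocks = n, k = k)
}

# compact letter display from a logical "significantly different" matrix,
# ordering letters by decreasing column mean
compact_letters <- function(sig, means) {
  k <- nrow(sig)
  adj <- !sig; diag(adj) <- TRUE
  subsets <- lapply(seq_len(2^k - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
  })
  is_clique <- vapply(subsets, function(s) all(adj[s, s]), logical(1))
  cliques <- subsets[is_clique]
  maximal <- vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(o) {
      length(o) > length(cliques[[i]]) && all(cliques[[i]] %in% o)
    }, logical(1)))
  }, logical(1))
  cliques <- cliques[maximal]
  ord <- order(-vapply(cliques, function(s) max(means[s]), numeric(1)))
  cliques <- cliques[ord]
  letters_out <- rep("", k)
  for (i in seq_along(cliques)) {
    letters_out[cliques[[i]]] <- paste0(letters_out[cliques[[i]]], letters[i])
  }
  letters_out
}

#' Pairwise post-hoc comparisons with Bonferroni correction
#'
#' All pairwise related-samples Wilcoxon signed-rank tests between methods,
#' with p-values multiplied by the number of comparisons (capped at 1), and
#' a compact letter display: methods sharing a letter do not differ
#' significantly.  By default the post-hoc is guarded by the Friedman test:
#' when the omnibus test is not significant, all methods share one letter.
#'
#' @param m Numeric matrix, blocks x methods, with column names.
#' @param alpha Significance level for the letter display.
#' @param guard Run [friedman_test()] first and suppress letter separation
#'   when it is not significant (default `TRUE`).
#' @return List with `pairs` (tibble `method_a`, `method_b`, `statistic`,
#'   `p_value`, `p_adj`), `letters` (named character), `friedman_p`,
#'   `n_comparisons`.
#' @export
pairwise_posthoc <- function(m, alpha = 0.05, guard = TRUE) {
  m <- as.matrix(m)
  k <- ncol(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("m", seq_len(k))
  cmb <- utils::combn(k, 2)
  n_comp <- ncol(cmb)
  res <- lapply(seq_len(n_comp), function(j) {
    i1 <- cmb[1, j]; i2 <- cmb[2, j]
    wt <- compare_error_distributions(m[, i1], m[, i2])
    tibble::tibble(method_a = colnames(m)[i1], method_b = colnames(m)[i2],
                   statistic = wt$statistic, p_value = wt$p_value)
  })
  pairs <- dplyr::bind_rows(res)
  pairs$p_adj <- pmin(1, pairs$p_value * n_comp)
  fr_p <- if (guard) friedman_test(m)$p_value else NA_real_
  sig <- matrix(FALSE, k, k)
  if (!guard || (is.finite(fr_p) && fr_p < alpha)) {
    for (j in seq_len(n_comp)) {
      s <- pairs$p_adj[j] < alpha
      sig[cmb[1, j], cmb[2, j]] <- s
      sig[cmb[2, j], cmb[1, j]] <- s
    }
  }
  letters_out <- compact_letters(sig, colMeans(m))
  list(pairs = pairs, letters = setNames(letters_out, colnames(m)),
       friedman_p = fr_p, n_comparisons = n_comp)
}

#' Fit a Tweedie generalized linear model to occurrence values
#'
#' Occurrence percentages are non-negative with exact zeros, which the
#' Tweedie family (power variance function `V(mu) = mu^p`, `1 < p < 2`,
#' log link) accommodates as a compound Poisson-gamma quasi-likelihood.
#' The model is fit by iteratively reweighted least squares; dispersion is
#' estimated by Pearson chi-square over residual degrees of freedom, and
#' Wald standard errors, z tests and 95% CIs follow.  Exponentiated
#' coefficients are reported as `or` -- the conventional "odds ratio" label
#' for such effect sizes in the applied literature, though with a log link
#' they are formally ratios of expected occurrences.
#'
#' @param formula Model formula, e.g. `value ~ group + day`.
#' @param data Data frame of occurrence records (one row per session).
#' @param power Tweedie variance power, in (1, 2); default 1.5.
#' @param conf_level Level for the Wald confidence intervals.
#' @return A list of class `"tweedie_glm"`: `terms` (tibble `term`,
#'   `estimate`, `se`, `or`, `ci_low`, `ci_high`, `z`, `p_value`), `power`,
#'   `dispersion`, `converged`, `n_obs`, `fit` (the underlying `glm`).
#' @export
fit_tweedie_glm <- function(formula, data, power = 1.5, conf_level = 0.95) {
  assert_number(power, "power", lower = 1 + 1e-9, upper = 2 - 1e-9)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0)) stop_scanopt("response values must be non-negative")
  for (v in names(mf)[-1]) {
    if (is.factor(mf[[v]]) || is.character(mf[[v]])) {
      lv <- split(y, mf[[v]])
      allzero <- names(lv)[vapply(lv, function(x) all(x == 0), logical(1))]
      if (length(allzero)) {
        stop_scanopt(
          "all responses are zero for level(s) ",
          paste(allzero, collapse = ", "), " of `", v,
          "`; the log-link mean is unbounded below -- consider pooling ",
          "levels or a different variance power/profile")
      }
    }
  }
  fit <- suppressWarnings(
    glm(formula, data = data,
        family = mgcv::Tweedie(p = power, link = "log"),
        control = stats::glm.control(epsilon = 1e-12, maxit = 50))
  )
  disp <- sum(residuals(fit, "pearson")^2) / fit$df.residual
  cf <- coef(fit)
  cov_u <- summary(fit)$cov.unscaled
  se <- sqrt(diag(cov_u) * disp)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  z <- cf / se
  terms <- tibble::tibble(
    term = names(cf), estimate = unname(cf), se = unname(se),
    or = exp(unname(cf)),
    ci_low = exp(unname(cf) - zq * se), ci_high = exp(unname(cf) + zq * se),
    z = unname(z), p_value = 2 * pnorm(-abs(unname(z)))
  )
  out <- list(terms = terms, power = power, dispersion = disp,
              converged = isTRUE(fit$converged), n_obs = nrow(mf), fit = fit)
  class(out) <- "tweedie_glm"
  out
}

#' @export
print.tweedie_glm <- function(x, ...) {
  cat(sprintf("<tweedie_glm> power=%.2f dispersion=%.3g n=%d%s\n", x$power,
              x$dispersion, x$n_obs,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  print(as.data.frame(x$terms), digits = 3)
  invisible(x)
}

#' Test whether two estimated effects differ
#'
#' Given two independent estimates of an effect on the log scale (e.g. the
#' same group contrast fitted under two sampling methods), the difference
#' is tested with `z = (coef_a - coef_b) / sqrt(se_a^2 + se_b^2)` and a
#' two-sided standard-normal p-value.
#'
#' @param coef_a,coef_b Log-scale coefficients.
#' @param se_a,se_b Their standard errors.
#' @return A list of class `"effect_comparison"`: `z`, `p_value`, `diff`,
#'   `se_diff`.
#' @examples
#' compare_effect_sizes(0.5, 0.2, 0.0, 0.15)  # z = 2, p ~ 0.0455
#' @export
compare_effect_sizes <- function(coef_a, se_a, coef_b, se_b) {
  if (se_a < 0 || se_b < 0) stop_scanopt("standard errors must be >= 0")
  if (se_a == 0 && se_b == 0) {
    stop_scanopt("both standard errors are zero; the z statistic is undefined")
  }
  d <- coef_a - coef_b
  se_d <- sqrt(se_a^2 + se_b^2)
  z <- d / se_d
  out <- list(z = z, p_value = 2 * pnorm(-abs(z)), diff = d, se_diff = se_d)
  class(out) <- "effect_comparison"
  out
}

#' Compare one model term across two Tweedie fits
#'
#' Convenience wrapper applying [compare_effect_sizes()] to the same named
#' term of two [fit_tweedie_glm()] results.
#'
#' @param fit_a,fit_b `"tweedie_glm"` objects.
#' @param term Term name present in both fits.
#' @return An `"effect_comparison"`.
#' @export
compare_glm_terms <- function(fit_a, fit_b, term) {
  ta <- fit_a$terms[fit_a$terms$term == term, ]
  tb <- fit_b$terms[fit_b$terms$term == term, ]
  if (!nrow(ta) || !nrow(tb)) stop_scanopt("term not found in both fits: ", term)
  compare_effect_sizes(ta$estimate, ta$se, tb$estimate, tb$se)
}
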