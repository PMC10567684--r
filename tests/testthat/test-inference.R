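test_that("Friedman test handles degenerate and tied inputs", {
  m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- friedman_test(m)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  expect_error(friedman_test(cbind(c(1, NA), c(2, 3))), "missing")
  expect_error(friedman_test(matrix(1:3, 3, 1)), "at least 2")

  # ties fall back to the asymptotic tie-corrected statistic
  mt <- rbind(c(1, 1, 2), c(2, 3, 1), c(1, 2, 3), c(3, 1, 2))
  res_t <- friedman_test(mt)
  expect_equal(res_t$method, "asymptotic")
  expect_equal(res_t$statistic,
               unname(stats::friedman.test(mt)$statistic))
})

test_that("exact Friedman p-values equal brute-force permutation enumeration", {
  brute <- function(m) {
    n <- nrow(m); k <- ncol(m)
    perms <- scanopt:::all_permutations(k)
    robs <- t(apply(m, 1, rank))
    stat_of <- function(r) {
      12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
    }
    sobs <- stat_of(robs)
    grid <- expand.grid(rep(list(seq_len(nrow(perms))), n))
    stats_all <- apply(grid, 1, function(ix) {
      stat_of(perms[ix, , drop = FALSE])
    })
    mean(stats_all >= sobs - 1e-9)
  }
  set.seed(80)
  for (i in 1:3) {
    m <- matrix(rnorm(9), 3, 3)
    res <- friedman_test(m)
    expect_equal(res$method, "exact")
    expect_equal(res$p_value, brute(m))
  }
  m4 <- matrix(rnorm(12), 4, 3)
  expect_equal(friedman_test(m4)$p_value, brute(m4))
})

test_that("Friedman detects a uniformly shifted method", {
  set.seed(81)
  base <- matrix(rnorm(20), 10, 2)
  m <- cbind(base, base[, 1] + 3 + rnorm(10, sd = 0.1))
  expect_lt(friedman_test(m)$p_value, 0.05)
})

test_that("post-hoc Bonferroni arithmetic and letter displays are correct", {
  set.seed(82)
  null_m <- matrix(rnorm(30, mean = 5), 10, 3,
                   dimnames = list(NULL, c("10min", "15min", "30min")))
  ph <- pairwise_posthoc(null_m)
  expect_equal(unname(ph$letters), c("a", "a", "a"))
  expect_equal(ph$pairs$p_adj, pmin(1, ph$pairs$p_value * 3))
  expect_equal(ph$n_comparisons, 3)

  # a clearly separated method earns its own letter
  sep <- cbind(null_m[, 1:2], far = null_m[, 3] + 50)
  ph2 <- pairwise_posthoc(sep)
  expect_equal(unname(ph2$letters), c("b", "b", "a"))
  expect_lt(ph2$friedman_p, 0.05)
})

test_that("letter display separates exactly the significant pairs", {
  # constructed significance structure: hi != lo only
  sig <- matrix(FALSE, 3, 3)
  sig[1, 3] <- sig[3, 1] <- TRUE
  expect_equal(scanopt:::compact_letters(sig, c(3, 2, 1)), c("a", "ab", "b"))
  # all different
  sig_all <- !diag(3) > 0
  expect_equal(scanopt:::compact_letters(sig_all, c(3, 2, 1)),
               c("a", "b", "c"))
  # none different
  expect_equal(scanopt:::compact_letters(matrix(FALSE, 3, 3), c(3, 2, 1)),
               rep("a", 3))
})

test_that("Tweedie GLM reproduces analytic fixed points", {
  set.seed(90)
  y <- c(rgamma(12, 2, 1), rep(0, 4))
  d <- data.frame(value = y)
  for (p in c(1.2, 1.5, 1.8)) {
    f <- fit_tweedie_glm(value ~ 1, d, power = p)
    expect_true(f$converged)
    expect_equal(exp(f$terms$estimate[1]), mean(y), tolerance = 1e-6)
  }

  # saturated two-group model: fitted means are the group means,
  # and the exponentiated contrast is their ratio
  d2 <- data.frame(value = c(rgamma(10, 2, 2), rgamma(10, 2, 0.8)),
                   group = gl(2, 10, labels = c("A", "B")))
  f2 <- fit_tweedie_glm(value ~ group, d2)
  mA <- mean(d2$value[d2$group == "A"]); mB <- mean(d2$value[d2$group == "B"])
  expect_equal(exp(f2$terms$estimate[1]), mA, tolerance = 1e-6)
  expect_equal(f2$terms$or[f2$terms$term == "groupB"], mB / mA,
               tolerance = 1e-6)
})

test_that("Wald standard errors match the quasi-likelihood information matrix", {
  set.seed(91)
  d <- data.frame(value = rgamma(20, 2, 1) * rbinom(20, 1, 0.85),
                  group = gl(2, 10, labels = c("A", "B")),
                  day = rep(1:5, 4))
  p <- 1.5
  f <- fit_tweedie_glm(value ~ group + day, d, power = p)
  # expected information for a log-link quasi-model with V(mu) = mu^p:
  #   I = X' diag(mu^(2-p)) X / phi,  se = sqrt(diag(I^-1))
  X <- stats::model.matrix(~ group + day, d)
  mu <- stats::fitted(f$fit)
  info <- t(X) %*% (X * mu^(2 - p)) / f$dispersion
  se_oracle <- sqrt(diag(solve(info)))
  expect_equal(f$terms$se, unname(se_oracle), tolerance = 1e-6)
})

test_that("Tweedie GLM rejects invalid inputs informatively", {
  d <- data.frame(value = c(0, 0, 0, 1, 2, 3),
                  group = gl(2, 3, labels = c("A", "B")))
  expect_error(fit_tweedie_glm(value ~ group, d), "all responses are zero")
  expect_error(fit_tweedie_glm(value ~ 1, data.frame(value = c(-1, 2, 3))),
               "non-negative")
  expect_error(fit_tweedie_glm(value ~ 1, data.frame(value = 1:3), power = 2.5),
               "power")
})

test_that("effect-size comparison is a calibrated normal z-test", {
  cmp <- compare_effect_sizes(0.5, 0.2, 0.0, 0.15)
  expect_equal(cmp$z, 2)
  expect_equal(cmp$p_value, 2 * pnorm(-2))

  same <- compare_effect_sizes(0.3, 0.1, 0.3, 0.2)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)

  # antisymmetry
  swap <- compare_effect_sizes(0.0, 0.15, 0.5, 0.2)
  expect_equal(swap$z, -cmp$z)
  expect_equal(swap$p_value, cmp$p_value)

  expect_error(compare_effect_sizes(1, 0, 2, 0), "undefined")
})

test_that("a doubled time budget is recovered as a mean ratio near 2", {
  base <- fast_sim_config(n_animals = 10, duration_s = 3600)
  des <- sim_study_design(base, effects = list(A = c(), B = c(forage = 1.6)),
                          sessions_per_group = 20, seed = 92)
  tls <- simulate_study(des)
  occ <- dplyr::bind_rows(lapply(tls, occurrence_continuous))
  d <- occ[occ$behavior == "forage", ]
  d$group <- factor(d$group)
  f <- fit_tweedie_glm(value ~ group + day, d)
  # renormalization: the true mean ratio is 1.6 / (1 + 0.6 * 0.5)
  true_ratio <- 1.6 / (1 + 0.6 * 0.5)
  est <- f$terms$estimate[f$terms$term == "groupB"]
  expect_lt(abs(est - log(true_ratio)), 0.1)
})
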