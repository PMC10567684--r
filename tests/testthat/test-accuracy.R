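test_that("reference metrics reproduce hand-computed values", {
  truth <- occ_tbl("s1", "continuous", c("a", "b", "c"), c(1, 2, 3))
  cand <- occ_tbl("s1", "10min", c("a", "b", "c"), c(1, 3, 5))
  m <- reference_metrics(cand, truth)
  expect_equal(m$mae, 1.0)
  expect_equal(m$rmse, sqrt(5 / 3))
  expect_equal(m$n, 3)

  same <- reference_metrics(truth, truth)
  expect_equal(same$r2, 1)
  expect_equal(same$mae, 0)
  expect_equal(same$rmse, 0)

  expect_error(reference_metrics(cand[1:2, ], truth[1:2, ]), "at least 3")
})

test_that("RMSE never falls below MAE", {
  set.seed(60)
  for (i in 1:20) {
    truth <- occ_tbl("s1", "c", letters[1:8], runif(8, 0, 30))
    cand <- occ_tbl("s1", "t", letters[1:8],
                    pmax(0, truth$value + rnorm(8, sd = 2)))
    m <- reference_metrics(cand, truth)
    expect_gte(m$rmse, m$mae)
  }
})

test_that("reference selection takes the majority of the three criteria", {
  tab <- tibble::tibble(
    method = c("10min", "15min", "30min"), interval_s = c(600, 900, 1800),
    r2 = c(0.521, 0.435, 0.386), mae = c(3.73, 3.93, 4.58),
    rmse = c(7.68, 8.33, 8.69))
  expect_equal(select_reference(tab), "10min")
  expect_equal(select_reference(tab[2, ]), "15min")

  # conflict: one candidate wins R2, the other wins both error criteria
  conflict <- tibble::tibble(
    method = c("A", "B"), interval_s = c(600, 900),
    r2 = c(0.9, 0.5), mae = c(4, 2), rmse = c(5, 3))
  expect_equal(select_reference(conflict), "B")

  # full tie resolves to the shortest interval
  tie <- tibble::tibble(method = c("x", "y"), interval_s = c(900, 600),
                        r2 = c(0.5, 0.5), mae = c(1, 1), rmse = c(1, 1))
  expect_message(out <- select_reference(tie), "shortest")
  expect_equal(out, "y")
})

test_that("occurrence binning applies the thresholds at the stated boundaries", {
  occ <- occ_tbl("s1", "10min",
                 c("Drinking", "Stretching", "Attacking", "Grass pecking",
                   "Edge", "Others"),
                 c(0.92, 0.49, 0.46, 14.39, 0.50, 1.0))
  eth <- ethogram(unique(occ$behavior),
                  excluded_from_binning = c(rep(FALSE, 5), TRUE))
  bins <- bin_behaviors(occ, eth)
  lookup <- setNames(as.character(bins$category), bins$behavior)
  expect_equal(lookup[["Drinking"]], "medium")
  expect_equal(lookup[["Stretching"]], "low")    # 0.49 is still low
  expect_equal(lookup[["Edge"]], "medium")       # 0.50 crosses the boundary
  expect_equal(lookup[["Attacking"]], "low")
  expect_equal(lookup[["Grass pecking"]], "high")
  expect_false("Others" %in% bins$behavior)

  # values are averaged across sessions before binning
  occ2 <- dplyr::bind_rows(occ_tbl("s1", "m", "x", 3.0),
                           occ_tbl("s2", "m", "x", 5.0))
  expect_equal(as.character(bin_behaviors(occ2)$category), "high")
  expect_error(bin_behaviors(occ, low_max = 2, medium_max = 1), "low_max")
})

test_that("error scores are signed test-minus-reference differences", {
  ref <- occ_tbl("s1", "10min", c("Attacking", "Walking"), c(0.46, 17.61))
  tst <- occ_tbl("s1", "30min", c("Attacking", "Walking"), c(0.24, 19.29))
  err <- error_scores(tst, ref)
  expect_equal(err$error[err$behavior == "Attacking"], -0.22)
  expect_equal(err$method[1], "30min")

  expect_equal(error_scores(ref, ref)$error, c(0, 0))
  # antisymmetry under swapping roles
  expect_equal(error_scores(ref, tst)$error, -err$error)
  # unmatched records are named
  expect_error(error_scores(occ_tbl("s2", "30min", "Walking", 1), ref), "s2")
})

test_that("category error summaries use exact t intervals", {
  vals <- c(-1.2, -0.8, -1.5, -0.3, -0.9)
  errors <- tibble::tibble(session_id = paste0("s", 1:5), behavior = "x",
                           method = "30min", error = vals)
  cats <- tibble::tibble(behavior = "x", mean_value = 0.2,
                         category = factor("low", c("low", "medium", "high"),
                                           ordered = TRUE))
  sm <- summarize_errors(errors, cats)
  m <- mean(vals); half <- qt(0.975, 4) * sd(vals) / sqrt(5)
  expect_equal(sm$mean_error, m)
  expect_equal(sm$ci_low, m - half)
  expect_equal(sm$ci_high, m + half)
  expect_true(sm$significant)  # all-negative errors: CI below zero

  # symmetric errors straddle zero
  errors2 <- errors; errors2$error <- c(-2, -1, 0, 1, 2)
  sm2 <- summarize_errors(errors2, cats)
  expect_equal(sm2$mean_error, 0)
  expect_false(sm2$significant)

  # behaviors without a category are dropped with a warning
  errors3 <- dplyr::bind_rows(errors, tibble::tibble(
    session_id = "s1", behavior = "zzz", method = "30min", error = 1))
  expect_warning(summarize_errors(errors3, cats), "zzz")
})

test_that("the paired Wilcoxon comparison matches full sign-flip enumeration", {
  a <- c(2.3, 1.1, 4.0, 0.2, 3.3, 2.8)
  b <- c(1.9, 1.6, 2.1, 0.9, 2.2, 2.9)
  got <- compare_error_distributions(a, b)
  expect_true(got$exact)

  d <- a - b
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  # enumerate all 2^6 sign assignments of the ranks
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  v_all <- signs %*% r
  p_enum <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  expect_equal(got$p_value, p_enum)

  expect_warning(same <- compare_error_distributions(a, a), "zero")
  expect_equal(same$p_value, 1)

  # a large shift is detected
  set.seed(71)
  shifted <- compare_error_distributions(rnorm(20), rnorm(20) + 10)
  expect_lt(shifted$p_value, 0.05)
})

test_that("limits of agreement obey the closed form in both modes", {
  loa <- loa_limits(-0.0003, 2.558)
  expect_equal(unname(loa["upper"] - loa["lower"]), 2 * 1.96 * 2.558)

  set.seed(70)
  a <- occ_tbl(rep(paste0("s", 1:5), each = 4), "10min",
               rep(letters[1:4], 5), runif(20, 0, 20))
  b <- a; b$method <- "30min"
  b$value <- pmax(0, a$value + rnorm(20, sd = 1.5))
  for (mode in c("raw", "percent")) {
    ba <- bland_altman(a, b, mode)
    expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff)
    expect_equal(ba$bias, mean(ba$points$diff))
    expect_equal(ba$n, nrow(ba$points))
  }
})

test_that("percent-mode differences are relative to the reference", {
  a <- occ_tbl("s1", "10min", c("x", "y"), c(2, 4))
  b <- occ_tbl("s1", "15min", c("x", "y"), c(1, 5))
  a3 <- dplyr::bind_rows(a, occ_tbl("s1", "10min", "z", 8))
  b3 <- dplyr::bind_rows(b, occ_tbl("s1", "15min", "z", 8))
  ba <- bland_altman(a3, b3, "percent")
  expect_equal(sort(ba$points$diff), c(-25, 0, 50))
  expect_equal(ba$bias, 25 / 3)

  # zero-reference pairs are dropped and counted
  a0 <- dplyr::bind_rows(a3, occ_tbl("s1", "10min", "w", 0))
  b0 <- dplyr::bind_rows(b3, occ_tbl("s1", "15min", "w", 1))
  ba0 <- bland_altman(a0, b0, "percent")
  expect_equal(ba0$n_dropped, 1L)
  expect_equal(ba0$n, 3L)
  # ...but contribute in raw mode
  expect_equal(bland_altman(a0, b0, "raw")$n, 4L)

  # perfect agreement collapses the limits
  same <- bland_altman(a3, a3, "raw")
  expect_equal(same$bias, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  expect_error(bland_altman(a, b, "percent"), "3 usable")
})
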