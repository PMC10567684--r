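# shared fixtures built in code

tiny_eth <- function() {
  ethogram(c("walk", "rest"), class = c("active", "static"))
}

# deterministic hand-built timeline: one animal walking then resting
walk_rest_timeline <- function(split = 60, duration = 120, visible = TRUE) {
  session_timeline(
    "s1", duration,
    bouts = tibble::tibble(
      animal_id = "a1", behavior = c("walk", "rest"),
      start_s = c(0, split), end_s = c(split, duration)),
    visibility = if (isTRUE(visible)) NULL else visible
  )
}

# occurrence-record tibble shorthand
occ_tbl <- function(session, method, behavior, value) {
  tibble::tibble(session_id = session, method = method,
                 behavior = behavior, value = value)
}

# small ethogram + config for fast simulations
fast_sim_config <- function(n_animals = 8, duration_s = 1800,
                            visible_fraction = 1, ...) {
  eth <- ethogram(c("forage", "rest", "dart"),
                  class = c("eat", "static", "active"))
  sim_config(
    eth,
    target_occupancy = c(forage = 0.5, rest = 0.45, dart = 0.05),
    mean_bout_s = c(forage = 60, rest = 120, dart = 10),
    n_animals = n_animals, duration_s = duration_s,
    visible_fraction = visible_fraction, ...
  )
}

# independent Shrout-Fleiss oracle used by agreement tests: mean squares from
# base aov(), ICC point estimates transcribed from the published formulas
icc_oracle <- function(m, definition, type) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  av <- summary(stats::aov(y ~ subj + rater, data = d))[[1]]
  # rows in model order: subj, rater, Residuals
  msr <- av[1, "Mean Sq"]; msc <- av[2, "Mean Sq"]; mse <- av[3, "Mean Sq"]
  if (type == "consistency") {
    single <- (msr - mse) / (msr + (k - 1) * mse)
  } else {
    single <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
  if (definition == "single") single else k * single / (1 + (k - 1) * single)
}
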