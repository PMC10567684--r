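#' Simulation configuration for one flock session
#'
#' Defines the stochastic model behind [simulate_flock()]: each animal is an
#' independent renewal sequence of behavior segments.  A segment's behavior
#' is drawn with probability proportional to
#' `target_occupancy / mean_bout_s` and its duration is exponential with the
#' behavior's mean bout length, so by the renewal-reward theorem the long-run
#' fraction of time spent in each behavior equals `target_occupancy`
#' exactly in expectation.  Visibility is an independent alternating on/off
#' renewal process with stationary on-fraction `visible_fraction`.
#'
#' @param ethogram An [ethogram()].
#' @param target_occupancy Named numeric vector over the ethogram's
#'   behaviors: desired long-run time budget, summing to 1 (zeros allowed).
#' @param mean_bout_s Named numeric vector of mean bout durations in
#'   seconds, all positive.
#' @param n_animals Number of animals in the pen.
#' @param duration_s Session length in seconds.
#' @param visible_fraction Stationary probability that an animal is visible;
#'   in (0, 1].
#' @param mean_visibility_bout_s Mean duration of a visible spell, seconds.
#' @param seed Optional integer seed making the simulation reproducible.
#' @return A list of class `"sim_config"`.
#' @seealso [broiler_preset()], [simulate_study()]
#' @export
sim_config <- function(ethogram, target_occupancy, mean_bout_s,
                       n_animals = 50, duration_s = 7200,
                       visible_fraction = 0.9,
                       mean_visibility_bout_s = 300, seed = NULL) {
  stopifnot(inherits(ethogram, "ethogram"))
  b <- ethogram$behavior
  if (!setequal(names(target_occupancy), b) ||
      !setequal(names(mean_bout_s), b)) {
    stop_scanopt("`target_occupancy` and `mean_bout_s` must be named over ",
                 "exactly the ethogram's behaviors")
  }
  target_occupancy <- target_occupancy[b]
  mean_bout_s <- mean_bout_s[b]
  if (any(target_occupancy < 0)) stop_scanopt("occupancies must be >= 0")
  if (abs(sum(target_occupancy) - 1) > 1e-9) {
    stop_scanopt("`target_occupancy` must sum to 1 (got ",
                 format(sum(target_occupancy)), ")")
  }
  if (any(mean_bout_s <= 0)) stop_scanopt("mean bout durations must be > 0")
  if (n_animals < 1) stop_scanopt("`n_animals` must be >= 1")
  assert_number(duration_s, "duration_s", lower = 1e-9)
  assert_number(visible_fraction, "visible_fraction", lower = 1e-9, upper = 1)
  assert_number(mean_visibility_bout_s, "mean_visibility_bout_s", lower = 1e-9)
  structure(
    list(ethogram = ethogram, target_occupancy = target_occupancy,
         mean_bout_s = mean_bout_s, n_animals = as.integer(n_animals),
         duration_s = duration_s, visible_fraction = visible_fraction,
         mean_visibility_bout_s = mean_visibility_bout_s, seed = seed),
    class = "sim_config"
  )
}

# one animal's behavior sequence over [0, duration]; time-stationary start
# (first state drawn from the occupancy distribution, later states from the
# segment-frequency weights w ~ occupancy / mean bout)
renewal_bouts <- function(duration, behaviors, occ, mean_bout) {
  active <- occ > 0
  if (sum(active) == 1) {
    b <- behaviors[active]
    return(tibble::tibble(behavior = b, start_s = 0, end_s = duration))
  }
  w <- occ[active] / mean_bout[active]
  w <- w / sum(w)
  bs_act <- behaviors[active]
  mb_act <- mean_bout[active]
  mean_seg <- 1 / sum(occ[active] / mean_bout[active])

  i1 <- sample.int(length(bs_act), 1, prob = occ[active])
  states <- i1
  durs <- rexp(1, 1 / mb_act[i1])
  tot <- durs
  while (tot < duration) {
    n <- max(16L, ceiling((duration - tot) / mean_seg * 1.3))
    is <- sample.int(length(bs_act), n, replace = TRUE, prob = w)
    ds <- rexp(n, 1 / mb_act[is])
    states <- c(states, is)
    durs <- c(durs, ds)
    tot <- tot + sum(ds)
  }
  cum <- cumsum(durs)
  k <- which(cum >= duration)[1]
  ends <- pmin(cum[seq_len(k)], duration)
  tibble::tibble(behavior = bs_act[states[seq_len(k)]],
                 start_s = c(0, ends[-k]), end_s = ends)
}

# alternating visible/hidden renewal process with on-fraction v
renewal_visibility <- function(duration, v, mean_on) {
  if (v >= 1) {
    return(tibble::tibble(start_s = 0, end_s = duration, visible = TRUE))
  }
  mean_off <- mean_on * (1 - v) / v
  state <- runif(1) < v
  starts <- numeric(0); ends <- numeric(0); vis <- logical(0)
  t <- 0
  while (t < duration) {
    d <- rexp(1, 1 / if (state) mean_on else mean_off)
    starts <- c(starts, t); ends <- c(ends, min(t + d, duration))
    vis <- c(vis, state)
    t <- t + d
    state <- !state
  }
  tibble::tibble(start_s = starts, end_s = ends, visible = vis)
}

#' Simulate one continuous flock session
#'
#' Generates a ground-truth [session_timeline()] under the renewal model of
#' [sim_config()].  Animals are independent; adjacent identical behaviors
#' are merged into bouts; the output is fully reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @param session_id,group,replicate,day Labels attached to the session.
#' @param seed Optional seed overriding `config$seed`.
#' @return A [session_timeline()].
#' @examples
#' eth <- ethogram(c("walk", "rest"), class = c("active", "static"))
#' cfg <- sim_config(eth, c(walk = 0.3, rest = 0.7),
#'                   c(walk = 60, rest = 120), n_animals = 3,
#'                   duration_s = 600, visible_fraction = 1, seed = 1)
#' simulate_flock(cfg)
#' @export
simulate_flock <- function(config, session_id = "sim1", group = "A",
                           replicate = "1", day = 1L, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  b <- config$ethogram$behavior
  with_seed(seed, {
    ids <- sprintf("a%03d", seq_len(config$n_animals))
    bl <- lapply(ids, function(i) {
      renewal_bouts(config$duration_s, b, config$target_occupancy,
                    config$mean_bout_s)
    })
    bouts <- dplyr::bind_rows(bl)
    bouts$animal_id <- rep(ids, vapply(bl, nrow, integer(1)))
    vl <- lapply(ids, function(i) {
      renewal_visibility(config$duration_s, config$visible_fraction,
                         config$mean_visibility_bout_s)
    })
    vis <- dplyr::bind_rows(vl)
    vis$animal_id <- rep(ids, vapply(vl, nrow, integer(1)))
    session_timeline(session_id, config$duration_s, bouts, vis,
                     group = group, replicate = replicate, day = day,
                     ethogram = config$ethogram)
  })
}

#' Multi-group study design for the simulator
#'
#' Describes a study that compares groups (e.g. genotypes) whose behavioral
#' time budgets differ by multiplicative factors: group occupancies are
#' `base occupancy * factor`, renormalized to sum to 1, mirroring the
#' mean-ratio effect scale used in log-link models downstream.
#'
#' @param base A [sim_config()] giving the reference occupancies.
#' @param effects Named list, one element per group, each a (possibly empty)
#'   named numeric vector of multiplicative occupancy factors (> 0);
#'   behaviors not named get factor 1.
#' @param sessions_per_group Number of sessions simulated per group.
#' @param n_replicates Number of replicate pens per group; sessions cycle
#'   through replicates.
#' @param days Integer day covariate per session (recycled); default
#'   `1:sessions_per_group`.
#' @param seed Integer master seed; per-session child seeds are derived from
#'   it deterministically.
#' @return A list of class `"sim_study_design"`.
#' @export
sim_study_design <- function(base, effects, sessions_per_group,
                             n_replicates = 2, days = NULL, seed = NULL) {
  stopifnot(inherits(base, "sim_config"))
  if (length(effects) == 0 || is.null(names(effects)) ||
      any(!nzchar(names(effects)))) {
    stop_scanopt("`effects` must be a non-empty named list of groups")
  }
  for (g in names(effects)) {
    f <- effects[[g]]
    if (length(f)) {
      if (is.null(names(f)) || any(!names(f) %in% base$ethogram$behavior)) {
        stop_scanopt("effect factors for group ", g,
                     " must be named by ethogram behaviors")
      }
      if (any(f <= 0)) stop_scanopt("effect factors must be > 0")
    }
  }
  if (sessions_per_group < 1) stop_scanopt("`sessions_per_group` must be >= 1")
  days <- days %||% seq_len(sessions_per_group)
  structure(
    list(base = base, effects = effects,
         sessions_per_group = as.integer(sessions_per_group),
         n_replicates = as.integer(n_replicates),
         days = as.integer(days), seed = seed),
    class = "sim_study_design"
  )
}

# occupancies under a multiplicative group effect, renormalized
apply_effect <- function(occ, factors) {
  f <- rep(1, length(occ))
  names(f) <- names(occ)
  if (length(factors)) f[names(factors)] <- factors
  out <- occ * f
  out / sum(out)
}

#' Simulate a multi-group study
#'
#' Simulates `sessions_per_group` sessions for every group in a
#' [sim_study_design()], labelling each with group, replicate pen and day.
#' Child seeds are spawned deterministically from the master seed, so the
#' whole study is reproducible and adding a group does not perturb the
#' sessions of earlier groups' seeds.
#'
#' @param design A [sim_study_design()].
#' @param seed Optional master seed overriding `design$seed`.
#' @return A list of [session_timeline()]s.
#' @export
simulate_study <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sim_study_design"))
  seed <- seed %||% design$seed
  groups <- names(design$effects)
  n_total <- length(groups) * design$sessions_per_group
  child <- spawn_seeds(seed %||% sample.int(.Machine$integer.max, 1), n_total)
  out <- vector("list", n_total)
  idx <- 0
  for (g in groups) {
    occ_g <- apply_effect(design$base$target_occupancy, design$effects[[g]])
    cfg_g <- design$base
    cfg_g$target_occupancy <- occ_g
    for (i in seq_len(design$sessions_per_group)) {
      idx <- idx + 1
      rep_i <- as.character((i - 1) %% design$n_replicates + 1)
      day_i <- design$days[(i - 1) %% length(design$days) + 1]
      out[[idx]] <- simulate_flock(
        cfg_g, session_id = sprintf("%s_r%s_s%02d", g, rep_i, i),
        group = g, replicate = paste0(g, rep_i), day = day_i,
        seed = child[idx])
    }
  }
  out
}

# percent of visible animals per behavior typical of slow-growing broilers
# on pasture (range ~0.005% to ~33%), used by broiler_preset()
broiler_occupancy_pct <- c(
  "Roosting" = 31.34, "Walking" = 17.61, "Grass pecking" = 14.39,
  "Resting" = 13.49, "Other pecking" = 6.29, "Self-grooming" = 4.33,
  "Hiding" = 3.50, "Running" = 2.78, "Dust bathing" = 1.49,
  "Wing flapping" = 1.43, "Drinking" = 0.92, "Scratching" = 0.75,
  "Stretching" = 0.49, "Attacking" = 0.46, "Feed pecking" = 0.15,
  "Escaping" = 0.13, "Allo-grooming" = 0.06, "Swelling" = 0.05,
  "Sleeping" = 0.00, "Others" = 0.32
)

# default mean bout lengths (s): static behaviors long, eating/comfort
# intermediate, startle/interaction behaviors short
broiler_bout_means <- c(
  "Roosting" = 240, "Resting" = 180, "Sleeping" = 120,
  "Walking" = 60, "Running" = 15, "Hiding" = 45,
  "Feed pecking" = 20, "Drinking" = 20, "Grass pecking" = 45,
  "Other pecking" = 30, "Self-grooming" = 60, "Scratching" = 20,
  "Stretching" = 10, "Wing flapping" = 8, "Swelling" = 10,
  "Dust bathing" = 120, "Attacking" = 8, "Escaping" = 8,
  "Allo-grooming" = 15, "Others" = 30
)

#' Packaged pasture-broiler simulation preset
#'
#' A ready-made [sim_config()] over [broiler_ethogram()] whose target
#' occupancies follow the occurrence spectrum observed for slow-growing
#' broilers on pasture — from roosting around 31% of visible animals per
#' scan down to behaviors at or below 0.05% — rescaled to sum to 1.  Bout
#' means are a simulator choice (static behaviors long, interaction
#' behaviors short), exposed for overriding.
#'
#' @inheritParams sim_config
#' @param mean_bout_s Optional named vector overriding some or all default
#'   bout means.
#' @return A [sim_config()].
#' @examples
#' cfg <- broiler_preset(n_animals = 10, seed = 1)
#' round(sum(cfg$target_occupancy), 10)
#' @export
broiler_preset <- function(n_animals = 50, duration_s = 7200,
                           visible_fraction = 0.9,
                           mean_visibility_bout_s = 300,
                           mean_bout_s = NULL, seed = NULL) {
  occ <- broiler_occupancy_pct / sum(broiler_occupancy_pct)
  mb <- broiler_bout_means
  if (!is.null(mean_bout_s)) mb[names(mean_bout_s)] <- mean_bout_s
  sim_config(broiler_ethogram(), occ, mb, n_animals = n_animals,
             duration_s = duration_s, visible_fraction = visible_fraction,
             mean_visibility_bout_s = mean_visibility_bout_s, seed = seed)
}
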