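# internal helpers shared across modules

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# deterministic child seeds below 2^31 for per-session simulation
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Label a sampling interval
#'
#' Human-readable method label for an interval in seconds: `"10min"` for
#' 600 s, `"90s"` for sub-minute or non-integer-minute intervals.
#'
#' @param interval_s Interval length in seconds.
#' @return Character vector of labels.
#' @examples
#' interval_label(c(600, 900, 1800, 90))
#' @export
interval_label <- function(interval_s) {
  ifelse(interval_s %% 60 == 0,
         paste0(interval_s / 60, "min"),
         paste0(interval_s, "s"))
}

stop_scanopt <- function(..., call. = FALSE) stop(..., call. = call.)

`%||%` <- function(a, b) if (is.null(a)) b else a

# strictly increasing check with informative name
assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    stop_scanopt(sprintf("`%s` must be a single number in [%s, %s]",
                         name, format(lower), format(upper)))
  }
  invisible(x)
}
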