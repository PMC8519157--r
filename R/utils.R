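#' @keywords internal
"_PACKAGE"

## Circular clock-time helpers. All clock arithmetic in this package is on
## hours in [0, 24); intervals are half-open [start, end) and may wrap
## midnight.

# signed circular distance a - b on a 24 h clock, result in (-12, 12]
circ_diff_hours <- function(a, b, period = 24) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}

# absolute circular distance on the clock
circ_dist_hours <- function(a, b, period = 24) {
  abs(circ_diff_hours(a, b, period))
}

# membership of clock hour t in the half-open interval [start, end),
# wrapping midnight when start > end
in_clock_window <- function(t, start, end, period = 24) {
  t <- t %% period
  start <- start %% period
  end <- end %% period
  if (start <= end) t >= start & t < end else t >= start | t < end
}

#' Format a clock hour as "HH:MM"
#'
#' Rounds to the nearest minute and wraps at midnight, so 23.9999 becomes
#' "00:00". `NA` input gives `NA` output (used for an undefined acrophase).
#'
#' @param hours numeric vector of clock hours in `[0, 24)`.
#' @return character vector of "HH:MM" labels.
#' @examples
#' clock_label(c(14.7167, 0, 23.9999))
#' @export
clock_label <- function(hours) {
  out <- rep(NA_character_, length(hours))
  ok <- !is.na(hours)
  if (any(ok)) {
    mins <- round(hours[ok] * 60) %% (24 * 60)
    out[ok] <- sprintf("%02d:%02d", mins %/% 60, mins %% 60)
  }
  out
}

# stop() with a prefix naming the pipeline stage, keeps error sources greppable
stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

# evaluate expr with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
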