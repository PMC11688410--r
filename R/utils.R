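#' @import data.table
#' @importFrom stats rpois rlnorm rexp runif pf pt sd aggregate setNames
#' @importFrom utils write.table read.delim modifyList
NULL

SECONDS_PER_DAY <- 86400

#' Clock hour of an absolute protocol timestamp
#'
#' Timestamps are seconds since protocol start (`t0`), and the protocol is
#' anchored so that t = 0 falls at lights-on (06:00 by default). This converts
#' an absolute timestamp into a clock hour in `[0, 24)`.
#'
#' @param t numeric vector of timestamps (s since protocol start).
#' @param lights_on clock hour of lights-on (default 6).
#' @return numeric vector of clock hours.
#' @keywords internal
clock_hour <- function(t, lights_on = 6) {
  (lights_on + t / 3600) %% 24
}

#' Test membership of timestamps in a daily clock window
#'
#' @param t numeric timestamps (s since protocol start).
#' @param window a water-access window as returned by
#'   [water_access_window()]: list with `type` one of
#'   "unrestricted", "none", "interval" and, for intervals, clock hours
#'   `start` and `end` (the window may wrap past midnight).
#' @param lights_on clock hour of lights-on.
#' @return logical vector.
#' @export
in_clock_window <- function(t, window, lights_on = 6) {
  if (window$type == "unrestricted") return(rep(TRUE, length(t)))
  if (window$type == "none") return(rep(FALSE, length(t)))
  h <- clock_hour(t, lights_on)
  len <- (window$end - window$start) %% 24
  ((h - window$start) %% 24) < len
}

#' Protocol day index of a timestamp
#'
#' Days are 24-h periods anchored at protocol start: day d covers
#' `[(d-1)*86400, d*86400)`.
#'
#' @param t numeric timestamps (s).
#' @return integer day indices (1-based).
#' @export
day_of <- function(t) {
  as.integer(floor(t / SECONDS_PER_DAY)) + 1L
}

# 32-bit LCG step, exact in double arithmetic (69069 * 2^32 < 2^53).
lcg32 <- function(x) (69069 * x + 1234567) %% 4294967296

#' Counter-based uniform deviate keyed by (seed, animal, day, counter)
#'
#' A stateless, vectorised pseudo-random stream: the same key always yields
#' the same deviate, independent of how many other draws were made. Used so
#' the simulator and the adjudication engine can agree on per-trial pre-cue
#' delays without sharing RNG state (replay is exact).
#'
#' @param seed integer scalar master seed.
#' @param animal_index integer vector, 1-based roster index.
#' @param day integer vector, protocol day.
#' @param counter integer vector, within-(animal, day) trial index.
#' @return numeric vector of deviates in (0, 1).
#' @keywords internal
keyed_uniform <- function(seed, animal_index, day, counter) {
  x <- (seed %% 4294967296) + animal_index * 2654435761 +
    day * 97655331 + counter * 7919
  x <- x %% 4294967296
  x <- lcg32(lcg32(lcg32(x)))
  (x + 0.5) / 4294967296
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cage <- function(...) stop(sprintf(...), call. = FALSE)
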