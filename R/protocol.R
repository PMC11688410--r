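PHASE_NAMES <- c("FREE_ADAPT", "DOOR_ADAPT", "NP_ADAPT", "WD_ADAPT",
                 "PP", "REVERSAL", "RT1", "RT2", "RT3", "RT4",
                 "AVOIDANCE", "HOME_CAGE_DELAY", "EXTINCTION")

# Corner layout: 1,2 front; 3,4 back; diagonal opposition 1<->4, 2<->3.
OPPOSITE_CORNER <- c(4L, 3L, 2L, 1L)

#' Build the default 34-day protocol calendar
#'
#' Encodes the full phase schedule: Free Adaptation (days 1-4, all doors
#' open), Door Adaptation (5-6, doors open on corner entry), Nose Poke
#' Adaptation (7-8, doors open on nose poke), Water Deprivation Adaptation
#' (day 9, first day of the restricted 3-h dark-phase water window), Place
#' Preference (10-12) and Reversal (13-15), four reaction-time tasks of
#' increasing difficulty (RT1 days 16-18: fixed 2 s pre-cue, 7 s cue;
#' RT2 19-21: variable 2/4/8 s pre-cue, 7 s cue; RT3 22-24: variable
#' pre-cue, 3 s cue; RT4 25-28: variable pre-cue, 1 s cue), Place Avoidance
#' (day 29, all doors closed, air puff on poke at the assigned corner),
#' a home-cage delay day (30, no in-cage events), and Extinction (31-34,
#' doors open on poke at any corner, no air puff).
#'
#' The water window is unrestricted for days 1-8, restricted to 3 h of the
#' dark phase (default 18:00-21:00) from day 9 onward, and empty on the
#' avoidance day.
#'
#' @param t0 protocol start timestamp (default 0, anchored at lights-on).
#' @param water_start,water_end clock hours of the restricted water window.
#' @param lights_on,lights_off light-phase clock hours.
#' @return an object of class `ic_protocol`: a data.frame of phases with
#'   attributes for clock configuration.
#' @export
build_default_protocol <- function(t0 = 0, water_start = 18, water_end = 21,
                                   lights_on = 6, lights_off = 18) {
  phases <- data.frame(
    phase = PHASE_NAMES,
    day_first = c(1L, 5L, 7L, 9L, 10L, 13L, 16L, 19L, 22L, 25L, 29L, 30L, 31L),
    day_last  = c(4L, 6L, 8L, 9L, 12L, 15L, 18L, 21L, 24L, 28L, 29L, 30L, 34L),
    doors = c("always_open", "open_on_visit", "open_on_poke", "open_on_poke",
              "assigned_only", "assigned_only",
              "rt_contingency", "rt_contingency", "rt_contingency", "rt_contingency",
              "all_closed", "all_closed", "open_on_poke"),
    water = c("unrestricted", "unrestricted", "unrestricted", "restricted",
              "restricted", "restricted", "restricted", "restricted",
              "restricted", "restricted", "none", "none", "restricted"),
    precue_set = c(NA, NA, NA, NA, NA, NA, "2", "2,4,8", "2,4,8", "2,4,8",
                   NA, NA, NA),
    cue_duration = c(NA, NA, NA, NA, NA, NA, 7, 7, 3, 1, NA, NA, NA),
    air_puff = c(rep(FALSE, 10), TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  structure(phases, class = c("ic_protocol", "data.frame"),
            t0 = t0, water_start = water_start, water_end = water_end,
            lights_on = lights_on, lights_off = lights_off)
}

#' Look up the phase in force on a protocol day
#'
#' @param protocol an `ic_protocol`.
#' @param day integer day index.
#' @return the one-row phase data.frame.
#' @export
phase_for_day <- function(protocol, day) {
  hit <- protocol$day_first <= day & protocol$day_last >= day
  if (sum(hit) != 1) stop_cage("day %d is not covered by exactly one phase", day)
  protocol[hit, , drop = FALSE]
}

#' Pre-cue delay set of a phase
#'
#' @param phase_row one-row phase data.frame.
#' @return numeric vector of pre-cue delays (s), or NULL for non-RT phases.
#' @export
precue_set_of <- function(phase_row) {
  if (is.na(phase_row$precue_set)) return(NULL)
  as.numeric(strsplit(phase_row$precue_set, ",", fixed = TRUE)[[1]])
}

is_rt_phase <- function(phase) phase %in% c("RT1", "RT2", "RT3", "RT4")

#' Daily water-access window of a phase
#'
#' Adaptation days 1-8 are unrestricted; the avoidance day has no water at
#' all; every other phase restricts water to a 3-h window inside the dark
#' phase (default 18:00-21:00, configurable on the protocol).
#'
#' @param phase_row one-row phase data.frame (from an `ic_protocol`).
#' @param protocol the protocol (for the configured window clock times).
#' @return list with `type` ("unrestricted", "none", "interval") and, for
#'   intervals, clock hours `start`/`end`.
#' @export
water_access_window <- function(phase_row, protocol) {
  switch(phase_row$water,
    unrestricted = list(type = "unrestricted"),
    none = list(type = "none"),
    restricted = list(type = "interval",
                      start = attr(protocol, "water_start"),
                      end = attr(protocol, "water_end")),
    stop_cage("phase %s has no water policy", phase_row$phase)
  )
}

#' Diagonally opposite corner
#'
#' Corners 1 and 2 are front, 3 and 4 back; opposition is diagonal
#' (1<->4, 2<->3). The map is an involution with no fixed point.
#'
#' @param corner integer in 1..4 (vectorised).
#' @return the opposite corner.
#' @export
reversal_corner <- function(corner) {
  if (any(!corner %in% 1:4)) stop_cage("invalid corner (must be 1..4)")
  OPPOSITE_CORNER[corner]
}

#' Assign each animal its place-preference corner
#'
#' Each animal should receive its least-visited corner from the adaptation
#' phases (to cancel pre-existing corner bias), subject to balancing: corner
#' occupancies may differ by at most 1, and genotype counts per corner by at
#' most 1 where arithmetically possible. Deterministic greedy rule: animals
#' are taken in genotype-alternating order (sorted by id within genotype)
#' and placed in their least-visited corner that still has capacity
#' (ties broken toward the lowest corner number).
#'
#' @param visit_counts numeric matrix (animals x 4 corners) of adaptation
#'   visit counts, rownames = animal_id. Columns are corners 1..4.
#' @param roster data.frame with `animal_id`, `genotype` (active animals).
#' @return named integer vector: assigned corner per animal_id.
#' @export
assign_corners <- function(visit_counts, roster) {
  roster <- as.data.frame(roster)
  if (!nrow(roster)) stop_cage("empty roster")
  ids <- roster$animal_id
  if (!all(ids %in% rownames(visit_counts)))
    stop_cage("visit_counts must cover every animal in the roster")
  if (ncol(visit_counts) != 4)
    stop_cage("visit_counts must have 4 corner columns")
  n <- length(ids)
  cap_total <- ceiling(n / 4)
  min_total <- floor(n / 4)
  gsplit <- split(ids[order(ids)], roster$genotype[match(sort(ids), ids)])
  gsplit <- lapply(gsplit, sort)
  cap_geno <- vapply(gsplit, function(x) ceiling(length(x) / 4), numeric(1))
  # genotype-alternating processing order
  ord <- character(0)
  queues <- gsplit
  while (any(lengths(queues) > 0)) {
    for (g in names(queues)) {
      if (length(queues[[g]])) {
        ord <- c(ord, queues[[g]][1])
        queues[[g]] <- queues[[g]][-1]
      }
    }
  }
  count_c <- rep(0L, 4)
  count_gc <- matrix(0L, nrow = length(gsplit), ncol = 4,
                     dimnames = list(names(gsplit), NULL))
  assigned <- setNames(integer(n), ord)
  for (k in seq_along(ord)) {
    id <- ord[k]
    g <- roster$genotype[match(id, ids)]
    remaining_after <- n - k
    feasible <- vapply(1:4, function(cc) {
      if (count_c[cc] >= cap_total) return(FALSE)
      if (count_gc[g, cc] >= cap_geno[g]) return(FALSE)
      cc_counts <- count_c
      cc_counts[cc] <- cc_counts[cc] + 1L
      deficit <- sum(pmax(0L, min_total - cc_counts))
      remaining_after >= deficit
    }, logical(1))
    if (!any(feasible)) {
      # genotype cap cannot be honoured; relax it (balance on totals wins)
      feasible <- vapply(1:4, function(cc) {
        if (count_c[cc] >= cap_total) return(FALSE)
        cc_counts <- count_c
        cc_counts[cc] <- cc_counts[cc] + 1L
        remaining_after >= sum(pmax(0L, min_total - cc_counts))
      }, logical(1))
    }
    prefs <- visit_counts[id, ]
    cand <- which(feasible)
    pick <- cand[order(prefs[cand], cand)][1]
    assigned[id] <- as.integer(pick)
    count_c[pick] <- count_c[pick] + 1L
    count_gc[g, pick] <- count_gc[g, pick] + 1L
  }
  assigned[ids]
}

#' Corner assigned for a given phase
#'
#' PP uses the place-preference corner; Reversal, all RT tasks, and the
#' avoidance day use the diagonally opposite corner (the reversal corner,
#' which is kept through the rest of the protocol). Other phases have no
#' assigned corner.
#'
#' @param assignment named integer vector from [assign_corners()].
#' @param phase phase name.
#' @return named integer vector of corners, or NULL.
#' @export
phase_assignment <- function(assignment, phase) {
  if (phase == "PP") return(assignment)
  if (phase %in% c("REVERSAL", "RT1", "RT2", "RT3", "RT4", "AVOIDANCE"))
    return(setNames(reversal_corner(assignment), names(assignment)))
  NULL
}

#' Detect dropout animals from daily lick totals
#'
#' An animal that fails to consume any water across a 48-h period (two
#' consecutive full in-cage days with zero licks) is flagged: the first time
#' it is rescued (removed for rehydration and re-introduced), the second
#' time it is removed from the experiment. The home-cage-delay day is
#' skipped in the rolling window (no animal is in the cage that day).
#'
#' @param ds an `ic_dataset`.
#' @param protocol an `ic_protocol`.
#' @return data.frame (animal_id, trigger_day, action) with action
#'   "rescue" or "remove"; zero rows if nobody dropped out.
#' @export
detect_dropouts <- function(ds, protocol) {
  days <- seq_len(max(protocol$day_last))
  in_cage <- vapply(days, function(d) phase_for_day(protocol, d)$phase != "HOME_CAGE_DELAY",
                    logical(1))
  days <- days[in_cage]
  vday <- day_of(ds$visits$t_start - ds$t0)
  idx <- match(ds$licks$visit_id, ds$visits$visit_id)
  lick_animal <- ds$visits$animal_id[idx]
  lick_day <- vday[idx]
  out <- list()
  for (id in ds$animals$animal_id) {
    sel <- which(lick_animal == id)
    daily <- vapply(days, function(d)
      sum(ds$licks$n_licks[sel[lick_day[sel] == d]]), numeric(1))
    run <- 0L; rescued <- FALSE
    for (j in seq_along(days)) {
      if (daily[j] == 0) run <- run + 1L else run <- 0L
      if (run >= 2L) {
        action <- if (!rescued) "rescue" else "remove"
        out[[length(out) + 1L]] <- data.frame(
          animal_id = id, trigger_day = days[j], action = action)
        if (action == "remove") break
        rescued <- TRUE
        run <- 0L
      }
    }
  }
  if (!length(out))
    return(data.frame(animal_id = character(0), trigger_day = integer(0),
                      action = character(0)))
  do.call(rbind, out)
}
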