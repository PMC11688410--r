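TRIAL_OUTCOMES <- c("PREMATURE", "CORRECT", "ABANDONED")

#' Draw pre-cue delays
#'
#' Draws i.i.d. uniformly from the phase's pre-cue delay set using R's
#' session RNG (reproducible under `set.seed`).
#'
#' @param precue_set nonempty numeric vector of delays (s).
#' @param n number of draws.
#' @return numeric vector of delays.
#' @export
draw_precue <- function(precue_set, n = 1) {
  if (!length(precue_set)) stop_cage("empty pre-cue set")
  precue_set[sample.int(length(precue_set), n, replace = TRUE)]
}

#' Keyed, stateless pre-cue draw shared by simulator and engine
#'
#' The pre-cue delay of trial `counter` of an animal on a given day is a
#' pure function of (seed, roster index, day, counter), so replaying
#' recorded events through the engine re-derives exactly the delays the
#' simulator drew. All arguments are vectorised.
#'
#' @param seed master seed.
#' @param animal_index 1-based index of the animal in the sorted roster.
#' @param day protocol day.
#' @param counter within-(animal, day) trial index (1-based).
#' @param precue_set numeric vector of candidate delays.
#' @return numeric vector of delays.
#' @export
precue_draw_keyed <- function(seed, animal_index, day, counter, precue_set) {
  if (!length(precue_set)) stop_cage("empty pre-cue set")
  u <- keyed_uniform(seed, animal_index, day, counter)
  precue_set[floor(u * length(precue_set)) + 1L]
}

#' Classify one reaction-time trial
#'
#' A trial starts at the first nose poke of a visit (t_init). After a
#' pre-cue delay `D` the LED lights for `C` seconds. The first
#' post-initiation poke decides: before the LED (`offset < D`) the trial is
#' PREMATURE; while the LED is lit (`D <= offset < D + C`) it is CORRECT;
#' if no poke lands before cue offset the trial is ABANDONED (pokes at
#' offsets `>= D + C` are ignored - the trial has already lapsed).
#'
#' @param offsets ascending numeric vector of poke times after t_init (s);
#'   may be empty.
#' @param D pre-cue delay (s), > 0.
#' @param C cue duration (s), > 0.
#' @return list(outcome, t_response) where t_response is the classifying
#'   offset or NA for ABANDONED.
#' @export
classify_trial <- function(offsets, D, C) {
  if (D <= 0 || C <= 0) stop_cage("D and C must be positive")
  if (length(offsets)) {
    if (any(offsets <= 0)) stop_cage("poke offsets must be positive")
    offsets <- sort(offsets)
    first <- offsets[1]
    if (first < D) return(list(outcome = "PREMATURE", t_response = first))
    if (first < D + C) return(list(outcome = "CORRECT", t_response = first))
  }
  list(outcome = "ABANDONED", t_response = NA_real_)
}

empty_trial_table <- function() {
  data.frame(animal_id = character(0), day = integer(0), visit_id = integer(0),
             phase = character(0), D = numeric(0), C = numeric(0),
             t_init = numeric(0), outcome = character(0),
             t_response = numeric(0), reward = logical(0))
}

#' Adjudicate a single corner visit under the phase contingency
#'
#' Applies the door/cue/puff policy of the phase in force to one visit's
#' poke stream:
#' \itemize{
#'   \item FREE_ADAPT: doors open, nothing to adjudicate.
#'   \item DOOR_ADAPT: door opens on corner entry.
#'   \item NP_ADAPT: door opens at the first nose poke.
#'   \item WD_ADAPT, PP, REVERSAL, EXTINCTION: door opens at the first poke
#'     if the water window is open at that moment (PP/REVERSAL additionally
#'     require the assigned corner; EXTINCTION rewards any corner).
#'   \item RT1-RT4 at the assigned corner: the first poke initiates a trial,
#'     the pre-cue delay is drawn from the keyed stream, and the trial is
#'     classified; the door opens only on a CORRECT response inside the
#'     water window. Non-assigned corners: no door, no trial.
#'   \item AVOIDANCE: a poke at the assigned corner triggers the air puff;
#'     doors never open.
#' }
#'
#' @param visit one-row visit data.frame.
#' @param pokes data.frame of this visit's pokes (may be empty).
#' @param phase_row one-row phase data.frame.
#' @param assignment named corner assignment (PP corners) or NULL.
#' @param ctx list with `seed`, `animal_index`, `trial_counter` (index this
#'   trial would get), and `protocol`.
#' @return list(door_opened, puff, trial) where trial is a one-row trial
#'   table or NULL.
#' @export
adjudicate_visit <- function(visit, pokes, phase_row, assignment, ctx) {
  phase <- phase_row$phase
  if (!phase %in% PHASE_NAMES) stop_cage("no contingency policy for phase %s", phase)
  window <- water_access_window(phase_row, ctx$protocol)
  lights_on <- attr(ctx$protocol, "lights_on") %||% 6
  poke_t <- sort(pokes$t)
  has_poke <- length(poke_t) > 0
  first_poke <- if (has_poke) poke_t[1] else NA_real_
  day <- day_of(visit$t_start - attr(ctx$protocol, "t0"))
  corner_assigned <- if (!is.null(assignment)) {
    pa <- phase_assignment(assignment, phase)
    !is.null(pa) && identical(as.integer(pa[[visit$animal_id]]),
                              as.integer(visit$corner))
  } else FALSE

  door <- FALSE; puff <- FALSE; trial <- NULL
  if (phase == "FREE_ADAPT") {
    door <- TRUE
  } else if (phase == "DOOR_ADAPT") {
    door <- TRUE
  } else if (phase == "NP_ADAPT") {
    door <- has_poke
  } else if (phase %in% c("WD_ADAPT", "EXTINCTION")) {
    door <- has_poke && in_clock_window(first_poke, window, lights_on)
  } else if (phase %in% c("PP", "REVERSAL")) {
    door <- has_poke && corner_assigned &&
      in_clock_window(first_poke, window, lights_on)
  } else if (is_rt_phase(phase)) {
    if (corner_assigned && has_poke) {
      D <- precue_draw_keyed(ctx$seed, ctx$animal_index, day,
                             ctx$trial_counter, precue_set_of(phase_row))
      C <- phase_row$cue_duration
      cls <- classify_trial(poke_t[-1] - first_poke, D, C)
      reward <- cls$outcome == "CORRECT" &&
        in_clock_window(first_poke + cls$t_response, window, lights_on)
      door <- reward
      trial <- data.frame(
        animal_id = visit$animal_id, day = day, visit_id = visit$visit_id,
        phase = phase, D = D, C = C, t_init = first_poke,
        outcome = cls$outcome,
        t_response = if (is.na(cls$t_response)) NA_real_ else first_poke + cls$t_response,
        reward = reward)
    }
  } else if (phase == "AVOIDANCE") {
    puff <- corner_assigned && has_poke
  } else if (phase == "HOME_CAGE_DELAY") {
    # animals are out of the cage; any stray visit gets closed doors
  }
  list(door_opened = door, puff = puff, trial = trial)
}

#' Adjudicate a whole recording
#'
#' Vectorised batch form of [adjudicate_visit()]: walks every visit in
#' entry-time order, maintains per-(animal, day) trial counters for the
#' keyed pre-cue stream, and returns the annotated visit table plus the
#' trial table (one row per initiated reaction-time trial). Semantics are
#' identical to applying [adjudicate_visit()] visit by visit (tested as a
#' property); deterministic given `seed`.
#'
#' @param ds an `ic_dataset`.
#' @param protocol an `ic_protocol`.
#' @param assignment named corner assignment from [assign_corners()].
#' @param seed master seed (the one the recording was generated with, for
#'   exact replay of pre-cue draws).
#' @return list(visits, trials): visits with `door_opened`, `puff`, `day`
#'   columns; trials as a trial table.
#' @export
run_session <- function(ds, protocol, assignment, seed) {
  v <- ds$visits
  if (!nrow(v)) {
    return(list(visits = cbind(v, day = integer(0), door_opened = logical(0),
                               puff = logical(0)),
                trials = empty_trial_table()))
  }
  t0 <- attr(protocol, "t0")
  lights_on <- attr(protocol, "lights_on") %||% 6
  n_days <- max(protocol$day_last)
  vt <- data.table::as.data.table(v)
  vt[, day := day_of(t_start - t0)]
  if (any(!vt$day %in% seq_len(n_days)))
    stop_cage("visit outside the protocol day range 1..%d", n_days)

  # first and second poke per visit (pokes are time-sorted in the dataset)
  pk <- data.table::as.data.table(ds$pokes)
  if (nrow(pk)) {
    data.table::setorder(pk, visit_id, t)
    pks <- pk[, list(p1 = t[1], p2 = if (.N > 1) t[2] else NA_real_,
                     np = .N), by = "visit_id"]
    vt <- merge(vt, pks, by = "visit_id", all.x = TRUE, sort = FALSE)
  } else {
    vt[, c("p1", "p2", "np") := list(NA_real_, NA_real_, 0L)]
  }
  vt[is.na(np), np := 0L]

  day_phase <- vapply(seq_len(n_days), function(d)
    phase_for_day(protocol, d)$phase, character(1))
  vt[, phase := day_phase[day]]
  if (any(!vt$phase %in% PHASE_NAMES))
    stop_cage("no contingency policy for phase %s", setdiff(vt$phase, PHASE_NAMES)[1])
  roster_ids <- sort(ds$animals$animal_id)
  vt[, animal_index := match(animal_id, roster_ids)]

  # assigned corner in force per visit (NA when the phase has none)
  vt[, assigned := NA_integer_]
  if (!is.null(assignment)) {
    for (ph in unique(vt$phase)) {
      pa <- phase_assignment(assignment, ph)
      if (!is.null(pa))
        vt[phase == ph, assigned := as.integer(pa[animal_id])]
    }
  }

  # water-window state of the first poke, per phase policy
  day_water <- vapply(seq_len(n_days), function(d)
    phase_for_day(protocol, d)$water, character(1))
  window <- list(type = "interval", start = attr(protocol, "water_start"),
                 end = attr(protocol, "water_end"))
  vt[, water := day_water[day]]
  vt[, p1_in_window := data.table::fifelse(
    water == "unrestricted", TRUE,
    data.table::fifelse(water == "none", FALSE,
                        in_clock_window(p1, window, lights_on) & !is.na(p1)))]

  vt[, has_poke := np > 0]
  vt[, at_assigned := !is.na(assigned) & corner == assigned]
  vt[, door_opened := FALSE]
  vt[, puff := FALSE]
  vt[phase %in% c("FREE_ADAPT", "DOOR_ADAPT"), door_opened := TRUE]
  vt[phase == "NP_ADAPT", door_opened := has_poke]
  vt[phase %in% c("WD_ADAPT", "EXTINCTION"), door_opened := has_poke & p1_in_window]
  vt[phase %in% c("PP", "REVERSAL"),
     door_opened := has_poke & at_assigned & p1_in_window]
  vt[phase == "AVOIDANCE", puff := has_poke & at_assigned]

  # reaction-time trials: first poke initiates, keyed pre-cue draw, classify
  is_trial <- is_rt_phase(vt$phase) & vt$at_assigned & vt$has_poke
  trials <- empty_trial_table()
  if (any(is_trial)) {
    tr <- vt[is_trial]
    data.table::setorder(tr, animal_id, t_start)
    tr[, counter := seq_len(.N), by = c("animal_id", "day")]
    cue_of <- setNames(protocol$cue_duration, protocol$phase)
    pset_of <- lapply(setNames(nm = unique(tr$phase)), function(ph)
      precue_set_of(protocol[protocol$phase == ph, , drop = FALSE]))
    tr[, C := cue_of[phase]]
    tr[, D := NA_real_]
    for (ph in names(pset_of))
      tr[phase == ph,
         D := precue_draw_keyed(seed, animal_index, day, counter, pset_of[[ph]])]
    off <- tr$p2 - tr$p1
    outcome <- data.table::fifelse(
      is.na(off) | off >= tr$D + tr$C, "ABANDONED",
      data.table::fifelse(off < tr$D, "PREMATURE", "CORRECT"))
    t_response <- data.table::fifelse(outcome == "ABANDONED", NA_real_, tr$p2)
    in_win <- data.table::fifelse(
      tr$water == "unrestricted", TRUE,
      data.table::fifelse(tr$water == "none", FALSE,
                          in_clock_window(t_response, window, lights_on)))
    reward <- outcome == "CORRECT" & !is.na(in_win) & in_win
    trials <- data.frame(animal_id = tr$animal_id, day = tr$day,
                         visit_id = tr$visit_id, phase = tr$phase,
                         D = tr$D, C = tr$C, t_init = tr$p1,
                         outcome = outcome, t_response = t_response,
                         reward = reward)
    trials <- trials[order(trials$t_init), , drop = FALSE]
    rownames(trials) <- NULL
    rw <- setNames(reward, tr$visit_id)
    vt[is_trial, door_opened := unname(rw[as.character(visit_id)])]
  }
  out_v <- as.data.frame(vt[, c("visit_id", "animal_id", "corner", "t_start",
                                "t_end", "day", "door_opened", "puff")])
  out_v <- out_v[order(out_v$t_start, out_v$visit_id), , drop = FALSE]
  rownames(out_v) <- NULL
  list(visits = out_v, trials = trials)
}

#' Export a trial table to CSV
#'
#' @param trials a trial table from [run_session()] or the simulator.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}
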