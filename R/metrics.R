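pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)

#' Per animal-day visit/lick counts
#'
#' Computes the adaptation-phase dependent variables for one animal-day
#' slice: Total Visits, Total Licks (sum of burst counts), Total Visits
#' with Nose Poke, Visits with >= 1 Lick, and Total Visits During Water
#' Access (membership by visit entry time).
#'
#' @param slice list with `visits`, `pokes`, `licks` for one animal-day.
#' @param window water-access window (see [water_access_window()]).
#' @param lights_on clock hour of lights-on.
#' @return one-row data.frame of counts.
#' @export
daily_counts <- function(slice, window = list(type = "unrestricted"),
                         lights_on = 6) {
  v <- slice$visits
  data.frame(
    total_visits = nrow(v),
    total_licks = sum(slice$licks$n_licks),
    visits_with_poke = length(unique(slice$pokes$visit_id)),
    visits_with_lick = length(unique(slice$licks$visit_id)),
    visits_during_water_access =
      if (window$type == "interval")
        sum(in_clock_window(v$t_start, window, lights_on)) else NA_integer_
  )
}

#' Place-preference dependent variables
#'
#' Assigned Visits, Assigned Visits with >= 1 Lick, and
#' %Correct Response = (Assigned Visits with >= 1 Lick / Total Visits) * 100.
#' The denominator is *all* visits, exactly as the protocol defines it; the
#' percentage is NA (not 0) when the animal made no visits.
#'
#' @param slice one animal-day slice.
#' @param assigned_corner the corner assigned for the phase in force
#'   (PP corner during PP, its diagonal opposite during Reversal).
#' @return one-row data.frame.
#' @export
place_preference_metrics <- function(slice, assigned_corner) {
  v <- slice$visits
  assigned <- v$visit_id[v$corner == assigned_corner]
  with_lick <- intersect(assigned, unique(slice$licks$visit_id))
  data.frame(
    assigned_visits = length(assigned),
    assigned_visits_with_lick = length(with_lick),
    pct_correct_pp = pct(length(with_lick), nrow(v))
  )
}

#' Reaction-time dependent variables for one animal-day
#'
#' Overall and per-pre-cue-delay outcome percentages:
#' %Abandoned = abandoned/trials * 100, %Premature = premature/trials * 100,
#' %Correct = correct/trials * 100, each also stratified by the individual
#' pre-cue delays (e.g. %Premature at D = 8 uses only D = 8 trials).
#' Percentages are NA when their denominator is zero.
#'
#' @param trials trial-table rows of one animal-day.
#' @param precue_set the phase's pre-cue delay set.
#' @return one-row data.frame with overall columns (`trials`,
#'   `pct_abandoned`, `pct_premature`, `pct_correct`) and per-delay columns
#'   `trials_D<d>`, `pct_abandoned_D<d>`, ...
#' @export
rt_metrics <- function(trials, precue_set) {
  if (nrow(trials) && any(!trials$D %in% precue_set))
    stop_cage("trial with pre-cue delay outside the phase set: %s",
              paste(setdiff(unique(trials$D), precue_set), collapse = ", "))
  tally <- function(tt) {
    n <- nrow(tt)
    data.frame(
      trials = n,
      pct_abandoned = pct(sum(tt$outcome == "ABANDONED"), n),
      pct_premature = pct(sum(tt$outcome == "PREMATURE"), n),
      pct_correct = pct(sum(tt$outcome == "CORRECT"), n)
    )
  }
  out <- tally(trials)
  for (d in precue_set) {
    sub <- tally(trials[trials$D == d, , drop = FALSE])
    names(sub) <- paste0(names(sub), "_D", d)
    out <- cbind(out, sub)
  }
  out
}

#' Avoidance / extinction dependent variables
#'
#' Total visits, visits to the (former reward, now air-puff) assigned
#' corner, and assigned-corner visits containing a nose poke - the working
#' memory error count of the avoidance phase. Also used on extinction days,
#' where lick counts come from [daily_counts()].
#'
#' @param slice one animal-day slice.
#' @param assigned_corner the air-puff corner.
#' @return one-row data.frame.
#' @export
avoidance_metrics <- function(slice, assigned_corner) {
  v <- slice$visits
  assigned <- v$visit_id[v$corner == assigned_corner]
  with_poke <- intersect(assigned, unique(slice$pokes$visit_id))
  data.frame(
    assigned_visits = length(assigned),
    assigned_visits_with_poke = length(with_poke)
  )
}

#' Assemble the long metric table for the whole cohort
#'
#' One row per (animal, day, dependent variable) across every protocol day
#' except the home-cage-delay day. Animals flagged as removed contribute
#' only days strictly before their removal day. This is the table the
#' statistics layer consumes.
#'
#' @param ds an `ic_dataset`.
#' @param protocol an `ic_protocol`.
#' @param assignment named corner assignment from [assign_corners()].
#' @param trial_table trial table from [run_session()] or the simulator.
#' @return data.frame (animal_id, genotype, phase, day, phase_day,
#'   variable, value); `phase_day` is the 1-based day within its phase.
#' @export
build_metric_table <- function(ds, protocol, assignment, trial_table) {
  lights_on <- attr(protocol, "lights_on")
  vdt <- data.table::as.data.table(ds$visits)
  vdt[, day := day_of(t_start - attr(protocol, "t0"))]
  pk <- data.table::as.data.table(ds$pokes)
  lk <- data.table::as.data.table(ds$licks)
  rows <- list()
  roster <- ds$animals
  for (dd in seq_len(max(protocol$day_last))) {
    ph <- phase_for_day(protocol, dd)
    if (ph$phase == "HOME_CAGE_DELAY") next
    window <- water_access_window(ph, protocol)
    day_visits <- vdt[day == dd]
    for (a in seq_len(nrow(roster))) {
      id <- roster$animal_id[a]
      if (roster$status[a] == "removed" && !is.na(roster$removal_day[a]) &&
          dd >= roster$removal_day[a]) next
      av <- day_visits[animal_id == id]
      slice <- list(
        visits = as.data.frame(av),
        pokes = as.data.frame(pk[visit_id %in% av$visit_id]),
        licks = as.data.frame(lk[visit_id %in% av$visit_id])
      )
      m <- daily_counts(slice, window, lights_on)
      pa <- phase_assignment(assignment, ph$phase)
      if (ph$phase %in% c("PP", "REVERSAL"))
        m <- cbind(m, place_preference_metrics(slice, pa[[id]]))
      if (is_rt_phase(ph$phase)) {
        tt <- trial_table[trial_table$animal_id == id & trial_table$day == dd, ,
                          drop = FALSE]
        m <- cbind(m, rt_metrics(tt, precue_set_of(ph)))
      }
      if (ph$phase == "AVOIDANCE")
        m <- cbind(m, avoidance_metrics(slice, pa[[id]]))
      if (ph$phase == "EXTINCTION") {
        avoid_corner <- phase_assignment(assignment, "AVOIDANCE")[[id]]
        m <- cbind(m, avoidance_metrics(slice, avoid_corner))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = id, genotype = roster$genotype[a], phase = ph$phase,
        day = dd, phase_day = dd - ph$day_first + 1L,
        variable = names(m), value = as.numeric(m[1, ]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the long metric table and per-day wide tables
#'
#' @param metric_table long table from [build_metric_table()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_metric_tables <- function(metric_table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(metric_table, file.path(dir, "metrics_long.csv"),
                   row.names = FALSE)
  for (d in sort(unique(metric_table$day))) {
    sub <- metric_table[metric_table$day == d, ]
    wide <- data.table::dcast(data.table::as.data.table(sub),
                              animal_id + genotype + phase + day ~ variable,
                              value.var = "value")
    utils::write.csv(wide, file.path(dir, sprintf("day_%02d.csv", d)),
                     row.names = FALSE)
  }
  invisible(dir)
}
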