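#' Genotype-level generative parameters
#'
#' The simulator models each genotype as a stationary behavioural phenotype:
#' corner visits follow an inhomogeneous Poisson process with separate
#' dark- and light-phase intensities (thinned to a 60 s minimum inter-visit
#' gap, since a mouse cannot re-enter a corner instantly); a visit contains
#' a nose poke with probability `p_poke`; premature poking during the
#' pre-cue delay is a Poisson process with hazard `h` (s^-1), so
#' P(premature) = 1 - exp(-h D); the post-cue response latency is
#' exponential with rate `r` (s^-1), so P(correct | not premature) =
#' 1 - exp(-r C); rewarded visits yield a lick burst with mean
#' `lick_burst_mean` licks; and a visit targets the currently assigned
#' corner with probability `p_visit_assigned`.
#'
#' @param visit_rate_dark,visit_rate_light visits per hour in each phase.
#' @param p_poke probability a visit contains at least one nose poke.
#' @param lick_burst_mean mean licks per rewarded visit (>= 1).
#' @param h premature-poke hazard during the pre-cue delay (s^-1).
#' @param r cue-response rate after LED onset (s^-1).
#' @param p_visit_assigned probability a visit targets the assigned corner.
#' @return a `genotype_params` list.
#' @export
genotype_params <- function(visit_rate_dark, visit_rate_light, p_poke,
                            lick_burst_mean, h, r, p_visit_assigned) {
  stopifnot(visit_rate_dark >= 0, visit_rate_light >= 0,
            p_poke >= 0, p_poke <= 1, lick_burst_mean >= 1,
            h >= 0, r >= 0, p_visit_assigned >= 0, p_visit_assigned <= 1)
  structure(list(visit_rate_dark = visit_rate_dark,
                 visit_rate_light = visit_rate_light,
                 p_poke = p_poke, lick_burst_mean = lick_burst_mean,
                 h = h, r = r, p_visit_assigned = p_visit_assigned),
            class = "genotype_params")
}

#' Simulation configuration
#'
#' @param n_per_genotype named integer vector of cohort sizes, e.g.
#'   `c(NonTg = 14, TG = 10)`.
#' @param params named list of [genotype_params()], one per genotype.
#' @param protocol an `ic_protocol` (default [build_default_protocol()]).
#' @param seed master seed.
#' @param days optional integer vector restricting simulation to a subset of
#'   protocol days (default: all days in the protocol).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_per_genotype, params, protocol = build_default_protocol(),
                       seed = 1, days = NULL) {
  stopifnot(all(n_per_genotype >= 1), all(names(n_per_genotype) %in% names(params)))
  structure(list(n_per_genotype = n_per_genotype, params = params,
                 protocol = protocol, seed = seed,
                 days = days %||% seq_len(max(protocol$day_last))),
            class = "sim_config")
}

#' Closed-form expected trial-outcome fractions
#'
#' Under the generative model (constant premature hazard `h` during the
#' pre-cue delay `D`, exponential cue-response latency with rate `r` during
#' the cue `C`):
#' \deqn{p_{prem} = 1 - e^{-hD}, \quad
#'       p_{corr} = e^{-hD}(1 - e^{-rC}), \quad
#'       p_{aband} = e^{-hD} e^{-rC}}
#' The three fractions sum to 1.
#'
#' @param h premature hazard (s^-1), >= 0.
#' @param r cue-response rate (s^-1), >= 0.
#' @param D pre-cue delay (s), > 0.
#' @param C cue duration (s), > 0.
#' @return named numeric vector (p_prem, p_corr, p_aband).
#' @export
expected_outcome_fractions <- function(h, r, D, C) {
  if (h < 0 || r < 0) stop_cage("rates must be nonnegative")
  if (D <= 0 || C <= 0) stop_cage("D and C must be positive")
  s <- exp(-h * D)
  c(p_prem = 1 - s, p_corr = s * (1 - exp(-r * C)), p_aband = s * exp(-r * C))
}

#' Simulate bare trial outcomes from the hazard model
#'
#' Trial-level Monte Carlo primitive (no cage geometry): draws a premature
#' latency Exp(h) and a cue-response latency Exp(r) per trial and classifies
#' against (D, C). The stochastic counterpart of
#' [expected_outcome_fractions()].
#'
#' @param n number of trials.
#' @param h,r hazard and response rates (s^-1).
#' @param D,C pre-cue delay and cue duration (s).
#' @return character vector of outcomes.
#' @export
simulate_trials <- function(n, h, r, D, C) {
  t_prem <- if (h > 0) rexp(n, h) else rep(Inf, n)
  t_resp <- if (r > 0) rexp(n, r) else rep(Inf, n)
  out <- rep("ABANDONED", n)
  out[t_resp < C] <- "CORRECT"
  out[t_prem < D] <- "PREMATURE"
  out
}

#' Estimate the premature hazard from an observed premature percentage
#'
#' Inverts p_prem = 1 - exp(-h D): `h_hat = -log(1 - pct/100) / D`.
#'
#' @param pct_premature percentage of premature trials at delay `D`.
#' @param D pre-cue delay (s).
#' @return hazard estimate (s^-1).
#' @export
estimate_hazard <- function(pct_premature, D) {
  -log(1 - pct_premature / 100) / D
}

# --- cohort simulation ------------------------------------------------------

MIN_VISIT_GAP <- 60   # hard-core thinning: min seconds between visit entries
MAX_VISIT_DUR <- 50   # cap on drawn visit duration; spans stay < MIN_VISIT_GAP

sim_roster <- function(n_per_genotype) {
  ids <- unlist(lapply(names(n_per_genotype), function(g)
    sprintf("%s%03d", substr(g, 1, 2), seq_len(n_per_genotype[[g]]))))
  genos <- rep(names(n_per_genotype), unlist(n_per_genotype))
  data.frame(animal_id = ids, genotype = genos, cage_id = "cage1",
             status = "active", removal_day = NA_integer_)
}

# keep sorted start times at least `gap` apart (sequential hard-core thinning)
thin_min_gap <- function(start, gap) {
  n <- length(start)
  if (n < 2) return(rep(TRUE, n))
  keep <- logical(n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (start[i] - last >= gap) {
      keep[i] <- TRUE
      last <- start[i]
    }
  }
  keep
}

# One animal-day of events; start times are final before any event is placed,
# so water-window checks here agree exactly with replay through the engine.
sim_animal_day <- function(animal_id, animal_index, par, day, phase_row,
                           protocol, assignment, seed) {
  phase <- phase_row$phase
  if (phase == "HOME_CAGE_DELAY") return(NULL)
  day0 <- (day - 1) * SECONDS_PER_DAY
  lights_on <- attr(protocol, "lights_on")
  # the protocol day starts at lights-on: light phase = first 12 h
  n_light <- rpois(1, par$visit_rate_light * 12)
  n_dark <- rpois(1, par$visit_rate_dark * 12)
  start <- sort(c(runif(n_light, 0, 12 * 3600),
                  runif(n_dark, 12 * 3600, 24 * 3600)))
  start <- start[start <= SECONDS_PER_DAY - MIN_VISIT_GAP]
  start <- start[thin_min_gap(start, MIN_VISIT_GAP)]
  n <- length(start)
  if (!n) return(NULL)
  start <- day0 + start

  pa <- phase_assignment(assignment, phase)
  target <- if (!is.null(pa)) as.integer(pa[[animal_id]]) else NA_integer_
  if (!is.na(target)) {
    hit <- runif(n) < par$p_visit_assigned
    corner <- ifelse(hit, target,
                     ((target - 1L + sample.int(3, n, replace = TRUE)) %% 4L) + 1L)
  } else {
    corner <- sample.int(4, n, replace = TRUE)
  }
  has_poke <- runif(n) < par$p_poke
  dur <- pmin(rlnorm(n, log(10), 0.6), MAX_VISIT_DUR)
  window <- water_access_window(phase_row, protocol)

  poke1_off <- runif(n, 0.3, 1.5)          # first poke after corner entry
  poke2_off <- rep(NA_real_, n)            # classifying second poke (RT)
  lick_off <- rep(NA_real_, n)
  n_licks <- rep(NA_integer_, n)
  trial <- NULL
  span <- dur

  burst <- function(k) 1L + rpois(k, par$lick_burst_mean - 1)

  if (phase %in% c("FREE_ADAPT", "DOOR_ADAPT")) {
    # doors open without poking; visits with drinking intent lick directly
    has_poke[] <- FALSE
    drink <- which(runif(n) < par$p_poke)
    lick_off[drink] <- pmax(0.5, 0.5 * dur[drink])
  } else if (phase %in% c("NP_ADAPT", "WD_ADAPT")) {
    poked <- which(has_poke)
    ok <- if (phase == "NP_ADAPT") poked else
      poked[in_clock_window(start[poked] + poke1_off[poked], window, lights_on)]
    lick_off[ok] <- poke1_off[ok] + 1.5
  } else if (phase %in% c("PP", "REVERSAL")) {
    ok <- which(has_poke & corner == target &
                  in_clock_window(start + poke1_off, window, lights_on))
    lick_off[ok] <- poke1_off[ok] + 1.5
  } else if (is_rt_phase(phase)) {
    C <- phase_row$cue_duration
    pset <- precue_set_of(phase_row)
    idx <- which(has_poke & corner == target)
    if (length(idx)) {
      k <- length(idx)
      D <- precue_draw_keyed(seed, animal_index, day, seq_len(k), pset)
      t_prem <- if (par$h > 0) rexp(k, par$h) else rep(Inf, k)
      t_resp <- if (par$r > 0) rexp(k, par$r) else rep(Inf, k)
      premature <- t_prem < D
      correct <- !premature & t_resp < C
      resp_off <- ifelse(premature, t_prem, ifelse(correct, D + t_resp, NA))
      t_init <- start[idx] + poke1_off[idx]
      t_response <- t_init + resp_off
      reward <- correct & in_clock_window(t_response, window, lights_on)
      reward[is.na(reward)] <- FALSE
      poke2_off[idx] <- poke1_off[idx] + resp_off
      rew <- idx[reward]
      lick_off[rew] <- poke2_off[rew] + 1.5
      span[idx] <- pmax(span[idx], poke1_off[idx] +
                          ifelse(is.na(resp_off), D + C, resp_off) + 1)
      outcome <- ifelse(premature, "PREMATURE",
                        ifelse(correct, "CORRECT", "ABANDONED"))
      trial <- data.frame(
        animal_id = animal_id, day = day, visit_row = idx, phase = phase,
        D = D, C = C, t_init = t_init, outcome = outcome,
        t_response = ifelse(is.na(resp_off), NA_real_, t_response),
        reward = reward)
    }
  } else if (phase == "AVOIDANCE") {
    # doors closed everywhere, no water; pokes at the assigned corner puff
  } else if (phase == "EXTINCTION") {
    ok <- which(has_poke & in_clock_window(start + poke1_off, window, lights_on))
    lick_off[ok] <- poke1_off[ok] + 1.5
  }

  has_lick <- !is.na(lick_off)
  n_licks[has_lick] <- burst(sum(has_lick))
  span <- pmax(span, poke1_off + 0.5, ifelse(has_lick, lick_off + 2, 0))
  visits <- data.frame(animal_id = animal_id, corner = corner,
                       t_start = start, t_end = start + span)
  list(visits = visits, has_poke = has_poke, poke1_off = poke1_off,
       poke2_off = poke2_off, lick_off = lick_off, n_licks = n_licks,
       trials = trial)
}

#' Simulate a full cohort event stream
#'
#' Generates an `ic_dataset` with the statistical structure the analysis
#' assumes, plus the ground-truth trial table recorded as the events were
#' generated. Corner assignment mirrors the real protocol: adaptation-phase
#' visit counts (days 1-9) determine each animal's least-visited corner via
#' [assign_corners()]; if the simulated day subset contains no adaptation
#' days, assignment falls back to the same deterministic balancing rule on
#' zero counts. Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list(dataset, trials, assignment, config).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  protocol <- config$protocol
  roster <- sim_roster(config$n_per_genotype)
  roster <- roster[order(roster$animal_id), , drop = FALSE]
  days <- sort(config$days)
  set.seed(config$seed)

  adapt_days <- days[days <= 9]
  later_days <- days[days > 9]
  pieces <- list()

  run_days <- function(day_set, assignment, acc) {
    for (day in day_set) {
      ph <- phase_for_day(protocol, day)
      for (a in seq_len(nrow(roster))) {
        par <- config$params[[roster$genotype[a]]]
        res <- sim_animal_day(roster$animal_id[a], a, par, day, ph,
                              protocol, assignment, config$seed)
        if (!is.null(res)) acc[[length(acc) + 1L]] <- res
      }
    }
    acc
  }

  pieces <- run_days(adapt_days, NULL, pieces)
  # corner assignment from adaptation visit counts (zero counts if absent)
  counts <- matrix(0, nrow = nrow(roster), ncol = 4,
                   dimnames = list(roster$animal_id, NULL))
  for (p in pieces) {
    id <- p$visits$animal_id[1]
    counts[id, ] <- counts[id, ] +
      as.numeric(table(factor(p$visits$corner, levels = 1:4)))
  }
  assignment <- assign_corners(counts, roster)
  pieces <- run_days(later_days, assignment, pieces)

  # assemble global tables with visit ids in entry-time order
  visits <- do.call(rbind, lapply(pieces, `[[`, "visits"))
  if (is.null(visits) || !nrow(visits)) {
    ds <- ic_dataset(roster,
                     data.frame(visit_id = integer(0), animal_id = character(0),
                                corner = integer(0), t_start = numeric(0),
                                t_end = numeric(0)),
                     data.frame(visit_id = integer(0), side = character(0),
                                t = numeric(0)),
                     data.frame(visit_id = integer(0), t = numeric(0),
                                n_licks = integer(0)),
                     t0 = attr(protocol, "t0"),
                     lights_on = attr(protocol, "lights_on"),
                     lights_off = attr(protocol, "lights_off"))
    return(list(dataset = ds, trials = empty_trial_table(),
                assignment = assignment, config = config))
  }
  ord <- order(visits$t_start)
  global_id <- integer(nrow(visits))
  global_id[ord] <- seq_len(nrow(visits))
  visits$visit_id <- global_id
  offs <- cumsum(c(0, vapply(pieces, function(p) nrow(p$visits), numeric(1))))

  pokes <- list(); licks <- list(); trial_rows <- list()
  for (j in seq_along(pieces)) {
    p <- pieces[[j]]
    ids <- global_id[(offs[j] + 1):offs[j + 1]]
    t_start <- p$visits$t_start
    p1 <- which(p$has_poke)
    if (length(p1))
      pokes[[length(pokes) + 1L]] <- data.frame(
        visit_id = ids[p1], side = "left", t = t_start[p1] + p$poke1_off[p1])
    p2 <- which(!is.na(p$poke2_off))
    if (length(p2))
      pokes[[length(pokes) + 1L]] <- data.frame(
        visit_id = ids[p2], side = "left", t = t_start[p2] + p$poke2_off[p2])
    li <- which(!is.na(p$lick_off))
    if (length(li))
      licks[[length(licks) + 1L]] <- data.frame(
        visit_id = ids[li], t = t_start[li] + p$lick_off[li],
        n_licks = p$n_licks[li])
    if (!is.null(p$trials)) {
      tr <- p$trials
      tr$visit_id <- ids[tr$visit_row]
      trial_rows[[length(trial_rows) + 1L]] <- tr
    }
  }
  visits <- visits[ord, c("visit_id", "animal_id", "corner", "t_start", "t_end")]
  pokes <- if (length(pokes)) do.call(rbind, pokes) else
    data.frame(visit_id = integer(0), side = character(0), t = numeric(0))
  licks <- if (length(licks)) do.call(rbind, licks) else
    data.frame(visit_id = integer(0), t = numeric(0), n_licks = integer(0))

  trials <- if (length(trial_rows)) do.call(rbind, trial_rows) else NULL
  if (!is.null(trials)) {
    trials <- trials[order(trials$t_init),
                     c("animal_id", "day", "visit_id", "phase", "D", "C",
                       "t_init", "outcome", "t_response", "reward")]
    rownames(trials) <- NULL
  } else trials <- empty_trial_table()

  ds <- ic_dataset(roster, visits, pokes, licks,
                   t0 = attr(protocol, "t0"),
                   lights_on = attr(protocol, "lights_on"),
                   lights_off = attr(protocol, "lights_off"))
  list(dataset = ds, trials = trials, assignment = assignment, config = config)
}

#' Packaged cohort scenario mirroring the published study design
#'
#' 14 NonTg and 10 TG (3xTg-AD-like) females under the full 34-day
#' protocol. TG animals have higher visit rates and water-seeking drive,
#' a higher premature-poke hazard (impulsivity) and a lower cue-response
#' rate (attention), so the simulated pipeline reproduces the qualitative
#' signature of the study: TG make more Total Visits and Total Trials,
#' NonTg make more Total Licks and reach a higher %Correct in the harder
#' reaction-time tasks.
#'
#' @param seed master seed.
#' @param days optional day subset (see [sim_config()]).
#' @return a `sim_config`.
#' @export
scenario_paper_like <- function(seed = 1, days = NULL) {
  sim_config(
    n_per_genotype = c(NonTg = 14, TG = 10),
    params = list(
      NonTg = genotype_params(visit_rate_dark = 6, visit_rate_light = 1.5,
                              p_poke = 0.70, lick_burst_mean = 30,
                              h = 0.05, r = 0.5, p_visit_assigned = 0.40),
      TG = genotype_params(visit_rate_dark = 8, visit_rate_light = 2,
                           p_poke = 0.75, lick_burst_mean = 34,
                           h = 0.15, r = 0.3, p_visit_assigned = 0.40)
    ),
    seed = seed, days = days
  )
}

#' Null scenario: both genotypes share one phenotype
#'
#' Identical generative parameters for NonTg and TG (the NonTg parameters of
#' [scenario_paper_like()]), for type-I-error calibration of the
#' statistical layer.
#'
#' @param seed master seed.
#' @param days optional day subset.
#' @return a `sim_config`.
#' @export
scenario_null <- function(seed = 1, days = NULL) {
  p <- genotype_params(visit_rate_dark = 6, visit_rate_light = 1.5,
                       p_poke = 0.70, lick_burst_mean = 30,
                       h = 0.05, r = 0.5, p_visit_assigned = 0.40)
  sim_config(n_per_genotype = c(NonTg = 14, TG = 10),
             params = list(NonTg = p, TG = p), seed = seed, days = days)
}
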