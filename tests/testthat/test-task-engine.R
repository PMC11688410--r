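test_that("classify_trial implements the three-outcome window rule", {
  expect_equal(classify_trial(2.5, D = 2, C = 7),
               list(outcome = "CORRECT", t_response = 2.5))
  # boundary of the [D, D+C) cue window at D=8, C=1
  expect_equal(classify_trial(8.95, 8, 1)$outcome, "CORRECT")
  expect_equal(classify_trial(9.05, 8, 1)$outcome, "ABANDONED")
  expect_equal(classify_trial(8, 8, 1)$outcome, "CORRECT")  # poke exactly at LED onset
  # the first post-initiation poke decides
  expect_equal(classify_trial(c(1.0, 5.0), 4, 3),
               list(outcome = "PREMATURE", t_response = 1.0))
  expect_equal(classify_trial(numeric(0), 2, 7)$outcome, "ABANDONED")
  expect_error(classify_trial(-1, 2, 7), "positive")
  expect_error(classify_trial(1, 0, 7), "positive")
})

test_that("classify_trial agrees with the interval-membership oracle", {
  set.seed(11)
  for (i in 1:2000) {
    D <- sample(c(2, 4, 8), 1)
    C <- sample(c(7, 3, 1), 1)
    n <- sample(0:5, 1)
    offsets <- sort(runif(n, 0.01, D + C + 4))
    got <- classify_trial(offsets, D, C)
    want <- oracle_classify(offsets, D, C)
    expect_identical(got$outcome, want$outcome)
    expect_identical(got$t_response, want$t_response)
  }
})

test_that("draw_precue is uniform over the set and respects the seed", {
  expect_true(all(draw_precue(2, 100) == 2))
  expect_error(draw_precue(numeric(0)), "empty")
  set.seed(99); a <- draw_precue(c(2, 4, 8), 50)
  set.seed(99); b <- draw_precue(c(2, 4, 8), 50)
  expect_identical(a, b)
  set.seed(7)
  draws <- draw_precue(c(2, 4, 8), 30000)
  se <- sqrt((1 / 3) * (2 / 3) / 30000)
  for (d in c(2, 4, 8))
    expect_lt(abs(mean(draws == d) - 1 / 3), 3 * se)
})

test_that("keyed pre-cue stream is stateless, deterministic, and uniform", {
  d1 <- precue_draw_keyed(42, 1:10, 16, 1:10, c(2, 4, 8))
  d2 <- precue_draw_keyed(42, 1:10, 16, 1:10, c(2, 4, 8))
  expect_identical(d1, d2)
  expect_false(identical(d1, precue_draw_keyed(43, 1:10, 16, 1:10, c(2, 4, 8))))
  draws <- precue_draw_keyed(5, 1, 20, 1:30000, c(2, 4, 8))
  se <- sqrt((1 / 3) * (2 / 3) / 30000)
  for (d in c(2, 4, 8))
    expect_lt(abs(mean(draws == d) - 1 / 3), 3 * se)
})

test_that("adjudicate_visit applies each phase policy", {
  protocol <- build_default_protocol()
  assignment <- c(m1 = 1L, m2 = 2L)
  ctx <- list(seed = 1, animal_index = 1L, trial_counter = 1L,
              protocol = protocol)
  # day 10 (PP), visit in the 18:00-21:00 window: day offset 12.5 h
  tw <- 9 * 86400 + 12.5 * 3600
  visit_pp <- data.frame(visit_id = 1L, animal_id = "m1", corner = 1L,
                         t_start = tw, t_end = tw + 40)
  pokes <- data.frame(visit_id = 1L, side = "left", t = tw + 2)
  res <- adjudicate_visit(visit_pp, pokes, phase_for_day(protocol, 10),
                          assignment, ctx)
  expect_true(res$door_opened)
  expect_null(res$trial)
  # same visit outside the window: no door
  visit_day <- visit_pp; visit_day$t_start <- 9 * 86400 + 3 * 3600
  visit_day$t_end <- visit_day$t_start + 40
  pokes_day <- data.frame(visit_id = 1L, side = "left",
                          t = visit_day$t_start + 2)
  expect_false(adjudicate_visit(visit_day, pokes_day,
                                phase_for_day(protocol, 10), assignment,
                                ctx)$door_opened)

  # RT3 (day 22), non-assigned corner: pokes but no trial
  t3 <- 21 * 86400 + 13 * 3600
  visit_rt <- data.frame(visit_id = 2L, animal_id = "m1", corner = 2L,
                         t_start = t3, t_end = t3 + 40)
  res <- adjudicate_visit(visit_rt, data.frame(visit_id = 2L, side = "left",
                                               t = t3 + 1),
                          phase_for_day(protocol, 22), assignment, ctx)
  expect_null(res$trial)
  expect_false(res$door_opened)

  # RT3 assigned corner (m1's RT corner = reversal of 1 = 4): trial emitted
  visit_rt4 <- visit_rt; visit_rt4$corner <- 4L
  res <- adjudicate_visit(visit_rt4,
                          data.frame(visit_id = 2L, side = "left",
                                     t = c(t3 + 1, t3 + 1.5)),
                          phase_for_day(protocol, 22), assignment, ctx)
  expect_false(is.null(res$trial))
  expect_equal(res$trial$outcome, "PREMATURE")  # 0.5 s < any pre-cue delay

  # AVOIDANCE (day 29) at the assigned corner: puff, never a door
  t29 <- 28 * 86400 + 13 * 3600
  visit_av <- data.frame(visit_id = 3L, animal_id = "m1", corner = 4L,
                         t_start = t29, t_end = t29 + 30)
  res <- adjudicate_visit(visit_av, data.frame(visit_id = 3L, side = "left",
                                               t = t29 + 1),
                          phase_for_day(protocol, 29), assignment, ctx)
  expect_true(res$puff)
  expect_false(res$door_opened)
  expect_null(res$trial)

  bad_phase <- phase_for_day(protocol, 29); bad_phase$phase <- "MYSTERY"
  expect_error(adjudicate_visit(visit_av, pokes, bad_phase, assignment, ctx),
               "no contingency policy")
})

test_that("run_session matches per-visit adjudicate_visit", {
  sim <- simulate_cohort(small_config(seed = 21, days = c(10, 16, 22, 29)))
  ds <- sim$dataset
  protocol <- sim$config$protocol
  ses <- run_session(ds, protocol, sim$assignment, 21)

  # scalar reference path
  v <- ds$visits
  v$day <- day_of(v$t_start)
  v <- v[order(v$animal_id, v$t_start), ]
  roster_ids <- sort(ds$animals$animal_id)
  counters <- list()
  trials <- list(); door <- logical(nrow(v)); puff <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    vi <- v[i, ]
    key <- paste0(vi$animal_id, ".", vi$day)
    cnt <- (counters[[key]] %||% 0L) + 1L
    res <- adjudicate_visit(vi, ds$pokes[ds$pokes$visit_id == vi$visit_id, ],
                            phase_for_day(protocol, vi$day), sim$assignment,
                            list(seed = 21,
                                 animal_index = match(vi$animal_id, roster_ids),
                                 trial_counter = cnt, protocol = protocol))
    if (!is.null(res$trial)) {
      trials[[length(trials) + 1L]] <- res$trial
      counters[[key]] <- cnt
    }
    door[i] <- res$door_opened; puff[i] <- res$puff
  }
  ref_trials <- do.call(rbind, trials)
  ref_trials <- ref_trials[order(ref_trials$t_init), ]
  rownames(ref_trials) <- NULL
  expect_equal(ses$trials, ref_trials)
  ord <- match(ses$visits$visit_id, v$visit_id)
  expect_equal(ses$visits$door_opened, door[ord])
  expect_equal(ses$visits$puff, puff[ord])
})

test_that("run_session trivia: empty input, animal independence", {
  ds0 <- tiny_dataset()
  ds0$visits <- ds0$visits[0, ]; ds0$pokes <- ds0$pokes[0, ]
  ds0$licks <- ds0$licks[0, ]
  ses <- run_session(ds0, build_default_protocol(), c(m1 = 1L, m2 = 2L), 1)
  expect_equal(nrow(ses$trials), 0)

  sim <- simulate_cohort(small_config(seed = 8, days = 19:20))
  ses_all <- run_session(sim$dataset, sim$config$protocol, sim$assignment, 8)
  drop_id <- sim$dataset$animals$animal_id[1]
  ds <- sim$dataset
  keep <- ds$visits$animal_id != drop_id
  kept_ids <- ds$visits$visit_id[keep]
  ds2 <- ic_dataset(ds$animals, ds$visits[keep, ],
                    ds$pokes[ds$pokes$visit_id %in% kept_ids, ],
                    ds$licks[ds$licks$visit_id %in% kept_ids, ])
  ses_sub <- run_session(ds2, sim$config$protocol, sim$assignment, 8)
  a <- ses_all$trials[ses_all$trials$animal_id != drop_id, ]
  rownames(a) <- NULL
  expect_equal(ses_sub$trials, a)
})

test_that("trial records satisfy the outcome/response/reward invariants", {
  sim <- simulate_cohort(small_config(seed = 13, days = 16:28))
  tr <- sim$trials
  expect_gt(nrow(tr), 50)
  expect_true(all(tr$outcome %in% c("PREMATURE", "CORRECT", "ABANDONED")))
  prem <- tr[tr$outcome == "PREMATURE", ]
  expect_true(all(prem$t_response > prem$t_init & prem$t_response < prem$t_init + prem$D))
  expect_true(all(!prem$reward))
  corr <- tr[tr$outcome == "CORRECT", ]
  expect_true(all(corr$t_response >= corr$t_init + corr$D &
                    corr$t_response < corr$t_init + corr$D + corr$C))
  ab <- tr[tr$outcome == "ABANDONED", ]
  expect_true(all(is.na(ab$t_response)) && all(!ab$reward))
  # reward implies a correct response inside the water window
  expect_true(all(tr$outcome[tr$reward] == "CORRECT"))
  win <- list(type = "interval", start = 18, end = 21)
  expect_true(all(in_clock_window(tr$t_response[tr$reward], win)))
  corr_in <- corr[in_clock_window(corr$t_response, win), ]
  expect_true(all(corr_in$reward))
  # doors never open on the avoidance day
  sim29 <- simulate_cohort(small_config(seed = 14, days = 29))
  ses29 <- run_session(sim29$dataset, sim29$config$protocol, sim29$assignment, 14)
  expect_false(any(ses29$visits$door_opened))
  expect_equal(nrow(ses29$trials), 0)
})
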