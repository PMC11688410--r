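slice_of <- function(visits, pokes = NULL, licks = NULL) {
  list(visits = visits,
       pokes = pokes %||% data.frame(visit_id = integer(0), side = character(0),
                                     t = numeric(0)),
       licks = licks %||% data.frame(visit_id = integer(0), t = numeric(0),
                                     n_licks = integer(0)))
}

test_that("daily_counts counts visits, pokes, licks, and water-access visits", {
  v <- data.frame(visit_id = 1:7, animal_id = "m1", corner = 1,
                  t_start = c(1, 2, 3, 4, 5, 12.2, 13) * 3600,
                  t_end = c(1, 2, 3, 4, 5, 12.2, 13) * 3600 + 60)
  p <- data.frame(visit_id = c(1, 1, 2, 6), side = "left",
                  t = v$t_start[c(1, 1, 2, 6)] + 5)
  l <- data.frame(visit_id = c(2, 6), t = v$t_start[c(2, 6)] + 10,
                  n_licks = c(3, 9))
  m <- daily_counts(slice_of(v, p, l),
                    window = list(type = "interval", start = 18, end = 21))
  expect_equal(m$total_visits, 7)
  expect_equal(m$visits_with_poke, 3)
  expect_equal(m$visits_with_lick, 2)
  expect_equal(m$total_licks, 12)
  # t = 0 is 06:00, so starts at 12.2 h and 13 h are 18:12 and 19:00
  expect_equal(m$visits_during_water_access, 2)

  z <- daily_counts(slice_of(v[0, ]))
  expect_equal(z$total_visits, 0)
  expect_equal(z$total_licks, 0)

  # lick bursts sum, not count
  l5 <- data.frame(visit_id = rep(1, 5), t = v$t_start[1] + 1:5, n_licks = 3)
  expect_equal(daily_counts(slice_of(v, p, l5))$total_licks, 15)
})

test_that("place-preference %Correct uses total visits as denominator", {
  v <- data.frame(visit_id = 1:40, animal_id = "m1",
                  corner = rep(c(1, 2, 3, 4), 10),
                  t_start = (1:40) * 100, t_end = (1:40) * 100 + 50)
  assigned <- which(v$corner == 2)  # 10 assigned visits
  l <- data.frame(visit_id = assigned, t = v$t_start[assigned] + 5, n_licks = 5)
  m <- place_preference_metrics(slice_of(v, licks = l), assigned_corner = 2)
  expect_equal(m$assigned_visits, 10)
  expect_equal(m$assigned_visits_with_lick, 10)
  expect_equal(m$pct_correct_pp, 25)  # 10 / 40 * 100

  all_corner <- v; all_corner$corner <- 2
  l_all <- data.frame(visit_id = 1:40, t = v$t_start + 5, n_licks = 5)
  expect_equal(place_preference_metrics(slice_of(all_corner, licks = l_all),
                                        2)$pct_correct_pp, 100)
  expect_true(is.na(place_preference_metrics(slice_of(v[0, ]), 2)$pct_correct_pp))
})

mk_trials <- function(outcomes, D) {
  data.frame(animal_id = "m1", day = 20, visit_id = seq_along(outcomes),
             phase = "RT2", D = D, C = 7, t_init = seq_along(outcomes),
             outcome = outcomes, t_response = NA_real_, reward = FALSE)
}

test_that("rt_metrics computes overall and per-delay percentages", {
  tt <- mk_trials(rep(c("ABANDONED", "PREMATURE", "CORRECT"), c(2, 3, 5)),
                  D = rep(c(2, 4), 5))
  m <- rt_metrics(tt, precue_set = c(2, 4, 8))
  expect_equal(m$trials, 10)
  expect_equal(m$pct_abandoned, 20)
  expect_equal(m$pct_premature, 30)
  expect_equal(m$pct_correct, 50)
  expect_equal(m$trials_D2 + m$trials_D4, 10)
  expect_true(is.na(m$pct_correct_D8))  # no trials at D = 8
  expect_equal(m$trials_D8, 0)

  tt8 <- mk_trials(c("PREMATURE", "PREMATURE", "PREMATURE", "CORRECT"), D = 8)
  expect_equal(rt_metrics(tt8, c(2, 4, 8))$pct_premature_D8, 75)

  expect_error(rt_metrics(mk_trials("CORRECT", D = 5), c(2, 4, 8)),
               "outside the phase set")
})

test_that("rt_metrics percentages always sum to 100 and match a recount", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(1:30, 1)
    tt <- mk_trials(sample(c("ABANDONED", "PREMATURE", "CORRECT"), n, TRUE),
                    D = sample(c(2, 4, 8), n, TRUE))
    m <- rt_metrics(tt, c(2, 4, 8))
    expect_equal(m$pct_abandoned + m$pct_premature + m$pct_correct, 100,
                 tolerance = 1e-9)
    # independent recount
    expect_equal(m$pct_correct, 100 * sum(tt$outcome == "CORRECT") / n)
    for (d in c(2, 4, 8)) {
      nd <- sum(tt$D == d)
      expect_equal(m[[paste0("trials_D", d)]], nd)
      if (nd > 0) {
        expect_equal(m[[paste0("pct_abandoned_D", d)]] +
                       m[[paste0("pct_premature_D", d)]] +
                       m[[paste0("pct_correct_D", d)]], 100, tolerance = 1e-9)
        expect_equal(m[[paste0("pct_premature_D", d)]],
                     100 * sum(tt$outcome == "PREMATURE" & tt$D == d) / nd)
      }
    }
  }
})

test_that("avoidance_metrics counts puff-corner approaches", {
  v <- data.frame(visit_id = 1:12, animal_id = "m1",
                  corner = c(rep(1, 3), rep(2, 9)),
                  t_start = (1:12) * 100, t_end = (1:12) * 100 + 50)
  p <- data.frame(visit_id = 1, side = "left", t = 105)
  m <- avoidance_metrics(slice_of(v, p), assigned_corner = 1)
  expect_equal(m$assigned_visits, 3)
  expect_equal(m$assigned_visits_with_poke, 1)
  m2 <- avoidance_metrics(slice_of(v, p), assigned_corner = 3)
  expect_equal(m2$assigned_visits, 0)
  expect_equal(m2$assigned_visits_with_poke, 0)
})

test_that("build_metric_table has the right cardinality and honours removals", {
  sim <- simulate_cohort(small_config(seed = 9, days = 1:4))
  ses <- run_session(sim$dataset, sim$config$protocol, sim$assignment, 9)
  mt <- build_metric_table(sim$dataset, sim$config$protocol, sim$assignment,
                           ses$trials)
  free <- mt[mt$phase == "FREE_ADAPT", ]
  # 4 animals x 4 days x 5 daily-count variables
  expect_equal(nrow(free), 4 * 4 * 5)
  expect_equal(sort(unique(free$variable)),
               sort(c("total_visits", "total_licks", "visits_with_poke",
                      "visits_with_lick", "visits_during_water_access")))
  # total visits recounted independently
  id <- sim$dataset$animals$animal_id[1]
  day1 <- sim$dataset$visits[sim$dataset$visits$animal_id == id &
                               day_of(sim$dataset$visits$t_start) == 1, ]
  expect_equal(free$value[free$animal_id == id & free$day == 1 &
                            free$variable == "total_visits"], nrow(day1))

  # removed animal contributes only days before removal
  ds <- sim$dataset
  ds$animals$status[1] <- "removed"
  ds$animals$removal_day[1] <- 3L
  mt2 <- build_metric_table(ds, sim$config$protocol, sim$assignment, ses$trials)
  gone <- mt2[mt2$animal_id == ds$animals$animal_id[1], ]
  expect_true(all(gone$day < 3))
})

test_that("metrics are order-independent and survive CSV round-trip", {
  sim <- simulate_cohort(small_config(seed = 10, days = c(9, 10, 22)))
  ses <- run_session(sim$dataset, sim$config$protocol, sim$assignment, 10)
  mt <- build_metric_table(sim$dataset, sim$config$protocol, sim$assignment,
                           ses$trials)
  set.seed(1)
  ds2 <- sim$dataset
  ds2$visits <- ds2$visits[sample(nrow(ds2$visits)), ]
  ds2$pokes <- ds2$pokes[sample(nrow(ds2$pokes)), ]
  ds2$licks <- ds2$licks[sample(nrow(ds2$licks)), ]
  ds2 <- validate_dataset(ds2)
  mt2 <- build_metric_table(ds2, sim$config$protocol, sim$assignment,
                            ses$trials[sample(nrow(ses$trials)), ])
  expect_equal(mt2, mt)

  dir <- withr::local_tempdir()
  write_metric_tables(mt, dir)
  back <- read.csv(file.path(dir, "metrics_long.csv"), stringsAsFactors = FALSE)
  expect_equal(back$value, mt$value)
  expect_equal(back$variable, mt$variable)
  expect_true(file.exists(file.path(dir, "day_22.csv")))
})

test_that("RT day rows include per-delay strata; home-cage day is absent", {
  sim <- simulate_cohort(small_config(seed = 12, days = c(22, 29, 30, 31)))
  ses <- run_session(sim$dataset, sim$config$protocol, sim$assignment, 12)
  mt <- build_metric_table(sim$dataset, sim$config$protocol, sim$assignment,
                           ses$trials)
  expect_false(30 %in% mt$day)
  rt <- mt[mt$day == 22, ]
  expect_true(all(c("pct_correct", "pct_correct_D2", "pct_correct_D4",
                    "pct_correct_D8", "trials") %in% rt$variable))
  av <- mt[mt$day == 29, ]
  expect_true(all(c("assigned_visits", "assigned_visits_with_poke") %in%
                    av$variable))
  expect_equal(sum(av$value[av$variable == "total_licks"]), 0)  # no water
})
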