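# Shared fixtures and independent oracles for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny hand-built dataset: 2 animals, a handful of visits/pokes/licks.
tiny_dataset <- function() {
  animals <- data.frame(
    animal_id = c("m1", "m2"), genotype = c("NonTg", "TG"),
    cage_id = "c1", status = "active", removal_day = NA_integer_)
  visits <- data.frame(
    visit_id = 1:10,
    animal_id = rep(c("m1", "m2"), 5),
    corner = c(1, 2, 3, 4, 1, 2, 3, 4, 1, 2),
    t_start = c(100, 150, 300, 360, 500, 560, 700, 760, 900, 960),
    t_end   = c(120, 170, 330, 380, 520, 580, 730, 790, 930, 990))
  pokes <- data.frame(
    visit_id = c(1, 1, 3, 5, 8), side = "left",
    t = c(105, 110, 310, 505, 765))
  licks <- data.frame(
    visit_id = c(1, 3, 8), t = c(112, 320, 770), n_licks = c(12, 5, 7))
  ic_dataset(animals, visits, pokes, licks)
}

# A small cohort config (2 + 2 animals) for fast end-to-end tests.
small_config <- function(seed = 1, days = NULL, h_tg = 0.15, r_tg = 0.3) {
  sim_config(
    n_per_genotype = c(NonTg = 2, TG = 2),
    params = list(
      NonTg = genotype_params(6, 1.5, 0.7, 30, 0.05, 0.5, 0.4),
      TG = genotype_params(8, 2, 0.75, 34, h_tg, r_tg, 0.4)),
    seed = seed, days = days)
}

# Independent trial-classification oracle: interval membership on the set of
# post-initiation pokes that land before cue offset.
oracle_classify <- function(offsets, D, C) {
  offsets <- sort(offsets)
  cand <- offsets[offsets < D + C]
  if (!length(cand)) return(list(outcome = "ABANDONED", t_response = NA_real_))
  f <- cand[1]
  if (f < D) list(outcome = "PREMATURE", t_response = f)
  else list(outcome = "CORRECT", t_response = f)
}

# Independent brute-force split-plot decomposition via explicit cell-mean
# loops (balanced groups). d: data.frame(subject, group, day, value).
oracle_split_plot <- function(d) {
  subs <- sort(unique(d$subject))
  days <- sort(unique(d$day))
  grps <- sort(unique(d$group))
  N <- length(subs); k <- length(days); g <- length(grps)
  y <- function(s, dd) d$value[d$subject == s & d$day == dd]
  grp_of <- sapply(subs, function(s) d$group[d$subject == s][1])
  grand <- mean(d$value)
  ss_geno <- 0
  for (gg in grps) {
    m_g <- mean(d$value[d$group == gg])
    n_g <- sum(grp_of == gg)
    ss_geno <- ss_geno + k * n_g * (m_g - grand)^2
  }
  ss_subj <- 0
  for (s in subs) {
    m_s <- mean(d$value[d$subject == s])
    m_g <- mean(d$value[d$group == grp_of[s]])
    ss_subj <- ss_subj + k * (m_s - m_g)^2
  }
  ss_day <- 0
  for (dd in days) ss_day <- ss_day + N * (mean(d$value[d$day == dd]) - grand)^2
  ss_int <- 0
  for (gg in grps) for (dd in days) {
    m_gd <- mean(d$value[d$group == gg & d$day == dd])
    m_g <- mean(d$value[d$group == gg])
    m_d <- mean(d$value[d$day == dd])
    n_g <- sum(grp_of == gg)
    ss_int <- ss_int + n_g * (m_gd - m_g - m_d + grand)^2
  }
  ss_tot <- sum((d$value - grand)^2)
  ss_werr <- ss_tot - ss_geno - ss_subj - ss_day - ss_int
  list(
    ss = c(genotype = ss_geno, subjects_within = ss_subj, day = ss_day,
           interaction = ss_int, day_by_subjects = ss_werr, total = ss_tot),
    F = c(genotype = (ss_geno / (g - 1)) / (ss_subj / (N - g)),
          day = (ss_day / (k - 1)) / (ss_werr / ((k - 1) * (N - g))),
          interaction = (ss_int / ((k - 1) * (g - 1))) /
            (ss_werr / ((k - 1) * (N - g)))))
}

# aov()-based oracle for the same decomposition (handles unbalanced groups).
oracle_aov <- function(d) {
  d$subject <- factor(d$subject); d$group <- factor(d$group)
  d$day <- factor(d$day)
  fit <- stats::aov(value ~ group * day + Error(subject), data = d)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  list(F = c(genotype = between["group", "F value"],
             day = within["day", "F value"],
             interaction = within["group:day", "F value"]),
       ss = c(genotype = between["group", "Sum Sq"],
              day = within["day", "Sum Sq"],
              interaction = within["group:day", "Sum Sq"],
              subjects_within = between["Residuals", "Sum Sq"],
              day_by_subjects = within["Residuals", "Sum Sq"]))
}

# random metric-style design matrix for ANOVA fuzzing
random_design <- function(n1, n2, k, seed) {
  set.seed(seed)
  subs <- c(sprintf("a%02d", seq_len(n1)), sprintf("b%02d", seq_len(n2)))
  grp <- rep(c("G1", "G2"), c(n1, n2))
  expand <- expand.grid(subject = subs, day = seq_len(k),
                        stringsAsFactors = FALSE)
  expand$group <- grp[match(expand$subject, subs)]
  expand$value <- rnorm(nrow(expand), mean = as.numeric(factor(expand$group)),
                        sd = 1)
  expand
}

rand_seed_cases <- function(n, base = 100) base + seq_len(n)
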