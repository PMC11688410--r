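#' Two-way mixed repeated-measures ANOVA
#'
#' Classical univariate split-plot decomposition with one between-subjects
#' factor (genotype) and one within-subjects factor (testing day):
#' \itemize{
#'   \item between stratum: SS(genotype) tested against SS(subjects within
#'     genotype), `F(g-1, N-g)`;
#'   \item within stratum: SS(day) and SS(genotype x day) tested against
#'     SS(day x subjects within genotype), `F(k-1, (k-1)(N-g))` each.
#' }
#' With two genotypes and N complete subjects the genotype main effect has
#' df = (1, N-2). Subjects missing any day are excluded (complete-case)
#' with a warning. No sphericity correction is applied (plain univariate
#' df); the decomposition is sequential (day before genotype x day), which
#' for this design is exact also under unequal group sizes because day is
#' fully crossed with subjects.
#'
#' @param data data.frame with columns `subject`, `group`, `day`, `value`
#'   (one row per subject-day), or a long metric table from
#'   [build_metric_table()] together with `dv` (and optionally `phase`).
#' @param dv dependent-variable name when `data` is a long metric table.
#' @param phase optional phase filter for metric tables.
#' @return an object of class `cage_anova`: list with `effects` (data.frame
#'   effect/df1/df2/SS/MS/F/p), `n_per_group`, `k`, `excluded_subjects`.
#' @export
mixed_anova <- function(data, dv = NULL, phase = NULL) {
  if (!is.null(dv)) {
    tab <- data[data$variable == dv, , drop = FALSE]
    if (!nrow(tab)) stop_cage("no rows for dv '%s'", dv)
    if (!is.null(phase)) tab <- tab[tab$phase == phase, , drop = FALSE]
    data <- data.frame(subject = tab$animal_id, group = tab$genotype,
                       day = tab$phase_day %||% tab$day, value = tab$value)
  }
  stopifnot(all(c("subject", "group", "day", "value") %in% names(data)))
  data <- data[!is.na(data$value), , drop = FALSE]
  days <- sort(unique(data$day))
  k <- length(days)
  if (k < 2) stop_cage("need at least 2 within-subject days, got %d", k)
  ndays <- tapply(data$day, data$subject, function(x) length(unique(x)))
  complete <- names(ndays)[ndays == k]
  excluded <- setdiff(names(ndays), complete)
  if (length(excluded))
    warning(sprintf("excluding %d subject(s) with missing days: %s",
                    length(excluded), paste(excluded, collapse = ", ")))
  data <- data[data$subject %in% complete, , drop = FALSE]
  grp <- tapply(data$group, data$subject, function(x) x[1])
  n_per_group <- table(grp)
  g <- length(n_per_group)
  if (g < 2 || any(n_per_group < 2))
    stop_cage("need >= 2 subjects in each of >= 2 groups")
  N <- length(complete)

  y <- matrix(NA_real_, nrow = N, ncol = k,
              dimnames = list(sort(complete), days))
  y[cbind(match(data$subject, rownames(y)), match(data$day, days))] <- data$value
  sub_group <- as.character(grp[rownames(y)])

  grand <- mean(y)
  m_subj <- rowMeans(y)
  m_grp <- tapply(m_subj, sub_group, mean)[unique(sort(sub_group))]
  m_day <- colMeans(y)
  # cell means (group x day)
  m_cell <- rowsum(y, sub_group) / as.vector(table(sub_group))

  n_g <- table(sub_group)
  ss_geno <- k * sum(n_g * (tapply(m_subj, sub_group, mean) - grand)^2)
  ss_subj <- k * sum((m_subj - tapply(m_subj, sub_group, mean)[sub_group])^2)
  ss_day <- N * sum((m_day - grand)^2)
  gnames <- rownames(m_cell)
  ss_int <- sum(vapply(gnames, function(gg) {
    sum(n_g[gg] * (m_cell[gg, ] - mean(y[sub_group == gg, ]) - m_day + grand)^2)
  }, numeric(1)))
  ss_total <- sum((y - grand)^2)
  ss_werr <- ss_total - ss_geno - ss_subj - ss_day - ss_int

  df_geno <- g - 1
  df_subj <- N - g
  df_day <- k - 1
  df_int <- (k - 1) * (g - 1)
  df_werr <- (k - 1) * (N - g)
  ms <- c(geno = ss_geno / df_geno, subj = ss_subj / df_subj,
          day = ss_day / df_day, int = ss_int / df_int,
          werr = ss_werr / df_werr)
  if (ms[["subj"]] <= 0 || ms[["werr"]] <= 0)
    stop_cage("degenerate input: zero error variance (dv constant across cells)")
  eff <- data.frame(
    effect = c("genotype", "day", "genotype:day"),
    df1 = c(df_geno, df_day, df_int),
    df2 = c(df_subj, df_werr, df_werr),
    SS = c(ss_geno, ss_day, ss_int),
    MS = c(ms[["geno"]], ms[["day"]], ms[["int"]]),
    F = c(ms[["geno"]] / ms[["subj"]], ms[["day"]] / ms[["werr"]],
          ms[["int"]] / ms[["werr"]])
  )
  eff$p <- pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  structure(list(effects = eff, n_per_group = n_per_group, k = k,
                 days = days, excluded_subjects = excluded,
                 ss = c(genotype = ss_geno, subjects_within = ss_subj,
                        day = ss_day, interaction = ss_int,
                        day_by_subjects = ss_werr, total = ss_total),
                 data = data.frame(subject = rownames(y)[row(y)],
                                   group = sub_group[row(y)],
                                   day = days[col(y)], value = as.vector(y))),
            class = "cage_anova")
}

#' @export
print.cage_anova <- function(x, ...) {
  cat(sprintf("Mixed repeated-measures ANOVA: %s subjects (%s), %d days\n",
              sum(x$n_per_group),
              paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                    collapse = ", "), x$k))
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    lab <- if (eff$p[i] < 0.05) "*" else if (eff$p[i] < 0.10) " (trend)" else ""
    cat(sprintf("  %-13s F(%d,%d) = %.3f, p = %.4f%s\n", eff$effect[i],
                eff$df1[i], eff$df2[i], eff$F[i], eff$p[i], lab))
  }
  invisible(x)
}

#' Bonferroni-corrected post hoc comparisons
#'
#' Gated on a significant genotype x day interaction (p < 0.05): with a
#' non-significant interaction an empty table is returned with the reason
#' attached. Two comparison families, matching how such designs are
#' reported:
#' \itemize{
#'   \item `"genotype_within_day"`: an unpaired pooled-variance t-test
#'     between genotypes at each day; family size m = k.
#'   \item `"days_within_genotype"`: paired t-tests between every pair of
#'     days within each genotype; m = g * choose(k, 2).
#' }
#' Adjusted p = min(1, m * p_raw).
#'
#' @param anova_result a `cage_anova` (carries the complete-case data).
#' @param family comparison family.
#' @param gate_p interaction significance gate (default 0.05).
#' @return data.frame (comparison, mean_diff, p_raw, p_adj, significant);
#'   attribute `reason` explains an empty table.
#' @export
bonferroni_posthoc <- function(anova_result,
                               family = c("genotype_within_day",
                                          "days_within_genotype"),
                               gate_p = 0.05) {
  family <- match.arg(family)
  empty <- data.frame(comparison = character(0), mean_diff = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      significant = logical(0))
  p_int <- anova_result$effects$p[anova_result$effects$effect == "genotype:day"]
  if (p_int >= gate_p) {
    attr(empty, "reason") <- "gate not met: interaction not significant"
    return(empty)
  }
  dat <- anova_result$data
  days <- anova_result$days
  groups <- names(anova_result$n_per_group)
  rows <- list()
  if (family == "genotype_within_day") {
    for (d in days) {
      a <- dat$value[dat$day == d & dat$group == groups[1]]
      b <- dat$value[dat$day == d & dat$group == groups[2]]
      tt <- two_sample_ttest(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = sprintf("%s vs %s @ day %s", groups[1], groups[2], d),
        mean_diff = tt$mean_a - tt$mean_b, p_raw = tt$p)
    }
  } else {
    for (gg in groups) {
      sub <- dat[dat$group == gg, ]
      wide <- matrix(sub$value[order(sub$day, sub$subject)],
                     ncol = length(days))
      for (i in seq_len(length(days) - 1)) for (j in (i + 1):length(days)) {
        dif <- wide[, i] - wide[, j]
        tstat <- mean(dif) / (sd(dif) / sqrt(length(dif)))
        p <- 2 * pt(-abs(tstat), df = length(dif) - 1)
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = sprintf("%s: day %s vs day %s", gg, days[i], days[j]),
          mean_diff = mean(dif), p_raw = p)
      }
    }
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_adj <- pmin(1, m * out$p_raw)
  out$significant <- out$p_adj < 0.05
  attr(out, "family_size") <- m
  out
}

#' Unpaired two-sample Student's t-test (pooled variance)
#'
#' @param values_a,values_b numeric vectors (each n >= 2).
#' @param equal_var pooled-variance form (the only form implemented;
#'   kept as an argument to make the modelling choice explicit).
#' @return list(t, df, p, mean_a, mean_b, n_a, n_b).
#' @export
two_sample_ttest <- function(values_a, values_b, equal_var = TRUE) {
  stopifnot(isTRUE(equal_var))
  n1 <- length(values_a); n2 <- length(values_b)
  if (n1 < 2 || n2 < 2) stop_cage("each group needs n >= 2")
  m1 <- mean(values_a); m2 <- mean(values_b)
  sp2 <- ((n1 - 1) * stats::var(values_a) + (n2 - 1) * stats::var(values_b)) /
    (n1 + n2 - 2)
  if (sp2 == 0) {
    if (m1 == m2) stop_cage("degenerate input: zero variance and equal means")
    return(list(t = Inf * sign(m1 - m2), df = n1 + n2 - 2, p = 0,
                mean_a = m1, mean_b = m2, n_a = n1, n_b = n2))
  }
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df),
       mean_a = m1, mean_b = m2, n_a = n1, n_b = n2)
}

#' Run the full statistical plan over a metric table
#'
#' For each phase and dependent variable with at least two days and two
#' subjects per genotype, fits the mixed ANOVA and (when the interaction is
#' significant) the per-day Bonferroni post hocs. Shapes the effects table
#' like a published ANOVA summary: one row per (phase, dv, effect).
#'
#' @param metric_table long table from [build_metric_table()].
#' @param dvs optional character vector of variables (default: all).
#' @param phases optional character vector of phases (default: all).
#' @return list(effects, posthoc, skipped).
#' @export
stats_report <- function(metric_table, dvs = NULL, phases = NULL) {
  phases <- phases %||% unique(metric_table$phase)
  effects <- list(); posthoc <- list(); skipped <- list()
  for (ph in phases) {
    sub <- metric_table[metric_table$phase == ph, ]
    for (dv in (dvs %||% unique(sub$variable))) {
      res <- tryCatch(
        suppressWarnings(mixed_anova(sub, dv = dv)),
        error = function(e) conditionMessage(e))
      if (is.character(res)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          phase = ph, dv = dv, reason = res)
        next
      }
      eff <- res$effects
      eff <- cbind(phase = ph, dv = dv, eff)
      effects[[length(effects) + 1L]] <- eff
      ph_tab <- bonferroni_posthoc(res, "genotype_within_day")
      if (nrow(ph_tab))
        posthoc[[length(posthoc) + 1L]] <- cbind(phase = ph, dv = dv, ph_tab)
    }
  }
  list(
    effects = if (length(effects)) do.call(rbind, effects) else NULL,
    posthoc = if (length(posthoc)) do.call(rbind, posthoc) else NULL,
    skipped = if (length(skipped)) do.call(rbind, skipped) else NULL
  )
}
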