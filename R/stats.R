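# Group-level inference: three-factor linear mixed-effects model with Tukey
# post-hoc contrasts, response time-course analysis, behavioural summaries,
# and brain-behaviour rank correlations.

as_response_factors <- function(tbl) {
  tbl$subject <- factor(tbl$subject)
  tbl$group <- factor(tbl$group, levels = intersect(c("TD", "ASD"), unique(tbl$group)))
  tbl$stimulus <- factor(tbl$stimulus, levels = intersect(c("faces", "houses"),
                                                          unique(tbl$stimulus)))
  tbl$roi <- factor(tbl$roi, levels = intersect(c("MO", "LOT", "ROT"), unique(tbl$roi)))
  tbl
}

#' Fit the three-factor linear mixed-effects model
#'
#' Models summed baseline-corrected amplitudes with stimulus type and ROI as
#' within-subject factors and group as a between-subject factor (full
#' factorial fixed structure) plus a random intercept per participant. F tests
#' use type-III sums of squares with sum-to-zero contrasts; the denominator
#' degrees of freedom follow the chosen approximation (Satterthwaite by
#' default, Kenward-Roger selectable). The response table is rate-resolved:
#' each subject contributes one observation per stimulus x ROI x presentation
#' rate, so the two counterbalanced rate mappings act as replicates.
#'
#' @param tbl Response table: data.frame with columns `subject`, `group`
#'   (TD/ASD), `stimulus` (faces/houses), `roi` (MO/LOT/ROT), `amplitude`
#'   (microvolts) and optionally `rate`.
#' @param ddf Denominator-df method, `"satterthwaite"` (default) or
#'   `"kenward-roger"`.
#' @return An object of class `ft_lmem`: list with `model` (the `lmerMod`),
#'   `anova` (data.frame of F tests: effect, F, df1, df2, p), `cell_means`
#'   (group x stimulus x roi fitted means), `ranef_var` (random-intercept
#'   variance), `singular` (logical), `ddf`.
#' @export
fit_lmem <- function(tbl, ddf = c("satterthwaite", "kenward-roger")) {
  ddf <- match.arg(ddf)
  need <- c("subject", "group", "stimulus", "roi", "amplitude")
  if (!all(need %in% names(tbl)))
    ft_stop("response table must have columns %s", "ft_stats_error",
            paste(need, collapse = ", "))
  if (any(!is.finite(tbl$amplitude)))
    ft_stop("non-finite amplitudes in response table", "ft_stats_error")
  tbl <- as_response_factors(tbl)
  if (min(table(unique(tbl[c("subject", "group")])$group)) < 2)
    ft_stop("need at least 2 subjects per group", "ft_stats_error")
  m <- lmerTest::lmer(
    amplitude ~ group * stimulus * roi + (1 | subject), data = tbl,
    contrasts = list(group = "contr.sum", stimulus = "contr.sum",
                     roi = "contr.sum"))
  singular <- lme4::isSingular(m)
  at <- stats::anova(m, type = 3, ddf = if (ddf == "satterthwaite")
    "Satterthwaite" else "Kenward-Roger")
  av <- data.frame(effect = rownames(at), F = at[["F value"]],
                   df1 = at[["NumDF"]], df2 = at[["DenDF"]],
                   p = at[["Pr(>F)"]], row.names = NULL)
  emm <- emmeans::emmeans(m, ~ group * stimulus * roi,
                          lmer.df = ddf, data = tbl)
  cm <- as.data.frame(emm)
  vc <- as.data.frame(lme4::VarCorr(m))
  structure(list(model = m, anova = av, cell_means = cm,
                 ranef_var = vc$vcov[vc$grp == "subject"],
                 residual_var = vc$vcov[vc$grp == "Residual"],
                 singular = singular, ddf = ddf, data = tbl),
            class = "ft_lmem")
}

#' @export
print.ft_lmem <- function(x, ...) {
  cat(sprintf("Mixed model: amplitude ~ group * stimulus * roi + (1 | subject)%s\n",
              if (x$singular) "  [singular fit]" else ""))
  print(x$anova, digits = 4)
  invisible(x)
}

#' Tukey-corrected faces-vs-houses contrasts within each group and ROI
#'
#' Computes the faces minus houses contrast in every group x ROI cell on the
#' fitted model, with p-values adjusted for the Tukey family of all pairwise
#' comparisons among the twelve group x stimulus x ROI cell means.
#' Unstandardized estimates are reported in microvolts and equal the
#' difference of fitted cell means.
#'
#' @param fit An `ft_lmem`.
#' @return data.frame with columns `group`, `roi`, `estimate` (uV), `se`,
#'   `df`, `t`, `p_tukey`.
#' @export
posthoc_contrasts <- function(fit) {
  stopifnot(inherits(fit, "ft_lmem"))
  emm <- emmeans::emmeans(fit$model, ~ group * stimulus * roi,
                          lmer.df = fit$ddf, data = fit$data)
  prs <- summary(emmeans::contrast(emm, method = "pairwise"), adjust = "tukey")
  lab <- as.character(prs$contrast)
  cells <- as.data.frame(emm)[, c("group", "stimulus", "roi")]
  cell_id <- sprintf("%s %s %s", cells$group, cells$stimulus, cells$roi)
  # keep contrasts of the form "(g faces r) - (g houses r)"
  parts <- strsplit(gsub("[()]", "", lab), " - ")
  keep <- vapply(parts, function(p) {
    a <- strsplit(p[1], " ")[[1]]; b <- strsplit(p[2], " ")[[1]]
    a[1] == b[1] && a[3] == b[3] && a[2] != b[2]
  }, TRUE)
  out <- prs[keep, ]
  pa <- strsplit(gsub("[()]", "", as.character(out$contrast)), " ")
  res <- data.frame(
    group = vapply(pa, `[`, "", 1),
    roi = vapply(pa, `[`, "", 3),
    estimate = out$estimate, se = out$SE, df = out$df,
    t = out$t.ratio, p_tukey = out$p.value, row.names = NULL)
  # orient every contrast as faces - houses
  flip <- vapply(pa, function(p) p[2] != "faces", TRUE)
  res$estimate[flip] <- -res$estimate[flip]
  res$t[flip] <- -res$t[flip]
  res
}

#' Behavioural task summary and group comparison
#'
#' Group means and SDs of accuracy and mean reaction time, with two-sided
#' t-tests (Welch by default; pooled-variance selectable). A note is attached
#' when the realized degrees of freedom differ from `n1 + n2 - 2`.
#'
#' @param tbl Behaviour table: data.frame with `subject`, `group`, `accuracy`,
#'   `mean_rt`.
#' @param var_equal Use the pooled-variance t-test (default `FALSE`, Welch).
#' @return List with `summary` (per group x measure: mean, sd, n) and `tests`
#'   (per measure: t, df, p, note).
#' @export
behavior_summary <- function(tbl, var_equal = FALSE) {
  stopifnot(all(c("group", "accuracy", "mean_rt") %in% names(tbl)))
  if (min(table(tbl$group)) < 2)
    ft_stop("need at least 2 subjects per group", "ft_stats_error")
  groups <- sort(unique(tbl$group))
  summ <- do.call(rbind, lapply(c("accuracy", "mean_rt"), function(v)
    do.call(rbind, lapply(groups, function(g) {
      x <- tbl[[v]][tbl$group == g]
      data.frame(measure = v, group = g, mean = mean(x), sd = stats::sd(x),
                 n = length(x))
    }))))
  tests <- do.call(rbind, lapply(c("accuracy", "mean_rt"), function(v) {
    tt <- stats::t.test(tbl[[v]] ~ tbl$group, var.equal = var_equal)
    n <- nrow(tbl)
    note <- if (abs(tt$parameter - (n - 2)) > 0.5)
      sprintf("df %.1f differs from pooled df %d", tt$parameter, n - 2) else ""
    data.frame(measure = v, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value, note = note)
  }))
  list(summary = summ, tests = tests)
}

#' Spearman correlations between neural responses and SRS T-scores
#'
#' Correlates the rate-pooled summed amplitudes for faces, houses and their
#' difference with the Social Responsiveness Scale T-score, per ROI, within
#' each group and pooled across groups.
#'
#' @param tbl Response table (see [fit_lmem()]); rates are pooled by averaging
#'   within subject x stimulus x ROI.
#' @param subject_table data.frame with `subject`, `group`, `srs_t`.
#' @param on_constant What to do when a measure or the SRS scores are constant
#'   within a scope (rho undefined): `"error"` (default) or `"na"`.
#' @return data.frame with columns `scope` (TD/ASD/all), `roi`, `measure`
#'   (faces/houses/difference), `rho`, `p`, `n`.
#' @export
correlate_srs <- function(tbl, subject_table, on_constant = c("error", "na")) {
  on_constant <- match.arg(on_constant)
  pooled <- pool_rates(tbl)
  wide <- stats::reshape(pooled, idvar = c("subject", "group", "roi"),
                         timevar = "stimulus", direction = "wide")
  names(wide) <- sub("^amplitude\\.", "", names(wide))
  wide$difference <- wide$faces - wide$houses
  wide <- merge(wide, subject_table[, c("subject", "srs_t")], by = "subject")
  scopes <- c(as.list(sort(unique(wide$group))), list("all"))
  rows <- list()
  for (sc in scopes) for (r in unique(wide$roi)) for (msr in
       c("faces", "houses", "difference")) {
    d <- wide[wide$roi == r & (sc == "all" | wide$group == sc), ]
    if (stats::sd(d[[msr]]) == 0 || stats::sd(d$srs_t) == 0) {
      if (on_constant == "error")
        ft_stop("constant input; Spearman rho undefined", "ft_stats_error")
      rows[[length(rows) + 1]] <- data.frame(
        scope = sc, roi = r, measure = msr, rho = NA_real_, p = NA_real_,
        n = nrow(d))
      next
    }
    ct <- suppressWarnings(stats::cor.test(d[[msr]], d$srs_t,
                                           method = "spearman"))
    rows[[length(rows) + 1]] <- data.frame(
      scope = sc, roi = r, measure = msr, rho = unname(ct$estimate),
      p = ct$p.value, n = nrow(d))
  }
  do.call(rbind, rows)
}

#' Pool the two counterbalanced rate mappings
#'
#' Averages the rate-resolved response table within subject x group x
#' stimulus x ROI, yielding one row per subject, stimulus and ROI.
#'
#' @param tbl Rate-resolved response table.
#' @return Pooled data.frame.
#' @export
pool_rates <- function(tbl) {
  stats::aggregate(amplitude ~ subject + group + stimulus + roi, data = tbl,
                   FUN = mean)
}

#' Group-by-stimulus mixed model over occipito-temporal channels per length
#'
#' For a time-course table (one amplitude per subject x stimulus x rate x
#' segment length, occipito-temporal ROIs pooled), fits at each length the
#' mixed model `amplitude ~ group * stimulus + (1 | subject)` and reports the
#' group x stimulus interaction test.
#'
#' @param tc_tbl data.frame with columns `subject`, `group`, `stimulus`,
#'   `rate`, `length`, `amplitude`.
#' @param ddf Denominator-df method (see [fit_lmem()]).
#' @return An object of class `ft_time_course`: data.frame with one row per
#'   length: `length`, `F`, `df1`, `df2`, `p`, `mean_faces`, `mean_houses`.
#' @export
time_course_fit <- function(tc_tbl, ddf = c("satterthwaite", "kenward-roger")) {
  ddf <- match.arg(ddf)
  lengths <- sort(unique(tc_tbl$length))
  if (any(diff(lengths) <= 0)) ft_stop("lengths must increase", "ft_stats_error")
  rows <- lapply(lengths, function(L) {
    d <- tc_tbl[tc_tbl$length == L, ]
    d$subject <- factor(d$subject)
    d$group <- factor(d$group); d$stimulus <- factor(d$stimulus)
    m <- lmerTest::lmer(amplitude ~ group * stimulus + (1 | subject), data = d,
                        contrasts = list(group = "contr.sum",
                                         stimulus = "contr.sum"))
    at <- stats::anova(m, type = 3, ddf = if (ddf == "satterthwaite")
      "Satterthwaite" else "Kenward-Roger")
    i <- match("group:stimulus", rownames(at))
    data.frame(length = L, F = at[["F value"]][i], df1 = at[["NumDF"]][i],
               df2 = at[["DenDF"]][i], p = at[["Pr(>F)"]][i],
               mean_faces = mean(d$amplitude[d$stimulus == "faces"]),
               mean_houses = mean(d$amplitude[d$stimulus == "houses"]))
  })
  structure(do.call(rbind, rows), class = c("ft_time_course", "data.frame"))
}

#' Simulate a response table directly at the quantification level
#'
#' Draws summed baseline-corrected amplitudes from the same effect structure
#' as the EEG-level generator (group cell means, a mean-preserving lognormal
#' subject factor shared across cells, an independent lognormal factor per
#' cell-by-rate observation) without synthesizing EEG. Used for statistical
#' calibration (type-I error, power) where hundreds of cohorts are needed.
#'
#' @param n_per_group Subjects per group.
#' @param effect_config An [cohort_effects()] (or [null_effects()])
#'   configuration; only the cell means and variance components are used.
#' @param seed Integer seed.
#' @return A rate-resolved response table (`subject`, `group`, `stimulus`,
#'   `rate`, `roi`, `amplitude`) plus an `srs_t` column, suitable for
#'   [fit_lmem()] and [correlate_srs()].
#' @export
simulate_response_table <- function(n_per_group = 21,
                                    effect_config = cohort_effects(),
                                    seed = 1L) {
  cfg <- effect_config
  slog <- sqrt(log(1 + cfg$subject_cv^2))
  clog <- sqrt(log(1 + cfg$cell_cv^2))
  with_seed(seed, {
    rows <- list(); i <- 0
    for (grp in c("TD", "ASD")) for (j in seq_len(n_per_group)) {
      i <- i + 1
      sid <- sprintf("S%02d_%s", i, grp)
      f_s <- exp(rnorm(1, -slog^2 / 2, slog))
      srs_par <- cfg$srs[[grp]]
      srs_t <- round(rtrunc_norm(1, srs_par[["mean"]], srs_par[["sd"]], 30, 120))
      for (stim in c("faces", "houses")) {
        sums <- if (stim == "faces") cfg$face_sums else cfg$house_sums
        for (r in names(sums[[grp]])) {
          target <- sums[[grp]][[r]] * f_s
          for (rate in c("6", "7.5")) {
            amp <- target * exp(rnorm(1, -clog^2 / 2, clog))
            rows[[length(rows) + 1]] <- data.frame(
              subject = sid, group = grp, stimulus = stim, rate = rate,
              roi = r, amplitude = amp, srs_t = srs_t)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}
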