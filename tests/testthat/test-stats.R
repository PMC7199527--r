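test_that("the mixed model reproduces its design degrees of freedom", {
  tbl <- simulate_response_table(21, null_effects(), seed = 31)
  fit <- fit_lmem(tbl)
  av <- fit$anova
  expect_setequal(av$effect, c("group", "stimulus", "roi", "group:stimulus",
                               "group:roi", "stimulus:roi",
                               "group:stimulus:roi"))
  # balanced design, 504 observations, 12 fixed cells, random intercepts:
  # within-subject effects carry 452 denominator df, the between factor 40
  expect_equal(av$df2[av$effect == "group"], 40, tolerance = 1e-6)
  within <- setdiff(av$effect, "group")
  expect_equal(av$df2[av$effect %in% within], rep(452, 6), tolerance = 1e-6)
  expect_equal(av$df1[av$effect == "group:stimulus:roi"], 2)
  # Satterthwaite and Kenward-Roger agree here
  fit_kr <- fit_lmem(tbl, ddf = "kenward-roger")
  expect_equal(fit_kr$anova$df2, av$df2, tolerance = 1e-6)
})

test_that("fitted cell means match observed means and contrasts their difference", {
  tbl <- simulate_response_table(8, cohort_effects(), seed = 32)
  fit <- fit_lmem(tbl)
  obs <- aggregate(amplitude ~ group + stimulus + roi, tbl, mean)
  mrg <- merge(fit$cell_means, obs, by = c("group", "stimulus", "roi"))
  expect_equal(mrg$emmean, mrg$amplitude, tolerance = 1e-8)
  cons <- posthoc_contrasts(fit)
  expect_equal(nrow(cons), 6)
  for (r in seq_len(nrow(cons))) {
    g <- cons$group[r]; ro <- cons$roi[r]
    d_obs <- obs$amplitude[obs$group == g & obs$stimulus == "faces" & obs$roi == ro] -
      obs$amplitude[obs$group == g & obs$stimulus == "houses" & obs$roi == ro]
    expect_equal(cons$estimate[r], d_obs, tolerance = 1e-8)
  }
})

test_that("contrast estimates are invariant to factor level ordering", {
  tbl <- simulate_response_table(6, cohort_effects(), seed = 33)
  fit1 <- fit_lmem(tbl)
  tbl2 <- tbl[rev(seq_len(nrow(tbl))), ]
  tbl2$roi <- factor(tbl2$roi, levels = c("ROT", "MO", "LOT"))
  fit2 <- fit_lmem(tbl2)
  c1 <- posthoc_contrasts(fit1); c2 <- posthoc_contrasts(fit2)
  key <- function(x) x[order(x$group, x$roi), c("group", "roi", "estimate")]
  expect_equal(key(c1)$estimate, key(c2)$estimate, tolerance = 1e-8)
})

test_that("default cohorts show the TD-differentiated, ASD-flat pattern", {
  pat <- t(vapply(1:12, function(s) {
    cons <- posthoc_contrasts(fit_lmem(
      simulate_response_table(21, cohort_effects(), seed = 340 + s)))
    td_lot <- cons[cons$group == "TD" & cons$roi == "LOT", ]
    asd <- cons[cons$group == "ASD", ]
    c(td_sig = td_lot$p_tukey < 0.05 && td_lot$estimate > 0,
      asd_lot_ns = asd$p_tukey[asd$roi == "LOT"] > 0.05,
      asd_rot_ns = asd$p_tukey[asd$roi == "ROT"] > 0.05)
  }, c(td_sig = TRUE, asd_lot_ns = TRUE, asd_rot_ns = TRUE)))
  # TD LOT faces > houses detected essentially always; ASD occipito-temporal
  # contrasts non-significant in the majority of cohorts
  expect_gte(mean(pat[, "td_sig"]), 0.9)
  expect_gt(mean(pat[, "asd_lot_ns"]), 0.5)
  expect_gt(mean(pat[, "asd_rot_ns"]), 0.5)
})

test_that("a zero-subject-variance fit is flagged singular, not silent", {
  set.seed(35)
  tbl <- simulate_response_table(6, null_effects(), seed = 35)
  tbl$amplitude <- 1 + rnorm(nrow(tbl), 0, 0.1)
  # remove all between-subject variance: the intercept variance estimate hits
  # the boundary and the fit must carry a singularity flag
  tbl$amplitude <- tbl$amplitude -
    ave(tbl$amplitude, tbl$subject) + mean(tbl$amplitude)
  fit <- suppressMessages(fit_lmem(tbl))
  expect_true(fit$singular)
  expect_lt(fit$ranef_var, 1e-8)
})

test_that("behavioural summaries and t-tests follow their contracts", {
  tbl <- data.frame(subject = sprintf("s%d", 1:8),
                    group = rep(c("TD", "ASD"), each = 4),
                    accuracy = rep(c(0.9, 0.95, 1, 0.97), 2),
                    mean_rt = rep(c(0.4, 0.5, 0.45, 0.42), 2))
  bs <- behavior_summary(tbl)
  expect_equal(bs$tests$t, c(0, 0), tolerance = 1e-12)
  expect_equal(bs$tests$p, c(1, 1), tolerance = 1e-12)
  expect_equal(bs$summary$mean[bs$summary$measure == "accuracy"],
               c(0.955, 0.955))
  one <- tbl[c(1, 5:8), ]
  expect_error(behavior_summary(one), "at least 2")
  # Welch df is reported as realized, with a note when it deviates
  tbl$accuracy[1:4] <- c(0.2, 0.9, 0.95, 1)
  bs2 <- behavior_summary(tbl)
  expect_true(is.finite(bs2$tests$df[1]))
})

test_that("SRS correlations behave under monotone, null and sign-flipped data", {
  tbl <- simulate_response_table(21, null_effects(), seed = 36)
  st <- unique(tbl[, c("subject", "group", "srs_t")])
  # perfectly monotone pairing: rho = 1 for faces, houses and the difference
  tbl2 <- tbl
  ranks <- as.integer(factor(tbl2$subject))
  tbl2$amplitude <- ranks * ifelse(tbl2$stimulus == "faces", 1.1, 1)
  st2 <- st
  st2$srs_t <- as.integer(factor(st2$subject, levels = levels(factor(tbl2$subject)))) * 2 + 1
  out2 <- correlate_srs(tbl2, st2)
  expect_equal(out2$rho[out2$scope == "all"], rep(1, 9), tolerance = 1e-12)
  # independent draws: pooled |rho| small
  out <- correlate_srs(tbl, st)
  expect_true(all(abs(out$rho[out$scope == "all"]) < 0.3))
  # flipping the sign of the neural measure flips rho
  tbl3 <- tbl; tbl3$amplitude <- -tbl3$amplitude
  out3 <- correlate_srs(tbl3, st)
  expect_equal(out3$rho[out3$measure != "difference"],
               -out$rho[out$measure != "difference"], tolerance = 1e-12)
})

test_that("rate pooling yields one row per subject, stimulus and ROI", {
  tbl <- simulate_response_table(3, cohort_effects(), seed = 37)
  p <- pool_rates(tbl)
  expect_equal(nrow(p), 6 * 2 * 3)
  expect_equal(anyDuplicated(p[, c("subject", "stimulus", "roi")]), 0)
  one <- tbl[tbl$subject == tbl$subject[1] & tbl$stimulus == "faces" &
               tbl$roi == "MO", ]
  expect_equal(p$amplitude[p$subject == tbl$subject[1] & p$stimulus == "faces" &
                             p$roi == "MO"], mean(one$amplitude))
})

test_that("time-course fits report the interaction per segment length", {
  set.seed(38)
  subj <- sprintf("s%d", 1:12)
  grp <- rep(c("TD", "ASD"), each = 6)
  rows <- expand.grid(subject = subj, stimulus = c("faces", "houses"),
                      rate = c("6", "7.5"), length = c(10, 20, 30),
                      stringsAsFactors = FALSE)
  rows$group <- grp[match(rows$subject, subj)]
  eff <- ifelse(rows$group == "TD" & rows$stimulus == "faces", 0.6, 0)
  rows$amplitude <- 1 + eff + rnorm(nrow(rows), 0, 0.1)
  tc <- time_course_fit(rows)
  expect_equal(tc$length, c(10, 20, 30))
  expect_true(all(tc$p < 0.05))
  expect_true(all(tc$df1 == 1))
  rows0 <- rows; rows0$amplitude <- 1 + rnorm(nrow(rows), 0, 0.1)
  tc0 <- time_course_fit(rows0)
  expect_true(mean(tc0$p < 0.05) <= 1 / 3)
})
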