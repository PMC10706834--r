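# Validation metrics, LOD/LOQ rules, precision, ANOVA.

test_that("relative deviation is the signed percent difference", {
  expect_equal(round(relative_deviation(58.65, 60), 2), -2.25)
  expect_equal(relative_deviation(7, 7), 0)
  expect_equal(round(relative_deviation(0.1517, 0.1), 1), 51.7)
  expect_error(relative_deviation(1, 0), "undefined")
  # sign always follows measured - actual
  set.seed(2)
  for (i in 1:20) {
    m <- stats::runif(1, 0, 100); a <- stats::runif(1, 1, 100)
    expect_equal(sign(relative_deviation(m, a)), sign(m - a))
  }
})

test_that("RSD matches hand arithmetic and published spread", {
  expect_equal(round(rsd(c(0.44, 0.41, 0.43, 0.44, 0.44)), 2), 3.02)
  expect_equal(rsd(c(5, 5, 5)), 0)
  expect_equal(rsd(c(1, 2, 3)), 50)
  expect_error(rsd(3), "at least two")
  expect_error(rsd(c(-1, 1)), "zero mean")
})

test_that("dynamic-range regression equals the normal-equations oracle", {
  x <- c(1, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90)
  fit <- dynamic_range_fit(x, x)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  two <- dynamic_range_fit(c(10, 30), c(11, 28))
  expect_equal(two$r_squared, 1)
  set.seed(77)
  y <- 0.98 * x + 0.4 + stats::rnorm(length(x), 0, 1.5)
  fit2 <- dynamic_range_fit(x, y)
  orc <- oracle_ols(x, y)
  expect_equal(fit2$slope, unname(orc["slope"]), tolerance = 1e-10)
  expect_equal(fit2$intercept, unname(orc["intercept"]), tolerance = 1e-10)
  expect_error(dynamic_range_fit(c(5, 5, 5), c(1, 2, 3)), "degenerate")
})

published_lod_levels <- function() {
  tab <- published_table("lod_loq")
  data.frame(fraction_pct = tab$fraction_pct,
             detection_rate_pct = tab$detection_rate_pct)
}

test_that("LOD rule: lowest level with stable (100%) detection above it", {
  expect_equal(determine_lod(published_lod_levels()), 0.2)
  all100 <- data.frame(fraction_pct = c(0.1, 1, 5),
                       detection_rate_pct = c(100, 100, 100))
  expect_equal(determine_lod(all100), 0.1)
  none <- data.frame(fraction_pct = c(0.1, 1), detection_rate_pct = c(75, 99))
  expect_true(is.na(determine_lod(none)))
  # monotonicity: appending a passing higher level never changes the answer
  lv <- published_lod_levels()
  lv2 <- rbind(lv, data.frame(fraction_pct = 10, detection_rate_pct = 100))
  expect_equal(determine_lod(lv2), determine_lod(lv))
})

test_that("LOQ rule: deviation within 25% at the level and all higher levels", {
  tab <- published_table("lod_loq")
  detected <- tab[tab$detection_rate_pct == 100, ]
  lv <- data.frame(fraction_pct = detected$fraction_pct,
                   deviation_pct = detected$deviation_pct)
  expect_equal(determine_loq(lv), 0.8)
  allpass <- data.frame(fraction_pct = c(0.5, 1, 5),
                        deviation_pct = c(10, -5, 2))
  expect_equal(determine_loq(allpass), 0.5)
  allfail <- data.frame(fraction_pct = c(0.5, 1), deviation_pct = c(80, 40))
  expect_true(is.na(determine_loq(allfail)))
  lv2 <- rbind(lv, data.frame(fraction_pct = 10, deviation_pct = 3))
  expect_equal(determine_loq(lv2), determine_loq(lv))
  # a hypothetical failure above the candidate blocks it
  lv3 <- rbind(lv, data.frame(fraction_pct = 10, deviation_pct = 40))
  expect_true(is.na(determine_loq(lv3)))
})

test_that("one-way ANOVA matches the hand decomposition and the F-CDF oracle", {
  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  res <- one_way_anova(list(c(0, 1), c(2, 3)))
  expect_equal(res$F, 8)                       # SSB 4 on 1 df, SSW 1 on 2 df
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 2)
  expect_equal(res$p, oracle_f_pvalue(8, 1, 2), tolerance = 1e-8)
  deg <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_true(deg$degenerate)
  expect_equal(deg$F, Inf)
  expect_equal(deg$p, 0)
  expect_error(one_way_anova(list(c(1, 2))), "two groups")
  expect_error(one_way_anova(list(1, 2)), "two observations")
})

test_that("ANOVA F is invariant to shifting and positive rescaling", {
  set.seed(31)
  g <- list(stats::rnorm(5), stats::rnorm(5, 0.5), stats::rnorm(5, 1))
  base <- one_way_anova(g)
  shifted <- one_way_anova(lapply(g, `+`, 100))
  scaled <- one_way_anova(lapply(g, `*`, 3.7))
  expect_equal(shifted$F, base$F)
  expect_equal(scaled$F, base$F)
  expect_equal(shifted$p, base$p)
  expect_equal(scaled$p, base$p)
})

test_that("precision summary separates within-run and between-run spread", {
  # three runs x four replicates at one level, built with known structure
  set.seed(55)
  runs <- expand.grid(run = c("op1_d1", "op1_d2", "op2_d1"), rep = 1:4)
  shift <- c(op1_d1 = 0, op1_d2 = 1, op2_d1 = -1)
  dat <- data.frame(level = 50, run = runs$run,
                    value = 50 + shift[as.character(runs$run)] +
                      stats::rnorm(nrow(runs), 0, 0.25))
  ps <- precision_summary(dat)
  expect_equal(nrow(ps$per_level), 1L)
  # between-run shifts dominate the within-run noise
  expect_gt(ps$per_level$reproducibility_rsd_pct,
            ps$per_level$repeatability_rsd_pct)
  expect_equal(ps$avg_repeatability_rsd_pct,
               ps$per_level$repeatability_rsd_pct)
  # constant data: both vanish
  flat <- data.frame(level = rep(c(10, 30), each = 4),
                     run = rep(c("r1", "r2"), 4), value = 5)
  expect_equal(precision_summary(flat)$avg_repeatability_rsd_pct, 0)
  expect_equal(precision_summary(flat)$avg_reproducibility_rsd_pct, 0)
})

test_that("simulated repeatability matches the published <5% RSD regime", {
  # two operators x three days, six replicates, at the most variable level
  st_runs <- lapply(1:6, function(r) {
    des <- data.frame(sample_id = "mix30", trout_mass_fraction_pct = 30,
                      n_replicates = 6)
    st <- generate_study(des, species_constants(),
                         sim_config(extraction_cv = 0.05, seed = 600 + r))
    q <- quantify_sample(st$plate, k = 0.43)
    data.frame(level = 30, run = paste0("run", r),
               value = q$replicates$trout_fraction_pct)
  })
  ps <- precision_summary(do.call(rbind, st_runs))
  expect_lt(ps$avg_repeatability_rsd_pct, 5)
  expect_lt(ps$avg_reproducibility_rsd_pct, 5)
})
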