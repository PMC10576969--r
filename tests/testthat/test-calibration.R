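test_that("per-label summaries use the sample SD and skip singletons", {
  s <- summarizeByLabel(c(1, 2, 3), rep("Yes", 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$min, 1); expect_equal(s$max, 3)
  s2 <- summarizeByLabel(c(5, 1, 2, 3), c("Yes", "No", "No", "No"))
  expect_true(is.na(s2$sd[s2$label == "Yes"]))
  expect_equal(s2$mean[s2$label == "Yes"], 5)
  s3 <- summarizeByLabel(c(1, 2, 9), c("Yes", "Yes", NA))
  expect_identical(attr(s3, "n_unlabelled"), 1L)
  expect_false("Maybe" %in% s3$label)
  expect_error(summarizeByLabel(1:3, rep(NA_character_, 3)), "unlabelled")
})

test_that("hand-computed ANOVA: A = [0,2], B = [4,6] gives F = 8", {
  a <- onewayAnova(c(0, 2, 4, 6), c("A", "A", "B", "B"))
  # direct sums of squares: SSB = 16, SSW = 4, df = (1, 2)
  expect_equal(a$F, 8)
  expect_identical(a$df_between, 1L)
  expect_identical(a$df_within, 2L)
  orc <- ss_anova_oracle(c(0, 2, 4, 6), c("A", "A", "B", "B"))
  expect_equal(orc$ssb, 16); expect_equal(orc$ssw, 4)
  expect_equal(a$p, orc$p, tolerance = 1e-12)
  # F(1, df) is t(df) squared: same p as the two-sided pooled t
  expect_equal(a$p, pooled_t_oracle(c(0, 2), c(4, 6)), tolerance = 1e-12)
})

test_that("equal group means give F = 0, p = 1", {
  a <- onewayAnova(c(1, 2, 3, 3, 2, 1), rep(c("A", "B"), each = 3))
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)
  # all-constant degenerate input carries no signal
  a0 <- onewayAnova(rep(2, 6), rep(c("A", "B"), each = 3))
  expect_equal(a0$F, 0); expect_equal(a0$p, 1)
  expect_error(onewayAnova(c(1, 2), c("A", "B")), "two or more")
  expect_error(onewayAnova(1:4, rep("A", 4)), "two label groups")
})

test_that("ANOVA agrees with a direct-summation oracle on random data", {
  set.seed(2024)
  for (i in 1:100) {
    inst <- random_instance()
    got <- onewayAnova(inst$values, inst$labels)
    want <- ss_anova_oracle(inst$values, inst$labels)
    expect_lt(abs(got$F - want$F), 1e-9)
    expect_lt(abs(got$p - want$p), 1e-9)
  }
})

test_that("Tukey HSD handles degenerate and forced-separation cases", {
  t1 <- tukeyHsd(rep(5, 9), rep(c("A", "B", "C"), 3))
  expect_equal(t1$p_adj, rep(1, 3))
  expect_identical(nrow(t1), 3L)  # one row per unordered pair
  set.seed(1)
  t2 <- tukeyHsd(c(rnorm(10, 0), rnorm(10, 1000)),
                 rep(c("lo", "hi"), each = 10))
  expect_lt(t2$p_adj, 1e-6)
})

test_that("Tukey with two groups matches the pooled-variance t test", {
  set.seed(77)
  for (i in 1:50) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1), mean = 0.5)
    got <- tukeyHsd(c(a, b), rep(c("A", "B"), c(length(a), length(b))))
    expect_equal(got$p_adj, pooled_t_oracle(a, b), tolerance = 1e-5)
  }
})

test_that("Tukey p-values are invariant to relabeling and shifts", {
  set.seed(5)
  v <- rnorm(18); l <- rep(c("Yes", "Maybe", "No"), 6)
  base <- tukeyHsd(v, l)
  shift <- tukeyHsd(v + 100, l)
  expect_equal(sort(base$p_adj), sort(shift$p_adj), tolerance = 1e-10)
  relab <- tukeyHsd(v, c(Yes = "g1", Maybe = "g2", No = "g3")[l])
  expect_equal(sort(base$p_adj), sort(relab$p_adj), tolerance = 1e-10)
})

test_that("covariate regression matches the r-to-t oracle", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- runif(n, 0, 100)
    y <- 0.3 * x + rnorm(n, sd = 10)
    got <- covariateRegression(y, x)
    want <- r_to_t_oracle(y, x)
    expect_equal(got$slope, want$slope, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }
  # constant response: no slope, no evidence
  flat <- covariateRegression(rep(2, 5), 1:5)
  expect_equal(flat$slope, 0)
  expect_equal(flat$p, 1)
  expect_error(covariateRegression(1:5, rep(3, 5)), "zero variance")
  # missing covariates are dropped and counted
  m <- covariateRegression(c(1, 2, 3, 4), c(1, NA, 3, 4))
  expect_identical(m$n, 3L); expect_identical(m$n_dropped, 1L)
})

test_that("threshold estimators implement their stated conventions", {
  vals <- c(6.00, 2.32); labs <- c("Yes", "No")
  mid <- deriveThresholds(vals, labs, "midpoint_means")
  expect_equal(mid$value, 4.16)
  # lower-interpolation quantile of the No group
  nq <- deriveThresholds(c(0, 0, 0, 10, 5), c("No", "No", "No", "No", "Yes"),
                         "no_quantile", q = 0.5)
  expect_equal(nq$value, 0)
  # separated groups: the cut settles at the top of the No range
  sep <- deriveThresholds(c(5, 6, 7, 0.2, 0.4, 1.0),
                          rep(c("Yes", "No"), each = 3),
                          "min_misclassification")
  expect_equal(sep$value, 1.0)
  # exhaustive-search oracle: no other observed cut does better
  errs <- sapply(c(5, 6, 7, 0.2, 0.4, 1.0), function(cc)
    sum(c(0.2, 0.4, 1.0) > cc) + sum(c(5, 6, 7) <= cc))
  expect_identical(min(errs), 0L)
  # Maybe records are ignored by the estimators
  withm <- deriveThresholds(c(6, 2.32, 999), c("Yes", "No", "Maybe"),
                            "midpoint_means")
  expect_equal(withm$value, 4.16)
  expect_error(deriveThresholds(1:3, rep("Yes", 3), "midpoint_means"),
               "non-empty")
})

test_that("midpoint threshold is monotone in the Yes group", {
  set.seed(8)
  vals <- c(rexp(20, 1 / 3), rexp(20, 1))
  labs <- rep(c("Yes", "No"), each = 20)
  base <- deriveThresholds(vals, labs, "midpoint_means")$value
  raised <- vals; raised[labs == "Yes"] <- raised[labs == "Yes"] + 1
  expect_gte(deriveThresholds(raised, labs, "midpoint_means")$value, base)
})

test_that("the calibration report detects label-dependent densities", {
  x <- makeFixture("study_like", seed = 7)
  rep <- runCalibrationReport(x)
  expect_identical(rep$filter$records_in, 1273L)
  expect_identical(rep$filter$records_removed + rep$filter$records_kept,
                   1273L)
  # simulated from label-dependent means: Yes vs No separates decisively
  for (m in c("Alcyonacea", "Scleractinia", "Porifera", "overall_density"))
    expect_lt(rep$anova[[m]]$p, 0.01)
  # depth and substrate were not simulated as drivers: no relationship
  expect_gt(rep$regressions$depth$p, 0.01)
  expect_gt(rep$regressions$pct_soft_substrate$p, 0.01)
  # every configured estimator yields a Yes/No threshold per metric
  thr <- rep$thresholds$overall_density
  expect_setequal(names(thr), c("midpoint_means", "no_quantile",
                                "min_misclassification"))
  expect_true(all(sapply(thr, function(t) t$value) > 0))
  expect_identical(rep$n_tests, length(rep$metrics))
})

test_that("report bundles serialize to JSON and CSV", {
  x <- makeFixture("study_like", seed = 7)
  rep <- runCalibrationReport(x)
  dir <- tempfile()
  writeCalibrationReport(rep, dir)
  expect_true(all(file.exists(file.path(dir,
    c("report.json", "summary_stats.csv", "anova.csv", "tukey_hsd.csv")))))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$filter$records_in, 1273)
  an <- read.csv(file.path(dir, "anova.csv"))
  expect_true("overall_density" %in% an$metric)
  tk <- read.csv(file.path(dir, "tukey_hsd.csv"))
  expect_true(all(c("label_a", "label_b", "p_adj") %in% names(tk)))
})
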