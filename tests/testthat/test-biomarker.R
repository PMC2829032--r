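test_that("loading-control normalization divides by the housekeeping band", {
  expect_equal(normalize_band(10, 2), 5)
  expect_equal(normalize_band(7, 7), 1)
  expect_error(normalize_band(3, 0), class = "probdnf_normalization_error")
  expect_error(normalize_band(3, -1), class = "probdnf_normalization_error")
})

test_that("pro_fraction implements 100*pro/(pro+mat) and is scale invariant", {
  expect_equal(pro_fraction(40, 60), 40)
  expect_equal(pro_fraction(42, 58), 42)
  expect_equal(pro_fraction(0, 5), 0)
  expect_error(pro_fraction(0, 0), class = "probdnf_score_error")
  expect_error(pro_fraction(-1, 5), class = "probdnf_score_error")

  set.seed(41)
  pro <- runif(50, 1, 100)
  mat <- runif(50, 1, 100)
  k <- runif(50, 0.01, 100)
  expect_equal(pro_fraction(k * pro, k * mat), pro_fraction(pro, mat),
               tolerance = 1e-12)
})

test_that("scored samples have complementary pro and mat fractions", {
  cohort <- generate_densitometry_cohort(cohort_config("brain", seed = 14))
  scored <- score_samples(cohort)
  expect_equal(scored$pro_fraction + scored$mat_fraction, rep(100, 30),
               tolerance = 1e-9)
})

test_that("the stress threshold is control mean plus k sample SDs", {
  expect_equal(stress_threshold(c(40, 40, 40)), 40)
  expect_equal(stress_threshold(c(38, 40, 42)), 42)  # mean 40, sample SD 2
  # Controls with mean 40 and SD 3 put the cutoff at 43.
  expect_equal(stress_threshold(c(37, 40, 43)), 43)
  expect_equal(stress_threshold(c(38, 40, 42), sd_mult = 2), 44)
  expect_error(stress_threshold(40), class = "probdnf_threshold_error")
})

test_that("positivity is strict: ties at the threshold are negative", {
  scored <- tibble::tibble(pro_fraction = c(43, 43.01, 42.99))
  calls <- classify_samples(scored, 43)$call
  expect_equal(calls, c("negative", "positive", "negative"))
})

test_that("confusion tallies follow the a/b/c/d mapping", {
  cc <- confusion(
    c(rep("stressed", 15), rep("control", 15)),
    c(rep("positive", 15), rep("positive", 2), rep("negative", 13))
  )
  expect_equal(unlist(cc[c("a", "b", "c", "d")]),
               c(a = 15L, b = 2L, c = 0L, d = 13L))

  cc2 <- confusion(rep("stressed", 3), rep("negative", 3))
  expect_equal(unlist(cc2[c("a", "b", "c", "d")]),
               c(a = 0L, b = 0L, c = 3L, d = 0L))

  cc3 <- confusion(character(0), character(0))
  expect_equal(unlist(cc3[c("a", "b", "c", "d")]), c(a = 0L, b = 0L, c = 0L, d = 0L))

  expect_error(confusion("sick", "positive"), class = "probdnf_label_error")
  expect_error(confusion(c("control", "stressed"), "positive"),
               class = "probdnf_label_error")
})

test_that("confusion and metrics agree with a brute-force recount oracle", {
  set.seed(53)
  for (i in 1:200) {
    n <- sample(2:20, 1)
    groups <- sample(c("control", "stressed"), n, replace = TRUE)
    calls <- sample(c("positive", "negative"), n, replace = TRUE)
    cc <- confusion(groups, calls)
    oracle <- naive_confusion(groups, calls)
    expect_equal(unlist(cc[c("a", "b", "c", "d")]), oracle,
                 ignore_attr = TRUE)
    rep <- diagnostic_metrics(cc)
    ratio <- function(num, den) {
      if (den == 0) NA_real_ else unname(100 * num / den)
    }
    expect_equal(rep$sensitivity, ratio(oracle["a"], oracle["a"] + oracle["c"]))
    expect_equal(rep$specificity, ratio(oracle["d"], oracle["d"] + oracle["b"]))
    expect_equal(rep$ppv, ratio(oracle["a"], oracle["a"] + oracle["b"]))
    expect_equal(rep$npv, ratio(oracle["d"], oracle["c"] + oracle["d"]))
  }
})

test_that("the published worked example reproduces exactly", {
  rep <- diagnostic_metrics(confusion_counts(a = 15, b = 2, c = 0, d = 13))
  expect_equal(rep$sensitivity, 100)
  expect_equal(rep$specificity, 100 * 13 / 15)  # 86.7
  expect_equal(rep$ppv, 100 * 15 / 17)          # 88.2
  expect_equal(rep$npv, 100)
  expect_equal(rep$display$sensitivity, 100L)
  expect_equal(rep$display$specificity, 87L)
  expect_equal(rep$display$ppv, 88L)
  expect_equal(rep$display$npv, 100L)
})

test_that("zero-denominator metrics are undefined, not zero, and display rounds half away", {
  rep <- diagnostic_metrics(confusion_counts(a = 0, b = 0, c = 0, d = 10))
  expect_true(is.na(rep$sensitivity))
  expect_true(is.na(rep$ppv))
  expect_equal(rep$specificity, 100)
  expect_equal(rep$npv, 100)

  # 100 * 1/8 = 12.5 must display as 13 (half away from zero).
  rep2 <- diagnostic_metrics(confusion_counts(a = 1, b = 0, c = 7, d = 0))
  expect_equal(rep2$sensitivity, 12.5)
  expect_equal(rep2$display$sensitivity, 13L)
})

test_that("perfect exclusion structure: c = 0 with d > 0 forces sensitivity and NPV to 100", {
  for (b in 0:5) {
    rep <- diagnostic_metrics(confusion_counts(a = 7, b = b, c = 0, d = 9))
    expect_equal(rep$sensitivity, 100)
    expect_equal(rep$npv, 100)
  }
})

test_that("the homoscedastic t-test matches the pooled-variance formula", {
  same <- ttest_two_tailed_equalvar(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  x <- c(40, 41, 39); y <- c(52, 53, 51)
  res <- ttest_two_tailed_equalvar(x, y)
  # Textbook pooled formula, computed independently.
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)

  expect_error(ttest_two_tailed_equalvar(c(1, 1), c(1, 1)),
               class = "probdnf_degenerate_data_error")
  expect_error(ttest_two_tailed_equalvar(1, c(1, 2)),
               class = "probdnf_degenerate_data_error")
})

test_that("p-values shrink monotonically as the group shift grows", {
  x <- c(1, 2, 3)
  ps <- vapply(c(0.5, 1, 2, 4, 8), function(d) {
    ttest_two_tailed_equalvar(x, x + d)$p_value
  }, 1)
  expect_true(all(diff(ps) < 0))
})

test_that("one-way ANOVA: F = t^2 for two groups, zero for identical groups", {
  expect_equal(anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)

  set.seed(61)
  for (i in 1:25) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1), mean = 0.5)
    f <- anova_oneway(list(x, y))$statistic
    t <- ttest_two_tailed_equalvar(x, y)$statistic
    expect_equal(f, t^2, tolerance = 1e-9)
  }

  expect_error(anova_oneway(list(c(1, 1), c(1, 1))),
               class = "probdnf_degenerate_data_error")
  expect_error(anova_oneway(list(c(1, 2))),
               class = "probdnf_degenerate_data_error")
})

test_that("three null groups give an O(1) F statistic and calibrated p-values", {
  set.seed(71)
  ps <- replicate(400, {
    anova_oneway(list(rnorm(5), rnorm(5), rnorm(5)))$p_value
  })
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.035 / 0.05)
  expect_gt(mean(ps), 0.4)  # roughly uniform
})

test_that("Holm-Sidak posthoc reduces to the plain t-test for two groups", {
  x <- c(40, 41, 39); y <- c(52, 53, 51)
  hs <- holm_sidak_posthoc(list(ctl = x, str = y))
  tt <- ttest_two_tailed_equalvar(x, y)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$p_adjusted, tt$p_value, tolerance = 1e-12)

  set.seed(81)
  groups <- list(a = rnorm(5), b = rnorm(5, 2), c = rnorm(5, 4))
  hs3 <- holm_sidak_posthoc(groups)
  expect_equal(nrow(hs3), 3)
  expect_true(all(hs3$p_adjusted >= hs3$p_value - 1e-12))
  expect_true(all(hs3$p_adjusted <= 1))
})

test_that("adding a high control score never shrinks the predicted-positive set", {
  set.seed(91)
  for (i in 1:20) {
    controls <- runif(10, 35, 45)
    scores <- runif(20, 30, 60)
    thr1 <- stress_threshold(controls)
    extra <- max(controls) + runif(1, 0, 10)  # above the mean, raises it
    thr2 <- stress_threshold(c(controls, extra))
    expect_gte(mean(c(controls, extra)), mean(controls))
    pos1 <- scores > thr1
    pos2 <- scores > thr2
    if (thr2 >= thr1) expect_true(all(which(pos2) %in% which(pos1)))
  }
})

test_that("the pipeline output is invariant under per-lane rescaling", {
  cohort <- generate_densitometry_cohort(cohort_config("brain", seed = 33))
  res1 <- run_biomarker_pipeline(cohort)
  set.seed(2)
  k <- runif(nrow(cohort), 0.1, 10)
  rescaled <- dplyr::mutate(cohort,
                            band_pro = band_pro * k,
                            band_mat = band_mat * k,
                            band_tubulin = band_tubulin * k)
  res2 <- run_biomarker_pipeline(rescaled)
  expect_equal(glance(res2), glance(res1), tolerance = 1e-12)
})

test_that("identical controls give a degenerate threshold at their common value", {
  cohort <- tibble::tibble(
    animal_id = paste0("x", 1:6),
    group = rep(c("control", "stressed"), each = 3),
    tissue = "brain",
    band_pro = c(40, 40, 40, 50, 52, 54),
    band_mat = c(60, 60, 60, 50, 48, 46),
    band_tubulin = 1
  )
  res <- run_biomarker_pipeline(cohort)
  expect_equal(res$threshold, 40)
  expect_equal(res$counts$a, 3L)  # every stressed score exceeds 40
  expect_equal(res$counts$b, 0L)
})

test_that("the pipeline rejects malformed cohorts", {
  cohort <- generate_densitometry_cohort(cohort_config("brain", seed = 3))
  expect_error(run_biomarker_pipeline(dplyr::filter(cohort, group == "control")),
               class = "probdnf_cohort_error")
  mixed <- dplyr::bind_rows(
    cohort,
    generate_densitometry_cohort(cohort_config("liver", seed = 3))
  )
  expect_error(run_biomarker_pipeline(mixed), class = "probdnf_cohort_error")
  expect_error(run_biomarker_pipeline(cohort[, 1:3]),
               class = "probdnf_cohort_error")
})

test_that("verbose mode logs threshold and confusion counts", {
  cohort <- generate_densitometry_cohort(cohort_config("brain", seed = 3))
  expect_message(run_biomarker_pipeline(cohort, verbose = TRUE),
                 "threshold \\(brain\\)")
  expect_message(run_biomarker_pipeline(cohort, verbose = TRUE),
                 "confusion: a=")
})
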