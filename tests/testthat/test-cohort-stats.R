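# Cohort-level statistics: kappa, chi-squared, exact binomials, ANCOVA,
# time-in-scan trends.

test_that("Cohen's kappa: perfect agreement, chance level, closed form", {
  a <- rep(c(0, 1), 30)
  expect_equal(cohens_kappa(a, a)$kappa, 1)

  # contingency table (40, 10; 10, 40): kappa = 0.6
  x <- c(rep(0, 50), rep(1, 50))
  y <- c(rep(0, 40), rep(1, 10), rep(0, 10), rep(1, 40))
  k <- cohens_kappa(x, y)
  expect_equal(k$kappa, 0.6)
  expect_equal(k$percent_agreement, 80)
  expect_equal(k$kappa, oracle_kappa(x, y))

  # independent raters: mean kappa ~ 0 (rater-scale replicates)
  set.seed(10)
  ks <- replicate(300, {
    cohens_kappa(rbinom(1596, 1, 0.4), rbinom(1596, 1, 0.4))$kappa
  })
  expect_lt(abs(mean(ks)), 0.02)

  expect_true(is.na(cohens_kappa(rep(1, 10), rep(1, 10))$kappa))
  expect_error(cohens_kappa(1:3, 1:4), "length")
})

test_that("sex chi-squared matches the brute-force statistic", {
  sex <- rep(c("F", "M"), each = 1000)
  call <- c(rbinom(1000, 1, 0.35) * 0, rep(0, 1000))
  # deterministic counts: 450/550 vs 350/650 scaled x10
  sex <- rep(c("M", "F"), c(1000, 1000))
  call <- c(rep(1, 450), rep(0, 550), rep(1, 350), rep(0, 650))
  got <- sex_pattern_chi2(call, sex)
  tab <- table(factor(sex), factor(call, levels = c(0, 1)))
  expect_equal(got$statistic, oracle_chi2(tab))
  expect_equal(got$df, 1)

  # identical proportions: statistic 0, p = 1
  same <- sex_pattern_chi2(rep(c(1, 0), 100), rep(c("M", "F"), each = 100))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  expect_error(sex_pattern_chi2(rep(1, 10), rep("M", 10)), "margin")
})

test_that("exact binomial tails reproduce the sleep-list enrichment", {
  p <- binomial_enrichment(15, 21, 0.37, "upper")
  expect_equal(signif(p, 2), 0.0014)
  expect_equal(p, oracle_binom_upper(15, 21, 0.37), tolerance = 1e-12)

  expect_equal(binomial_enrichment(0, 21, 0.37, "upper"), 1)
  # tail symmetry P(X >= k; p) = P(X <= n-k; 1-p)
  expect_equal(binomial_enrichment(15, 21, 0.37, "upper"),
               binomial_enrichment(6, 21, 0.63, "lower"), tolerance = 1e-12)

  # pmf-summation agreement across sizes
  for (n in c(10, 100, 1000)) {
    k <- round(0.6 * n)
    expect_equal(binomial_enrichment(k, n, 0.5, "upper"),
                 oracle_binom_upper(k, n, 0.5), tolerance = 1e-12)
  }
  expect_error(binomial_enrichment(5, 3, 0.5), "k")
  expect_error(binomial_enrichment(1, 3, 1.5), "p0")
})

test_that("group sex-composition probability multiplies directed tails", {
  out <- group_composition_probability(c(6, 5, 14), 21, 228 / 440)
  manual <- pbinom(6, 21, 228 / 440) * pbinom(5, 21, 228 / 440) *
    oracle_binom_upper(14, 21, 228 / 440)
  expect_equal(out$joint_p, manual, tolerance = 1e-12)
  expect_equal(out$per_group$tail, c("lower", "lower", "upper"))

  # groups at expectation: each tail is ~0.5
  bal <- group_composition_probability(c(10, 11), 21, 0.5)
  expect_gt(bal$joint_p, 0.2)
  expect_error(group_composition_probability(c(25), 21, 0.5), "male counts")
  expect_error(group_composition_probability(c(0), 0, 0.5), "size 0")
})

test_that("ANCOVA reports marginal term tests and validates the model", {
  tbl <- simulate_subject_summaries(150, seed = 4)
  fit <- ancova_gfc(tbl, gfc ~ sex + icv_z + burst_index + deep_index)
  expect_setequal(names(fit$terms_p),
                  c("sex", "icv_z", "burst_index", "deep_index"))
  expect_lt(fit$terms_p[["burst_index"]], 0.001)
  expect_lt(fit$terms_p[["icv_z"]], 0.001)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(glance(fit)), 1L)

  # affine rescaling of covariates leaves p-values unchanged
  tbl2 <- dplyr::mutate(tbl, icv_z = 100 * icv_z - 7,
                        burst_index = 0.01 * burst_index + 2)
  fit2 <- ancova_gfc(tbl2, gfc ~ sex + icv_z + burst_index + deep_index)
  expect_equal(unname(fit$terms_p), unname(fit2$terms_p), tolerance = 1e-10)

  expect_error(ancova_gfc(tbl, gfc ~ sex + nonexistent), "absent")
  tbl$dup <- tbl$icv_z
  expect_error(ancova_gfc(tbl, gfc ~ icv_z + dup), "collinear")
})

test_that("ANCOVA term tests hold their type-I error on null cohorts", {
  set.seed(11)
  n_rep <- 400
  hits <- matrix(0, n_rep, 3)
  for (r in seq_len(n_rep)) {
    n <- 60
    tbl <- tibble::tibble(sex = sample(c("M", "F"), n, TRUE),
                          icv_z = rnorm(n), burst_index = rnorm(n),
                          gfc = rnorm(n))
    fit <- ancova_gfc(tbl, gfc ~ sex + icv_z + burst_index)
    hits[r, ] <- fit$terms_p < 0.05
  }
  rate <- colMeans(hits)
  expect_true(all(abs(rate - 0.05) < 0.02))
})

test_that("time-in-scan trends: null calibration sketch and power direction", {
  # identical early/late values: t = 0, p = 1
  mt <- tidyr::expand_grid(scan_id = 1:10, minute = 1:14)
  mt$index <- rep(0.02, nrow(mt))
  out <- time_in_scan_trend(mt)
  expect_equal(out$statistic, 0)
  expect_equal(out$p.value, 1)

  # uniform placement: n.s. on average; late placement: strongly significant
  set.seed(12)
  null_p <- replicate(200, {
    mt$index <- runif(nrow(mt))
    time_in_scan_trend(mt)$p.value
  })
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 0.04)

  late <- tidyr::expand_grid(scan_id = 1:20, minute = 1:14)
  late$index <- ifelse(late$minute > 6, 0.05, 0) + runif(nrow(late), 0, 0.01)
  out_l <- time_in_scan_trend(late)
  expect_lt(out_l$p.value, 1e-4)
  expect_gt(out_l$mean_late, out_l$mean_early)

  expect_error(time_in_scan_trend(mt[mt$minute < 10, ]), "shorter")
})

test_that("per-minute index decomposition feeds the trend test", {
  spec <- tiny_spec()
  g <- generate_scan(spec, list(resp_event("burst_train", 600, 2.5,
                                           n_cycles = 5, cycle_s = 40)),
                     seed = 77)
  det <- detect_scan(g$physio, g$scan)
  pm <- pattern_index_by_minute(det, "burst")
  expect_equal(nrow(pm), 15L) # 864 s = 14.4 min
  # the burst lives in minutes 10-14: late minutes dominate
  expect_gt(mean(pm$index[pm$minute %in% 11:14]),
            mean(pm$index[pm$minute %in% 1:4]))
  # count-weighted minute means recombine exactly to the scan index
  counts <- table(floor(((1:1200) - 0.5) * spec$tr_s / 60) + 1)
  expect_equal(sum(pm$index * as.numeric(counts)) / 1200,
               det$burst_index, tolerance = 1e-10)
})
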