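# The pattern detector: priors, template match, index, scoring.

spec <- tiny_spec()
tr <- spec$tr_s
nf <- spec$frames_per_scan
tgrid <- (seq_len(nf) - 0.5) * tr

test_that("priors stay low on pure eupnea", {
  for (s in 1:3) {
    g <- generate_scan(spec, list(), seed = 500 + s)
    m <- respiratory_measures(g$physio$resp, 400)
    expect_lt(max(deep_breath_prior(m, tr, nf)), 0.1)
    expect_lt(max(burst_prior(m, tr, nf)), 0.1)
  }
})

test_that("a single implanted deep breath drives its prior up locally only", {
  for (s in 1:3) {
    g <- generate_scan(spec, list(resp_event("deep_breath", 400, 2.5,
                                             apnea_s = 8)),
                       seed = 520 + s)
    m <- respiratory_measures(g$physio$resp, 400)
    on <- g$truth$onset_s[1]
    dp <- deep_breath_prior(m, tr, nf)
    near <- abs(tgrid - on) <= 5
    far <- tgrid < on - 20 | tgrid > on + 40
    expect_gt(max(dp[near]), 0.5)
    expect_lt(max(dp[far]), 0.1)
    # and the burst prior stays quiet throughout
    expect_lt(max(burst_prior(m, tr, nf)), 0.2)
  }
})

test_that("burst trains light the burst prior across the train, not the deep prior", {
  for (s in 1:3) {
    g <- generate_scan(spec, list(resp_event("burst_train", 300, 2.5,
                                             n_cycles = 5, cycle_s = 40)),
                       seed = 540 + s)
    m <- respiratory_measures(g$physio$resp, 400)
    on <- g$truth$onset_s[1]
    span <- tgrid >= on & tgrid <= on + 200
    bp <- burst_prior(m, tr, nf)
    dp <- deep_breath_prior(m, tr, nf)
    expect_gte(mean(bp[span] > 0.5), 0.5)
    expect_lt(median(dp[span]), median(bp[span]))
  }
})

test_that("template match is 1 at an embedded kernel and 0 for its sign flip", {
  k <- response_kernel("burst", dt_s = tr)
  sig <- rep(0, 400)
  sig[100:(99 + length(k$samples))] <- k$samples
  mt <- template_match(sig, k, tr)
  expect_equal(which.max(mt), 100)
  expect_equal(max(mt), 1, tolerance = 1e-9)

  mt_flip <- template_match(-sig, k, tr)
  expect_equal(mt_flip[100], 0)

  expect_error(template_match(rep(0, 10), k, tr), "shorter than")
})

test_that("white-noise template matches are rarely strong", {
  set.seed(7)
  k <- response_kernel("deep_breath", dt_s = tr)
  q95 <- replicate(5, {
    quantile(template_match(rnorm(1200), k, tr), 0.95)
  })
  expect_true(all(q95 < 0.5))
})

test_that("the index multiplicatively gates on the prior and on rate CV", {
  match <- runif(100)
  expect_identical(pattern_index(rep(0, 100), match), 0)
  # exact gating: zero prior contributes zero wherever it is zero
  prior <- c(rep(0, 50), rep(1, 50))
  expect_equal(pattern_index(prior, match),
               mean(match[51:100]) / 2, tolerance = 1e-12)

  i_low <- pattern_index(prior, match, rate_cv = 0.1)
  i_high <- pattern_index(prior, match, rate_cv = 0.5)
  expect_lt(i_high, i_low)
  # closed form: CV 0.4 is downweighted by >= 60%
  expect_lte(rate_cv_weight(0.4), 0.4)
  expect_equal(rate_cv_weight(0.4), exp(-5 * 0.25))
  expect_equal(rate_cv_weight(0.1), 1)

  expect_error(pattern_index(rep(1, 10), rep(1, 9)), "lengths differ")
})

test_that("indices separate implanted from clean scans and cross-pattern", {
  n_each <- 8
  idx <- purrr::map_dfr(seq_len(n_each), function(s) {
    gc_ <- generate_scan(spec, list(), seed = 600 + s)
    gb <- generate_scan(spec, list(resp_event("burst_train", 300, 2.5,
                                              n_cycles = 5, cycle_s = 40)),
                        seed = 700 + s)
    gd <- generate_scan(spec, list(resp_event("deep_breath", 400, 2.5,
                                              apnea_s = 8)),
                        seed = 800 + s)
    dplyr::bind_rows(
      dplyr::mutate(tidy(detect_scan(gc_$physio, gc_$scan)), type = "clean"),
      dplyr::mutate(tidy(detect_scan(gb$physio, gb$scan)), type = "burst"),
      dplyr::mutate(tidy(detect_scan(gd$physio, gd$scan)), type = "deep")
    )
  })
  by_type <- split(idx, idx$type)
  expect_gt(min(by_type$burst$burst_index), max(by_type$clean$burst_index))
  expect_gt(median(by_type$deep$deep_index), median(by_type$clean$deep_index))
  # specificity: each pattern's own index dominates on its own scans
  expect_lt(median(by_type$deep$burst_index),
            median(by_type$deep$deep_index))
  expect_lt(median(by_type$burst$deep_index),
            median(by_type$burst$burst_index))
})

test_that("detection survives +/-20% template timing perturbation", {
  n_each <- 6
  for (stretch in c(0.8, 1.2)) {
    kern <- list(deep_breath = perturb_kernel(response_kernel("deep_breath",
                                                              tr), stretch),
                 burst = perturb_kernel(response_kernel("burst", tr),
                                        stretch))
    vals <- purrr::map_dfr(seq_len(n_each), function(s) {
      gc_ <- generate_scan(spec, list(), seed = 900 + s)
      gb <- generate_scan(spec, list(resp_event("burst_train", 300, 2.5,
                                                n_cycles = 5, cycle_s = 40)),
                          seed = 950 + s)
      mc <- respiratory_measures(gc_$physio$resp, 400)
      mb <- respiratory_measures(gb$physio$resp, 400)
      tibble::tibble(
        clean = detect_patterns(mc, global_signal(gc_$scan)$z, tr,
                                kernels = kern)$burst_index,
        burst = detect_patterns(mb, global_signal(gb$scan)$z, tr,
                                kernels = kern)$burst_index)
    })
    # AUC of burst vs clean indices
    auc <- mean(outer(vals$burst, vals$clean, `>`)) +
      0.5 * mean(outer(vals$burst, vals$clean, `==`))
    expect_gte(auc, 0.85)
  }
})

test_that("binary calls and 0-4 scores follow the thresholds", {
  idx <- tibble::tibble(
    subject = rep(c("a", "b"), each = 4), scan = rep(1:4, 2),
    burst_index = c(0.04, 0.05, 0.03, 0.06, 0.001, 0.002, 0.04, 0.001),
    deep_index = rep(0.001, 8)
  )
  thr <- c(burst = 0.01, deep = 0.05)
  bs <- binarize_and_score(idx, thr)
  expect_equal(bs$scores$burst_score[bs$scores$subject == "a"], 4L)
  expect_equal(bs$scores$burst_score[bs$scores$subject == "b"], 1L)
  expect_equal(bs$scores$deep_score, c(0L, 0L))
  expect_false(any(bs$scores$incomplete))

  # subjects with a different scan count are flagged, not dropped
  bs2 <- binarize_and_score(idx[1:6, ], thr)
  expect_true(bs2$scores$incomplete[bs2$scores$subject == "b"])

  # thresholds put 5% of clean scans above by construction
  clean <- tibble::tibble(burst_index = seq(0, 1, length.out = 1000),
                          deep_index = seq(0, 1, length.out = 1000))
  thr2 <- calibrate_thresholds(clean)
  expect_equal(unname(thr2["burst"]), 0.95, tolerance = 0.001)
})
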