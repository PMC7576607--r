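# The ground-truthed generator: eupnea, event implanting, kernels, scans,
# cohorts.

test_that("deterministic eupnea is exactly periodic and seed-reproducible", {
  b <- generate_eupnea(60, 0.25)
  pk <- find_peaks_times(as.numeric(clean_trace(as.numeric(b), 400)))
  expect_equal(length(pk), 15L)
  expect_equal(unique(round(diff(pk), 6)), 4)

  b1 <- generate_eupnea(120, 0.3, rate_jitter = 0.2, depth_drift = 0.1,
                        seed = 77)
  b2 <- generate_eupnea(120, 0.3, rate_jitter = 0.2, depth_drift = 0.1,
                        seed = 77)
  expect_identical(as.numeric(b1), as.numeric(b2))

  expect_error(generate_eupnea(-5, 0.25), "duration_s")
  expect_error(generate_eupnea(60, 0.6), "rate_hz")
})

test_that("rate jitter maps onto the inter-peak interval CV", {
  b <- generate_eupnea(864, 0.25, rate_jitter = 0.2, seed = 13)
  m <- respiratory_measures(as.numeric(b), 400)
  expect_lt(abs(m$rate_cv - 0.2) / 0.2, 0.3)
})

test_that("response kernels honor their timing landmarks", {
  kd <- response_kernel("deep_breath", dt_s = 0.1)
  nadir_d <- kd$time_s[which.min(kd$samples)]
  expect_gte(nadir_d, 13)
  expect_lte(nadir_d, 17)
  expect_lt(max(abs(kd$samples[kd$time_s >= 30])),
            0.05 * abs(min(kd$samples)))
  # positive lobe precedes the trough
  expect_lt(kd$time_s[which.max(kd$samples)], nadir_d)
  expect_gt(max(kd$samples), 0)

  kb <- response_kernel("burst", dt_s = 0.1)
  nadir_b <- kb$time_s[which.min(kb$samples)]
  expect_gt(nadir_b, 20)
  expect_lt(max(abs(kb$samples[kb$time_s >= 40])),
            0.05 * abs(min(kb$samples)))
  # burst response peaks later than the sigh response
  expect_gt(kb$time_s[which.max(kb$samples)],
            kd$time_s[which.max(kd$samples)])
})

test_that("implanted deep breaths scale prominence and stamp apnea", {
  b <- generate_eupnea(600, 0.25, rate_jitter = 0.03, depth_drift = 0.03,
                       seed = 21)
  ev <- resp_event("deep_breath", onset_s = 300, amplitude_factor = 2.5,
                   apnea_s = 10)
  b2 <- implant_event(b, ev)
  log <- attr(b2, "events")
  expect_equal(nrow(log), 1L)
  m <- respiratory_measures(as.numeric(b2), 400)
  pk <- m$extrema$peaks
  near <- which(abs(pk$time_s - (log$onset_s + 2.5 * 4 / 2)) < 6)
  expect_gte(length(near), 1L)
  big <- near[which.max(pk$prominence[near])]
  base_prom <- median(pk$prominence[-big])
  expect_gte(pk$prominence[big] / base_prom, 2.2)
  expect_lte(pk$prominence[big] / base_prom, 2.8)
  # apnea: inter-breath gap at the event of at least 10 s
  gaps <- diff(pk$time_s)
  expect_gte(max(gaps[abs(pk$time_s[-1] - log$onset_s) < 40]), 10)
})

test_that("burst trains span n_cycles * cycle_s and overlaps are rejected", {
  b <- generate_eupnea(600, 0.25, seed = 22)
  ev <- resp_event("burst_train", onset_s = 200, amplitude_factor = 2.5,
                   n_cycles = 5, cycle_s = 40)
  b2 <- implant_event(b, ev)
  log <- attr(b2, "events")
  expect_equal(log$duration_s, 200, tolerance = 4 / 200) # one breath period
  expect_error(implant_event(b2, resp_event("deep_breath", 250, 2)),
               "overlap")
  expect_error(implant_event(b, resp_event("burst_train", 550, 2.5,
                                           n_cycles = 5, cycle_s = 40)),
               "does not fit")
})

test_that("event specifications are validated", {
  expect_error(resp_event("deep_breath", -1, 2.5), "onset_s")
  expect_error(resp_event("deep_breath", 10, 0.9), "amplitude_factor")
  expect_error(resp_event("deep_breath", 10, 2.5, apnea_s = 25), "apnea_s")
  expect_error(resp_event("burst_train", 10, 2.5, cycle_s = 20), "cycle_s")
  ok <- resp_event("burst_train", 10, 2.5, cycle_s = 20,
                   cycle_range = c(10, 60))
  expect_equal(ok$cycle_s, 20)
})

test_that("slow deep breaths dissociate RVT from ENV and RV", {
  spec <- tiny_spec()
  g <- generate_scan(spec, list(resp_event("deep_breath", 400, 2.5)),
                     seed = 5, rate_hz = 0.25, rate_jitter = 0,
                     depth_drift = 0)
  m <- respiratory_measures(g$physio$resp, 400)
  on <- g$truth$onset_s[1]
  dur <- g$truth$duration_s[1]
  t <- (seq_along(m$env) - 1) / 400
  ev <- t >= on & t <= on + dur + 8 # event plus recovery breaths
  base <- t > 100 & t < on - 20
  rvt_change <- abs(mean(m$rvt$series[ev]) / mean(m$rvt$series[base]) - 1)
  expect_lt(rvt_change, 0.15)
  expect_gt(max(m$env[ev]) / mean(m$env[base]), 1.5)
  expect_gt(max(m$rv[ev]) / mean(m$rv[base]), 1.5)
})

test_that("scan generation couples respiration, HR, motion and networks", {
  spec <- tiny_spec()
  # gfc_coupling 0: no shared respiratory signal in gFC
  sp0 <- cohort_spec(seed = 42, gfc_coupling = 0, shared_sd = 0,
                     network_sd = 0)
  g0 <- generate_scan(sp0, list(resp_event("burst_train", 200, 2.5,
                                           n_cycles = 5, cycle_s = 40)),
                      seed = 3)
  gray <- g0$scan$signals
  n_pairs_se <- 3 / sqrt(ncol(gray)) # ~3 standard errors of a null r
  expect_lt(abs(as.numeric(gfc(g0$scan))), n_pairs_se)

  # deep breaths elevate HR in (0, 10 s]
  g <- generate_scan(spec, list(resp_event("deep_breath", 300, 2.5),
                                resp_event("deep_breath", 500, 2.5)),
                     seed = 4)
  cs <- cardiac_series(g$physio$pulse, 400)
  grid <- seq(0, 863, by = 0.5)
  hr_g <- interp_to_grid(cs$hr, grid)
  ons <- g$truth$onset_s
  post <- mean(vapply(ons, function(on)
    mean(hr_g[grid > on & grid <= on + 10]), numeric(1)))
  pre <- mean(vapply(ons, function(on)
    mean(hr_g[grid > on - 10 & grid <= on]), numeric(1)))
  expect_gt(post, pre)

  # sensorimotor parcels correlate more strongly during bursts
  gb <- generate_scan(spec, list(resp_event("burst_train", 300, 2.5,
                                            n_cycles = 5, cycle_s = 40)),
                      seed = 6)
  parc <- default_parcellation(spec)
  sm <- parc$network %in% attr(parc, "sensorimotor")
  ec <- event_connectivity(gb$scan$signals, spec$tr_s,
                           gb$truth$onset_s[1] + (0:4) * 40)
  r_sm <- mean(ec$mean_r[sm, sm][upper.tri(ec$mean_r[sm, sm])])
  r_ot <- mean(ec$mean_r[!sm, !sm][upper.tri(ec$mean_r[!sm, !sm])])
  expect_gt(r_sm, r_ot)

  # motion spikes at deep-breath onsets
  fd <- framewise_displacement(g$scan$motion, "original")
  on_f <- floor(ons / spec$tr_s) + 1
  expect_gt(min(fd[on_f + 1]), 0.2)
})

test_that("cohorts are reproducible with sex-specific prevalence and head size", {
  spec <- cohort_spec(n_subjects = 150L, seed = 99L)
  co <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co$events, co2$events)
  expect_identical(co$subjects, co2$subjects)

  # empirical prevalences inside exact binomial 99% CIs
  tab <- dplyr::left_join(co$scans, co$subjects[, c("subject", "sex")],
                          by = "subject")
  for (sx in c("M", "F")) {
    p_true <- if (sx == "M") spec$p_burst_scan_male else
      spec$p_burst_scan_female
    k <- sum(tab$has_burst[tab$sex == sx])
    n <- sum(tab$sex == sx)
    ci <- binom.test(k, n, conf.level = 0.99)$conf.int
    expect_gte(p_true, ci[1])
    expect_lte(p_true, ci[2])
  }
  k_d <- sum(tab$has_deep)
  ci_d <- binom.test(k_d, nrow(tab), conf.level = 0.99)$conf.int
  expect_gte(spec$p_deep_scan, ci_d[1])
  expect_lte(spec$p_deep_scan, ci_d[2])

  # ICV separates by sex in the expected direction
  icv_m <- mean(co$subjects$icv[co$subjects$sex == "M"])
  icv_f <- mean(co$subjects$icv[co$subjects$sex == "F"])
  expect_gt(icv_m, icv_f)

  # p_deep_scan = 0 silences deep breaths entirely
  co0 <- generate_cohort(cohort_spec(n_subjects = 20L, p_deep_scan = 0,
                                     seed = 1L))
  expect_false(any(co0$events$kind == "deep_breath"))
})

test_that("realized scans are deterministic and consistent with the spec", {
  spec <- cohort_spec(n_subjects = 2L, seed = 3L)
  co <- generate_cohort(spec)
  r1 <- realize_scan(co, "sub0001", 1)
  r2 <- realize_scan(co, "sub0001", 1)
  expect_identical(r1$scan$signals, r2$scan$signals)
  expect_identical(r1$physio$resp, r2$physio$resp)
  expect_equal(r1$physio$n_samples / spec$physio_hz,
               spec$frames_per_scan * spec$tr_s)
  expect_equal(ncol(r1$scan$signals), spec$frames_per_scan)
  expect_error(realize_scan(co, "nope", 1), "unknown subject")
})
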