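# Breath detection and the ENV / RV / RVT measures.

test_that("breath peaks of a unit sine are found at 4-s spacing", {
  z <- sine_trace(60, period_s = 4, amp = sqrt(2))
  ex <- detect_breaths(z, sample_hz = 400)
  expect_equal(nrow(ex$peaks), 15L)
  expect_equal(unique(round(diff(ex$peaks$time_s), 6)), 4)
})

test_that("the greedy spacing rule keeps the higher of two close peaks", {
  # two candidate peaks 1 s apart at 100 Hz
  t <- seq(0, 10, by = 0.01)
  x <- exp(-((t - 5)^2) / 0.02) + 0.8 * exp(-((t - 6)^2) / 0.02) - 0.5
  ex <- detect_breaths(x, sample_hz = 100, min_spacing_s = 2)
  expect_equal(nrow(ex$peaks), 1L)
  expect_equal(ex$peaks$time_s, 5)
  expect_equal(oracle_peaks(x, 200, 0.5), round(5 * 100) + 1L)
})

test_that("sub-prominence ripples yield no peaks; constant traces flag degenerate", {
  ripple <- 0.2 * sine_trace(30, period_s = 4, hz = 100)
  expect_equal(nrow(detect_breaths(ripple, sample_hz = 100)$peaks), 0L)
  ex <- detect_breaths(rep(0, 1000), sample_hz = 100)
  expect_true(ex$degenerate)
  expect_equal(nrow(ex$peaks), 0L)
})

test_that("peak detector agrees with the brute-force oracle on noisy traces", {
  for (s in 1:10) {
    set.seed(s)
    x <- as.numeric(clean_trace(generate_eupnea(90, runif(1, 0.18, 0.4),
                                                rate_jitter = 0.15,
                                                depth_drift = 0.1,
                                                seed = s)))
    got <- detect_breaths(x, sample_hz = 400)
    expect_equal(round(got$peaks$time_s * 400) + 1L,
                 oracle_peaks(x, 800, 0.5))
  }
})

test_that("ENV matches the sliding-RMS oracle and its closed forms", {
  z <- as.numeric(zscore_trace(sine_trace(120, 4)))
  env <- compute_env(z, sample_hz = 400, window_s = 10)
  mid <- 20000:28000
  expect_lt(max(abs(env[mid] - 1)), 0.02)

  # amplitude step x2 halfway doubles ENV
  x2 <- c(sine_trace(60, 4), 2 * sine_trace(60, 4))
  env2 <- compute_env(x2, 400, 10)
  expect_equal(mean(env2[40000:44000]) / mean(env2[4000:8000]), 2,
               tolerance = 0.05 / 2)

  for (s in 1:5) {
    set.seed(s)
    r <- rnorm(700)
    expect_lt(max(abs(compute_env(r, 100, 1) -
                        oracle_slide_stat(r, 100, "rms"))), 1e-10)
  }
})

test_that("RV matches the sliding-SD oracle and its closed forms", {
  expect_equal(compute_rv(rep(3, 5000), 400, 6), rep(0, 5000))
  set.seed(9)
  w <- rnorm(240000)
  expect_lt(abs(mean(compute_rv(w, 400, 6)) - 1), 0.02)
  for (s in 1:5) {
    set.seed(s + 100)
    r <- rnorm(700)
    expect_lt(max(abs(compute_rv(r, 100, 1) -
                        oracle_slide_stat(r, 100, "sd"))), 1e-10)
  }
})

test_that("RVT closed forms: 2A/T at every scored peak, amplitude and co-scaling laws", {
  hz <- 400
  z <- sine_trace(120, period_s = 4, amp = sqrt(2), hz = hz)
  ex <- detect_breaths(z, sample_hz = hz)
  rvt <- compute_rvt(z, ex, hz)
  scored <- rvt$peaks$rvt[!is.na(rvt$peaks$rvt)]
  expect_gt(length(scored), 20)
  expect_equal(unique(round(scored, 6)), round(2 * sqrt(2) / 4, 6))

  # amplitude x2 only: RVT x2
  z2 <- sine_trace(120, 4, amp = 2 * sqrt(2), hz = hz)
  ex2 <- detect_breaths(z2, sample_hz = hz)
  rvt2 <- compute_rvt(z2, ex2, hz)
  expect_equal(mean(rvt2$peaks$rvt, na.rm = TRUE), 2 * 2 * sqrt(2) / 4,
               tolerance = 1e-9)

  # amplitude AND period x2: RVT unchanged within 1e-6, ENV doubles
  z3 <- sine_trace(240, 8, amp = 2 * sqrt(2), hz = hz)
  ex3 <- detect_breaths(z3, sample_hz = hz)
  rvt3 <- compute_rvt(z3, ex3, hz)
  expect_lt(abs(mean(rvt3$peaks$rvt, na.rm = TRUE) - 2 * sqrt(2) / 4), 1e-6)
  env1 <- mean(compute_env(z, hz, 16)[30000:34000])
  env3 <- mean(compute_env(z3, hz, 16)[30000:34000])
  expect_equal(env3 / env1, 2, tolerance = 1e-3)
})

test_that("peaks without an interceding trough are skipped", {
  # two peaks with a plateau between them instead of a trough
  x <- c(sine_trace(4, 4, hz = 100), rep(0, 50), sine_trace(4, 4, hz = 100))
  ex <- detect_breaths(x, sample_hz = 100, min_spacing_s = 1,
                       min_prominence = 0.3)
  rvt <- compute_rvt(x, ex, 100)
  troughs_between <- function(k) {
    any(ex$troughs$time_s > ex$peaks$time_s[k - 1] &
          ex$troughs$time_s < ex$peaks$time_s[k])
  }
  for (k in 2:nrow(rvt$peaks)) {
    expect_identical(is.na(rvt$peaks$rvt[k]), !troughs_between(k))
  }
})

test_that("breathing-rate statistics: constant spacing, alternating intervals, jitter recovery", {
  ex <- detect_breaths(sine_trace(62, 4, amp = sqrt(2)), 400)
  rs <- breathing_rate_stats(ex)
  expect_equal(unique(round(rs$rate$rate_bpm, 6)), 15)
  expect_equal(rs$rate_cv, 0)

  # alternating 3 s / 5 s inter-peak intervals: CV = 1/4
  fake <- list(peaks = tibble::tibble(time_s = cumsum(rep(c(3, 5), 10))))
  rs2 <- breathing_rate_stats(fake)
  expect_equal(rs2$rate_cv, 0.25, tolerance = 0.02)
  expect_setequal(round(unique(rs2$rate$rate_bpm), 6), c(20, 12))

  # generator jitter recovered within +/-30%
  for (jit in c(0.1, 0.2)) {
    b <- generate_eupnea(864, 0.25, rate_jitter = jit, seed = 33)
    m <- respiratory_measures(as.numeric(b), 400)
    expect_lt(abs(m$rate_cv - jit) / jit, 0.3)
  }
})

test_that("depth scaling over a segment raises ENV and RV there", {
  hz <- 100
  x <- sine_trace(300, 4, hz = hz)
  seg <- 10000:15000
  for (c_fac in c(1.5, 2, 3)) {
    y <- x
    y[seg] <- c_fac * y[seg]
    env_x <- compute_env(x, hz, 10)
    env_y <- compute_env(y, hz, 10)
    rv_x <- compute_rv(x, hz, 6)
    rv_y <- compute_rv(y, hz, 6)
    inner <- 11000:14000
    expect_true(all(env_y[inner] > env_x[inner]))
    expect_true(all(rv_y[inner] > rv_x[inner]))
  }
})

test_that("ENV, RV and RVT rise together during implanted bursts", {
  spec <- tiny_spec()
  for (s in 1:3) {
    g <- generate_scan(spec, list(resp_event("burst_train", 300, 2.5,
                                             n_cycles = 5, cycle_s = 40)),
                       seed = s)
    m <- respiratory_measures(g$physio$resp, 400)
    on <- g$truth$onset_s[1]
    t <- (seq_along(m$env) - 1) / 400
    span <- t >= on & t <= on + g$truth$duration_s[1]
    # downsample within the burst span for the sliding correlations
    i <- which(span)[seq(1, sum(span), by = 40)]
    expect_gt(cor(m$env[i], m$rv[i]), 0.5)
    expect_gt(cor(m$env[i], m$rvt$series[i]), 0.5)
    expect_gt(cor(m$rv[i], m$rvt$series[i]), 0.5)
  }
})
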