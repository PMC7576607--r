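# gFC, processing strategies, permutation contrasts, score regression.

test_that("gFC closed forms: null level, shared-variance fraction, clipping", {
  sc0 <- shared_noise_scan(100, 1200, shared_frac = 0, seed = 1)
  expect_lt(abs(as.numeric(gfc(sc0))), 0.05)

  sc3 <- shared_noise_scan(100, 1200, shared_frac = 0.3, seed = 2)
  expect_equal(as.numeric(gfc(sc3)), atanh(0.3), tolerance = 0.04 / 0.3)

  s <- rnorm(100)
  sc_same <- scan_data(rbind(s, s, s, s), 0.72)
  expect_equal(as.numeric(gfc(sc_same)), atanh(1 - 1e-6))

  # constant units are excluded with a report
  m <- rbind(matrix(rnorm(5 * 100), 5), rep(1, 100))
  expect_message(g <- gfc(scan_data(m, 0.72)), "excluded")
  expect_equal(attr(g, "n_excluded"), 1L)
})

test_that("processing strategies: GSR orthogonality, censoring, motion regression", {
  set.seed(3)
  spec <- tiny_spec()
  g <- generate_scan(spec, list(), seed = 31)
  gsr <- apply_processing(g$scan, "MP+GSR")
  expect_lt(max(abs(global_signal(gsr)$series)), 1e-8)

  # no suprathreshold DVARS: censoring leaves frame count intact
  calm <- scan_data(matrix(rnorm(20 * 100), 20), 0.72,
                    motion = motion_params(matrix(rnorm(600, 0, 1e-4),
                                                  100, 6),
                                           0.72, "radians"))
  cens <- apply_processing(calm, "MP+mot+cens", dvars_z_cut = 100)
  expect_equal(ncol(cens$signals), 100L)
  expect_length(attr(cens, "censored_frames"), 0L)

  # a unit that is an exact combination of motion regressors residualizes to 0
  mp <- matrix(rnorm(600), 100, 6)
  unit <- 2 * mp[, 1] - 3 * mp[, 4]
  sc <- scan_data(rbind(unit, matrix(rnorm(300), 3)), 0.72,
                  motion = motion_params(mp, 0.72, "radians"))
  proc <- apply_processing(sc, "MP+mot+cens", dvars_z_cut = 1e6)
  expect_lt(max(abs(proc$signals[1, ])), 1e-8)

  expect_error(apply_processing(calm, "MP+mot+cens", dvars_z_cut = -1),
               "review")
  expect_error(apply_processing(scan_data(matrix(rnorm(100), 4), 0.72),
                                "MP+mot+cens"),
               "requires motion")
})

test_that("permutation contrasts: identity null, calibration, power, reordering", {
  set.seed(4)
  make_mats <- function(n, p = 12, shift = 0, block = NULL) {
    lapply(seq_len(n), function(i) {
      z <- matrix(rnorm(p * p, 0, 0.2), p)
      z <- (z + t(z)) / 2
      diag(z) <- 0
      if (!is.null(block)) z[block, block] <- z[block, block] + shift
      z
    })
  }
  a <- make_mats(8)
  pc_same <- permutation_contrast(a, a, n_perm = 200, seed = 1)
  expect_true(all(abs(pc_same$delta) < 1e-12))

  # calibration: cellwise false-positive rate ~5% under the null
  fp <- replicate(60, {
    x <- make_mats(8)
    y <- make_mats(8)
    pc <- permutation_contrast(x, y, n_perm = 199, seed = 2)
    mean(pc$mask[upper.tri(pc$mask)])
  })
  expect_lt(abs(mean(fp) - 0.05), 0.015)

  # implanted block difference of Z = 0.5 is detected
  blk <- 1:4
  hits <- replicate(10, {
    x <- make_mats(21, shift = 0.5, block = blk)
    y <- make_mats(21)
    pc <- permutation_contrast(x, y, n_perm = 499, seed = 3)
    cells <- pc$mask[blk, blk][upper.tri(pc$mask[blk, blk])]
    mean(cells)
  })
  expect_gte(mean(hits), 0.9)

  # signed mode reports tails
  pcs <- permutation_contrast(make_mats(10, shift = 0.4, block = blk),
                              make_mats(10), n_perm = 199, seed = 4,
                              mode = "signed")
  expect_true(any(pcs$mask[blk, blk]))

  # parcel reordering permutes results exactly
  x <- make_mats(6)
  y <- make_mats(6)
  perm <- sample(12)
  pc1 <- permutation_contrast(x, y, n_perm = 99, seed = 5)
  pc2 <- permutation_contrast(lapply(x, function(m) m[perm, perm]),
                              lapply(y, function(m) m[perm, perm]),
                              n_perm = 99, seed = 5)
  expect_equal(pc2$delta, pc1$delta[perm, perm], tolerance = 1e-12)

  expect_error(permutation_contrast(a[1:3], a, n_perm = 10), "at least 5")
})

test_that("small designs fall back to exact enumeration", {
  set.seed(6)
  a <- lapply(1:5, function(i) {
    z <- matrix(rnorm(16, 0, 0.1), 4)
    z <- (z + t(z)) / 2
    diag(z) <- 0
    z
  })
  b <- lapply(1:5, function(i) {
    z <- matrix(rnorm(16, 0, 0.1), 4)
    z <- (z + t(z)) / 2
    diag(z) <- 0
    z
  })
  expect_message(pc <- permutation_contrast(a, b, n_perm = 10000, seed = 1),
                 "exact enumeration")
  expect_true(attr(pc, "exact"))
  expect_equal(pc$n_perm, choose(10, 5))
})

test_that("group-vs-random-groups ranks are uniform for random groups", {
  set.seed(7)
  cohort <- lapply(1:40, function(i) {
    z <- matrix(rnorm(100, 0, 0.3), 10)
    z <- (z + t(z)) / 2
    diag(z) <- 0
    z
  })
  grp <- cohort[sample(40, 10)]
  rr <- group_vs_random_groups(grp, cohort, n_draws = 500, seed = 2)
  ranks <- rr$rank[upper.tri(rr$rank)]
  # break the draw-grid ties before the KS comparison
  ranks <- ranks + runif(length(ranks), -5e-4, 5e-4)
  expect_gt(ks.test(ranks, "punif")$p.value, 0.01)
  expect_error(group_vs_random_groups(cohort, cohort, n_draws = 10),
               "twice the group")
})

test_that("an elevated-coupling group shows sensorimotor rank extremes", {
  spec <- tiny_spec()
  parc <- default_parcellation(spec)
  sm <- which(parc$network %in% attr(parc, "sensorimotor"))
  burst_ev <- list(resp_event("burst_train", 300, 2.5, n_cycles = 5,
                              cycle_s = 40))
  cohort_mats <- lapply(1:16, function(i) {
    ev <- if (i <= 6) burst_ev else list()
    connectivity_matrix(generate_scan(spec, ev, seed = 4000 + i)$scan)
  })
  rr <- group_vs_random_groups(cohort_mats[1:6], cohort_mats,
                               n_draws = 300, seed = 3)
  sm_ranks <- rr$rank[sm, sm][upper.tri(rr$rank[sm, sm])]
  other <- setdiff(seq_len(nrow(parc)), sm)
  ot_ranks <- rr$rank[other, other][upper.tri(rr$rank[other, other])]
  # sensorimotor cells sit in the top tail (the whole-brain coupling also
  # elevates other blocks, so only a weak ordering is asserted there)
  expect_gte(median(sm_ranks), 0.975)
  expect_gte(mean(sm_ranks), mean(ot_ranks))
})

test_that("score regression recovers coefficients and rejects bad designs", {
  set.seed(8)
  n <- 150
  tbl <- tibble::tibble(burst_score = rbinom(n, 4, 0.4),
                        deep_score = rbinom(n, 4, 0.5))
  y <- 0.1 + 0.05 * tbl$burst_score + rnorm(n, 0, 0.04)
  fit <- score_regression(y, tbl, c("burst_score", "deep_score"))
  b1 <- fit$estimate[fit$term == "burst_score"]
  # betas are on z-scored regressors
  expect_equal(b1, 0.05 * sd(tbl$burst_score), tolerance = 0.25)
  expect_lt(fit$p.value[fit$term == "burst_score"], 1e-6)
  expect_gt(fit$p.value[fit$term == "deep_score"], 0.01)

  tbl$dup <- tbl$burst_score
  expect_error(score_regression(y, tbl, c("burst_score", "dup")),
               "collinear|rank")
  tbl$const <- 1
  expect_error(score_regression(y, tbl, c("burst_score", "const")),
               "constant")
  expect_error(score_regression(y, tbl, c("burst_score", "missing_col")),
               "absent")
})

test_that("cellwise score regression flags the loaded block", {
  set.seed(9)
  n <- 30
  score <- rbinom(n, 4, 0.4)
  blk <- 1:3
  mats <- lapply(seq_len(n), function(i) {
    z <- matrix(rnorm(64, 0, 0.1), 8)
    z <- (z + t(z)) / 2
    z[blk, blk] <- z[blk, blk] + 0.15 * score[i]
    diag(z) <- 0
    z
  })
  tbl <- tibble::tibble(score = score)
  out <- score_regression(mats, tbl, "score", n_perm = 300, seed = 1)
  inside <- out$score$mask[blk, blk][upper.tri(out$score$mask[blk, blk])]
  expect_true(all(inside))
  expect_gt(mean(out$score$beta[blk, blk][upper.tri(out$score$beta[blk, blk])]),
            0)
})
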