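# Whole-scan functional connectivity: gFC, processing strategies,
# permutation contrasts.

#' Global functional connectivity (gFC) of one scan
#'
#' Median Pearson correlation over all pairs of gray-unit time series,
#' Fisher-Z transformed (correlations clipped to +/-(1 - 1e-6) first).
#' Constant units cannot be correlated and are excluded with a report.
#'
#' @param scan A [scan_data()] (or bare unit-by-frame matrix).
#' @return A scalar `gfc` value (Fisher-Z units) with attribute
#'   `n_excluded`.
#' @export
gfc <- function(scan) {
  m <- if (inherits(scan, "scan_data")) {
    scan$signals[scan$compartment == "gray", , drop = FALSE]
  } else as.matrix(scan)
  if (ncol(m) < 10L) stop("gFC needs at least 10 frames")
  sds <- apply(m, 1L, stats::sd)
  excl <- sds == 0
  if (any(excl)) {
    message(sum(excl), " constant unit(s) excluded from gFC")
    m <- m[!excl, , drop = FALSE]
  }
  if (nrow(m) < 3L) stop("gFC needs at least 3 non-constant gray units")
  r <- stats::cor(t(m))
  med <- stats::median(r[upper.tri(r)])
  structure(fisher_z(med), n_excluded = sum(excl))
}

#' Subject-level gFC: mean of per-scan values
#'
#' @param scan_gfc Numeric vector of per-scan gFC values (Fisher-Z).
#' @return Scalar mean.
#' @export
subject_gfc <- function(scan_gfc) mean(scan_gfc)

# Residualize rows of y against columns of X (with intercept).
residualize <- function(y, X) {
  X <- cbind(1, X)
  t(stats::resid(stats::lm.fit(X, t(y))))
}

#' Apply a signal-processing strategy to a scan
#'
#' Strategies mirror common resting-state processing streams:
#' \describe{
#'   \item{MP}{minimally processed input, returned as is.}
#'   \item{MP+GSR}{the mean gray-matter signal is regressed out of every
#'     unit.}
#'   \item{MP+mot+cens}{the 6 motion parameters and their backward
#'     differences (12 regressors) are regressed out, then frames with
#'     z-scored DVARS > `dvars_z_cut` are censored (removed listwise).}
#'   \item{MP+GSR+mot+cens}{both.}
#' }
#'
#' @param scan A [scan_data()].
#' @param strategy One of `"MP"`, `"MP+GSR"`, `"MP+mot+cens"`,
#'   `"MP+GSR+mot+cens"`.
#' @param dvars_z_cut Censoring threshold on z-scored DVARS (default 2).
#' @return A `scan_data` with processed signals (and possibly fewer
#'   frames); attribute `censored_frames` lists removed frame indices.
#' @export
apply_processing <- function(scan, strategy = c("MP", "MP+GSR",
                                                "MP+mot+cens",
                                                "MP+GSR+mot+cens"),
                             dvars_z_cut = 2) {
  strategy <- match.arg(strategy)
  m <- scan$signals
  censored <- integer(0)
  if (strategy %in% c("MP+mot+cens", "MP+GSR+mot+cens")) {
    if (is.null(scan$motion)) stop("strategy ", strategy,
                                   " requires motion parameters")
    mp <- as.matrix(scan$motion[, 1:6])
    dmp <- rbind(0, diff(mp))
    m <- residualize(m, cbind(mp, dmp))
    dz <- dvars(m)$z
    censored <- which(dz > dvars_z_cut)
    if (length(censored) > 0.5 * ncol(m)) {
      stop("censoring would remove ", length(censored), "/", ncol(m),
           " frames; review the DVARS threshold")
    }
    if (length(censored)) m <- m[, -censored, drop = FALSE]
  }
  if (strategy %in% c("MP+GSR", "MP+GSR+mot+cens")) {
    gray <- scan$compartment == "gray"
    gs <- colMeans(m[gray, , drop = FALSE])
    m <- residualize(m, matrix(gs, ncol = 1L))
  }
  out <- scan_data(m, tr_s = scan$tr_s,
                   compartment = scan$compartment, network = scan$network,
                   motion = if (length(censored)) NULL else scan$motion)
  attr(out, "censored_frames") <- censored
  attr(out, "strategy") <- strategy
  out
}

#' Parcel-by-parcel Fisher-Z connectivity matrix of a whole scan
#'
#' @param scan A [scan_data()] (or matrix).
#' @return Symmetric Fisher-Z matrix with zero diagonal.
#' @export
connectivity_matrix <- function(scan) {
  m <- if (inherits(scan, "scan_data")) scan$signals else as.matrix(scan)
  z <- fisher_z(stats::cor(t(m)))
  diag(z) <- 0
  z
}

# Stack a list of symmetric matrices into cells x subjects (upper triangle).
stack_cells <- function(mats) {
  ut <- upper.tri(mats[[1L]])
  vapply(mats, function(m) m[ut], numeric(sum(ut)))
}

unstack_cells <- function(v, p) {
  out <- matrix(0, p, p)
  out[upper.tri(out)] <- v
  out + t(out)
}

#' Cellwise permutation contrast between two sets of matrices
#'
#' Observed statistic: cellwise difference of group means (in Fisher-Z).
#' The null is built by randomly exchanging subject labels `n_perm` times.
#' Two p-value modes: `"abs"` compares |observed| against the permuted
#' |differences| (two-sided, add-one rule); `"signed"` flags cells whose
#' observed difference falls in the top or bottom `tail` of the signed
#' permutation distribution.
#'
#' @param mats_a,mats_b Lists of symmetric matrices (>= 5 per side).
#' @param n_perm Number of permutations (default 10000). If it exceeds the
#'   number of distinct label assignments, exact enumeration is used
#'   instead (reported via attribute `exact`).
#' @param seed Integer seed.
#' @param mode `"abs"` or `"signed"`.
#' @param alpha Significance level for the mask (default 0.05; in signed
#'   mode each tail gets `alpha/2`).
#' @return List: `delta` (mean A - mean B, parcel x parcel), `p`,
#'   `mask` (logical), `n_perm`, `mode`.
#' @export
permutation_contrast <- function(mats_a, mats_b, n_perm = 10000L,
                                 seed = 1L, mode = c("abs", "signed"),
                                 alpha = 0.05) {
  mode <- match.arg(mode)
  if (length(mats_a) < 5L || length(mats_b) < 5L) {
    stop("need at least 5 matrices per side")
  }
  p <- nrow(mats_a[[1L]])
  X <- cbind(stack_cells(mats_a), stack_cells(mats_b))
  na <- length(mats_a); nb <- length(mats_b); n <- na + nb
  obs <- rowMeans(X[, seq_len(na), drop = FALSE]) -
    rowMeans(X[, na + seq_len(nb), drop = FALSE])
  n_distinct <- choose(n, na)
  exact <- n_perm >= n_distinct
  perms <- if (exact) {
    message("exact enumeration of ", n_distinct, " label assignments")
    utils::combn(n, na, simplify = FALSE)
  } else {
    set.seed(derive_seed(seed, 31L))
    replicate(n_perm, sample.int(n, na), simplify = FALSE)
  }
  # contrast weights per permutation -> one matrix multiply for all cells
  W <- vapply(perms, function(idx) {
    w <- rep(-1 / nb, n)
    w[idx] <- 1 / na
    w
  }, numeric(n))
  null_d <- X %*% W
  if (mode == "abs") {
    b <- rowSums(abs(null_d) >= abs(obs) - 1e-15)
    pv <- (b + 1) / (ncol(W) + 1)
    mask <- pv < alpha
  } else {
    lo <- rowMeans(null_d <= matrix(obs, nrow(null_d), ncol(null_d)) + 1e-15)
    hi <- rowMeans(null_d >= matrix(obs, nrow(null_d), ncol(null_d)) - 1e-15)
    pv <- 2 * pmin(lo, hi)
    pv <- pmin(pmax(pv, 1 / (ncol(W) + 1)), 1)
    mask <- lo <= alpha / 2 | hi <= alpha / 2
  }
  structure(list(delta = unstack_cells(obs, p), p = unstack_cells(pv, p),
                 mask = unstack_cells(as.numeric(mask), p) > 0,
                 n_perm = ncol(W), mode = mode),
            exact = exact)
}

#' Rank of a group's mean matrix among random same-sized groups
#'
#' Per cell, the rank of the observed group mean within the means of
#' `n_draws` random subject draws of equal size from the cohort; cells in
#' the top or bottom `alpha/2` tails are flagged.
#'
#' @param group_mats Matrices of the group's subjects.
#' @param cohort_mats Matrices of all cohort subjects (superset;
#'   must be at least twice the group size).
#' @param n_draws Random draws (default 10000).
#' @param seed Integer seed.
#' @param alpha Two-sided flag level (default 0.05).
#' @return List: `rank` (parcel x parcel, in (0, 1]: fraction of draws at
#'   or below the observed mean), `mask`, `n_draws`.
#' @export
group_vs_random_groups <- function(group_mats, cohort_mats,
                                   n_draws = 10000L, seed = 1L,
                                   alpha = 0.05) {
  k <- length(group_mats)
  n <- length(cohort_mats)
  if (n < 2L * k) stop("cohort (", n, ") must be at least twice the group (",
                       k, ")")
  p <- nrow(group_mats[[1L]])
  X <- stack_cells(cohort_mats)
  obs <- rowMeans(stack_cells(group_mats))
  set.seed(derive_seed(seed, 37L))
  W <- vapply(seq_len(n_draws), function(i) {
    w <- rep(0, n)
    w[sample.int(n, k)] <- 1 / k
    w
  }, numeric(n))
  null_m <- X %*% W
  rk <- rowMeans(null_m <= matrix(obs, nrow(null_m), ncol(null_m)) + 1e-15)
  mask <- rk <= alpha / 2 | rk >= 1 - alpha / 2
  ut <- upper.tri(matrix(0, p, p))
  rank_m <- matrix(0.5, p, p)
  rank_m[ut] <- rk
  rank_m[lower.tri(rank_m)] <- t(rank_m)[lower.tri(rank_m)]
  list(rank = rank_m, mask = unstack_cells(as.numeric(mask), p) > 0,
       n_draws = n_draws)
}

#' Regression of connectivity (or gFC) on subject scores
#'
#' Ordinary least squares with z-scored regressors; significance by
#' permutation of subject rows. For a scalar outcome returns a tidy
#' coefficient table; for a list of matrices returns cellwise beta maps
#' with permutation masks.
#'
#' @param y Numeric vector (e.g. subject gFC) or list of subject matrices.
#' @param table Subject table containing the model terms.
#' @param terms Character vector of regressor columns (z-scored
#'   internally).
#' @param n_perm Permutations for the cellwise mask (matrices only).
#' @param seed Integer seed.
#' @param alpha Mask level.
#' @return For vector `y`: tibble with `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`. For matrix `y`: list of per-term `beta`
#'   matrices and `mask` matrices.
#' @export
score_regression <- function(y, table, terms, n_perm = 1000L, seed = 1L,
                             alpha = 0.05) {
  missing_terms <- setdiff(terms, names(table))
  if (length(missing_terms)) {
    stop("terms absent from table: ", paste(missing_terms, collapse = ", "))
  }
  X <- as.matrix(table[, terms])
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) stop("constant regressor(s): ",
                          paste(terms[sds == 0], collapse = ", "))
  X <- scale(X)
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) {
    cm <- stats::cor(X)
    diag(cm) <- 0
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1L, ]
    stop("rank-deficient design; collinear columns include: ",
         paste(terms[worst], collapse = " ~ "))
  }
  if (is.numeric(y)) {
    fit <- stats::lm(y ~ X)
    sm <- summary(fit)$coefficients
    return(tibble::tibble(term = c("(Intercept)", terms),
                          estimate = as.numeric(sm[, 1L]),
                          std.error = as.numeric(sm[, 2L]),
                          statistic = as.numeric(sm[, 3L]),
                          p.value = as.numeric(sm[, 4L])))
  }
  p <- nrow(y[[1L]])
  Yc <- stack_cells(y) # cells x subjects
  D <- cbind(1, X)
  H <- solve(crossprod(D), t(D)) # (terms+1) x subjects
  obs_b <- Yc %*% t(H) # cells x (terms+1)
  set.seed(derive_seed(seed, 41L))
  n_sub <- ncol(Yc)
  exceed <- matrix(0, nrow(Yc), length(terms))
  for (b in seq_len(n_perm)) {
    Hb <- H[, sample.int(n_sub), drop = FALSE]
    perm_b <- Yc %*% t(Hb)
    exceed <- exceed + (abs(perm_b[, -1L, drop = FALSE]) >=
                          abs(obs_b[, -1L, drop = FALSE]) - 1e-15)
  }
  pv <- (exceed + 1) / (n_perm + 1)
  out <- purrr::map(seq_along(terms), function(j) {
    list(beta = unstack_cells(obs_b[, j + 1L], p),
         p = unstack_cells(pv[, j], p),
         mask = unstack_cells(as.numeric(pv[, j] < alpha), p) > 0)
  })
  names(out) <- terms
  out
}
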