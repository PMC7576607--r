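# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles are deliberately naive (loops, direct definitions) and
# share no code with the package internals they check.

sine_trace <- function(duration_s, period_s = 4, amp = 1, hz = 400,
                       offset = 0, phase = 0) {
  t <- (seq_len(round(duration_s * hz)) - 1) / hz
  offset + amp * sin(2 * pi * (t / period_s) + phase)
}

# windowed RMS/SD by explicit per-sample loops (centered, shrinking)
oracle_slide_stat <- function(x, w, stat) {
  n <- length(x)
  before <- floor(w / 2)
  after <- ceiling(w / 2) - 1
  vapply(seq_len(n), function(i) {
    seg <- x[max(1, i - before):min(n, i + after)]
    if (stat == "rms") sqrt(mean(seg^2))
    else if (length(seg) < 2) 0 else sd(seg)
  }, numeric(1))
}

oracle_dvars <- function(m) {
  out <- numeric(ncol(m))
  for (t in 2:ncol(m)) out[t] <- sqrt(mean((m[, t] - m[, t - 1])^2))
  out
}

oracle_fd <- function(pos6, radius = 50) {
  p <- pos6
  p[, 4:6] <- p[, 4:6] * radius
  out <- numeric(nrow(p))
  for (t in 2:nrow(p)) out[t] <- sum(abs(p[t, ] - p[t - 1, ]))
  out
}

oracle_kappa <- function(a, b) {
  tab <- table(factor(a, levels = 0:1), factor(b, levels = 0:1))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

oracle_chi2 <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

oracle_binom_upper <- function(k, n, p) sum(dbinom(k:n, n, p))

# topographic prominence straight from the definition
oracle_prominence <- function(x, i) {
  n <- length(x)
  v <- x[i]
  left <- if (i == 1) v else {
    higher <- which(x[1:(i - 1)] > v)
    a <- if (length(higher)) max(higher) else 1
    min(x[a:i])
  }
  right <- if (i == n) v else {
    higher <- which(x[(i + 1):n] > v)
    b <- if (length(higher)) i + min(higher) else n
    min(x[i:b])
  }
  v - max(left, right)
}

# all strict local maxima, then greedy tallest-first spacing rule
oracle_peaks <- function(x, min_spacing, min_prom) {
  cand <- which(diff(sign(diff(x))) < 0) + 1
  cand <- cand[vapply(cand, function(i) oracle_prominence(x, i),
                      numeric(1)) >= min_prom]
  kept <- integer(0)
  for (i in cand[order(x[cand], decreasing = TRUE)]) {
    if (!length(kept) || all(abs(kept - i) >= min_spacing)) kept <- c(kept, i)
  }
  sort(kept)
}

find_peaks_times <- function(z, hz = 400) {
  detect_breaths(as.numeric(z), sample_hz = hz)$peaks$time_s
}

tiny_spec <- function(...) cohort_spec(seed = 42L, ...)

# small AR-free random matrices with a known shared component
shared_noise_scan <- function(n_units, n_frames, shared_frac = 0,
                              seed = 1) {
  set.seed(seed)
  g <- rnorm(n_frames)
  m <- matrix(rnorm(n_units * n_frames), n_units) *
    sqrt(1 - shared_frac) +
    matrix(g, n_units, n_frames, byrow = TRUE) * sqrt(shared_frac)
  scan_data(m, tr_s = 0.72)
}
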