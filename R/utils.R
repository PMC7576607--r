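# Internal numeric primitives shared across modules.

# Sliding-window sums over a centered window that shrinks at the endpoints.
# Window of `w` samples covers floor(w/2) samples before and ceiling(w/2)-1
# after the current sample (Matlab mov* convention for even windows).
slide_bounds <- function(n, w) {
  before <- floor(w / 2)
  after <- ceiling(w / 2) - 1L
  i <- seq_len(n)
  list(lo = pmax(1L, i - before), hi = pmin(n, i + after))
}

slide_sums <- function(x, w) {
  n <- length(x)
  b <- slide_bounds(n, w)
  cs1 <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  m <- b$hi - b$lo + 1L
  list(s1 = cs1[b$hi + 1L] - cs1[b$lo], s2 = cs2[b$hi + 1L] - cs2[b$lo], m = m)
}

#' @noRd
slide_rms <- function(x, w) {
  s <- slide_sums(x, w)
  sqrt(s$s2 / s$m)
}

#' @noRd
slide_sd <- function(x, w) {
  s <- slide_sums(x, w)
  v <- (s$s2 - s$s1^2 / s$m) / pmax(s$m - 1L, 1L)
  sqrt(pmax(v, 0))
}

slide_mean <- function(x, w) {
  s <- slide_sums(x, w)
  s$s1 / s$m
}

# centered running maximum over a window of w samples (shrinking ends)
slide_max <- function(x, w) {
  n <- length(x)
  b <- slide_bounds(n, w)
  vapply(seq_len(n), function(i) max(x[b$lo[i]:b$hi[i]]), numeric(1))
}

# Savitzky-Golay smoothing: local least-squares polynomial of order p over a
# centered window of n_w samples (n_w odd). Interior samples via FFT
# convolution with the central projection row; the first/last half-windows use
# the exact truncated-window projection rows, so the result equals the
# classical full-matrix filter.
sg_smooth <- function(x, n_w, p = 2L) {
  n <- length(x)
  if (n_w %% 2L == 0L) n_w <- n_w + 1L
  if (n_w > n) stop("smoothing window (", n_w, " samples) longer than trace (", n, ")")
  if (n_w < 5L) stop("smoothing window must span at least 5 samples")
  h <- (n_w - 1L) %/% 2L
  A <- outer(seq.int(-h, h), 0:p, `^`)
  FP <- A %*% solve(crossprod(A), t(A))
  central <- FP[h + 1L, ]
  y <- numeric(n)
  y[(h + 1L):(n - h)] <- fft_conv_filter(x, central)
  y[seq_len(h)] <- FP[seq_len(h), , drop = FALSE] %*% x[seq_len(n_w)]
  y[(n - h + 1L):n] <- FP[(h + 2L):n_w, , drop = FALSE] %*% x[(n - n_w + 1L):n]
  y
}

# FFT convolution padded to a power-of-2 length (fast for awkward trace
# lengths); returns sum_j x[i+j-1] * k[j] for i = 1 .. n-L+1, i.e. the
# "filter"-type alignment.
fft_conv_filter <- function(x, k) {
  n <- length(x)
  L <- length(k)
  N <- stats::nextn(n + L - 1L, 2L)
  xf <- stats::fft(c(x, numeric(N - n)))
  kf <- stats::fft(c(rev(k), numeric(N - L)))
  full <- Re(stats::fft(xf * kf, inverse = TRUE)) / N
  full[L:n]
}

# Local maxima of x with a topographic-prominence threshold and a greedy
# minimum-spacing rule (tallest peak wins), mirroring the common
# minpeakdistance/minpeakprominence semantics. Returns sorted sample indices.
find_peaks <- function(x, min_spacing = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  s <- sign(d)
  # plateaus inherit the preceding slope so a flat top yields one candidate;
  # leading flats stay 0 (no slope yet) and can never form a peak
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  idx <- seq_along(s)
  idx[!nz] <- 0L
  last_nz <- cummax(idx)
  s <- s[pmax(last_nz, 1L)]
  s[last_nz == 0L] <- 0
  cand <- which(s[-1L] == -1 & s[-length(s)] == 1) + 1L
  if (!length(cand)) return(integer(0))
  prom <- peak_prominence(x, cand)
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))
  # greedy spacing: keep tallest, drop any candidate closer than min_spacing
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_spacing)) kept <- c(kept, i)
  }
  sort(kept)
}

# Topographic prominence of candidate maxima: height above the higher of the
# two lowest descents toward the nearest strictly higher ground on each side.
# Works over inter-candidate valley minima (every sample higher than a
# candidate lies adjacent to a higher candidate or the trace edge), so cost
# is O(n + c^2) instead of O(n * c).
peak_prominence <- function(x, cand) {
  n <- length(x)
  if (!length(cand)) return(numeric(0))
  pos <- c(1L, cand, n)
  val <- x[pos]
  nseg <- length(pos) - 1L
  valley <- vapply(seq_len(nseg), function(k) min(x[pos[k]:pos[k + 1L]]),
                   numeric(1))
  vapply(seq_along(cand), function(ci) {
    j <- ci + 1L # index into pos/val
    v <- val[j]
    left_min <- Inf
    for (k in seq.int(j - 1L, 1L)) {
      left_min <- min(left_min, valley[k])
      if (val[k] > v) break
    }
    right_min <- Inf
    for (k in seq.int(j, nseg)) {
      right_min <- min(right_min, valley[k])
      if (val[k + 1L] > v) break
    }
    v - max(left_min, right_min)
  }, numeric(1))
}

# Mean of physio samples within each half-open frame interval [j*tr, (j+1)*tr).
frame_average <- function(x, sample_hz, tr_s, n_frames) {
  need <- n_frames * tr_s * sample_hz
  if (length(x) < floor(need) - 1e-9) {
    stop("physio trace (", length(x), " samples) shorter than ",
         n_frames, " frames at tr ", tr_s, " s")
  }
  # tolerance guards float noise in tr*hz products (e.g. 0.72 * 100)
  edges <- floor((seq_len(n_frames + 1L) - 1L) * tr_s * sample_hz + 1e-9) + 1L
  edges <- pmin(edges, length(x) + 1L)
  cs <- c(0, cumsum(x))
  lo <- edges[-(n_frames + 1L)]
  hi <- edges[-1L] - 1L
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

fisher_z <- function(r, clip = 1 - 1e-6) atanh(pmin(pmax(r, -clip), clip))

z_to_r <- function(z) tanh(z)

# Deterministic sub-seed derivation, kept below 2^31 for R's 32-bit integers.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 69069 + as.double(k) * 12345 + 1) %% 2147483647
  as.integer(s)
}

zscore_vec <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(name, " must be a single finite number in [", lower, ", ", upper, "]",
         call. = FALSE)
  }
  invisible(x)
}
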