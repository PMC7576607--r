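#' Global fMRI signal response templates for breathing patterns
#'
#' The two breathing patterns leave characteristic imprints on the global
#' (gray-matter mean) fMRI signal. An isolated deep breath produces a brief
#' signal rise followed by a marked trough with nadir near 15 s after onset
#' and resolution by about 30 s. A burst cycle produces a larger, later
#' positive deflection and a prolonged trough with nadir after 20 s,
#' resolving near 40 s. The templates are differences of two gamma density
#' lobes parameterized to honor those timing landmarks; the analytic family
#' itself is a free choice since only the landmarks are constrained.
#'
#' @param kind `"deep_breath"` or `"burst"`.
#' @param dt_s Sampling interval of the returned kernel in seconds
#'   (default 1 s; pass the repetition time to sample at the frame rate).
#' @return An object of class `response_kernel`: a list with `kind`,
#'   `samples` (numeric, unit peak-to-peak scale), `time_s`, `support_s`
#'   and `dt_s`.
#' @examples
#' k <- response_kernel("deep_breath")
#' k$time_s[which.min(k$samples)] # trough near 15 s
#' @export
response_kernel <- function(kind = c("deep_breath", "burst"), dt_s = 1) {
  kind <- match.arg(kind)
  assert_scalar_num(dt_s, "dt_s", lower = 1e-3)
  par <- switch(kind,
    deep_breath = list(support = 32, a_pos = 0.25, shape_pos = 5, rate_pos = 1.6,
                       a_neg = 1.0, shape_neg = 20, rate_neg = 1.3),
    burst = list(support = 44, a_pos = 0.9, shape_pos = 7, rate_pos = 1.0,
                 a_neg = 1.0, shape_neg = 22, rate_neg = 0.92)
  )
  t <- seq(0, par$support, by = dt_s)
  y <- par$a_pos * stats::dgamma(t, par$shape_pos, par$rate_pos) -
    par$a_neg * stats::dgamma(t, par$shape_neg, par$rate_neg)
  y <- y / max(abs(y))
  structure(
    list(kind = kind, samples = y, time_s = t, support_s = par$support, dt_s = dt_s),
    class = "response_kernel"
  )
}

#' @export
print.response_kernel <- function(x, ...) {
  cat("<response_kernel> ", x$kind,
      sprintf(": support %g s, nadir at %g s\n", x$support_s,
              x$time_s[which.min(x$samples)]))
  invisible(x)
}
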