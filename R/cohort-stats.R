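# Subject-level statistics: rater agreement, sex contrasts, enrichment,
# group composition, ANCOVA, time-in-scan trends.

#' Cohen's kappa and percent agreement between two binary raters
#'
#' kappa = (p_o - p_e) / (1 - p_e), with expected agreement from the
#' marginal products. Undefined (flagged NA) when both raters are constant.
#'
#' @param ratings_a,ratings_b Equal-length binary (0/1) vectors.
#' @return Tibble: `kappa`, `percent_agreement`, `n`.
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    stop("rating vectors differ in length")
  }
  a <- as.integer(ratings_a)
  b <- as.integer(ratings_b)
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(1 - a) * mean(1 - b)
  kappa <- if (pe >= 1) NA_real_ else (po - pe) / (1 - pe)
  tibble::tibble(kappa = kappa, percent_agreement = 100 * po, n = n)
}

#' Chi-squared test for a sex difference in pattern prevalence
#'
#' Pearson chi-squared on the 2x2 sex-by-call table, df = 1, without
#' continuity correction by default (cohort-scale counts).
#'
#' @param calls Binary (0/1) scan-level calls.
#' @param sex Per-scan sex labels (two levels).
#' @param correct Apply Yates continuity correction (default FALSE).
#' @return Tibble: `statistic`, `p.value`, `df`, and the per-sex
#'   prevalences `prev_1`, `prev_2` (in `levels(factor(sex))` order).
#' @export
sex_pattern_chi2 <- function(calls, sex, correct = FALSE) {
  tab <- table(factor(sex), factor(calls, levels = c(0, 1)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("empty margin in the sex x call table")
  }
  ht <- stats::chisq.test(tab, correct = correct)
  prev <- tab[, "1"] / rowSums(tab)
  tibble::tibble(statistic = unname(ht$statistic),
                 p.value = ht$p.value, df = unname(ht$parameter),
                 prev_1 = prev[1L], prev_2 = prev[2L])
}

#' Exact binomial tail probability
#'
#' Upper tail P(X >= k) or lower tail P(X <= k) for X ~ Binomial(n, p0).
#' With k = 15 of n = 21 at a base rate p0 = 0.37 the upper tail is
#' 0.0014 -- the sleep-list enrichment of the deep-breath group.
#'
#' @param k Observed count.
#' @param n Trials.
#' @param p0 Null success probability in (0, 1).
#' @param tail `"upper"` or `"lower"`.
#' @return Scalar tail probability.
#' @export
binomial_enrichment <- function(k, n, p0, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  assert_scalar_num(k, "k", lower = 0, upper = n)
  assert_scalar_num(n, "n", lower = 1)
  if (!is.numeric(p0) || p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  if (tail == "upper") {
    stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  } else {
    stats::pbinom(k, n, p0)
  }
}

#' Joint probability of observed group sex compositions
#'
#' For several groups drawn from a cohort with male fraction `male_frac`,
#' the product of one-sided exact binomial tail probabilities, each tail
#' directed toward that group's observed extreme (below-expectation counts
#' take the lower tail, above-expectation the upper).
#'
#' @param male_counts Males per group.
#' @param group_size Common group size (or vector).
#' @param male_frac Cohort male fraction (e.g. 228/440).
#' @return List: `joint_p`, `per_group` tibble (`males`, `size`, `tail`,
#'   `p`).
#' @export
group_composition_probability <- function(male_counts, group_size,
                                          male_frac) {
  sizes <- rep_len(group_size, length(male_counts))
  if (any(male_counts < 0 | male_counts > sizes)) {
    stop("male counts must lie in [0, group size]")
  }
  if (any(sizes == 0)) stop("group of size 0")
  per <- purrr::map_dfr(seq_along(male_counts), function(i) {
    expect <- sizes[i] * male_frac
    tail <- if (male_counts[i] <= expect) "lower" else "upper"
    tibble::tibble(males = male_counts[i], size = sizes[i], tail = tail,
                   p = binomial_enrichment(male_counts[i], sizes[i],
                                           male_frac, tail))
  })
  list(joint_p = prod(per$p), per_group = per)
}

#' ANCOVA of gFC on sex, head size and respiratory variables
#'
#' Linear model with marginal (each term adjusted for all others) F-tests
#' per term, the form behind model charts where a sex main effect is
#' significant alone but vanishes once head size and respiratory indices
#' are modeled.
#'
#' @param table Subject table (one row per subject).
#' @param formula Model formula, e.g. `gfc ~ sex + icv_z + burst_index`.
#' @param type Sum-of-squares type: `"marginal"` (default; Type II via
#'   `car::Anova`) or `"sequential"` (Type I).
#' @return An `ancova_fit`: list with `fit` (lm), `terms_p` (named term ->
#'   p map), `table` (tidy per-term tibble).
#' @export
ancova_gfc <- function(table, formula, type = c("marginal", "sequential")) {
  type <- match.arg(type)
  vars <- all.vars(formula)
  missing_v <- setdiff(vars, names(table))
  if (length(missing_v)) {
    stop("model terms absent from table: ", paste(missing_v, collapse = ", "))
  }
  fit <- stats::lm(formula, data = table)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("perfectly collinear terms: ", paste(bad, collapse = ", "))
  }
  if (type == "marginal") {
    if (!requireNamespace("car", quietly = TRUE)) {
      stop("marginal (Type II) tests require the car package")
    }
    an <- car::Anova(fit, type = 2)
    tab <- tibble::tibble(term = rownames(an),
                          sumsq = an[["Sum Sq"]], df = an[["Df"]],
                          statistic = an[["F value"]],
                          p.value = an[["Pr(>F)"]])
  } else {
    an <- stats::anova(fit)
    tab <- tibble::tibble(term = rownames(an),
                          sumsq = an[["Sum Sq"]], df = an[["Df"]],
                          statistic = an[["F value"]],
                          p.value = an[["Pr(>F)"]])
  }
  tab <- tab[tab$term != "Residuals", ]
  structure(list(fit = fit, terms_p = stats::setNames(tab$p.value, tab$term),
                 table = tab, type = type),
            class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat("<ancova_fit> ", deparse(stats::formula(x$fit)), " (", x$type,
      " tests)\n", sep = "")
  print(x$table)
  invisible(x)
}

#' @describeIn ancova_gfc Per-term tibble of the marginal tests.
#' @param x An `ancova_fit`.
#' @param ... Unused.
#' @export
tidy.ancova_fit <- function(x, ...) x$table

#' @describeIn ancova_gfc One-row model summary.
#' @export
glance.ancova_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma, df.residual = x$fit$df.residual,
                 nobs = length(stats::resid(x$fit)))
}

#' Early-versus-late paired t-test of per-minute pattern indices
#'
#' Compares mean per-minute indices in scan minutes `early` against
#' `late` across scans with a paired two-sided t-test (bursts grow more
#' likely as scans progress; this is the test that shows it).
#'
#' @param minute_tbl Tibble with columns `scan_id`, `minute`, `index`
#'   (e.g. stacked [pattern_index_by_minute()] outputs).
#' @param early,late Minute ranges (defaults 1-4 and 11-14).
#' @return Tibble: `mean_early`, `mean_late`, `statistic`, `p.value`, `n`.
#' @export
time_in_scan_trend <- function(minute_tbl, early = 1:4, late = 11:14) {
  if (max(minute_tbl$minute) < max(late)) {
    stop("scans shorter than ", max(late), " minutes")
  }
  per_scan <- minute_tbl |>
    dplyr::group_by(.data$scan_id) |>
    dplyr::summarise(
      early = mean(.data$index[.data$minute %in% early]),
      late = mean(.data$index[.data$minute %in% late]),
      .groups = "drop"
    )
  if (all(per_scan$early == per_scan$late)) {
    return(tibble::tibble(mean_early = mean(per_scan$early),
                          mean_late = mean(per_scan$late),
                          statistic = 0, p.value = 1, n = nrow(per_scan)))
  }
  ht <- stats::t.test(per_scan$late, per_scan$early, paired = TRUE)
  tibble::tibble(mean_early = mean(per_scan$early),
                 mean_late = mean(per_scan$late),
                 statistic = unname(ht$statistic), p.value = ht$p.value,
                 n = nrow(per_scan))
}
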