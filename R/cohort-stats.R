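# Cohort statistics: impairment classification, Wald proportion intervals,
# one-sample reference tests, sex-stratified morphometry-exposure models,
# correlations, and FDR control.

#' Classify executive impairment from age-adjusted z-scores
#'
#' A measure is impaired when its z-score is strictly below the threshold
#' (z < -1.3, the 10th percentile of the reference distribution); a subject is
#' executively impaired when any executive-function measure is impaired.
#'
#' @param scores Long neurocognitive table (`subject_id`, `measure`, `z`).
#' @param threshold Impairment cut-point (strict inequality).
#' @param executive Character vector of executive measure names (must all be
#'   present in `scores`).
#' @return Tibble: `subject_id`, one logical column per executive measure
#'   (`imp_<measure>`), and `any_executive_impaired`.
#' @export
#' @examples
#' s <- tibble::tibble(subject_id = "S1", measure = "verbal_fluency", z = -1.31)
#' classify_impairment(s, executive = "verbal_fluency")
classify_impairment <- function(scores, threshold = -1.3,
                                executive = executive_measures()) {
  unknown <- setdiff(executive, unique(scores$measure))
  if (length(unknown)) {
    abort(paste0("unknown executive measure(s): ",
                 paste(unknown, collapse = ", ")),
          class = "ctcnet_input_error")
  }
  wide <- tidyr::pivot_wider(
    dplyr::filter(scores, .data$measure %in% executive),
    id_cols = "subject_id", names_from = "measure", values_from = "z")
  flags <- dplyr::mutate(wide, dplyr::across(
    dplyr::all_of(executive), ~ .x < threshold, .names = "imp_{.col}"))
  flags <- flags[c("subject_id", paste0("imp_", executive))]
  flags$any_executive_impaired <-
    rowSums(as.matrix(flags[paste0("imp_", executive)])) > 0
  flags
}

#' Wald confidence interval for an impairment proportion
#'
#' `p-hat +/- z * sqrt(p-hat (1 - p-hat) / n)`, reported as percentages and
#' clipped to `[0, 100]`; this interval form reproduces the published
#' impairment tables. A Wilson interval is available behind `method`. At
#' `k = 0` or `k = n` the Wald interval collapses to a point and a warning is
#' issued.
#'
#' @param k Number of impaired subjects.
#' @param n Number assessed (>= 1).
#' @param level Confidence level (default 0.95).
#' @param method `"wald"` (default) or `"wilson"`.
#' @return One-row tibble: `k`, `n`, `proportion`, `ci_low`, `ci_high` (all
#'   proportions in percent, full precision) and a `label` formatted to two
#'   decimals.
#' @export
#' @examples
#' impairment_proportion_ci(17, 104)
impairment_proportion_ci <- function(k, n, level = 0.95,
                                     method = c("wald", "wilson")) {
  method <- match.arg(method)
  n <- check_count(n, "n")
  k <- check_count(k, "k", min = 0L)
  if (k > n) abort("`k` cannot exceed `n`", class = "ctcnet_input_error")
  z <- stats::qnorm(1 - (1 - level) / 2)
  ph <- k / n
  if (method == "wald") {
    half <- z * sqrt(ph * (1 - ph) / n)
    lo <- ph - half; hi <- ph + half
    if (k == 0L || k == n) {
      warn("Wald interval is degenerate at k = 0 or k = n",
           class = "ctcnet_degenerate_ci_warning")
    }
  } else {
    den <- 1 + z^2 / n
    ctr <- (ph + z^2 / (2 * n)) / den
    half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
    lo <- ctr - half; hi <- ctr + half
  }
  lo <- max(0, lo); hi <- min(1, hi)
  tibble::tibble(
    k = k, n = n, proportion = 100 * ph, ci_low = 100 * lo, ci_high = 100 * hi,
    label = sprintf("%.2f (%.2f-%.2f)", 100 * ph, 100 * lo, 100 * hi))
}

#' One-sample t-test against the reference population
#'
#' Compares one measure's age-adjusted z-scores with the expected population
#' value (mu = 0, sigma = 1 reference norms) by a classical two-sided
#' one-sample t-test.
#'
#' @param z Numeric vector of scores (n >= 2, nonzero variance).
#' @param mu Reference mean (default 0).
#' @return One-row tibble: `estimate`, `statistic`, `df`, `p.value`, `n`.
#' @export
one_sample_vs_reference <- function(z, mu = 0) {
  z <- z[!is.na(z)]
  if (length(z) < 2L) abort("need at least 2 scores", class = "ctcnet_input_error")
  if (var(z) == 0) abort("scores have zero variance", class = "ctcnet_input_error")
  tt <- t.test(z, mu = mu)
  tibble::tibble(estimate = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p.value = tt$p.value,
                 n = length(z))
}

#' Sex-stratified morphometry-exposure-cognition model
#'
#' Within one sex stratum, fits the least-squares model
#' `region ~ z + dex_auc + mtx_auc + it_count + age_dx + age_eval + icv`,
#' where `region` is a morphometric measurement (mm^3 or mm) and `z` the
#' age-adjusted score of one neurocognitive measure. Coefficients follow the
#' published unit conventions: the `z` coefficient is morphometry change per
#' 1-SD change in the neurocognitive outcome (mm^3 per SD for volumes), the
#' exposure coefficients are mm^3 per (g x hr/L) of AUC and mm^3 per
#' intrathecal count.
#'
#' @param subjects Subject table (one row per subject).
#' @param scores Long neurocognitive table.
#' @param outcome Neurocognitive measure name.
#' @param region Morphometric column of `subjects` used as the response.
#' @param stratum `"male"` or `"female"`.
#' @param covariates Adjustment columns (default age at diagnosis, age at
#'   assessment, intracranial volume).
#' @param one_sided Halve p-values for the published one-sided GLM convention
#'   (sign taken from the coefficient).
#' @return A `ctc_glm` object; `tidy()` gives `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
glm_brain_exposure <- function(subjects, scores, outcome, region,
                               stratum = c("male", "female"),
                               covariates = c("age_dx", "age_eval", "icv"),
                               one_sided = FALSE) {
  stratum <- match.arg(stratum)
  if (!region %in% names(subjects)) {
    abort(sprintf("region column `%s` not in subject table", region),
          class = "ctcnet_input_error")
  }
  sc <- scores[scores$measure == outcome, c("subject_id", "z")]
  if (!nrow(sc)) {
    abort(sprintf("no scores for measure `%s`", outcome),
          class = "ctcnet_input_error")
  }
  d <- dplyr::inner_join(subjects, sc, by = "subject_id")
  d <- d[d$sex == stratum, ]
  predictors <- c("z", "dex_auc", "mtx_auc", "it_count", covariates)
  x <- cbind(`(Intercept)` = 1, as.matrix(d[predictors]))
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    drop <- colnames(x)[qrx$pivot[seq(qrx$rank + 1L, ncol(x))]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(drop, collapse = ", ")),
          class = "ctcnet_input_error")
  }
  fit <- lm(stats::reformulate(predictors, response = region), data = d)
  sm <- summary(fit)$coefficients
  tab <- tibble::tibble(
    term = rownames(sm), estimate = sm[, 1L], std.error = sm[, 2L],
    statistic = sm[, 3L],
    p.value = if (one_sided) sm[, 4L] / 2 else sm[, 4L])
  structure(list(fit = fit, table = tab, outcome = outcome, region = region,
                 stratum = stratum, n = nrow(d), one_sided = one_sided),
            class = "ctc_glm")
}

#' @export
print.ctc_glm <- function(x, ...) {
  cat(sprintf("<ctc_glm> %s ~ %s + exposures, %s stratum (n = %d)\n",
              x$region, x$outcome, x$stratum, x$n))
  print(x$table, n = nrow(x$table))
  invisible(x)
}

#' Tidy a stratified morphometry-exposure model
#'
#' @param x A `ctc_glm`.
#' @param ... Unused.
#' @return Coefficient tibble (`term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`).
#' @method tidy ctc_glm
#' @export
tidy.ctc_glm <- function(x, ...) x$table

#' @rdname tidy.ctc_glm
#' @method glance ctc_glm
#' @export
glance.ctc_glm <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma, n = x$n,
                 outcome = x$outcome, region = x$region, stratum = x$stratum)
}

#' Pearson correlation between a network metric and a neurocognitive score
#'
#' @param x,y Numeric vectors (pairwise complete, n >= 3, nonzero variance).
#' @return One-row tibble: `estimate` (r), `statistic`, `df`, `p.value`, `n`.
#' @export
correlate_metric <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("need at least 3 pairs", class = "ctcnet_input_error")
  if (var(x) == 0 || var(y) == 0) {
    abort("zero-variance input", class = "ctcnet_input_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p.value = ct$p.value,
                 n = length(x))
}

#' False discovery rate correction
#'
#' Step-up FDR adjustment; the default Benjamini-Yekutieli variant includes
#' the harmonic-sum factor `c(m) = sum(1/i)` and is valid under arbitrary
#' dependence. Adjusted values are monotone and clipped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BY"` (default) or `"BH"`.
#' @return Numeric vector of adjusted p-values, same order as `p`.
#' @export
#' @examples
#' fdr_correct(c(0.01, 0.02, 0.5))
fdr_correct <- function(p, method = c("BY", "BH")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]", class = "ctcnet_input_error")
  }
  p.adjust(p, method = method)
}
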