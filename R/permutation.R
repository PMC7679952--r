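# Permutation-distribution inference for group differences in network metrics.

#' Permutation test for a group difference in a subject-level metric
#'
#' Observed statistic is `mean(group 1) - mean(group 0)`. Group labels are
#' shuffled across subjects (the exchangeable unit) without replacement
#' `n_perm` times. Following the study's printed rule, the one-sided p-value
#' is the proportion of permutation mean differences greater than or equal to
#' the actual mean difference; the two-sided variant compares absolute values.
#' The reported interval is the empirical 2.5/97.5 percentile band of the null
#' distribution (observed differences outside it are deemed significant).
#'
#' @param data Data frame with one row per subject.
#' @param value Column of metric values (tidy-eval).
#' @param group Column with the binary group label (tidy-eval); a factor's
#'   second level, logical `TRUE`, or the larger of two values is "group 1".
#' @param n_perm Number of permutations (default 2000).
#' @param sided `"one"` (default, the printed rule) or `"two"`.
#' @param seed Optional integer seed.
#' @param plus_one Apply the `(b + 1)/(n_perm + 1)` small-sample correction,
#'   which keeps p away from exactly zero.
#' @param level Coverage of the null-distribution interval.
#' @param exhaustive Enumerate all `choose(n, n1)` label assignments instead
#'   of sampling (only allowed when that count is at most 20000); `n_perm` is
#'   then ignored and the p-value is exact over the permutation group.
#' @return A `ctc_permtest` object; see [tidy.ctc_permtest()] /
#'   [glance.ctc_permtest()].
#' @export
#' @examples
#' d <- data.frame(eff = c(rnorm(10), rnorm(10, 1)),
#'                 grp = rep(c(FALSE, TRUE), each = 10))
#' permutation_group_test(d, eff, grp, n_perm = 200, seed = 1)
permutation_group_test <- function(data, value, group, n_perm = 2000,
                                   sided = c("one", "two"), seed = NULL,
                                   plus_one = FALSE, level = 0.95,
                                   exhaustive = FALSE) {
  sided <- match.arg(sided)
  n_perm <- check_count(n_perm, "n_perm")
  v <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  ok <- complete.cases(v, g)
  v <- v[ok]; g <- g[ok]
  lv <- if (is.factor(g)) levels(g) else sort(unique(g))
  if (length(lv) != 2L) {
    abort("`group` must take exactly two values", class = "ctcnet_input_error")
  }
  g1 <- g == lv[2L]
  if (!any(g1) || all(g1)) {
    abort("both groups must be non-empty", class = "ctcnet_input_error")
  }
  if (var(v) == 0) {
    warn("metric is constant across subjects; observed difference is 0",
         class = "ctcnet_constant_warning")
  }
  observed <- mean(v[g1]) - mean(v[!g1])
  n1 <- sum(g1)
  if (exhaustive) {
    if (choose(length(v), n1) > 20000) {
      abort("too many label assignments for exhaustive enumeration",
            class = "ctcnet_input_error")
    }
    null_diffs <- combn(length(v), n1, function(idx) {
      mean(v[idx]) - mean(v[-idx])
    })
    n_perm <- length(null_diffs)
  } else {
    null_diffs <- withr_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(length(v), n1)
        mean(v[idx]) - mean(v[-idx])
      }, numeric(1))
    })
  }
  hits <- if (sided == "one") sum(null_diffs >= observed) else
    sum(abs(null_diffs) >= abs(observed))
  p <- if (plus_one) (hits + 1) / (n_perm + 1) else hits / n_perm
  a <- (1 - level) / 2
  ci <- unname(quantile(null_diffs, c(a, 1 - a)))
  structure(list(
    observed_diff = observed, null_diffs = null_diffs, p_value = p,
    ci = ci, n_perm = n_perm, sided = sided, plus_one = plus_one,
    level = level, seed = seed, groups = lv,
    n = c(sum(!g1), n1)
  ), class = "ctc_permtest")
}

#' @export
print.ctc_permtest <- function(x, ...) {
  cat(sprintf(
    "<ctc_permtest> %s - %s: observed diff %.4g, %s-sided p = %.4g (%d permutations)\n",
    x$groups[2L], x$groups[1L], x$observed_diff, x$sided, x$p_value, x$n_perm))
  cat(sprintf("  null %.0f%% interval: [%.4g, %.4g]\n", 100 * x$level,
              x$ci[1L], x$ci[2L]))
  invisible(x)
}

#' Tidy a permutation test
#'
#' @param x A `ctc_permtest`.
#' @param ... Unused.
#' @return One-row tibble: estimate, p-value, null-interval bounds,
#'   permutation count.
#' @method tidy ctc_permtest
#' @export
tidy.ctc_permtest <- function(x, ...) {
  tibble::tibble(
    estimate = x$observed_diff, p.value = x$p_value,
    null.low = x$ci[1L], null.high = x$ci[2L],
    n.perm = x$n_perm, sided = x$sided
  )
}

#' @rdname tidy.ctc_permtest
#' @method glance ctc_permtest
#' @export
glance.ctc_permtest <- function(x, ...) tidy(x, ...)

#' @method autoplot ctc_permtest
#' @export
autoplot.ctc_permtest <- function(object, ...) {
  df <- data.frame(null = object$null_diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_diff,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$ci, linetype = "dashed") +
    ggplot2::labs(
      x = "permutation mean difference", y = "count",
      title = sprintf("Observed difference %.4g (p = %.3g, %s-sided)",
                      object$observed_diff, object$p_value, object$sided))
}

#' Compare global efficiency between impaired and unimpaired survivors
#'
#' Wraps [permutation_group_test()] on the `global_efficiency` column of a
#' per-subject metrics table, with the sign convention impaired minus
#' unimpaired.
#'
#' @param metrics Per-subject metrics (needs `subject_id`,
#'   `global_efficiency`).
#' @param subjects Subject table with `subject_id` and a logical `impaired`
#'   column.
#' @param ... Passed on to [permutation_group_test()].
#' @return A `ctc_permtest` (positive difference = higher efficiency in the
#'   impaired group).
#' @export
efficiency_group_comparison <- function(metrics, subjects, ...) {
  d <- dplyr::inner_join(metrics[c("subject_id", "global_efficiency")],
                         subjects[c("subject_id", "impaired")],
                         by = "subject_id")
  d$impaired <- factor(ifelse(d$impaired, "impaired", "unimpaired"),
                       levels = c("unimpaired", "impaired"))
  permutation_group_test(d, .data$global_efficiency, .data$impaired, ...)
}
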