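#' Shapiro-Wilk normality test
#'
#' Wraps the Royston algorithm behind [stats::shapiro.test()]; used as the
#' gate deciding between the parametric t-test and the rank-based
#' Mann-Whitney U test for each metric.
#'
#' @param x Numeric sample, 3 to 5000 non-constant values.
#' @return `list(statistic, p_value)`.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3 || length(x) > 5000) stop("sample size must be in [3, 5000]")
  if (diff(range(x)) == 0) stop("degenerate input: constant sample")
  r <- stats::shapiro.test(x)
  list(statistic = unname(r$statistic), p_value = r$p.value)
}

#' Two-sample t-test for metric means
#'
#' Two-tailed t-test comparing the per-fold means of one metric between the
#' two structures. Defaults to Welch's unequal-variance form, which is the
#' variant whose p-values reproduce the published comparison tables;
#' `var_equal = TRUE` gives the classical pooled-variance test.
#'
#' @param a,b Numeric samples (per-fold metric values), each of size >= 2.
#' @param var_equal Pool the variances.
#' @return `list(statistic, p_value, df, method)`.
#' @export
students_t <- function(a, b, var_equal = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("both samples need >= 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(statistic = 0, p_value = 1, df = length(a) + length(b) - 2,
                  method = if (var_equal) "t_pooled" else "t_welch"))
    }
    stop("degenerate variance: both samples constant")
  }
  r <- stats::t.test(a, b, var.equal = var_equal, alternative = "two.sided")
  list(statistic = unname(r$statistic), p_value = r$p.value,
       df = unname(r$parameter),
       method = if (var_equal) "t_pooled" else "t_welch")
}

#' Mann-Whitney U test
#'
#' Rank-based two-sample location test, computed with the tie-corrected
#' normal approximation and continuity correction (at n = 10 per group with
#' heavily tied metric values, exact enumeration is not defined across
#' conventions).
#'
#' @param a,b Numeric samples.
#' @param correct Apply the continuity correction.
#' @return `list(statistic, p_value)` where `statistic` is U for sample `a`.
#' @export
mann_whitney_u <- function(a, b, correct = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  r <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = correct,
                       alternative = "two.sided")
  )
  list(statistic = unname(r$statistic), p_value = r$p.value)
}

#' Normality-gated comparison of one metric
#'
#' The study's test-selection protocol: Shapiro-Wilk on both samples; if
#' both normality p-values are at least `alpha` the means are compared with
#' the two-tailed t-test, otherwise with the Mann-Whitney U test. The null
#' hypothesis (no difference between the structures) is rejected when the
#' selected test's p-value falls below `alpha`.
#'
#' @param a,b Numeric samples of the same metric for the two structures.
#' @param alpha Significance level (default 0.05).
#' @param metric Optional metric name carried into the result.
#' @param var_equal Passed to [students_t()].
#' @return An object of class `"comparison_result"`: means, both normality
#'   p-values, chosen test (`"t"` or `"U"`), statistic, p-value, decision.
#' @export
select_and_compare <- function(a, b, alpha = 0.05, metric = NA_character_,
                               var_equal = FALSE) {
  # a constant sample has no defined Shapiro-Wilk statistic and is
  # certainly not a draw from a continuous normal: treat normality as
  # rejected and fall through to the rank test
  sw <- function(x) {
    if (diff(range(x)) == 0) list(statistic = NA_real_, p_value = NA_real_)
    else shapiro_wilk(x)
  }
  sa <- sw(a); sb <- sw(b)
  use_t <- !is.na(sa$p_value) && !is.na(sb$p_value) &&
    sa$p_value >= alpha && sb$p_value >= alpha
  r <- if (use_t) students_t(a, b, var_equal = var_equal) else mann_whitney_u(a, b)
  structure(list(
    metric = metric,
    mean_a = mean(a), mean_b = mean(b),
    shapiro_p_a = sa$p_value, shapiro_p_b = sb$p_value,
    test = if (use_t) "t" else "U",
    statistic = r$statistic, p_value = r$p_value,
    decision = if (r$p_value < alpha) "rejected" else "retained",
    alpha = alpha
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: mean %.5f vs %.5f | normality p %.5f / %.5f -> %s-test p = %.3g (H0 %s)\n",
              x$metric %||% "metric", x$mean_a, x$mean_b,
              x$shapiro_p_a, x$shapiro_p_b, x$test, x$p_value, x$decision))
  invisible(x)
}

#' Euclidean distance to the ideal classifier in ROC space
#'
#' A classifier operating at sensitivity (true-positive rate) `se` and
#' specificity `sp` sits at `(1 - sp, se)` in ROC space; its quality is
#' summarised by the Euclidean distance to the ideal corner `(0, 1)`:
#' `sqrt((1 - sp)^2 + (1 - se)^2)`, between 0 (perfect) and `sqrt(2)`.
#'
#' @param sensitivity,specificity Values in `[0, 1]` (vectorised).
#' @return Distance(s) in `[0, sqrt(2)]`.
#' @examples
#' roc_distance(0.914098, 0.75325)  # 0.26127
#' @export
roc_distance <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1)) {
    stop("sensitivity and specificity must lie in [0, 1]")
  }
  sqrt((1 - specificity)^2 + (1 - sensitivity)^2)
}

#' Relative superiority of the better ROC distance
#'
#' Percent reduction of the worse structure's ROC distance achieved by the
#' better one: `100 * (d_worse - d_better) / d_worse`.
#'
#' @param d_better,d_worse ROC distances; `d_worse` must be positive.
#' @return Percent superiority (negative if `d_better` exceeds `d_worse`).
#' @examples
#' relative_superiority(0.26127, 0.36022)  # 27.47
#' @export
relative_superiority <- function(d_better, d_worse) {
  if (any(d_worse <= 0)) stop("d_worse must be > 0")
  100 * (d_worse - d_better) / d_worse
}

#' Full statistical comparison report for one dataset
#'
#' Runs the normality-gated comparison for each of the five metrics and
#' summarises both structures in ROC space: each structure's operating
#' point is its mean sensitivity and mean specificity over the folds, from
#' which the distance to the ideal classifier and the relative superiority
#' of the closer structure are derived.
#'
#' @param complex_tbl,real_tbl [fold_metric_table()]s for the two
#'   structures (matching datasets).
#' @param alpha Significance level for all tests.
#' @param var_equal Passed to [students_t()].
#' @return An object of class `"comparison_report"`.
#' @export
build_report <- function(complex_tbl, real_tbl, alpha = 0.05,
                         var_equal = FALSE) {
  da <- attr(complex_tbl, "dataset_id"); db <- attr(real_tbl, "dataset_id")
  if (!is.null(da) && !is.null(db) && !identical(da, db)) {
    stop("fold tables come from different datasets: ", da, " vs ", db)
  }
  metrics <- c("f1_score", "precision", "recall_sensitivity", "accuracy",
               "specificity")
  results <- lapply(metrics, function(m) {
    select_and_compare(complex_tbl[[m]], real_tbl[[m]], alpha = alpha,
                       metric = m, var_equal = var_equal)
  })
  names(results) <- metrics
  point <- function(tbl) {
    se <- mean(tbl$recall_sensitivity); sp <- mean(tbl$specificity)
    list(sensitivity = se, specificity = sp, fpr = 1 - sp,
         distance = roc_distance(se, sp))
  }
  pc <- point(complex_tbl); pr <- point(real_tbl)
  better <- if (pc$distance <= pr$distance) "complex" else "real"
  sup <- if (better == "complex") {
    relative_superiority(pc$distance, pr$distance)
  } else {
    relative_superiority(pr$distance, pc$distance)
  }
  structure(list(
    dataset_id = da %||% db %||% NA_character_,
    alpha = alpha,
    results = results,
    roc = list(complex = pc, real = pr),
    superior_structure = better,
    relative_superiority = sup
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Comparison report - dataset ", x$dataset_id, " (alpha = ", x$alpha,
      ")\n", sep = "")
  for (r in x$results) print(r)
  cat(sprintf("ROC distance to ideal: complex %.5f | real %.5f\n",
              x$roc$complex$distance, x$roc$real$distance))
  cat(sprintf("%s-valued structure superior by %.2f%% in ROC distance\n",
              x$superior_structure, x$relative_superiority))
  invisible(x)
}

#' Write a comparison report to JSON and text
#'
#' @param report A [build_report()] result.
#' @param json_path,txt_path Output file paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, json_path = NULL, txt_path = NULL) {
  if (!is.null(json_path)) {
    plain <- unclass(report)
    plain$results <- lapply(plain$results, unclass)
    jsonlite::write_json(plain, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    sink(con); print(report); sink()
    close(con)
  }
  invisible(report)
}
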