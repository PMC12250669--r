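# Replicate aggregation and significance machinery: paired t-tests and
# Tukey HSD multiple comparisons at alpha = 0.05, mirroring the annotation
# conventions of fluorescence figure panels ("*" vs "ns").

#' Aggregate replicate measurements
#'
#' Mean, sample standard deviation (n - 1 denominator) and count of a
#' replicate list -- the "mean +/- SD (n = 3)" summary of figure captions.
#'
#' @param values Numeric replicate measurements.
#' @param warn Warn when `n < 2` leaves the SD undefined (default TRUE).
#' @return List with `mean`, `sd` (NA when `n < 2`) and `n`.
#' @export
aggregate_replicates <- function(values, warn = TRUE) {
  check_numeric(values, "values")
  n <- length(values)
  s <- if (n >= 2) stats::sd(values) else NA_real_
  if (n < 2 && warn) {
    mf_warn("fewer than 2 replicates: SD undefined", class = "membrafluor_degenerate")
  }
  list(mean = mean(values), sd = s, n = n)
}

#' Two-sided paired t-test
#'
#' Closed-form paired t on aligned replicate measurements:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom,
#' where `d = a - b`. Zero-variance differences (identical series, or a
#' constant shift) leave the statistic undefined and raise a
#' degenerate-input error rather than returning an infinite t.
#'
#' @param a,b Paired replicate measurements, equal length >= 2, aligned
#'   replicate order.
#' @param alpha Significance level for the flag (default 0.05).
#' @return List with `t`, `df`, `p`, `significant`, `mean_diff`, `n`.
#' @export
paired_t_test <- function(a, b, alpha = 0.05) {
  check_numeric(a, "a")
  check_numeric(b, "b")
  if (length(a) != length(b)) mf_stop("'a' and 'b' must have equal length")
  n <- length(a)
  if (n < 2) mf_stop("at least 2 pairs are required")
  d <- a - b
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    mf_stop(if (all(d == 0)) "identical series: differences all zero"
            else "constant difference between series: zero-variance differences",
            class = "membrafluor_degenerate")
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  list(t = t_stat, df = n - 1, p = p, significant = p < alpha,
       mean_diff = mean(d), n = n)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range based all-pairs comparisons at level `alpha`
#' (Tukey-Kramer adjustment for unbalanced groups), encoding each pair as
#' `"*"` (significant) or `"ns"`, the annotation scheme of the figures this
#' kind of assay is reported with. Backed by `stats::aov` +
#' `stats::TukeyHSD`.
#'
#' @param values Numeric measurements (or a data frame with columns
#'   `value` and `group`).
#' @param groups Group labels, same length as `values`; at least two
#'   groups, each with n >= 2.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `tukey_result` data frame: `group1`, `group2`, `diff`,
#'   `lwr`, `upr`, `p_adj`, `code`.
#' @export
tukey_hsd <- function(values, groups = NULL, alpha = 0.05) {
  if (is.data.frame(values)) {
    if (!all(c("value", "group") %in% names(values))) {
      mf_stop("data frame input must have columns 'value' and 'group'")
    }
    groups <- values$group
    values <- values$value
  }
  check_numeric(values, "values")
  if (length(groups) != length(values)) {
    mf_stop("'groups' must match 'values' in length")
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) mf_stop("at least two groups are required")
  counts <- table(groups)
  if (any(counts < 2)) {
    mf_stop(sprintf("group(s) with a single replicate: %s",
                    paste(names(counts)[counts < 2], collapse = ", ")))
  }
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(
    group1 = vapply(pair, `[`, character(1), 1),
    group2 = vapply(pair, `[`, character(1), 2),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    code = ifelse(tk[, "p adj"] < alpha, "*", "ns"),
    row.names = NULL)
  structure(out, alpha = alpha, class = c("tukey_result", "data.frame"))
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("Tukey HSD pairwise comparisons (alpha = %g)\n", attr(x, "alpha")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
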