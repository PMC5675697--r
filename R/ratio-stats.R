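# Per-sample isoform ratio and grade-wise nonparametric testing.
#
# The delta/alpha ratio is computed per sample from normalized isoform
# expression. Samples with alpha = 0 are excluded and recorded (never
# coerced to Inf). Grade comparisons use the two-group Mann-Whitney U test
# with Benjamini-Hochberg FDR adjustment within each measure's family of
# pairwise contrasts.

#' Compute the isoform ratio for one sample
#'
#' @param delta,alpha non-negative normalized expression of the two isoforms.
#' @return `delta/alpha`, or `NA` when `alpha == 0` (callers exclude such
#'   samples; see [compute_isoform_table()]).
#' @export
compute_ratio <- function(delta, alpha) {
  stopifnot(length(delta) == length(alpha))
  if (any(delta < 0, na.rm = TRUE) || any(alpha < 0, na.rm = TRUE))
    stop("isoform expression must be non-negative", call. = FALSE)
  ifelse(alpha > 0, delta / alpha, NA_real_)
}

#' Build a per-sample isoform table with the delta/alpha ratio
#'
#' Samples with `alpha == 0` are dropped from the table and listed in the
#' `excluded` attribute with a reason, so downstream ratio statistics never
#' see infinite values.
#'
#' @param delta,alpha per-sample normalized isoform expression.
#' @param sample_ids sample identifiers.
#' @return data frame (`sample_id`, `alpha`, `delta`, `ratio`) with an
#'   `excluded` attribute (data frame `sample_id`, `reason`).
#' @export
compute_isoform_table <- function(delta, alpha, sample_ids) {
  stopifnot(length(delta) == length(alpha), length(alpha) == length(sample_ids))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_id: ", sample_ids[duplicated(sample_ids)][1],
         call. = FALSE)
  ratio <- compute_ratio(delta, alpha)
  drop <- alpha == 0
  excluded <- data.frame(sample_id = as.character(sample_ids[drop]),
                         reason = rep("alpha = 0: ratio undefined", sum(drop)),
                         stringsAsFactors = FALSE)
  out <- data.frame(sample_id = as.character(sample_ids[!drop]),
                    alpha = alpha[!drop], delta = delta[!drop],
                    ratio = ratio[!drop], stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Shapiro-Wilk normality gate
#'
#' Labels a sample as `normal` or `non-normal` at the 0.05 level. Constant
#' vectors are labelled non-normal with a warning (the test statistic is
#' undefined there).
#'
#' @param values numeric vector, `length >= 3`.
#' @param alpha significance level of the gate.
#' @return `"normal"` or `"non-normal"`.
#' @export
shapiro_wilk_gate <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  if (stats::sd(values) == 0) {
    warning("constant vector: normality undefined, labelled non-normal")
    return("non-normal")
  }
  p <- stats::shapiro.test(values)$p.value
  if (p < alpha) "non-normal" else "normal"
}

#' Two-group Mann-Whitney U test
#'
#' Exact p by enumeration when the combined sample size is at most 20 and
#' there are no ties; otherwise the tie-corrected normal approximation with
#' continuity correction. When every value is identical across both groups
#' the p-value is 1.
#'
#' @param group_a,group_b numeric vectors, both non-empty.
#' @param contrast label carried into the result.
#' @return data frame (`contrast`, `U`, `p_value`, `percent_change`) where
#'   `percent_change` is `100 * mean(group_b) / mean(group_a)`.
#' @export
mann_whitney <- function(group_a, group_b, contrast = "B_vs_A") {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1) {
    u <- length(group_a) * length(group_b) / 2
    return(data.frame(contrast = contrast, U = u, p_value = 1,
                      percent_change = 100, stringsAsFactors = FALSE))
  }
  exact <- (length(pooled) <= 20) && !any(duplicated(pooled))
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  data.frame(contrast = contrast, U = unname(wt$statistic),
             p_value = wt$p.value,
             percent_change = 100 * mean(group_b) / mean(group_a),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values; output is invariant under permutation of the
#' input (each value keeps its position). NaN inputs are rejected.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length/order as the input.
#' @export
adjust_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)))
    stop("NaN/NA p-value passed to adjust_fdr", call. = FALSE)
  if (any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Grade-wise tests of isoform levels and the ratio
#'
#' For each measure (alpha, delta, ratio) runs the three pairwise
#' Mann-Whitney contrasts II-vs-III, II-vs-IV, III-vs-IV and BH-adjusts the
#' three p-values within that measure's family (the smallest family
#' consistent with per-contrast FDR reporting). Percent change is mean-based
#' (see `percent_change` in [mann_whitney()]); group medians are reported
#' alongside since boxplot-style summaries are median-based.
#'
#' @param isoforms isoform table from [compute_isoform_table()].
#' @param clinical clinical table (see [read_clinical()]).
#' @return data frame with one row per (measure, contrast): `measure`,
#'   `contrast`, `U`, `p_value`, `fdr`, `percent_change`, `median_a`,
#'   `median_b`.
#' @export
grade_isoform_tests <- function(isoforms, clinical) {
  grade <- clinical$grade[match(isoforms$sample_id, clinical$sample_id)]
  if (any(is.na(grade)))
    stop("isoform sample missing from clinical table: ",
         isoforms$sample_id[is.na(grade)][1], call. = FALSE)
  pairs <- list(c("II", "III"), c("II", "IV"), c("III", "IV"))
  out <- list()
  for (measure in c("alpha", "delta", "ratio")) {
    vals <- isoforms[[measure]]
    rows <- lapply(pairs, function(p) {
      a <- vals[grade == p[1]]; b <- vals[grade == p[2]]
      r <- mann_whitney(a, b, contrast = paste0(p[2], "_vs_", p[1]))
      r$median_a <- stats::median(a); r$median_b <- stats::median(b)
      r
    })
    res <- do.call(rbind, rows)
    res$fdr <- adjust_fdr(res$p_value)
    res <- cbind(measure = measure, res, stringsAsFactors = FALSE)
    out[[measure]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("measure", "contrast", "U", "p_value", "fdr", "percent_change",
          "median_a", "median_b")]
}

#' Paired comparison of normalized proportions
#'
#' Two-sided paired t-test on per-experiment normalized fractions (as in a
#' BrdU-incorporation comparison), preceded by a Shapiro-Wilk gate on the
#' paired differences (gate requires at least 3 pairs; its label is reported,
#' the t-test is run either way as the primary analysis). Identical vectors
#' give p = 1 with a warning; non-zero constant differences are a degenerate
#' zero-variance case reported as p = 0 with a warning.
#'
#' @param treated_fractions,control_fractions equal-length numeric vectors,
#'   paired by experiment index, `length >= 2`.
#' @return list with `p_value`, `mean_difference`, `normality` label.
#' @export
compare_normalized_proportions <- function(treated_fractions, control_fractions) {
  if (length(treated_fractions) != length(control_fractions))
    stop("paired vectors must have equal length", call. = FALSE)
  n <- length(treated_fractions)
  if (n < 2) stop("need at least 2 paired experiments", call. = FALSE)
  d <- treated_fractions - control_fractions
  normality <- if (n >= 3 && stats::sd(d) > 0)
    shapiro_wilk_gate(d) else NA_character_
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      warning("identical vectors: no difference detectable, p = 1")
      return(list(p_value = 1, mean_difference = 0, normality = normality))
    }
    warning("paired differences have zero variance: degenerate t statistic, p = 0")
    return(list(p_value = 0, mean_difference = mean(d), normality = normality))
  }
  tt <- stats::t.test(treated_fractions, control_fractions, paired = TRUE)
  list(p_value = tt$p.value, mean_difference = mean(d), normality = normality)
}
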