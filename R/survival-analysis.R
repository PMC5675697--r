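# Median-split Kaplan-Meier estimation and log-rank screening.
#
# Patients are dichotomized at the median expression of a gene within the
# analysed grade (values equal to the median go to the low stratum), the
# product-limit survival curves of the two strata are compared with the
# two-group log-rank test, and p-values are BH-adjusted over all genes
# screened for one (grade, endpoint) pair.

#' Kaplan-Meier product-limit estimate
#'
#' @param time follow-up times in days (non-negative).
#' @param event 1 = event, 0 = censored.
#' @return data frame (`time`, `n_risk`, `n_event`, `surv`) at the distinct
#'   event/censoring times, with S(0) = 1 prepended; `surv` is
#'   non-increasing and drops only at event times.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0) stop("need at least 1 record", call. = FALSE)
  if (any(time < 0)) stop("negative survival time", call. = FALSE)
  if (!all(event %in% c(0, 1))) stop("event must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  data.frame(time = c(0, fit$time),
             n_risk = c(length(time), fit$n.risk),
             n_event = c(0, fit$n.event),
             surv = c(1, fit$surv))
}

#' Two-group log-rank test
#'
#' Observed-versus-expected events over the pooled risk sets; p-value from
#' the chi-squared distribution with 1 df. With no events in either
#' stratum the curves are indistinguishable and p = 1 with a warning.
#'
#' @param time follow-up times in days.
#' @param event 1 = event, 0 = censored.
#' @param stratum two-level grouping (e.g. `"low"`/`"high"`).
#' @return list with `chi2` and `p_value`.
#' @export
logrank_test <- function(time, event, stratum) {
  stratum <- as.factor(stratum)
  if (nlevels(droplevels(stratum)) != 2)
    stop("need exactly 2 non-empty strata", call. = FALSE)
  if (sum(event) == 0) {
    warning("no events in either stratum: log-rank undefined, p = 1")
    return(list(chi2 = 0, p_value = 1))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ stratum, rho = 0)
  list(chi2 = unname(sd_$chisq),
       p_value = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Median split of expression values
#'
#' Low stratum: value at or below the median; high stratum: above. The
#' tie rule (exact-median values go low) is fixed. A constant vector has a
#' single stratum and cannot be split.
#'
#' @param values expression values within the analysed grade (n >= 4).
#' @return character vector of `"low"`/`"high"` labels, or `NULL` when the
#'   gene is constant (callers skip such genes).
#' @export
median_split <- function(values) {
  if (length(values) < 4) stop("need at least 4 values", call. = FALSE)
  med <- stats::median(values)
  lab <- ifelse(values <= med, "low", "high")
  if (length(unique(lab)) < 2) return(NULL)
  lab
}

#' Median-split survival screen over genes
#'
#' For each gene: within-grade median split of its expression, Kaplan-Meier
#' comparison of the two strata by log-rank, then BH FDR over the screened
#' gene family for this (grade, endpoint) pair, flagged at `fdr_threshold`
#' (significant) and `trend_threshold` (trend).
#'
#' @param mat linear-scale [expression_matrix()].
#' @param clinical clinical table with `os_*`/`pfs_*` columns.
#' @param genes genes to screen.
#' @param grade tumour grade to analyse (`"II"`, `"III"`, `"IV"`).
#' @param endpoint `"OS"` (overall) or `"PFS"` (progression-free survival).
#' @param fdr_threshold significance level on the FDR scale (default 0.05).
#' @param trend_threshold trend level (default 0.1).
#' @return data frame (`gene_id`, `chi2`, `p_value`, `fdr`, `significant`,
#'   `trend`); genes skipped (constant expression, or no split) are listed
#'   in the `skipped` attribute.
#' @export
screen_genes <- function(mat, clinical, genes, grade,
                         endpoint = c("OS", "PFS"),
                         fdr_threshold = 0.05, trend_threshold = 0.1) {
  endpoint <- match.arg(endpoint)
  if (!grade %in% GRADE_LEVELS)
    stop("unknown grade: ", grade, call. = FALSE)
  cols <- if (endpoint == "OS") c("os_days", "os_event")
          else c("pfs_days", "pfs_event")
  cl <- clinical[clinical$grade == grade &
                   !is.na(clinical[[cols[1]]]) &
                   !is.na(clinical[[cols[2]]]), , drop = FALSE]
  ids <- intersect(cl$sample_id, colnames(mat))
  if (length(ids) < 4)
    stop("no usable ", endpoint, " data for grade ", grade, call. = FALSE)
  cl <- cl[match(ids, cl$sample_id), ]
  time <- cl[[cols[1]]]; event <- cl[[cols[2]]]
  missing <- setdiff(genes, rownames(mat))
  if (length(missing) > 0)
    stop("gene absent from matrix: ", missing[1], call. = FALSE)
  res <- list(); skipped <- character(0)
  for (g in genes) {
    lab <- median_split(mat[g, ids])
    if (is.null(lab)) { skipped <- c(skipped, g); next }
    lr <- suppressWarnings(logrank_test(time, event, lab))
    res[[g]] <- data.frame(gene_id = g, chi2 = lr$chi2,
                           p_value = lr$p_value, stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    stop("no screenable genes for grade ", grade, call. = FALSE)
  out <- do.call(rbind, res)
  out$fdr <- adjust_fdr(out$p_value)
  out$significant <- out$fdr < fdr_threshold
  out$trend <- out$fdr < trend_threshold
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "n_patients") <- length(ids)
  out
}
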