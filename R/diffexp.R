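# Empirical-Bayes moderated differential expression.
#
# Per gene, a one-way fit of condition means on log2 expression gives a
# residual variance s2_g on d_g degrees of freedom. Variances are shrunk
# towards a prior s2_prior with prior degrees of freedom d0 via the
# posterior mean
#     s2_post = (d0 * s2_prior + d_g * s2_g) / (d0 + d_g)
# and the moderated t for a contrast (A, B) is
#     t = (mean_B - mean_A) / (sqrt(s2_post) * sqrt(1/n_A + 1/n_B))
# on d0 + d_g degrees of freedom. (d0, s2_prior) are estimated by matching
# the first two moments of log s2_g to the log of a scaled F distribution,
# the standard moment estimator: with
#     e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)
# one has E[e] = log(s2_prior) - digamma(d0/2) + log(d0/2) and
# Var[e] = trigamma(d_g/2) + trigamma(d0/2).

#' Inverse of the trigamma function
#'
#' Newton iteration solving `trigamma(y) = x` for y > 0; used by the
#' moment estimator of the prior degrees of freedom.
#'
#' @param x positive value.
#' @return y with `trigamma(y) = x` (to ~1e-10 relative accuracy).
#' @export
trigamma_inverse <- function(x) {
  if (x <= 0) stop("trigamma_inverse needs x > 0", call. = FALSE)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-12) break
  }
  y
}

#' Moment estimator of the variance prior
#'
#' Estimates `(s2_prior, d0)` from per-gene residual variances assuming
#' `s2_g ~ s2_prior * F(d_g, d0)`. Returns `d0 = Inf` when the observed
#' spread of `log s2_g` does not exceed its sampling floor.
#'
#' @param s2 per-gene residual variances (zero/NA entries are excluded).
#' @param df residual degrees of freedom (scalar or per gene).
#' @return list with `s2_prior` and `d0`.
#' @export
estimate_moderation <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2)
    stop("need at least 2 positive variances to estimate the prior", call. = FALSE)
  s2 <- s2[ok]; df <- df[ok]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (!is.finite(evar) || evar <= 0) {
    return(list(s2_prior = exp(emean), d0 = Inf))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s2_prior <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(s2_prior = s2_prior, d0 = d0)
}

#' Moderated differential-expression fit for one contrast
#'
#' Ordinary least-squares condition means per gene, empirical-Bayes
#' variance moderation, moderated t, BH FDR and the two significance gates
#' (FDR below `fdr_threshold` and absolute linear fold change of at least
#' `fc_threshold`).
#'
#' @param mat gene-by-sample matrix of log2-scale expression.
#' @param design condition label per column of `mat` (character or factor).
#' @param contrast length-2 character vector `c(A, B)`; the log2 fold
#'   change is B minus A.
#' @param fdr_threshold FDR gate (default 0.1).
#' @param fc_threshold absolute linear fold-change gate (default 1.5).
#' @param d0 `NULL` to estimate the prior degrees of freedom from the data;
#'   `0` forces the ordinary (unmoderated) t; `Inf` forces full shrinkage to
#'   the prior variance.
#' @param s2_prior prior variance, only used with a forced finite `d0`
#'   (otherwise estimated).
#' @return data frame with one row per gene: `gene_id`, `log2fc`,
#'   `t_moderated`, `p_value`, `fdr`, `abs_linear_fc`, `passes`; the
#'   estimated/forced `s2_prior`, `d0` and residual df are attached as the
#'   `moderation` attribute.
#' @export
fit_moderated <- function(mat, design, contrast, fdr_threshold = 0.1,
                          fc_threshold = 1.5, d0 = NULL, s2_prior = NULL) {
  design <- as.character(design)
  if (length(design) != ncol(mat))
    stop("one design label per sample required", call. = FALSE)
  if (length(contrast) != 2 || !all(contrast %in% design))
    stop("contrast conditions must appear in the design", call. = FALSE)
  groups <- unique(design)
  k <- length(groups)
  n <- ncol(mat)
  d_resid <- n - k
  if (d_resid <= 0)
    stop("zero residual degrees of freedom: need replicates", call. = FALSE)
  if (any(table(design)[contrast] < 2))
    stop("need at least 2 samples per contrasted condition", call. = FALSE)

  means <- sapply(groups, function(g)
    rowMeans(mat[, design == g, drop = FALSE]))
  means <- matrix(means, nrow = nrow(mat), dimnames = list(rownames(mat), groups))
  rss <- rowSums((mat - means[, design, drop = FALSE])^2)
  s2 <- rss / d_resid

  estimated <- FALSE
  if (is.null(d0)) {
    est <- tryCatch(estimate_moderation(s2, d_resid), error = function(e) NULL)
    if (is.null(est)) {
      warning("prior estimation failed; falling back to ordinary t (d0 = 0)")
      d0 <- 0; s2_prior <- mean(s2)
    } else {
      d0 <- est$d0; s2_prior <- est$s2_prior; estimated <- TRUE
    }
  } else if (is.null(s2_prior)) {
    s2_prior <- if (is.finite(d0) && d0 > 0)
      estimate_moderation(s2, d_resid)$s2_prior else mean(s2[s2 > 0])
  }

  if (is.infinite(d0)) {
    s2_post <- rep(s2_prior, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2_post <- s2
    df_total <- d_resid
  } else {
    s2_post <- (d0 * s2_prior + d_resid * s2) / (d0 + d_resid)
    df_total <- d0 + d_resid
  }

  nA <- sum(design == contrast[1]); nB <- sum(design == contrast[2])
  scal <- sqrt(1 / nA + 1 / nB)
  log2fc <- means[, contrast[2]] - means[, contrast[1]]
  t_mod <- log2fc / (sqrt(s2_post) * scal)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[!is.finite(t_mod)] <- NA
  if (any(is.na(p))) {
    # constant genes with zero fold change: no evidence either way
    p[is.na(p) & log2fc == 0] <- 1
    t_mod[is.na(t_mod)] <- 0
  }
  fdr <- adjust_fdr(p)
  abs_fc <- 2^abs(log2fc)
  res <- data.frame(gene_id = rownames(mat), log2fc = log2fc,
                    t_moderated = t_mod, p_value = p, fdr = fdr,
                    abs_linear_fc = abs_fc,
                    passes = fdr < fdr_threshold & abs_fc >= fc_threshold,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "moderation") <- list(s2_prior = s2_prior, d0 = d0,
                                  d_resid = d_resid, estimated = estimated)
  res
}

#' Patient grade contrast
#'
#' Moderated differential expression between two tumour grades on
#' log2(count + 1)-transformed normalized expression, with the same
#' FDR/fold-change gates as the microarray contrasts. The reported log2
#' fold change is grade `pair[2]` minus grade `pair[1]`.
#'
#' @param mat linear-scale [expression_matrix()] (normalized counts).
#' @param clinical clinical table (see [read_clinical()]).
#' @param pair length-2 grade vector, e.g. `c("II", "IV")`.
#' @inheritParams fit_moderated
#' @return data frame of per-gene results as in [fit_moderated()].
#' @export
patient_grade_contrast <- function(mat, clinical, pair,
                                   fdr_threshold = 0.1, fc_threshold = 1.5) {
  if (!all(pair %in% GRADE_LEVELS) || length(pair) != 2)
    stop("pair must be two of ", paste(GRADE_LEVELS, collapse = "/"), call. = FALSE)
  grade <- as.character(clinical$grade[match(colnames(mat), clinical$sample_id)])
  if (!all(pair %in% grade))
    stop("grade absent from clinical table: ",
         paste(setdiff(pair, grade), collapse = ", "), call. = FALSE)
  keep <- grade %in% pair & !is.na(grade)
  sub <- log2(mat[, keep, drop = FALSE] + 1)
  fit_moderated(sub, grade[keep], contrast = pair,
                fdr_threshold = fdr_threshold, fc_threshold = fc_threshold)
}

#' Rank correlation of array and qPCR fold changes
#'
#' Spearman rank correlation between per-gene log2 fold changes measured on
#' the array and by qPCR; exact p-value for n at most 10 without ties,
#' t-approximation otherwise. A constant vector leaves rho undefined.
#'
#' @param array_log2fc,qpcr_log2fc paired per-gene log2 fold changes
#'   (at least 3 genes).
#' @return list with `rho` and `p_value` (both `NA` when undefined).
#' @export
validate_against_qpcr <- function(array_log2fc, qpcr_log2fc) {
  if (length(array_log2fc) != length(qpcr_log2fc))
    stop("fold-change vectors must be paired", call. = FALSE)
  n <- length(array_log2fc)
  if (n < 3) stop("need at least 3 paired genes", call. = FALSE)
  if (stats::sd(array_log2fc) == 0 || stats::sd(qpcr_log2fc) == 0) {
    warning("constant fold-change vector: rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ties <- anyDuplicated(array_log2fc) || anyDuplicated(qpcr_log2fc)
  exact <- n <= 10 && !ties
  ct <- suppressWarnings(
    stats::cor.test(array_log2fc, qpcr_log2fc, method = "spearman",
                    exact = exact))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
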