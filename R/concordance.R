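# Direction-concordant intersection of in-vitro perturbation responses
# with patient grade contrasts, and the correlation-sign-pattern
# classification into high-/low-malignant genes.
#
# Sign conventions. In-vitro conditions informative for each covariate:
#   GFAPalpha covariate: GFAPalpha+ (+1), GFAPalpha- (-1), GFAPpan- (-1)
#   delta/alpha ratio:   GFAPdelta+ (+1), GFAPalpha+ (-1), GFAPalpha- (+1)
# where the bracketed factor converts a gene's observed direction under the
# perturbation into its direction per unit increase of the covariate
# (e.g. up under a GFAPalpha knockdown means down per unit GFAPalpha).
# In patients the covariate's grade-IV direction is fixed by the cohort
# pattern: GFAPalpha is lower in grade IV (-1), the ratio higher (+1).

COVARIATE_CONDITIONS <- list(
  alpha = c(`GFAPalpha+` = 1, `GFAPalpha-` = -1, `GFAPpan-` = -1),
  ratio = c(`GFAPdelta+` = 1, `GFAPalpha+` = -1, `GFAPalpha-` = 1))

COVARIATE_GRADE4_DIRECTION <- c(alpha = -1, ratio = 1)

#' Harmonize in-vitro gene directions to a covariate
#'
#' Re-expresses each differentially expressed gene's direction of change
#' per unit increase of the covariate (GFAPalpha or the delta/alpha
#' ratio), across the conditions informative for that covariate. Genes
#' significant in two conditions with conflicting harmonized signs are
#' excluded and logged.
#'
#' @param de_by_condition named list of per-condition DE tables (as from
#'   [fit_moderated()], each contrast oriented condition-vs-control); names
#'   must be condition labels.
#' @param covariate `"alpha"` or `"ratio"`.
#' @return list with `genes` (data frame `gene_id`, `direction` in
#'   \{-1, +1\}) and `excluded` (data frame `gene_id`, `reason`).
#' @export
harmonize_direction <- function(de_by_condition, covariate = c("alpha", "ratio")) {
  covariate <- match.arg(covariate)
  factors <- COVARIATE_CONDITIONS[[covariate]]
  use <- intersect(names(de_by_condition), names(factors))
  if (length(use) == 0)
    stop("no condition informative for covariate ", covariate, call. = FALSE)
  recs <- list()
  for (cond in use) {
    de <- de_by_condition[[cond]]
    sig <- de[de$passes & de$log2fc != 0, , drop = FALSE]
    if (nrow(sig) == 0) next
    recs[[cond]] <- data.frame(gene_id = sig$gene_id,
                               direction = sign(sig$log2fc) * factors[[cond]],
                               stringsAsFactors = FALSE)
  }
  if (length(recs) == 0)
    return(list(genes = data.frame(gene_id = character(0),
                                   direction = numeric(0),
                                   stringsAsFactors = FALSE),
                excluded = data.frame(gene_id = character(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE)))
  all <- do.call(rbind, recs)
  agg <- tapply(all$direction, all$gene_id, function(d) {
    u <- unique(d)
    if (length(u) == 1) u else NA_real_
  })
  conflicted <- names(agg)[is.na(agg)]
  ok <- names(agg)[!is.na(agg)]
  list(genes = data.frame(gene_id = ok,
                          direction = as.numeric(agg[ok]),
                          stringsAsFactors = FALSE),
       excluded = data.frame(gene_id = conflicted,
                             reason = rep("conflicting harmonized directions",
                                          length(conflicted)),
                             stringsAsFactors = FALSE))
}

#' Direction-concordant overlap of in-vitro and patient gene sets
#'
#' Intersects the covariate's in-vitro regulated genes with the patient
#' grade-DE genes (union over the II-vs-IV and III-vs-IV contrasts),
#' keeping a gene only when its patient direction in grade IV equals its
#' harmonized in-vitro direction times the covariate's own grade-IV
#' direction. Genes passing in both patient contrasts with inconsistent
#' signs are excluded.
#'
#' @param in_vitro result of [harmonize_direction()].
#' @param patient_de named list of patient DE tables, each oriented
#'   IV-vs-lower-grade (as from [patient_grade_contrast()] with pairs
#'   `c("II","IV")` and `c("III","IV")`).
#' @param covariate_grade4_direction +1 if the covariate is higher in grade
#'   IV, -1 if lower (see `COVARIATE_GRADE4_DIRECTION`).
#' @return list with `genes` (character vector of concordant genes) and
#'   `excluded` (data frame `gene_id`, `reason`).
#' @export
concordant_overlap <- function(in_vitro, patient_de, covariate_grade4_direction) {
  stopifnot(covariate_grade4_direction %in% c(-1, 1))
  reg <- in_vitro$genes
  if (nrow(reg) == 0)
    return(list(genes = character(0),
                excluded = data.frame(gene_id = character(0),
                                      reason = character(0))))
  pat <- lapply(patient_de, function(de)
    de[de$passes & de$log2fc != 0, c("gene_id", "log2fc"), drop = FALSE])
  pat <- do.call(rbind, pat)
  if (is.null(pat) || nrow(pat) == 0)
    return(list(genes = character(0),
                excluded = data.frame(gene_id = character(0),
                                      reason = character(0))))
  sign_by_gene <- tapply(sign(pat$log2fc), pat$gene_id, function(s) {
    u <- unique(s)
    if (length(u) == 1) u else NA_real_
  })
  inconsistent <- names(sign_by_gene)[is.na(sign_by_gene)]
  shared <- intersect(reg$gene_id, names(sign_by_gene)[!is.na(sign_by_gene)])
  predicted <- reg$direction[match(shared, reg$gene_id)] *
    covariate_grade4_direction
  concordant <- shared[sign_by_gene[shared] == predicted]
  discordant <- setdiff(shared, concordant)
  inc <- intersect(inconsistent, reg$gene_id)
  excluded <- rbind(
    data.frame(gene_id = inc,
               reason = rep("inconsistent patient direction across grade contrasts",
                            length(inc)),
               stringsAsFactors = FALSE),
    data.frame(gene_id = discordant,
               reason = rep("patient direction discordant with in-vitro direction",
                            length(discordant)),
               stringsAsFactors = FALSE))
  rownames(excluded) <- NULL
  list(genes = concordant, excluded = excluded)
}

#' Correlate genes with the isoform covariates
#'
#' For each gene, Spearman's rho and the simple-linear-regression slope
#' test p-value against each of GFAPalpha, GFAPdelta and the delta/alpha
#' ratio across all pooled patients (gene expression and covariates on the
#' log2(x + 1) scale for the regression; rho is transform-invariant). BH
#' FDR is applied per covariate family. Zero-variance genes are skipped
#' with a record.
#'
#' @param mat linear-scale [expression_matrix()].
#' @param isoforms isoform table from [compute_isoform_table()]; only
#'   samples present in both inputs are used.
#' @param genes genes to test (default: all rows of `mat`).
#' @return data frame with per-gene `rho_*`, `p_*`, `fdr_*` for
#'   `alpha`, `delta`, `ratio`; skipped genes in the `skipped` attribute.
#' @export
correlate_genes <- function(mat, isoforms, genes = NULL) {
  if (is.null(genes)) genes <- rownames(mat)
  missing <- setdiff(genes, rownames(mat))
  if (length(missing) > 0)
    stop("gene absent from matrix: ", missing[1], call. = FALSE)
  samples <- intersect(colnames(mat), isoforms$sample_id)
  if (length(samples) < 3)
    stop("need at least 3 shared samples", call. = FALSE)
  iso <- isoforms[match(samples, isoforms$sample_id), ]
  rr <- iso$ratio
  if (any(rr <= 0)) rr[rr <= 0] <- min(rr[rr > 0]) / 2  # delta = 0 samples
  covs <- list(alpha = log2(iso$alpha + 1), delta = log2(iso$delta + 1),
               ratio = log2(rr))
  sub <- log2(mat[genes, samples, drop = FALSE] + 1)
  sds <- apply(sub, 1, stats::sd)
  skipped <- genes[sds == 0]
  keep <- genes[sds > 0]
  sub <- sub[keep, , drop = FALSE]
  n <- length(samples)
  out <- data.frame(gene_id = keep, stringsAsFactors = FALSE)
  for (cv in names(covs)) {
    x <- covs[[cv]]
    rho <- as.numeric(stats::cor(t(sub), x, method = "spearman"))
    r <- as.numeric(stats::cor(t(sub), x, method = "pearson"))
    tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    out[[paste0("rho_", cv)]] <- rho
    out[[paste0("p_", cv)]] <- p
    out[[paste0("fdr_", cv)]] <- adjust_fdr(p)
  }
  attr(out, "skipped") <- data.frame(
    gene_id = skipped,
    reason = rep("zero variance", length(skipped)),
    stringsAsFactors = FALSE)
  out
}

#' Classify genes by their correlation sign pattern
#'
#' A gene is `low-malignant` when it correlates positively with GFAPalpha
#' and negatively with the delta/alpha ratio (both at FDR below
#' `class_fdr`) while showing no correlation to GFAPdelta (FDR above
#' `delta_null_fdr`); `high-malignant` is the mirrored pattern; everything
#' else is `unclassified`. The three label sets partition the input.
#'
#' @param correlations output of [correlate_genes()].
#' @param class_fdr FDR threshold for the strong correlations (default 0.01).
#' @param delta_null_fdr FDR above which GFAPdelta is considered
#'   uncorrelated (default 0.1).
#' @return the input with an added `label` column.
#' @export
classify_genes <- function(correlations, class_fdr = 0.01,
                           delta_null_fdr = 0.1) {
  cc <- correlations
  need <- c("rho_alpha", "fdr_alpha", "rho_ratio", "fdr_ratio", "fdr_delta")
  miss <- setdiff(need, names(cc))
  if (length(miss) > 0)
    stop("missing covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  delta_null <- cc$fdr_delta > delta_null_fdr
  low <- cc$rho_alpha > 0 & cc$fdr_alpha < class_fdr &
    cc$rho_ratio < 0 & cc$fdr_ratio < class_fdr & delta_null
  high <- cc$rho_alpha < 0 & cc$fdr_alpha < class_fdr &
    cc$rho_ratio > 0 & cc$fdr_ratio < class_fdr & delta_null
  cc$label <- ifelse(low, "low-malignant",
                     ifelse(high, "high-malignant", "unclassified"))
  cc
}

#' Hierarchical clustering on absolute correlation coefficients
#'
#' Average-linkage agglomeration on the Euclidean distance between genes'
#' |rho| vectors (alpha, delta, ratio), with rows pre-ordered by gene id so
#' the result is invariant to input order; the 2-cluster cut recovers the
#' two sign-pattern blocks.
#'
#' @param correlations output of [correlate_genes()] (at least 2 genes).
#' @param k number of clusters for the cut (default 2).
#' @return list with `hclust` (the dendrogram) and `clusters` (named
#'   integer vector; singleton input gives cluster 1 and no dendrogram).
#' @export
cluster_abs_correlations <- function(correlations, k = 2) {
  ord <- order(correlations$gene_id)
  m <- abs(as.matrix(correlations[ord, c("rho_alpha", "rho_delta",
                                         "rho_ratio")]))
  rownames(m) <- correlations$gene_id[ord]
  if (nrow(m) == 1)
    return(list(hclust = NULL,
                clusters = stats::setNames(1L, rownames(m))))
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "average")
  clusters <- stats::cutree(hc, k = min(k, nrow(m)))
  list(hclust = hc, clusters = clusters)
}

#' Within-grade correlation follow-up
#'
#' Re-runs [correlate_genes()] restricted to each tumour grade, with BH
#' adjustment within each grade-by-covariate family and a significance
#' flag at `fdr_threshold`. Grades with fewer than 3 patients are skipped
#' with a record.
#'
#' @param mat linear-scale [expression_matrix()].
#' @param isoforms isoform table.
#' @param clinical clinical table.
#' @param genes genes to test.
#' @param fdr_threshold within-grade significance level (default 0.05).
#' @return long data frame (`grade`, `gene_id`, `covariate`, `rho`, `p`,
#'   `fdr`, `significant`); skipped grades in the `skipped_grades`
#'   attribute.
#' @export
within_grade_correlation <- function(mat, isoforms, clinical, genes,
                                     fdr_threshold = 0.05) {
  out <- list(); skipped <- character(0)
  for (gr in GRADE_LEVELS) {
    ids <- clinical$sample_id[clinical$grade == gr]
    ids <- intersect(ids, intersect(colnames(mat), isoforms$sample_id))
    if (length(ids) < 3) { skipped <- c(skipped, gr); next }
    cc <- correlate_genes(mat[, ids, drop = FALSE],
                          isoforms[isoforms$sample_id %in% ids, ], genes)
    for (cv in c("alpha", "delta", "ratio")) {
      out[[paste(gr, cv)]] <- data.frame(
        grade = gr, gene_id = cc$gene_id, covariate = cv,
        rho = cc[[paste0("rho_", cv)]], p = cc[[paste0("p_", cv)]],
        fdr = cc[[paste0("fdr_", cv)]],
        significant = cc[[paste0("fdr_", cv)]] < fdr_threshold,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out)
         else data.frame(grade = character(0), gene_id = character(0),
                         covariate = character(0), rho = numeric(0),
                         p = numeric(0), fdr = numeric(0),
                         significant = logical(0))
  rownames(res) <- NULL
  attr(res, "skipped_grades") <- skipped
  res
}
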