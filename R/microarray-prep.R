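# Two-colour microarray preprocessing. Each (array, channel) is treated as
# an independent single-channel sample for an intensity-based analysis; no
# ratio-of-channels model. The pipeline order is fixed:
#   flag filter -> quantile normalize -> collapse probes -> intensity filter
# and is enforced by prep_microarray() being the only composition offered.

sample_key <- function(batch) paste(batch$array_id, batch$channel, sep = ":")

#' Remove flagged spots from a microarray batch
#'
#' Drops every spot carrying a saturated / non-uniform / artefact flag.
#' Transcripts that thereby lose all spots in every sample of some condition
#' can no longer be tested in that condition and are recorded as missing.
#'
#' @param batch spot-level data frame (see [read_microarray()]).
#' @return list with `batch` (unflagged spots) and `missing` (data frame
#'   `transcript_id`, `condition` of transcripts left without any spot in a
#'   condition).
#' @export
filter_flagged_spots <- function(batch) {
  flagged <- batch$flag != ""
  kept <- batch[!flagged, , drop = FALSE]
  conds <- unique(batch$condition)
  trans <- unique(batch$transcript_id)
  have <- unique(kept[, c("transcript_id", "condition")])
  full <- expand.grid(transcript_id = trans, condition = conds,
                      stringsAsFactors = FALSE)
  key_have <- paste(have$transcript_id, have$condition)
  missing <- full[!(paste(full$transcript_id, full$condition) %in% key_have), ,
                  drop = FALSE]
  rownames(missing) <- NULL
  list(batch = kept, missing = missing, n_flagged = sum(flagged))
}

#' Quantile normalization across arrays
#'
#' Forces every column (array/channel sample) to share the reference
#' quantile distribution: the mean of per-rank sorted values. Rank ties
#' share the tied-rank mean; missing entries are normalized on each
#' column's own non-missing ranks against quantiles interpolated from the
#' reference vector (no imputation). Idempotent.
#'
#' @param mat numeric matrix of per-sample log2 intensities (columns =
#'   samples); at least 2 columns, each with at least 2 non-missing values.
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  if (!is.matrix(mat) || ncol(mat) < 2)
    stop("need a matrix with at least 2 arrays", call. = FALSE)
  if (any(colSums(!is.na(mat)) < 2))
    stop("array with fewer than 2 non-missing values", call. = FALSE)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Collapse redundant probes to transcript level
#'
#' Per transcript and sample, the arithmetic mean of the probes' log2
#' intensities (missing spots excluded from the mean).
#'
#' @param mat probe-by-sample matrix of log2 intensities.
#' @param probe_to_transcript character vector mapping each row of `mat`
#'   to its transcript id.
#' @return transcript-by-sample matrix.
#' @export
collapse_probes <- function(mat, probe_to_transcript) {
  stopifnot(nrow(mat) == length(probe_to_transcript))
  grp <- factor(probe_to_transcript)
  ok <- !is.na(mat)
  sums <- rowsum(ifelse(ok, mat, 0), grp)
  ns <- rowsum(ok + 0, grp)
  out <- sums / ns
  out[ns == 0] <- NA_real_
  out
}

#' Minimum-intensity filter
#'
#' Retains a gene iff the maximum over conditions of its mean log2
#' intensity is strictly greater than the threshold (a gene expressed in a
#' single condition suffices).
#'
#' @param mat gene-by-sample matrix of log2 intensities.
#' @param conditions condition label per column of `mat`.
#' @param threshold log2 intensity cutoff (default 6).
#' @return list with `matrix` (retained genes) and `removed` (gene ids).
#' @export
intensity_filter <- function(mat, conditions, threshold = 6) {
  if (length(conditions) != ncol(mat))
    stop("one condition label per sample required", call. = FALSE)
  if (any(is.na(conditions)))
    stop("unknown (NA) condition label", call. = FALSE)
  conds <- unique(conditions)
  cond_means <- sapply(conds, function(cc)
    rowMeans(mat[, conditions == cc, drop = FALSE], na.rm = TRUE))
  cond_means <- matrix(cond_means, nrow = nrow(mat),
                       dimnames = list(rownames(mat), conds))
  keep <- apply(cond_means, 1, function(x) any(is.finite(x) & x > threshold))
  list(matrix = mat[keep, , drop = FALSE],
       removed = rownames(mat)[!keep])
}

#' Full microarray preprocessing pipeline
#'
#' Runs the fixed stage order (flag filter, quantile normalization, probe
#' collapsing, intensity filter) on a spot-level batch and returns a
#' transcript-level log2 expression matrix plus a preprocessing report.
#'
#' @param batch spot-level data frame (see [read_microarray()]).
#' @param intensity_threshold log2 cutoff for [intensity_filter()].
#' @return list with `matrix` (an [expression_matrix()] on the log2 scale),
#'   `conditions` (condition label per column) and `report` (spot/gene
#'   accounting; omitted + retained spot counts add up to the input total).
#' @export
prep_microarray <- function(batch, intensity_threshold = 6) {
  total_spots <- nrow(batch)
  flagtab <- table(unlist(strsplit(batch$flag[batch$flag != ""], ",")))
  ff <- filter_flagged_spots(batch)
  b <- ff$batch
  skey <- sample_key(b)
  samples <- sort(unique(sample_key(batch)))
  probes <- sort(unique(batch$probe_id))
  m <- matrix(NA_real_, nrow = length(probes), ncol = length(samples),
              dimnames = list(probes, samples))
  m[cbind(match(b$probe_id, probes), match(skey, samples))] <- b$log2_intensity
  m <- quantile_normalize(m)
  p2t <- batch$transcript_id[match(probes, batch$probe_id)]
  tm <- collapse_probes(m, p2t)
  cond_map <- unique(data.frame(key = sample_key(batch),
                                condition = batch$condition,
                                stringsAsFactors = FALSE))
  conditions <- cond_map$condition[match(samples, cond_map$key)]
  filt <- intensity_filter(tm, conditions, threshold = intensity_threshold)
  out <- filt$matrix
  # Fully missing cells (transcript lost in a sample) are not representable
  # in a validated expression matrix; they are rare and reported instead.
  n_missing_cells <- sum(is.na(out))
  if (n_missing_cells > 0) {
    drop <- apply(is.na(out), 1, any)
    report_dropped <- rownames(out)[drop]
    out <- out[!drop, , drop = FALSE]
  } else report_dropped <- character(0)
  report <- list(
    total_spots = total_spots,
    spots_omitted_by_flag = as.list(flagtab),
    spots_retained = nrow(ff$batch),
    transcripts_missing_condition = ff$missing,
    probes_per_transcript = table(p2t),
    genes_removed_by_intensity_filter = filt$removed,
    genes_dropped_missing_values = report_dropped)
  stopifnot(report$spots_retained + ff$n_flagged == total_spots)
  list(matrix = expression_matrix(out, "log2"),
       conditions = conditions, report = report)
}
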