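#' @keywords internal
"_PACKAGE"

# Shared TSV conventions: UTF-8, tab-separated, '.' decimal separator, no
# quoting, 'NA' for missing. Readers reject malformed input rather than
# coerce; writers produce files their readers accept unchanged.

GRADE_LEVELS <- c("II", "III", "IV")
SPOT_FLAGS <- c("saturated", "non-uniform", "artefact")

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA", fileEncoding = "UTF-8")
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a validated expression matrix
#'
#' An expression matrix is a numeric genes-by-samples matrix with unique,
#' non-empty row (gene) and column (sample) names and a `scale` attribute
#' recording whether values are linear normalized counts or log2
#' intensities. Linear values must be non-negative; all values finite.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param scale `"linear"` (normalized counts) or `"log2"` (log2 intensities).
#' @return the matrix with class `expr_matrix` and attribute `scale`.
#' @export
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) && nrow(values) == 0) gid <- character(0)
  if ((is.null(gid) && nrow(values) > 0) || is.null(sid))
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(gid))
    stop("duplicate gene id: ", gid[duplicated(gid)][1], call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1], call. = FALSE)
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-finite value at gene ", gid[bad[1, 1]], ", sample ",
         sid[bad[1, 2]], call. = FALSE)
  if (scale == "linear") {
    neg <- which(values < 0, arr.ind = TRUE)
    if (nrow(neg) > 0)
      stop("negative linear value at gene ", gid[neg[1, 1]], ", sample ",
           sid[neg[1, 2]], call. = FALSE)
  }
  attr(values, "scale") <- scale
  class(values) <- c("expr_matrix", class(values))
  values
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column `gene_id`, and one row
#' per gene. Duplicated ids, non-numeric cells and negative linear values are
#' rejected with the offending row/column named.
#'
#' @param path TSV file path.
#' @inheritParams expression_matrix
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  df <- read_tsv_strict(path)
  if (ncol(df) < 2 || names(df)[1] != "gene_id")
    stop("expression TSV must start with a gene_id column", call. = FALSE)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) & !is.na(vals[[j]]))[1]
      stop("non-numeric cell at gene ", ids[if (is.na(bad)) 1 else bad],
           ", sample ", names(vals)[j], call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  expression_matrix(m, scale)
}

#' Write an expression matrix to TSV
#'
#' @param mat matrix with gene rownames and sample colnames.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE)
  write_tsv_strict(df, path)
}

#' Read a clinical table from TSV
#'
#' Columns: `sample_id`, `grade` (II/III/IV), `os_days`, `os_event`,
#' `pfs_days`, `pfs_event`. Progression-free columns may be missing (NA) for
#' individual patients. Unknown grade strings and negative times are
#' rejected.
#'
#' @param path TSV file path.
#' @return a validated data frame.
#' @export
read_clinical <- function(path) {
  df <- read_tsv_strict(path)
  validate_clinical(df)
}

validate_clinical <- function(df) {
  need <- c("sample_id", "grade", "os_days", "os_event", "pfs_days", "pfs_event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1],
         call. = FALSE)
  bad <- setdiff(unique(as.character(df$grade)), GRADE_LEVELS)
  if (length(bad) > 0)
    stop("unknown grade value: ", bad[1], call. = FALSE)
  df$grade <- factor(as.character(df$grade), levels = GRADE_LEVELS)
  for (col in c("os_days", "pfs_days")) {
    v <- df[[col]]
    if (any(!is.na(v) & v < 0))
      stop("negative time in ", col, " for sample ",
           df$sample_id[which(!is.na(v) & v < 0)[1]], call. = FALSE)
  }
  for (col in c("os_event", "pfs_event")) {
    v <- df[[col]]
    if (any(!is.na(v) & !(v %in% c(0, 1))))
      stop(col, " must be 0/1; offending sample ",
           df$sample_id[which(!is.na(v) & !(v %in% c(0, 1)))[1]], call. = FALSE)
  }
  df
}

#' Write a clinical table to TSV
#' @param clinical clinical data frame as from [read_clinical()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  out <- clinical
  out$grade <- as.character(out$grade)
  write_tsv_strict(out, path)
}

#' Read an isoform table from TSV
#'
#' Columns: `sample_id`, `alpha`, `delta` and optionally `ratio`. The ratio
#' is (re)computed with [compute_isoform_table()] so that samples with zero
#' alpha are excluded rather than coerced to infinity.
#'
#' @param path TSV file path.
#' @return an isoform table (see [compute_isoform_table()]).
#' @export
read_isoforms <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("sample_id", "alpha", "delta")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("isoform table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  compute_isoform_table(df$delta, df$alpha, as.character(df$sample_id))
}

#' Write an isoform table to TSV
#' @param isoforms isoform table from [compute_isoform_table()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_isoforms <- function(isoforms, path) {
  write_tsv_strict(isoforms, path)
}

#' Read a microarray spot table from TSV
#'
#' One row per spot with columns `probe_id`, `transcript_id`, `array_id`,
#' `channel`, `condition`, `log2_intensity`, `flag`. `flag` is empty/NA for
#' clean spots or a comma-separated subset of `saturated`, `non-uniform`,
#' `artefact` ("visually identified artefacts" are carried as a pre-set flag;
#' no image analysis is performed). Every probe must map to exactly one
#' transcript and every (array, channel) pair to exactly one condition label.
#'
#' @param path TSV file path.
#' @return a validated spot-level data frame of class `microarray_batch`.
#' @export
read_microarray <- function(path) {
  df <- read_tsv_strict(path)
  validate_microarray(df)
}

validate_microarray <- function(df) {
  need <- c("probe_id", "transcript_id", "array_id", "channel", "condition",
            "log2_intensity", "flag")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("microarray table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("probe_id", "transcript_id", "array_id", "channel",
                "condition", "flag"))
    df[[col]] <- as.character(df[[col]])
  df$flag[is.na(df$flag)] <- ""
  flags <- setdiff(unique(unlist(strsplit(df$flag[df$flag != ""], ","))), SPOT_FLAGS)
  if (length(flags) > 0)
    stop("unknown spot flag: ", flags[1], call. = FALSE)
  map <- unique(df[, c("probe_id", "transcript_id")])
  if (anyDuplicated(map$probe_id))
    stop("probe mapped to multiple transcripts: ",
         map$probe_id[duplicated(map$probe_id)][1], call. = FALSE)
  cond <- unique(df[, c("array_id", "channel", "condition")])
  key <- paste(cond$array_id, cond$channel)
  if (anyDuplicated(key))
    stop("array/channel with multiple condition labels: ",
         key[duplicated(key)][1], call. = FALSE)
  if (!is.numeric(df$log2_intensity))
    stop("log2_intensity must be numeric", call. = FALSE)
  class(df) <- c("microarray_batch", class(df))
  df
}

#' Write a microarray spot table to TSV
#' @param batch spot-level data frame from [read_microarray()] or
#'   [generate_microarray_batch()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_microarray <- function(batch, path) {
  write_tsv_strict(as.data.frame(unclass(batch)), path)
}

#' Read a gene-to-GO-term annotation map
#'
#' Two-column TSV (`gene_id`, `term_id`); repeated pairs are deduplicated.
#'
#' @param path TSV file path.
#' @return data frame with unique (gene_id, term_id) rows.
#' @export
read_go_annotations <- function(path) {
  df <- read_tsv_strict(path)
  if (!all(c("gene_id", "term_id") %in% names(df)))
    stop("annotation TSV needs columns gene_id, term_id", call. = FALSE)
  df <- unique(df[, c("gene_id", "term_id")])
  df$gene_id <- as.character(df$gene_id)
  df$term_id <- as.character(df$term_id)
  rownames(df) <- NULL
  df
}

#' Write a gene-to-GO-term annotation map to TSV
#' @param annotations data frame with columns gene_id, term_id.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_go_annotations <- function(annotations, path) {
  write_tsv_strict(annotations[, c("gene_id", "term_id")], path)
}
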