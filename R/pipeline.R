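# End-to-end orchestration: simulate -> microarray prep -> in-vitro DE ->
# ratio tests -> patient DE -> direction-concordant overlap -> correlation
# classification -> survival screen -> GO enrichment, from one config,
# with a machine-readable run manifest. Intermediate files are the same
# TSVs the standalone readers/writers use, so every stage is independently
# re-runnable.

#' Default pipeline configuration
#'
#' All thresholds default to the printed analysis values: DE gates FDR 0.1
#' and fold change 1.5; classification FDR 0.01 with a GFAPdelta null
#' filter at FDR 0.1; within-grade correlation FDR 0.05; survival FDR 0.05
#' with a trend level of 0.1; GO report filter at 5 study-set genes.
#'
#' @param seed integer seed driving every simulation stage.
#' @param out_dir output directory for stage TSVs and the manifest.
#' @param cohort a [cohort_spec()]; its seed is derived from `seed`.
#' @param de_fdr,de_fc,class_fdr,delta_null_fdr,within_grade_fdr,surv_fdr,
#'   surv_trend_fdr,go_min_hits,go_alpha analysis thresholds.
#' @param array_log2fc magnitude of the planted in-vitro responses of the
#'   cohort's malignancy genes.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("splicegrade_run_"),
                       cohort = NULL,
                       de_fdr = 0.1, de_fc = 1.5, class_fdr = 0.01,
                       delta_null_fdr = 0.1, within_grade_fdr = 0.05,
                       surv_fdr = 0.05, surv_trend_fdr = 0.1,
                       go_min_hits = 5, go_alpha = 0.05,
                       array_log2fc = 1.0) {
  cfg <- list(seed = seed, out_dir = out_dir, cohort = cohort,
              de_fdr = de_fdr, de_fc = de_fc, class_fdr = class_fdr,
              delta_null_fdr = delta_null_fdr,
              within_grade_fdr = within_grade_fdr, surv_fdr = surv_fdr,
              surv_trend_fdr = surv_trend_fdr, go_min_hits = go_min_hits,
              go_alpha = go_alpha, array_log2fc = array_log2fc)
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  for (f in c("de_fdr", "class_fdr", "delta_null_fdr", "within_grade_fdr",
              "surv_fdr", "surv_trend_fdr", "go_alpha"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop(f, " must lie in (0, 1); got ", cfg[[f]], call. = FALSE)
  if (cfg$de_fc <= 1) stop("de_fc must exceed 1", call. = FALSE)
  if (cfg$go_min_hits < 1) stop("go_min_hits must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; a `cohort` block
#' mirrors [cohort_spec()] (named vectors may be given as mappings).
#'
#' @param path YAML file path.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- NULL
  if (!is.null(y$cohort)) {
    cargs <- y$cohort
    for (f in c("censor_rate_by_grade", "median_os_by_grade",
                "survival_n_by_grade"))
      if (!is.null(cargs[[f]])) cargs[[f]] <- unlist(cargs[[f]])
    cohort <- do.call(cohort_spec, cargs)
  }
  y$cohort <- NULL
  do.call(run_config, c(y, list(cohort = cohort)))
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[splicegrade] %s | %s", stage, paste0(...)))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Stages: cohort + microarray simulation; microarray preprocessing;
#' in-vitro moderated DE per condition; grade-wise isoform-ratio tests;
#' patient grade DE (II-vs-IV, III-vs-IV); direction harmonization and
#' concordant overlap per covariate; pooled correlation and sign-pattern
#' classification of the overlap genes; median-split survival screen of
#' the classified genes per grade and endpoint; GO overrepresentation of
#' the classified sets. Every stage output is written as TSV under
#' `config$out_dir` and summarised in a JSON run manifest with per-stage
#' gene counts and file checksums; rerunning with an identical config
#' reproduces identical checksums.
#'
#' @param config a [run_config()].
#' @return list with all stage results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  cohort_sp <- config$cohort
  if (is.null(cohort_sp)) cohort_sp <- cohort_spec(seed = config$seed)
  pipeline_log("simulate", "cohort ", cohort_sp$n_grade2, "/",
               cohort_sp$n_grade3, "/", cohort_sp$n_grade4, " patients")
  cohort <- generate_cohort(cohort_sp)
  planted <- planted_array_effects(cohort$truth, log2fc = config$array_log2fc)
  plant_rec <- planted[planted$condition %in%
                         c("GFAPalpha+", "GFAPdelta+"), , drop = FALSE]
  plant_kd <- planted[planted$condition %in%
                        c("GFAPalpha-", "GFAPpan-"), , drop = FALSE]
  gene_ids <- cohort$truth$gene_id
  arrays <- list(
    recombinant = generate_microarray_batch(
      array_spec("recombinant", gene_ids = gene_ids, planted = plant_rec,
                 seed = config$seed + 1)),
    knockdown = generate_microarray_batch(
      array_spec("knockdown", gene_ids = gene_ids, planted = plant_kd,
                 seed = config$seed + 2)))

  write_expression(cohort$expression, file.path(config$out_dir, "expression.tsv"))
  write_isoforms(cohort$isoforms, file.path(config$out_dir, "isoforms.tsv"))
  write_clinical(cohort$clinical, file.path(config$out_dir, "clinical.tsv"))
  write_tsv_strict(cohort$truth, file.path(config$out_dir, "ground_truth.tsv"))

  pipeline_log("prep-arrays", "preprocessing 2 batches")
  prepped <- lapply(arrays, function(a) prep_microarray(a$batch))

  # In-vitro DE: overexpression and knockdown analysed independently;
  # each condition contrasted against its own control.
  contrasts <- list(
    `GFAPalpha+` = list(batch = "recombinant", ctrl = "control"),
    `GFAPdelta+` = list(batch = "recombinant", ctrl = "control"),
    `GFAPalpha-` = list(batch = "knockdown", ctrl = "NTC"),
    `GFAPpan-` = list(batch = "knockdown", ctrl = "NTC"))
  de_invitro <- lapply(names(contrasts), function(cond) {
    b <- contrasts[[cond]]
    pp <- prepped[[b$batch]]
    fit_moderated(unclass(pp$matrix), pp$conditions,
                  contrast = c(b$ctrl, cond),
                  fdr_threshold = config$de_fdr, fc_threshold = config$de_fc)
  })
  names(de_invitro) <- names(contrasts)
  for (cond in names(de_invitro)) {
    write_tsv_strict(de_invitro[[cond]],
                     file.path(config$out_dir,
                               paste0("de_invitro_", gsub("[+]", "pos",
                                      gsub("-", "neg", cond)), ".tsv")))
    counts[[paste0("de_", cond)]] <- sum(de_invitro[[cond]]$passes)
  }
  pipeline_log("diffexp-invitro",
               paste(names(de_invitro), vapply(de_invitro, function(x)
                 sum(x$passes), numeric(1)), collapse = ", "))

  pipeline_log("ratio-test", "grade-wise isoform tests")
  ratio_tests <- grade_isoform_tests(cohort$isoforms, cohort$clinical)
  write_tsv_strict(ratio_tests, file.path(config$out_dir, "ratio_tests.tsv"))

  patient_de <- list(
    II_vs_IV = patient_grade_contrast(cohort$expression, cohort$clinical,
                                      c("II", "IV"), config$de_fdr,
                                      config$de_fc),
    III_vs_IV = patient_grade_contrast(cohort$expression, cohort$clinical,
                                       c("III", "IV"), config$de_fdr,
                                       config$de_fc))
  for (nm in names(patient_de)) {
    write_tsv_strict(patient_de[[nm]],
                     file.path(config$out_dir, paste0("de_patient_", nm, ".tsv")))
    counts[[paste0("de_patient_", nm)]] <- sum(patient_de[[nm]]$passes)
  }
  pipeline_log("diffexp-patient",
               "II-vs-IV: ", sum(patient_de$II_vs_IV$passes),
               ", III-vs-IV: ", sum(patient_de$III_vs_IV$passes))

  overlaps <- lapply(c(alpha = "alpha", ratio = "ratio"), function(cv) {
    harm <- harmonize_direction(de_invitro, cv)
    concordant_overlap(harm, patient_de, COVARIATE_GRADE4_DIRECTION[[cv]])
  })
  counts$overlap_alpha <- length(overlaps$alpha$genes)
  counts$overlap_ratio <- length(overlaps$ratio$genes)
  pipeline_log("concordance", "alpha overlap: ", counts$overlap_alpha,
               ", ratio overlap: ", counts$overlap_ratio)
  candidates <- sort(union(overlaps$alpha$genes, overlaps$ratio$genes))

  classification <- NULL
  classified_genes <- character(0)
  if (length(candidates) > 0) {
    corr <- correlate_genes(cohort$expression, cohort$isoforms, candidates)
    classification <- classify_genes(corr, config$class_fdr,
                                     config$delta_null_fdr)
    write_tsv_strict(classification,
                     file.path(config$out_dir, "classification.tsv"))
    classified_genes <- classification$gene_id[
      classification$label != "unclassified"]
  }
  counts$low_malignant <- sum(classification$label == "low-malignant")
  counts$high_malignant <- sum(classification$label == "high-malignant")
  pipeline_log("classify", "low-malignant: ", counts$low_malignant,
               ", high-malignant: ", counts$high_malignant)

  within_grade <- if (length(classified_genes) > 0)
    within_grade_correlation(cohort$expression, cohort$isoforms,
                             cohort$clinical, classified_genes,
                             config$within_grade_fdr) else NULL
  if (!is.null(within_grade))
    write_tsv_strict(within_grade,
                     file.path(config$out_dir, "within_grade_correlation.tsv"))

  surv <- list()
  if (length(classified_genes) > 0) {
    for (gr in GRADE_LEVELS) {
      for (ep in c("OS", "PFS")) {
        res <- tryCatch(
          screen_genes(cohort$expression, cohort$clinical, classified_genes,
                       gr, ep, config$surv_fdr, config$surv_trend_fdr),
          error = function(e) NULL)
        if (!is.null(res)) {
          surv[[paste(gr, ep, sep = "_")]] <- res
          write_tsv_strict(res, file.path(config$out_dir,
                                          paste0("survival_", gr, "_", ep,
                                                 ".tsv")))
          counts[[paste0("surv_", gr, "_", ep)]] <- sum(res$significant)
        }
      }
    }
  }
  pipeline_log("survival-screen", length(surv), " grade/endpoint panels")

  annotations <- generate_go_annotations(cohort$truth, seed = config$seed + 3)
  write_go_annotations(annotations, file.path(config$out_dir, "go_annotations.tsv"))
  go <- list()
  if (length(classified_genes) > 0) {
    universe <- rownames(cohort$expression)
    for (lab in c("low-malignant", "high-malignant")) {
      set <- classification$gene_id[classification$label == lab]
      if (length(set) == 0) next
      go[[lab]] <- fisher_enrich(set, universe, annotations,
                                 min_hits = config$go_min_hits)
      write_tsv_strict(go[[lab]],
                       file.path(config$out_dir,
                                 paste0("go_", sub("-malignant", "", lab),
                                        ".tsv")))
      counts[[paste0("go_terms_", lab)]] <- nrow(go[[lab]])
    }
  }
  pipeline_log("go-enrichment", "done")

  files <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  checksums <- tools::md5sum(files)
  names(checksums) <- basename(names(checksums))
  manifest <- list(
    config = config[setdiff(names(config), "out_dir")],
    counts = counts,
    checksums = as.list(checksums))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  list(cohort = cohort, arrays = arrays, prepped = prepped,
       de_invitro = de_invitro, ratio_tests = ratio_tests,
       patient_de = patient_de, overlaps = overlaps,
       classification = classification, within_grade = within_grade,
       survival = surv, go = go, manifest = manifest)
}
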