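# Seeded synthetic cohorts and microarray batches with planted structure.
#
# Expression noise is log-normal around per-grade means (non-negative,
# right-skewed, matching normalized continuous counts). Correlated genes
# are generated through a Gaussian copula on the latent standard-normal
# score of log GFAPalpha, giving exact control of the sign and strength of
# the planted correlation. The grade-IV GFAPalpha distribution drops its
# mean to `alpha_grade4_fraction` of the lower-grade mean while its
# log-scale dispersion widens just enough that the expected delta/alpha
# ratio rises by `ratio_grade4_multiplier` with the delta marginal held
# fixed across grades (ratio planting acts through alpha only). Survival is
# exponential with a grade-specific baseline hazard, per-gene multiplicative
# hazard effects for above-median expression of the planted survival genes,
# and administrative censoring calibrated to the per-grade censoring rates.

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("a single integer seed is required for reproducible output", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Specification of a synthetic patient cohort
#'
#' Defaults encode the emulated study population: 55 grade II, 105 grade
#' III and 150 grade IV astrocytoma samples; grade-IV GFAPalpha at 55% of
#' the lower-grade mean (a 45% decrease); a 2.2-fold grade-IV increase of
#' the expected delta/alpha ratio; per-grade censoring of 94.64%, 77.36%
#' and 34.67%; and overall-survival data available for 41, 91 and 150
#' patients per grade.
#'
#' @param n_grade2,n_grade3,n_grade4 patients per grade.
#' @param n_null_genes genes independent of both covariates.
#' @param n_low_malignant genes planted to correlate positively with
#'   GFAPalpha (hence negatively with the ratio, and lower in grade IV).
#' @param n_high_malignant the mirrored class.
#' @param n_survival_genes genes with a planted hazard effect, independent
#'   of the isoforms.
#' @param alpha_grade4_fraction fraction of the grade II/III GFAPalpha mean
#'   retained in grade IV (0.55 = a 45% decrease).
#' @param ratio_grade4_multiplier factor by which the expected delta/alpha
#'   ratio rises in grade IV.
#' @param correlation_strength target absolute latent correlation of
#'   planted genes to the covariate, in (0, 1).
#' @param alpha_mean,delta_mean linear-scale means of the two isoforms in
#'   grades II/III.
#' @param sdlog_isoform log-scale standard deviation of the isoform noise
#'   in grades II/III.
#' @param gene_sdlog log-scale standard deviation of gene expression noise.
#' @param survival_hazard_ratio per-gene hazard multiplier for above-median
#'   expression of a planted survival gene.
#' @param censor_rate_by_grade named fractions (II, III, IV) of censored
#'   patients.
#' @param median_os_by_grade named baseline median overall survival in days
#'   per grade (before gene effects).
#' @param survival_n_by_grade named counts of patients per grade with
#'   overall-survival data (others get NA survival columns).
#' @param pfs_hazard_multiplier hazard multiplier for progression-free
#'   relative to overall survival (PFS is generated for grades II and III
#'   only).
#' @param seed integer RNG seed; identical specs give bit-identical output.
#' @param max_cells memory guard on genes x samples.
#' @return a validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_grade2 = 55, n_grade3 = 105, n_grade4 = 150,
                        n_null_genes = 2000, n_low_malignant = 40,
                        n_high_malignant = 40, n_survival_genes = 8,
                        alpha_grade4_fraction = 0.55,
                        ratio_grade4_multiplier = 2.2,
                        correlation_strength = 0.6,
                        alpha_mean = 5000, delta_mean = 250,
                        sdlog_isoform = 0.5, gene_sdlog = 1.0,
                        survival_hazard_ratio = 2,
                        censor_rate_by_grade = c(II = 0.9464, III = 0.7736,
                                                 IV = 0.3467),
                        median_os_by_grade = c(II = 2900, III = 1600, IV = 430),
                        survival_n_by_grade = c(II = 41, III = 91, IV = 150),
                        pfs_hazard_multiplier = 1.6,
                        seed = 1, max_cells = 5e7) {
  spec <- list(n_grade2 = n_grade2, n_grade3 = n_grade3, n_grade4 = n_grade4,
               n_null_genes = n_null_genes, n_low_malignant = n_low_malignant,
               n_high_malignant = n_high_malignant,
               n_survival_genes = n_survival_genes,
               alpha_grade4_fraction = alpha_grade4_fraction,
               ratio_grade4_multiplier = ratio_grade4_multiplier,
               correlation_strength = correlation_strength,
               alpha_mean = alpha_mean, delta_mean = delta_mean,
               sdlog_isoform = sdlog_isoform, gene_sdlog = gene_sdlog,
               survival_hazard_ratio = survival_hazard_ratio,
               censor_rate_by_grade = censor_rate_by_grade,
               median_os_by_grade = median_os_by_grade,
               survival_n_by_grade = survival_n_by_grade,
               pfs_hazard_multiplier = pfs_hazard_multiplier,
               seed = seed, max_cells = max_cells)
  validate_cohort_spec(spec)
  class(spec) <- "cohort_spec"
  spec
}

validate_cohort_spec <- function(s) {
  for (f in c("n_grade2", "n_grade3", "n_grade4"))
    if (s[[f]] < 2) stop(f, " must be at least 2", call. = FALSE)
  for (f in c("n_null_genes", "n_low_malignant", "n_high_malignant",
              "n_survival_genes"))
    if (s[[f]] < 0) stop(f, " must be non-negative", call. = FALSE)
  if (s$alpha_grade4_fraction <= 0 || s$alpha_grade4_fraction > 1)
    stop("alpha_grade4_fraction must lie in (0, 1]", call. = FALSE)
  if (s$ratio_grade4_multiplier < 1)
    stop("ratio_grade4_multiplier must be >= 1", call. = FALSE)
  if (s$correlation_strength <= 0 || s$correlation_strength >= 1)
    stop("correlation_strength must lie in (0, 1)", call. = FALSE)
  if (s$survival_hazard_ratio <= 0)
    stop("survival_hazard_ratio must be positive", call. = FALSE)
  for (f in c("censor_rate_by_grade", "median_os_by_grade",
              "survival_n_by_grade"))
    if (!all(GRADE_LEVELS %in% names(s[[f]])))
      stop(f, " must be named with grades II/III/IV", call. = FALSE)
  if (any(s$censor_rate_by_grade < 0 | s$censor_rate_by_grade >= 1))
    stop("censor rates must lie in [0, 1)", call. = FALSE)
  # widened grade-IV dispersion must stay a real standard deviation
  s4sq <- s$sdlog_isoform^2 +
    log(s$ratio_grade4_multiplier * s$alpha_grade4_fraction)
  if (s4sq <= 0)
    stop("infeasible fraction/multiplier pair: grade-IV log-sd^2 would be ",
         signif(s4sq, 3), call. = FALSE)
  n_genes <- s$n_null_genes + s$n_low_malignant + s$n_high_malignant +
    s$n_survival_genes
  n_samp <- s$n_grade2 + s$n_grade3 + s$n_grade4
  if (n_genes * n_samp > s$max_cells)
    stop("spec exceeds memory guard: ", n_genes, " x ", n_samp,
         " cells > max_cells", call. = FALSE)
  invisible(s)
}

grade4_sdlog <- function(spec) {
  sqrt(spec$sdlog_isoform^2 +
         log(spec$ratio_grade4_multiplier * spec$alpha_grade4_fraction))
}

#' Generate a synthetic patient cohort
#'
#' Draws isoform expression, planted/null gene expression, clinical and
#' survival data according to a [cohort_spec()], together with ground-truth
#' labels for recovery tests.
#'
#' Grade II/III GFAPalpha is log-normal with mean `alpha_mean`; grade IV has
#' mean `alpha_grade4_fraction * alpha_mean` and widened log-sd so that the
#' expected delta/alpha ratio is multiplied by `ratio_grade4_multiplier`
#' (delta identical across grades). Low-malignant genes share a Gaussian
#' copula with the pooled log-GFAPalpha score at `+correlation_strength`
#' (hence inherit its grade-IV decrease and correlate negatively with the
#' ratio); high-malignant genes at `-correlation_strength`; null and
#' survival genes are independent. Survival-gene hazard effects enter as
#' `survival_hazard_ratio^(I - 1/2)` per gene, where I indicates
#' above-median expression within the patient's grade.
#'
#' @param spec a [cohort_spec()].
#' @return list with `expression` (linear [expression_matrix()]),
#'   `isoforms` (see [compute_isoform_table()]), `clinical` (data frame),
#'   and `truth` (data frame `gene_id`, `class`, `dir_alpha`, `dir_ratio`).
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    grade <- factor(rep(GRADE_LEVELS, c(spec$n_grade2, spec$n_grade3,
                                        spec$n_grade4)),
                    levels = GRADE_LEVELS)
    n <- length(grade)
    sample_ids <- sprintf("P%04d", seq_len(n))

    s <- spec$sdlog_isoform
    s4 <- grade4_sdlog(spec)
    sd_a <- ifelse(grade == "IV", s4, s)
    meanlog_a <- ifelse(grade == "IV",
                        log(spec$alpha_mean * spec$alpha_grade4_fraction) - s4^2 / 2,
                        log(spec$alpha_mean) - s^2 / 2)
    z_a <- stats::rnorm(n)
    log_alpha <- meanlog_a + sd_a * z_a
    alpha <- exp(log_alpha)
    delta <- exp(log(spec$delta_mean) - s^2 / 2 + s * stats::rnorm(n))
    isoforms <- compute_isoform_table(delta, alpha, sample_ids)

    z_pool <- as.numeric(scale(log_alpha))
    classes <- rep(c("low-malignant", "high-malignant", "survival-effect",
                     "null"),
                   c(spec$n_low_malignant, spec$n_high_malignant,
                     spec$n_survival_genes, spec$n_null_genes))
    n_genes <- length(classes)
    gene_ids <- sprintf("G%05d", seq_len(n_genes))
    rho <- spec$correlation_strength
    dir_alpha <- ifelse(classes == "low-malignant", 1,
                        ifelse(classes == "high-malignant", -1, 0))
    meanlog_g <- stats::runif(n_genes, log(50), log(2000))
    expr <- matrix(NA_real_, nrow = n_genes, ncol = n,
                   dimnames = list(gene_ids, sample_ids))
    eps <- matrix(stats::rnorm(n_genes * n), nrow = n_genes)
    for (g in seq_len(n_genes)) {
      u <- if (dir_alpha[g] == 0) eps[g, ]
           else dir_alpha[g] * rho * z_pool + sqrt(1 - rho^2) * eps[g, ]
      expr[g, ] <- exp(meanlog_g[g] + spec$gene_sdlog * u)
    }

    clinical <- simulate_survival(spec, grade, sample_ids, expr, classes)
    truth <- data.frame(gene_id = gene_ids, class = classes,
                        dir_alpha = dir_alpha, dir_ratio = -dir_alpha,
                        stringsAsFactors = FALSE)
    list(expression = expression_matrix(expr, "linear"),
         isoforms = isoforms, clinical = clinical, truth = truth)
  })
}

simulate_survival <- function(spec, grade, sample_ids, expr, classes) {
  n <- length(grade)
  surv_genes <- which(classes == "survival-effect")
  log_hr <- rep(0, n)
  for (g in surv_genes) {
    for (gr in GRADE_LEVELS) {
      idx <- which(grade == gr)
      if (length(idx) == 0) next
      med <- stats::median(expr[g, idx])
      above <- expr[g, idx] > med
      log_hr[idx] <- log_hr[idx] +
        log(spec$survival_hazard_ratio) * (above - 0.5)
    }
  }
  os_days <- os_event <- rep(NA_real_, n)
  pfs_days <- pfs_event <- rep(NA_real_, n)
  for (gr in GRADE_LEVELS) {
    idx <- which(grade == gr)
    base <- log(2) / spec$median_os_by_grade[[gr]]
    lambda <- base * exp(log_hr[idx])
    t_ev <- stats::rexp(length(idx), rate = lambda)
    target <- spec$censor_rate_by_grade[[gr]]
    tau <- if (target <= 0) Inf else
      stats::uniroot(function(tt) mean(exp(-lambda * tt)) - target,
                     lower = 1e-6, upper = 1e9, tol = 1e-6)$root
    os_days[idx] <- pmin(t_ev, tau)
    os_event[idx] <- as.numeric(t_ev <= tau)
    if (gr != "IV") {
      t_p <- stats::rexp(length(idx),
                         rate = lambda * spec$pfs_hazard_multiplier)
      pfs_days[idx] <- pmin(t_p, tau)
      pfs_event[idx] <- as.numeric(t_p <= tau)
    }
    n_surv <- min(spec$survival_n_by_grade[[gr]], length(idx))
    drop <- if (n_surv < length(idx))
      sample(idx, length(idx) - n_surv) else integer(0)
    os_days[drop] <- NA; os_event[drop] <- NA
    pfs_days[drop] <- NA; pfs_event[drop] <- NA
  }
  data.frame(sample_id = sample_ids, grade = grade,
             os_days = round(os_days, 1), os_event = os_event,
             pfs_days = round(pfs_days, 1), pfs_event = pfs_event,
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic two-colour microarray batch
#'
#' Replicate counts default to the emulated experiments: 8/8/8 for the
#' recombinant design (control, GFAPalpha+, GFAPdelta+) and 6/5/5 for the
#' knockdown design (NTC, GFAPalpha-, GFAPpan-).
#'
#' @param design `"recombinant"` or `"knockdown"`.
#' @param replicates named integer vector of replicates per condition;
#'   `NULL` for the design default. All counts must be at least 2.
#' @param gene_ids transcripts measured by the array.
#' @param planted data frame (`gene_id`, `condition`, `log2fc`) of planted
#'   per-gene fold changes relative to the design's control condition, or
#'   `NULL` for a null batch.
#' @param flag_fraction fraction of spots flagged (saturated / non-uniform
#'   / artefact), applied exactly (rounded to a spot count).
#' @param probes_per_gene redundant probes per transcript.
#' @param baseline_range log2 baseline intensity range for expressed genes.
#' @param low_expressed_fraction fraction of non-planted genes drawn below
#'   the intensity filter (baseline log2 in [4, 5.5]) to exercise it.
#' @param distortion apply array-specific monotone (affine) intensity
#'   distortions, to exercise quantile normalization.
#' @param noise_sd spot-level log2 noise standard deviation.
#' @param seed integer RNG seed.
#' @return a validated list of class `array_spec`.
#' @export
array_spec <- function(design = c("recombinant", "knockdown"),
                       replicates = NULL,
                       gene_ids = sprintf("G%05d", 1:500),
                       planted = NULL,
                       flag_fraction = 0.05, probes_per_gene = 2,
                       baseline_range = c(7, 12),
                       low_expressed_fraction = 0.1,
                       distortion = TRUE, noise_sd = 0.3, seed = 1) {
  design <- match.arg(design)
  if (is.null(replicates))
    replicates <- if (design == "recombinant")
      c(control = 8, `GFAPalpha+` = 8, `GFAPdelta+` = 8)
    else c(NTC = 6, `GFAPalpha-` = 5, `GFAPpan-` = 5)
  if (any(replicates < 2))
    stop("replicate count < 2: variance undefined", call. = FALSE)
  if (flag_fraction < 0 || flag_fraction >= 1)
    stop("flag_fraction must lie in [0, 1)", call. = FALSE)
  if (!is.null(planted)) {
    need <- c("gene_id", "condition", "log2fc")
    if (!all(need %in% names(planted)))
      stop("planted needs columns gene_id, condition, log2fc", call. = FALSE)
    bad <- setdiff(planted$condition, names(replicates))
    if (length(bad) > 0)
      stop("planted condition not in design: ", bad[1], call. = FALSE)
    if (!all(planted$gene_id %in% gene_ids))
      stop("planted gene absent from gene_ids", call. = FALSE)
  }
  spec <- list(design = design, replicates = replicates, gene_ids = gene_ids,
               planted = planted, flag_fraction = flag_fraction,
               probes_per_gene = probes_per_gene,
               baseline_range = baseline_range,
               low_expressed_fraction = low_expressed_fraction,
               distortion = distortion, noise_sd = noise_sd, seed = seed)
  class(spec) <- "array_spec"
  spec
}

#' Generate a synthetic microarray batch
#'
#' Produces spot-level log2 intensities with redundant probes per
#' transcript, array-specific monotone distortions, a stated fraction of
#' flagged spots, and planted per-gene fold changes recorded in the
#' returned ground truth.
#'
#' @param spec an [array_spec()].
#' @return list with `batch` (spot-level data frame as accepted by
#'   [prep_microarray()]) and `truth` (the planted fold-change table).
#' @export
generate_microarray_batch <- function(spec) {
  stopifnot(inherits(spec, "array_spec"))
  with_seed(spec$seed, {
    conds <- rep(names(spec$replicates), spec$replicates)
    n_samp <- length(conds)
    arrays <- sprintf("A%02d", rep(seq_len(ceiling(n_samp / 2)), each = 2))[seq_len(n_samp)]
    channels <- rep(c("Cy3", "Cy5"), length.out = n_samp)
    genes <- spec$gene_ids
    n_genes <- length(genes)

    baseline <- stats::runif(n_genes, spec$baseline_range[1],
                             spec$baseline_range[2])
    planted_genes <- if (is.null(spec$planted)) character(0)
                     else unique(spec$planted$gene_id)
    free <- which(!(genes %in% planted_genes))
    n_low <- round(length(free) * spec$low_expressed_fraction)
    if (n_low > 0) {
      low <- sample(free, n_low)
      baseline[low] <- stats::runif(n_low, 4, 5.5)
    }

    effect <- matrix(0, nrow = n_genes, ncol = n_samp,
                     dimnames = list(genes, NULL))
    if (!is.null(spec$planted)) {
      for (i in seq_len(nrow(spec$planted))) {
        g <- spec$planted$gene_id[i]; cc <- spec$planted$condition[i]
        effect[g, conds == cc] <- effect[g, conds == cc] + spec$planted$log2fc[i]
      }
    }

    probe_off <- stats::runif(n_genes * spec$probes_per_gene, -0.2, 0.2)
    a_j <- if (spec$distortion) stats::runif(n_samp, 0.85, 1.15) else rep(1, n_samp)
    b_j <- if (spec$distortion) stats::runif(n_samp, -0.7, 0.7) else rep(0, n_samp)

    rows <- vector("list", spec$probes_per_gene)
    for (p in seq_len(spec$probes_per_gene)) {
      off <- probe_off[(p - 1) * n_genes + seq_len(n_genes)]
      mu <- baseline + off + effect           # genes x samples
      noise <- matrix(stats::rnorm(n_genes * n_samp, sd = spec$noise_sd),
                      nrow = n_genes)
      val <- sweep(sweep(mu + noise, 2, a_j, `*`), 2, b_j, `+`)
      rows[[p]] <- data.frame(
        probe_id = rep(sprintf("%s_pr%02d", genes, p), n_samp),
        transcript_id = rep(genes, n_samp),
        array_id = rep(arrays, each = n_genes),
        channel = rep(channels, each = n_genes),
        condition = rep(conds, each = n_genes),
        log2_intensity = as.vector(val),
        stringsAsFactors = FALSE)
    }
    batch <- do.call(rbind, rows)
    batch$flag <- ""
    n_flag <- round(nrow(batch) * spec$flag_fraction)
    if (n_flag > 0) {
      idx <- sample(nrow(batch), n_flag)
      batch$flag[idx] <- sample(SPOT_FLAGS, n_flag, replace = TRUE)
    }
    batch <- validate_microarray(batch)
    truth <- if (is.null(spec$planted))
      data.frame(gene_id = character(0), condition = character(0),
                 log2fc = numeric(0), stringsAsFactors = FALSE)
    else spec$planted
    list(batch = batch, truth = truth)
  })
}

#' Default planted fold-change table for the pipeline arrays
#'
#' Gives every planted malignancy gene of a cohort an in-vitro response
#' consistent with its class: low-malignant genes move with GFAPalpha
#' (up under GFAPalpha+, down under the knockdowns, down under GFAPdelta+
#' as the ratio rises), high-malignant genes the opposite.
#'
#' @param truth ground-truth table from [generate_cohort()].
#' @param log2fc planted effect magnitude on the log2 scale.
#' @return data frame (`gene_id`, `condition`, `log2fc`).
#' @export
planted_array_effects <- function(truth, log2fc = 1.0) {
  sel <- truth[truth$class %in% c("low-malignant", "high-malignant"), ]
  if (nrow(sel) == 0)
    return(data.frame(gene_id = character(0), condition = character(0),
                      log2fc = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(sel)), function(i) {
    d <- sel$dir_alpha[i]
    data.frame(gene_id = sel$gene_id[i],
               condition = c("GFAPalpha+", "GFAPalpha-", "GFAPpan-",
                             "GFAPdelta+"),
               log2fc = log2fc * c(d, -d, -d, -d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic gene-to-GO annotation map
#'
#' Builds a small flat ontology over the cohort's genes in which a few
#' terms preferentially annotate the planted malignancy classes (so
#' overrepresentation is recoverable) and the rest annotate random genes.
#'
#' @param truth ground-truth table from [generate_cohort()].
#' @param n_terms total number of terms.
#' @param n_enriched_terms terms enriched for planted classes.
#' @param mean_term_size expected random-term size.
#' @param seed integer RNG seed.
#' @return data frame (`gene_id`, `term_id`).
#' @export
generate_go_annotations <- function(truth, n_terms = 50,
                                    n_enriched_terms = 4,
                                    mean_term_size = 40, seed = 1) {
  with_seed(seed, {
    genes <- truth$gene_id
    planted <- truth$gene_id[truth$class %in%
                               c("low-malignant", "high-malignant")]
    rows <- list()
    for (i in seq_len(n_terms)) {
      term <- sprintf("TERM%04d", i)
      if (i <= n_enriched_terms && length(planted) > 0) {
        k <- max(5, round(length(planted) / n_enriched_terms))
        members <- unique(c(sample(planted, min(k, length(planted))),
                            sample(genes, mean_term_size %/% 2)))
      } else {
        members <- sample(genes, min(length(genes),
                                     max(2, stats::rpois(1, mean_term_size))))
      }
      rows[[i]] <- data.frame(gene_id = members, term_id = term,
                              stringsAsFactors = FALSE)
    }
    unique(do.call(rbind, rows))
  })
}
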