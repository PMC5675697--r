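# Small fixture builders shared across test files. All randomness is
# seeded by the caller through the spec seeds.

small_cohort_spec <- function(seed = 1, ...) {
  defaults <- list(n_grade2 = 12, n_grade3 = 14, n_grade4 = 16,
                   n_null_genes = 40, n_low_malignant = 5,
                   n_high_malignant = 5, n_survival_genes = 2,
                   survival_n_by_grade = c(II = 12, III = 14, IV = 16),
                   seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_spec, args)
}

null_cohort_spec <- function(seed = 1, n_genes = 30, n = 12) {
  cohort_spec(n_grade2 = n, n_grade3 = n, n_grade4 = n,
              n_null_genes = n_genes, n_low_malignant = 0,
              n_high_malignant = 0, n_survival_genes = 0,
              alpha_grade4_fraction = 1, ratio_grade4_multiplier = 1,
              survival_n_by_grade = c(II = n, III = n, IV = n),
              seed = seed)
}

tiny_batch <- function(seed = 1, ...) {
  defaults <- list(design = "recombinant",
                   replicates = c(control = 4, `GFAPalpha+` = 4,
                                  `GFAPdelta+` = 4),
                   gene_ids = sprintf("G%05d", 1:60),
                   flag_fraction = 0.05, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(array_spec, args)
}
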