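test_that("identical specs give bit-identical cohorts and leave the RNG alone", {
  sp <- small_cohort_spec(seed = 81)
  a <- generate_cohort(sp)
  set.seed(999); before <- .Random.seed
  b <- generate_cohort(sp)
  expect_identical(before, .Random.seed)  # generator restores RNG state
  expect_identical(unclass(a$expression)[, ], unclass(b$expression)[, ])
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$isoforms, b$isoforms)
  expect_identical(a$truth, b$truth)
  d1 <- withr::local_tempfile(fileext = ".tsv")
  d2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(a$expression, d1); write_expression(b$expression, d2)
  expect_identical(unname(tools::md5sum(d1)), unname(tools::md5sum(d2)))
  c_ <- generate_cohort(small_cohort_spec(seed = 82))
  expect_false(identical(unclass(a$expression)[, ], unclass(c_$expression)[, ]))
})

test_that("spec validation enforces the documented invariants", {
  expect_error(cohort_spec(alpha_grade4_fraction = 0), "0, 1")
  expect_error(cohort_spec(ratio_grade4_multiplier = 0.9), ">= 1")
  expect_error(cohort_spec(correlation_strength = 1), "0, 1")
  expect_error(cohort_spec(n_grade2 = 1), "at least 2")
  expect_error(cohort_spec(n_null_genes = 1e6, max_cells = 1e5),
               "memory guard")
  # dispersion widening must stay feasible
  expect_error(cohort_spec(alpha_grade4_fraction = 0.1,
                           ratio_grade4_multiplier = 1), "infeasible")
  expect_error(generate_cohort(
    small_cohort_spec(seed = NA_real_)), "seed")
})

test_that("planted correlations carry the planted sign", {
  sp <- small_cohort_spec(seed = 83, correlation_strength = 0.99,
                          n_null_genes = 0, n_survival_genes = 0,
                          n_low_malignant = 10, n_high_malignant = 10)
  co <- generate_cohort(sp)
  la <- log(co$isoforms$alpha)
  lr <- log(co$isoforms$ratio)
  for (i in seq_len(nrow(co$truth))) {
    g <- co$truth$gene_id[i]
    rho_a <- cor(unclass(co$expression)[g, ], la, method = "spearman")
    rho_r <- cor(unclass(co$expression)[g, ], lr, method = "spearman")
    expect_equal(sign(rho_a), co$truth$dir_alpha[i], info = g)
    expect_equal(sign(rho_r), co$truth$dir_ratio[i], info = g)
  }
})

test_that("planted-sign fidelity holds at the default correlation strength", {
  co <- generate_cohort(cohort_spec(seed = 84))
  la <- log(co$isoforms$alpha)
  planted <- co$truth[co$truth$dir_alpha != 0, ]
  rho <- apply(unclass(co$expression)[planted$gene_id, ], 1,
               function(y) cor(y, la, method = "spearman"))
  expect_gte(mean(sign(rho) == planted$dir_alpha), 0.95)
})

test_that("the default cohort plants the printed grade-IV isoform pattern", {
  co <- generate_cohort(cohort_spec(seed = 85))
  iso <- co$isoforms
  grade <- co$clinical$grade[match(iso$sample_id, co$clinical$sample_id)]
  m2 <- mean(iso$alpha[grade == "II"]); m4 <- mean(iso$alpha[grade == "IV"])
  frac <- m4 / m2
  # Monte-Carlo standard error of the ratio of means (delta method)
  se <- frac * sqrt(var(iso$alpha[grade == "IV"]) / (m4^2 * 150) +
                      var(iso$alpha[grade == "II"]) / (m2^2 * 55))
  expect_lt(abs(frac - 0.55), 3 * se)
  rmult <- mean(iso$ratio[grade == "IV"]) / mean(iso$ratio[grade == "II"])
  se_r <- rmult * sqrt(var(iso$ratio[grade == "IV"]) /
                         (mean(iso$ratio[grade == "IV"])^2 * 150) +
                       var(iso$ratio[grade == "II"]) /
                         (mean(iso$ratio[grade == "II"])^2 * 55))
  expect_lt(abs(rmult - 2.2), 3 * se_r)
  # delta planted flat across grades
  expect_lt(abs(mean(iso$delta[grade == "IV"]) /
                  mean(iso$delta[grade == "II"]) - 1), 0.2)
})

test_that("null cohorts give uniform Mann-Whitney p-values on alpha", {
  set.seed(86)
  ps <- vapply(1:200, function(i) {
    co <- generate_cohort(null_cohort_spec(seed = 4000 + i, n_genes = 0,
                                           n = 10))
    iso <- co$isoforms
    grade <- co$clinical$grade[match(iso$sample_id, co$clinical$sample_id)]
    mann_whitney(iso$alpha[grade == "II"], iso$alpha[grade == "IV"])$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("microarray batches carry exactly the requested flags and effects", {
  sp <- tiny_batch(seed = 87, flag_fraction = 0.1)
  ab <- generate_microarray_batch(sp)
  expect_equal(sum(ab$batch$flag != ""), round(0.1 * nrow(ab$batch)))
  expect_error(array_spec(replicates = c(control = 1, `GFAPalpha+` = 4,
                                         `GFAPdelta+` = 4)),
               "replicate count")

  # null batch without distortion: condition means equal in expectation
  null_sp <- tiny_batch(seed = 88, flag_fraction = 0, distortion = FALSE)
  nb <- generate_microarray_batch(null_sp)
  pp <- prep_microarray(nb$batch)
  m <- unclass(pp$matrix)
  diffs <- rowMeans(m[, pp$conditions == "GFAPalpha+"]) -
    rowMeans(m[, pp$conditions == "control"])
  expect_lt(abs(mean(diffs)), 0.05)
  expect_equal(nrow(nb$truth), 0)

  # determinism
  ab2 <- generate_microarray_batch(sp)
  expect_identical(ab$batch$log2_intensity, ab2$batch$log2_intensity)
})

test_that("synthetic annotations cover planted classes and deduplicate", {
  co <- generate_cohort(small_cohort_spec(seed = 89))
  ann <- generate_go_annotations(co$truth, seed = 90)
  expect_false(any(duplicated(paste(ann$gene_id, ann$term_id))))
  expect_true(all(ann$gene_id %in% co$truth$gene_id))
  planted <- co$truth$gene_id[co$truth$class %in%
                                c("low-malignant", "high-malignant")]
  hits <- tapply(ann$gene_id %in% planted, ann$term_id, sum)
  expect_gte(max(hits), 5)  # at least one term is enriched for planted genes
})
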