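de_row <- function(gene, lfc, passes = TRUE) {
  data.frame(gene_id = gene, log2fc = lfc, t_moderated = sign(lfc) * 5,
             p_value = 1e-4, fdr = 1e-3, abs_linear_fc = 2^abs(lfc),
             passes = passes, stringsAsFactors = FALSE)
}

test_that("in-vitro directions harmonize with the expected sign algebra", {
  de <- list(`GFAPalpha-` = de_row("g1", +1),   # up under knockdown
             `GFAPalpha+` = de_row("g2", +1))   # up under overexpression
  h_alpha <- harmonize_direction(de, "alpha")
  expect_equal(h_alpha$genes$direction[h_alpha$genes$gene_id == "g1"], -1)
  expect_equal(h_alpha$genes$direction[h_alpha$genes$gene_id == "g2"], +1)
  h_ratio <- harmonize_direction(de, "ratio")
  # up under GFAPalpha+ means down per unit ratio; up under GFAPalpha- means up
  expect_equal(h_ratio$genes$direction[h_ratio$genes$gene_id == "g2"], -1)
  expect_equal(h_ratio$genes$direction[h_ratio$genes$gene_id == "g1"], +1)

  # conflicting harmonized signs are excluded and logged
  de2 <- list(`GFAPalpha+` = de_row("g3", +1),
              `GFAPalpha-` = de_row("g3", +1))
  h <- harmonize_direction(de2, "alpha")
  expect_equal(nrow(h$genes), 0)
  expect_equal(h$excluded$gene_id, "g3")
})

test_that("concordant overlap applies the covariate's grade-IV direction", {
  reg <- list(genes = data.frame(gene_id = c("gA", "gB"),
                                 direction = c(+1, +1)),
              excluded = data.frame(gene_id = character(0),
                                    reason = character(0)))
  pat <- list(II_vs_IV = rbind(de_row("gA", -1), de_row("gB", +1)))
  # GFAPalpha is down in grade IV: +1 genes must be down in IV
  ov <- concordant_overlap(reg, pat, covariate_grade4_direction = -1)
  expect_equal(ov$genes, "gA")
  expect_true("gB" %in% ov$excluded$gene_id)
  # flipping the covariate's patient direction flips every decision
  ov_flip <- concordant_overlap(reg, pat, covariate_grade4_direction = +1)
  expect_equal(ov_flip$genes, "gB")
  expect_true("gA" %in% ov_flip$excluded$gene_id)
  # empty inputs give empty output, not an error
  empty <- concordant_overlap(reg, list(II_vs_IV = de_row("gZ", 1, FALSE)), -1)
  expect_length(empty$genes, 0)
  # inconsistent patient direction across grade contrasts excludes
  pat2 <- list(II_vs_IV = de_row("gA", -1), III_vs_IV = de_row("gA", +1))
  ov2 <- concordant_overlap(reg, pat2, -1)
  expect_length(ov2$genes, 0)
  expect_true("gA" %in% ov2$excluded$gene_id)
})

test_that("pooled correlations match a per-gene regression oracle", {
  co <- generate_cohort(small_cohort_spec(seed = 51, n_grade2 = 7,
                                          n_grade3 = 7, n_grade4 = 6))
  genes <- rownames(co$expression)[1:8]
  cc <- correlate_genes(co$expression, co$isoforms, genes)
  iso <- co$isoforms[match(colnames(co$expression), co$isoforms$sample_id), ]
  x_alpha <- log2(iso$alpha + 1)
  for (g in genes) {
    y <- log2(unclass(co$expression)[g, ] + 1)
    want <- oracle_slope_test(x_alpha, y)
    row <- cc[cc$gene_id == g, ]
    expect_equal(row$p_alpha, want$p, tolerance = 1e-10, info = g)
    expect_equal(row$rho_alpha,
                 cor(y, x_alpha, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("a gene equal to the covariate correlates perfectly; independent
           genes have uniform p-values", {
  co <- generate_cohort(small_cohort_spec(seed = 52, n_grade2 = 12,
                                          n_grade3 = 12, n_grade4 = 12))
  iso <- co$isoforms
  m <- rbind(unclass(co$expression)[, iso$sample_id],
             self = iso$alpha)
  cc <- correlate_genes(expression_matrix(m, "linear"), iso, "self")
  expect_equal(cc$rho_alpha, 1)
  expect_lt(cc$p_alpha, 1e-20)

  set.seed(53)
  nullco <- generate_cohort(null_cohort_spec(seed = 53, n_genes = 200, n = 15))
  nullcc <- correlate_genes(nullco$expression, nullco$isoforms)
  ks <- ks.test(nullcc$p_alpha, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("sign-pattern classification follows the printed rule and partitions", {
  cc <- data.frame(
    gene_id = c("low", "high", "deltafail", "weak"),
    rho_alpha = c(0.8, -0.8, 0.8, 0.3),
    p_alpha = c(1e-5, 1e-5, 1e-5, 0.2),
    fdr_alpha = c(0.001, 0.001, 0.001, 0.3),
    rho_delta = c(0.01, 0.02, 0.5, 0.01),
    p_delta = c(0.9, 0.8, 0.001, 0.9),
    fdr_delta = c(0.5, 0.5, 0.05, 0.9),
    rho_ratio = c(-0.7, 0.7, -0.7, -0.1),
    p_ratio = c(2e-4, 2e-4, 2e-4, 0.5),
    fdr_ratio = c(0.002, 0.002, 0.002, 0.6),
    stringsAsFactors = FALSE)
  got <- classify_genes(cc)
  expect_equal(got$label,
               c("low-malignant", "high-malignant", "unclassified",
                 "unclassified"))
  expect_true(all(table(got$label) >= 0))
  expect_equal(sum(got$label %in% c("low-malignant", "high-malignant",
                                    "unclassified")), nrow(cc))
})

test_that("|rho| clustering recovers planted blocks and ignores input order", {
  set.seed(54)
  block1 <- data.frame(rho_alpha = runif(6, 0.7, 0.9),
                       rho_delta = runif(6, 0, 0.05),
                       rho_ratio = -runif(6, 0.7, 0.9))
  block2 <- data.frame(rho_alpha = runif(6, 0, 0.1),
                       rho_delta = runif(6, 0, 0.05),
                       rho_ratio = runif(6, 0, 0.1))
  cc <- rbind(block1, block2)
  cc$gene_id <- sprintf("g%02d", 1:12)
  cl <- cluster_abs_correlations(cc)
  groups <- split(names(cl$clusters), cl$clusters)
  expect_setequal(groups[[cl$clusters[["g01"]]]], sprintf("g%02d", 1:6))
  perm <- cc[sample(12), ]
  cl2 <- cluster_abs_correlations(perm)
  expect_equal(cl2$clusters[names(cl$clusters)], cl$clusters)

  twin <- cc[1:3, ]; twin$rho_alpha[2] <- twin$rho_alpha[1]
  twin$rho_delta[2] <- twin$rho_delta[1]; twin$rho_ratio[2] <- twin$rho_ratio[1]
  cl3 <- cluster_abs_correlations(twin)
  expect_equal(cl3$hclust$height[1], 0)  # identical genes merge first
  single <- cluster_abs_correlations(cc[1, ])
  expect_equal(unname(single$clusters), 1L)
})

test_that("within-grade correlations expose grade-restricted structure", {
  # alpha keeps its grade-IV decrease so grade-mean genes correlate pooled
  co <- generate_cohort(small_cohort_spec(
    seed = 55, n_grade2 = 20, n_grade3 = 20, n_grade4 = 20,
    n_null_genes = 5, n_low_malignant = 0, n_high_malignant = 0,
    n_survival_genes = 0,
    survival_n_by_grade = c(II = 20, III = 20, IV = 20)))
  iso <- co$isoforms
  cl <- co$clinical
  grade <- cl$grade[match(iso$sample_id, cl$sample_id)]
  # planted: correlates with alpha within grade III only
  g3 <- log2(iso$alpha + 1)
  y <- rnorm(length(g3), sd = 0.05)
  y[grade == "III"] <- y[grade == "III"] + g3[grade == "III"]
  m <- rbind(unclass(co$expression)[, iso$sample_id],
             only3 = 2^y,
             simpson = 2^(ifelse(grade == "II", 10, ifelse(grade == "III", 8, 6)) +
                            rnorm(length(g3), sd = 0.2)),
             flat = rep(5, length(g3)))
  em <- expression_matrix(m, "linear")
  wg <- within_grade_correlation(em, iso, cl, c("only3", "simpson", "flat"))
  o3 <- wg[wg$gene_id == "only3" & wg$covariate == "alpha", ]
  expect_true(o3$significant[o3$grade == "III"])
  expect_false(any(o3$significant[o3$grade != "III"]))
  # pooled-significant (grade means only) but null within every grade
  pooled <- correlate_genes(em, iso, "simpson")
  expect_lt(pooled$p_alpha, 0.01)
  simp <- wg[wg$gene_id == "simpson" & wg$covariate == "alpha", ]
  expect_false(any(simp$significant))
  # constant gene skipped (absent from the within-grade results)
  expect_false("flat" %in% wg$gene_id)
})
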