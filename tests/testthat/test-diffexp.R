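make_two_group <- function(seed, n_genes = 50, n_per = 4, shift = 0) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 2 * n_per, sd = runif(n_genes, 0.3, 1.5)),
              nrow = n_genes)
  m[, (n_per + 1):(2 * n_per)] <- m[, (n_per + 1):(2 * n_per)] + shift
  rownames(m) <- sprintf("g%03d", seq_len(n_genes))
  colnames(m) <- sprintf("s%02d", seq_len(2 * n_per))
  list(mat = m, design = rep(c("A", "B"), each = n_per))
}

test_that("with prior df 0 the moderated t equals the classical equal-variance t", {
  fx <- make_two_group(31)
  de <- fit_moderated(fx$mat, fx$design, c("A", "B"), d0 = 0)
  classical <- apply(fx$mat, 1, function(y) {
    tt <- t.test(y[fx$design == "B"], y[fx$design == "A"], var.equal = TRUE)
    c(t = unname(tt$statistic), p = tt$p.value)
  })
  expect_lt(max(abs(de$t_moderated - classical["t", ])), 1e-10)
  expect_lt(max(abs(de$p_value - classical["p", ])), 1e-10)
})

test_that("with prior df Inf every posterior variance equals the prior", {
  fx <- make_two_group(32)
  de <- fit_moderated(fx$mat, fx$design, c("A", "B"), d0 = Inf, s2_prior = 0.7)
  mod <- attr(de, "moderation")
  expect_identical(mod$d0, Inf)
  nA <- nB <- 4
  expected_t <- de$log2fc / sqrt(0.7 * (1 / nA + 1 / nB))
  expect_equal(de$t_moderated, expected_t, tolerance = 1e-12)
})

test_that("the vectorized fit matches a gene-by-gene formula oracle", {
  fx <- make_two_group(33)
  de <- fit_moderated(fx$mat, fx$design, c("A", "B"))
  mod <- attr(de, "moderation")
  t_oracle <- oracle_moderated_t(fx$mat, fx$design, c("A", "B"),
                                 mod$d0, mod$s2_prior)
  expect_equal(de$t_moderated, t_oracle, tolerance = 1e-10)
  p_oracle <- 2 * pt(-abs(t_oracle), df = mod$d0 + mod$d_resid)
  expect_equal(de$p_value, p_oracle, tolerance = 1e-10)
})

test_that("the fit agrees with an independent empirical-Bayes implementation", {
  set.seed(34)
  n_genes <- 300; n_per <- 4
  sigma2 <- 0.5 * rf(n_genes, 4 * n_per - 2, 10) # heteroskedastic truth
  m <- matrix(rnorm(n_genes * 2 * n_per, sd = sqrt(rep(sigma2, 2 * n_per))),
              nrow = n_genes)
  dimnames(m) <- list(sprintf("g%03d", 1:n_genes), sprintf("s%02d", 1:(2 * n_per)))
  design <- rep(c("A", "B"), each = n_per)
  de <- fit_moderated(m, design, c("A", "B"))
  mod <- attr(de, "moderation")
  dm <- stats::model.matrix(~ 0 + factor(design, levels = c("A", "B")))
  colnames(dm) <- c("A", "B")
  fit <- limma::lmFit(m, dm)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(B - A, levels = dm))
  eb <- limma::eBayes(fit)
  expect_equal(mod$d0, eb$df.prior, tolerance = 1e-6)
  expect_equal(mod$s2_prior, eb$s2.prior, tolerance = 1e-6)
  expect_equal(de$t_moderated, unname(eb$t[, 1]), tolerance = 1e-8)
  expect_equal(de$p_value, unname(eb$p.value[, 1]), tolerance = 1e-8)
})

test_that("the moment estimator recovers known hyperparameters", {
  set.seed(35)
  s2_true <- 2; d0_true <- 8; d <- 4
  s2 <- s2_true * rf(5000, d, d0_true)
  est <- estimate_moderation(s2, d)
  expect_lt(abs(est$s2_prior - s2_true) / s2_true, 0.1)
  expect_lt(abs(est$d0 - d0_true) / d0_true, 0.1)
  # trigamma inverse is a true inverse
  for (x in c(1e-5, 0.01, 0.5, 2, 50, 1e6))
    expect_equal(trigamma(trigamma_inverse(x)), x, tolerance = 1e-6)
})

test_that("moderated t ranking interpolates between fold-change and t ranking", {
  fx <- make_two_group(36, n_genes = 80)
  de0 <- fit_moderated(fx$mat, fx$design, c("A", "B"), d0 = 0)
  deInf <- fit_moderated(fx$mat, fx$design, c("A", "B"), d0 = Inf,
                         s2_prior = 1)
  expect_equal(order(abs(deInf$t_moderated)), order(abs(deInf$log2fc)))
  de_small <- fit_moderated(fx$mat, fx$design, c("A", "B"), d0 = 1e-9,
                            s2_prior = 1)
  expect_equal(order(abs(de_small$t_moderated)), order(abs(de0$t_moderated)))
})

test_that("patient grade contrasts flag the planted isoform decrease and
           respect the fold-change gate", {
  co <- generate_cohort(small_cohort_spec(seed = 37, n_grade2 = 30,
                                          n_grade3 = 30, n_grade4 = 40))
  iso <- co$isoforms
  cl <- co$clinical[match(iso$sample_id, co$clinical$sample_id), ]
  m <- rbind(unclass(co$expression)[, iso$sample_id],
             GFAPalpha = iso$alpha, GFAPdelta = iso$delta)
  m <- expression_matrix(m, "linear")
  de <- patient_grade_contrast(m, cl, c("II", "IV"))
  row <- de[de$gene_id == "GFAPalpha", ]
  expect_true(row$passes)
  expect_lt(row$log2fc, 0)  # down in grade IV
  drow <- de[de$gene_id == "GFAPdelta", ]
  expect_false(drow$passes)
  expect_error(patient_grade_contrast(m, cl[cl$grade != "II", ], c("II", "IV")),
               "grade absent")

  # small p but linear FC 1.4: fails on the fold-change gate
  set.seed(38)
  n <- 20
  tiny <- rbind(gate = c(rnorm(n, 8, 0.01), rnorm(n, 8 + log2(1.4), 0.01)),
                filler = rnorm(2 * n))
  colnames(tiny) <- sprintf("s%02d", 1:(2 * n))
  de2 <- fit_moderated(tiny, rep(c("A", "B"), each = n), c("A", "B"))
  g <- de2[de2$gene_id == "gate", ]
  expect_lt(g$fdr, 0.1)
  expect_lt(g$abs_linear_fc, 1.5)
  expect_false(g$passes)
})

test_that("null genes pass the DE gates at no more than the nominal rate", {
  co <- generate_cohort(null_cohort_spec(seed = 39, n_genes = 300, n = 25))
  de <- patient_grade_contrast(co$expression, co$clinical, c("II", "IV"))
  expect_lte(mean(de$passes), 0.1 + 0.03)
})

test_that("qPCR validation correlation matches rank-permutation enumeration", {
  expect_equal(validate_against_qpcr(c(1, 2, 3), c(2, 4, 6))$rho, 1)
  expect_equal(validate_against_qpcr(c(1, 2, 3), c(3, 1, 0))$rho, -1)
  set.seed(40)
  for (i in 1:5) {
    x <- sample(100, 5); y <- sample(100, 5)
    got <- validate_against_qpcr(x, y)
    expect_equal(got$p_value, oracle_spearman_exact(x, y), tolerance = 1e-12,
                 info = paste("iter", i))
  }
  expect_warning(r <- validate_against_qpcr(rep(1, 4), c(1, 2, 3, 4)),
                 "constant")
  expect_true(is.na(r$rho))
})
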