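test_that("sim_config validates its domains", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.6, 0.7)), "maf_range")
  expect_error(sim_config(ld_decay = 1), "ld_decay")
  expect_error(sim_config(eqtl_r2 = 1), "eqtl_r2")
  expect_error(sim_config(copula_theta = 0.9), "copula_theta")
  # phi > 0 solving tau = 1 - 2/(theta(phi+2)) needs tau > 1 - 1/theta
  expect_error(sim_config(tau = 0.3, copula_theta = 2), "tau")
  expect_s3_class(sim_config(tau = 0.6, copula_theta = 2), "sim_config")
})

test_that("genotypes are independent across SNVs when ld_decay = 0", {
  cfg <- quick_cfg(n_samples = 10000, n_genes = 1, n_snvs_per_gene = 6,
                   ld_decay = 0)
  g <- simulate_genotypes(cfg)
  cors <- cor(t(g$genotypes))
  expect_lt(mean(abs(cors[upper.tri(cors)])), 0.1)
})

test_that("adjacent-SNV genotype correlation matches the enumerated haplotype model", {
  # two adjacent SNVs with equal maf p and allele correlation r: enumerate
  # the haplotype joint, convolve two independent haplotypes into the 9
  # genotype combinations, and compute the implied Pearson correlation
  p <- 0.3; r <- 0.95
  p11 <- p^2 + r * p * (1 - p)
  hap <- matrix(c(1 - 2 * p + p11, p - p11, p - p11, p11), 2,
                dimnames = list(a = 0:1, b = 0:1))
  geno <- matrix(0, 3, 3)
  for (a1 in 0:1) for (b1 in 0:1) for (a2 in 0:1) for (b2 in 0:1)
    geno[a1 + a2 + 1, b1 + b2 + 1] <- geno[a1 + a2 + 1, b1 + b2 + 1] +
      hap[a1 + 1, b1 + 1] * hap[a2 + 1, b2 + 1]
  gv <- 0:2
  eg <- sum(gv * rowSums(geno))
  vg <- sum(gv^2 * rowSums(geno)) - eg^2
  egh <- sum(outer(gv, gv) * geno)
  rho_expected <- (egh - eg^2) / vg
  expect_equal(rho_expected, r, tolerance = 1e-12) # model is attenuation-free

  cfg <- quick_cfg(n_samples = 50000, n_genes = 1, n_snvs_per_gene = 2,
                   maf_range = c(p, p), ld_decay = r, seed = 5)
  g <- simulate_genotypes(cfg)
  expect_equal(cor(g$genotypes[1, ], g$genotypes[2, ]), rho_expected,
               tolerance = 0.05)
})

test_that("genotype mean is 2 * maf (symmetry at maf = 0.5)", {
  cfg <- quick_cfg(n_samples = 100000, n_genes = 1, n_snvs_per_gene = 3,
                   maf_range = c(0.5, 0.5), seed = 6)
  g <- simulate_genotypes(cfg)
  expect_equal(unname(rowMeans(g$genotypes)), rep(1, 3), tolerance = 0.02)
})

test_that("cis SNVs explain the configured share of expression variance", {
  cfg <- quick_cfg(n_samples = 10000, n_genes = 2, eqtl_r2 = 0.10, seed = 7)
  g <- simulate_genotypes(cfg)
  e <- simulate_expression(g$genotypes, g$snv_meta, cfg)
  for (gn in rownames(e$latent)) {
    G <- g$genotypes[g$snv_meta$gene_id == gn, ]
    r2 <- summary(lm(e$latent[gn, ] ~ t(G)))$r.squared
    expect_lt(abs(r2 - 0.10), 0.02)
  }
  # independence when eqtl_r2 = 0
  cfg0 <- quick_cfg(n_samples = 1000, n_genes = 1, eqtl_r2 = 0, seed = 8)
  g0 <- simulate_genotypes(cfg0)
  e0 <- simulate_expression(g0$genotypes, g0$snv_meta, cfg0)
  r2_0 <- summary(lm(e0$latent[1, ] ~ t(g0$genotypes)))$r.squared
  expect_lt(r2_0, 0.05)
  # noiseless limit
  cfg1 <- quick_cfg(n_samples = 500, n_genes = 1, eqtl_r2 = 1 - 1e-9, seed = 9)
  g1 <- simulate_genotypes(cfg1)
  e1 <- simulate_expression(g1$genotypes, g1$snv_meta, cfg1)
  r2_1 <- summary(lm(e1$latent[1, ] ~ t(g1$genotypes)))$r.squared
  expect_equal(r2_1, 1, tolerance = 1e-6)
})

test_that("expression counts are non-negative and the eQTL fixture has GTEx columns", {
  co <- quick_cohort()
  expect_true(all(co$expression >= 0))
  expect_true(all(c("variant_id", "gene_id", "tss_distance", "maf",
                    "pval_nominal", "slope", "slope_se") %in% names(co$eqtl)))
})

test_that("covariates reproduce the emulated cohort profile", {
  cv <- simulate_covariates(100000, seed = 10)
  expect_equal(mean(cv$sex == "woman"), 0.55, tolerance = 0.01)
  expect_equal(mean(cv$age[cv$sex == "woman"]), 62.7, tolerance = 0.1)
  expect_equal(mean(cv$age[cv$sex == "man"]), 66.9, tolerance = 0.1)
  expect_equal(mean(cv$smoking[cv$sex == "woman"] == "never"),
               54.5 / 99.9, tolerance = 0.01)
  cv1 <- simulate_covariates(1, seed = 11)
  expect_identical(nrow(cv1), 1L)
  expect_false(anyNA(cv1))
})

test_that("phenotype residual dependence hits the target Kendall's tau", {
  cfg <- quick_cfg(n_samples = 5000, n_genes = 2, tau = 0.36, seed = 12)
  co <- simulate_cohort(cfg)
  res <- attr(co$phenotypes, "residuals")
  expect_equal(kendall_tau(res[, "eps1"], res[, "eps2"]), 0.36,
               tolerance = 0.03)
})

test_that("phenotypes are physiologically coherent and clipping warns when extreme", {
  co <- quick_cohort(n_samples = 2000)
  expect_true(all(co$phenotypes$SAT > 0))
  expect_true(all(co$phenotypes$SAT < co$phenotypes$TAT))
  ratio <- co$phenotypes$SAT / co$phenotypes$TAT
  expect_true(all(ratio > 0 & ratio < 1))
  cfg_big <- quick_cfg(n_samples = 500, sigma_ratio = 0.5)
  expect_warning(simulate_cohort(cfg_big), "clipped")
})

test_that("null generator yields uniform association p-values", {
  cfg <- quick_cfg(n_samples = 200, n_genes = 500, beta_sat = 0,
                   beta_ratio = 0, n_causal_sat = 0, n_causal_ratio = 0,
                   causal_overlap = 0, seed = 13)
  co <- simulate_cohort(cfg)
  pre <- preprocess_cohort(co, lengths = co$gene_meta$length)
  scr <- linear_screen(pre)
  expect_gt(ks.test(scr$p_sat, "punif")$p.value, 0.01)
  expect_gt(ks.test(scr$p_ratio, "punif")$p.value, 0.01)
})

test_that("identical seeds give bit-identical cohorts", {
  a <- quick_cohort(seed = 99)
  b <- quick_cohort(seed = 99)
  expect_identical(a, b)
  c2 <- quick_cohort(seed = 100)
  expect_false(identical(a$expression, c2$expression))
})

test_that("replication cohort reuses the architecture with an availability mask", {
  co <- quick_cohort(n_samples = 100)
  cb <- simulate_replication_cohort(co, n_samples = 300, avail_prob = 0.5,
                                    seed = 7)
  expect_identical(ncol(cb$genotypes), 300L)
  expect_true(all(rownames(cb$genotypes) %in% co$snv_meta$variant_id))
  expect_lt(nrow(cb$genotypes), nrow(co$genotypes))
  expect_true(all(c("aSAT", "VAT") %in% names(cb$phenotypes)))
  expect_true(all(cb$phenotypes$aSAT > 0 & cb$phenotypes$VAT > 0))
  ratio <- cb$phenotypes$aSAT / (cb$phenotypes$aSAT + cb$phenotypes$VAT)
  expect_true(all(ratio > 0 & ratio < 1))
})
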