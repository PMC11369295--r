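test_that("weights are recovered exactly from noiseless linear expression", {
  set.seed(1)
  n <- 60
  G <- rbind(v1 = rbinom(n, 2, 0.3), v2 = rbinom(n, 2, 0.4))
  expr <- 2 + 0.3 * G["v1", ] + 0.1 * G["v2", ]
  m <- learn_weights(expr, G, gene = "g1")
  expect_equal(unname(m$weights), c(0.3, 0.1), tolerance = 1e-9)
  expect_equal(m$intercept, 2, tolerance = 1e-9)
  expect_equal(m$r2, 1, tolerance = 1e-9)
  expect_identical(m$dropped, character())
})

test_that("joint weights equal univariate slopes for orthogonal genotypes and the single-SNV slope", {
  set.seed(2)
  n <- 500
  g1 <- rnorm(n); g2 <- rnorm(n)
  g2 <- residuals(lm(g2 ~ g1))          # exactly orthogonal after centering
  g1 <- g1 - mean(g1)
  G <- rbind(v1 = g1, v2 = g2)
  expr <- 0.5 * g1 - 0.2 * g2 + rnorm(n)
  m <- learn_weights(expr, G)
  expect_equal(unname(m$weights["v1"]), cov(g1, expr) / var(g1),
               tolerance = 1e-9)
  expect_equal(unname(m$weights["v2"]), cov(g2, expr) / var(g2),
               tolerance = 1e-9)
  m1 <- learn_weights(expr, G[1, , drop = FALSE])
  expect_equal(unname(m1$weights), unname(coef(lm(expr ~ g1))[2]),
               tolerance = 1e-9)
})

test_that("collinear SNVs are dropped to a full-rank subset", {
  set.seed(3)
  n <- 80
  g <- rbinom(n, 2, 0.4)
  G <- rbind(v1 = g, v2 = g, v3 = rbinom(n, 2, 0.3))
  expr <- 0.4 * g + rnorm(n)
  m <- learn_weights(expr, G)
  expect_identical(m$dropped, "v2")
  expect_setequal(names(m$weights), c("v1", "v3"))
})

test_that("imputation applies discovery weights to available SNVs only", {
  G_train <- rbind(v1 = c(0, 1, 2, 1, 0, 2), v2 = c(2, 1, 0, 1, 2, 1),
                   v3 = c(1, 1, 0, 2, 0, 1))
  expr <- c(1.2, 1.5, 0.9, 2.0, 0.8, 1.6)
  m <- learn_weights(expr, G_train)
  # full availability on the training cohort reproduces the fitted values
  imp_full <- impute_expression(m, G_train)
  fitted <- m$intercept + drop(crossprod(G_train, m$weights))
  expect_equal(imp_full$score, fitted, tolerance = 1e-12)
  expect_identical(imp_full$n_var_available, 3L)
  expect_equal(imp_full$r2_available, m$r2, tolerance = 1e-12)
  # half the SNVs masked: hand-computed restricted combination
  G_b <- rbind(v1 = c(2, 0, 1), v3 = c(0, 1, 2))
  imp <- impute_expression(m, G_b)
  hand <- m$intercept + m$weights["v1"] * G_b["v1", ] +
    m$weights["v3"] * G_b["v3", ]
  expect_equal(imp$score, unname(hand), tolerance = 1e-12)
  expect_identical(imp$n_var_available, 2L)
  # restricting availability cannot increase explained variance
  expect_lte(imp$r2_available, m$r2 + 1e-12)
  imp1 <- impute_expression(m, G_b[1, , drop = FALSE])
  expect_lte(imp1$r2_available, imp$r2_available + 1e-12)
  # all genotypes zero -> intercept everywhere
  G_z <- rbind(v1 = c(0, 0), v2 = c(0, 0), v3 = c(0, 0))
  expect_equal(impute_expression(m, G_z)$score, rep(m$intercept, 2))
  # no available SNV -> NULL
  expect_null(impute_expression(m, rbind(zz = c(0, 1))))
})

test_that("imputation is linear: scores interpolate between genotype profiles", {
  set.seed(4)
  G <- rbind(v1 = rbinom(30, 2, .4), v2 = rbinom(30, 2, .3))
  m <- learn_weights(0.3 * G[1, ] - 0.1 * G[2, ] + rnorm(30), G)
  gA <- c(2, 0); gB <- c(0, 2)
  mix <- 0.3 * gA + 0.7 * gB
  sc <- impute_expression(m, cbind(a = gA, b = gB, mix = mix) |>
                            (\(x) {rownames(x) <- c("v1", "v2"); x})())
  expect_equal(sc$score[["mix"]],
               0.3 * sc$score[["a"]] + 0.7 * sc$score[["b"]],
               tolerance = 1e-12)
})

test_that("replication test recovers an engineered score effect and guards degeneracy", {
  set.seed(5)
  n <- 4904
  covars <- simulate_covariates(n, seed = 5)
  score <- rnorm(n)
  y <- 3 + 0.2 * score + 0.003 * (covars$age - 64) + rnorm(n, sd = 0.4)
  r <- replication_test(score, y, covars)
  expect_equal(r$beta, 0.2, tolerance = 3 * r$se)
  expect_lt(r$p, 1e-10)
  expect_error(replication_test(rep(1, n), y, covars), "constant")
  expect_error(replication_test(score, rep(0.5, n), covars), "constant")
})

test_that("permuted scores give uniform replication p-values", {
  set.seed(6)
  n <- 300
  covars <- simulate_covariates(n, seed = 6)
  score <- rnorm(n)
  y <- 3 + 0.01 * (covars$age - 64) + rnorm(n, sd = 0.3)
  ps <- replicate(400, replication_test(sample(score), y, covars)$p)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("replication pipeline confirms covered causal genes end-to-end", {
  # strong effects and instruments so every covered causal gene confirms
  cfg <- quick_cfg(n_samples = 800, n_genes = 6, n_snvs_per_gene = 6,
                   n_causal_sat = 2, n_causal_ratio = 2, causal_overlap = 0,
                   eqtl_r2 = 0.3, beta_sat = 0.25, beta_ratio = 0.03,
                   seed = 60)
  co <- simulate_cohort(cfg)
  pre <- preprocess_cohort(co, lengths = co$gene_meta$length)
  assoc <- data.frame(gene = co$gene_meta$gene_id,
                      significant_sat = co$gene_meta$causal_sat,
                      significant_ratio = co$gene_meta$causal_ratio)
  mr <- mr_screen(assoc, co$eqtl, pre)
  cb <- simulate_replication_cohort(co, n_samples = 3000, avail_prob = 1,
                                    seed = 61)
  # sever coverage for one causal gene entirely
  sat_genes <- co$gene_meta$gene_id[co$gene_meta$causal_sat]
  drop_gene <- sat_genes[1]
  keep <- co$snv_meta$gene_id[match(rownames(cb$genotypes),
                                    co$snv_meta$variant_id)] != drop_gene
  cb$genotypes <- cb$genotypes[keep, , drop = FALSE]
  rep_res <- replication_pipeline(mr, pre, cb)
  covered_causal <- setdiff(mr$gene[mr$causal], drop_gene)
  expect_setequal(rep_res$gene, covered_causal)
  expect_false(drop_gene %in% rep_res$gene)
  cnt <- attr(rep_res, "counts")
  expect_identical(unname(cnt["investigated"]), length(covered_causal))
  # alpha = 1 confirms everything investigated
  rep_all <- replication_pipeline(mr, pre, cb, alpha = 1)
  expect_identical(unname(attr(rep_all, "counts")["confirmed"]),
                   unname(attr(rep_all, "counts")["investigated"]))
})
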