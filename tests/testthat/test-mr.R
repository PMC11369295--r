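test_that("single-SNV IVW is exactly the Wald ratio", {
  r <- ivw_correlated(inst_set(0.5, 0.25, 0.1, 0.1), "first_order")
  expect_identical(r$theta, 0.5)
  expect_identical(r$n_var, 1L)
})

test_that("uncorrelated first-order IVW equals the classic closed form", {
  set.seed(1)
  m <- 6
  bx <- rnorm(m, 0.3, 0.1); by <- rnorm(m, 0.15, 0.05)
  se_by <- runif(m, 0.02, 0.1)
  r <- ivw_correlated(inst_set(bx, by, runif(m, 0.01, 0.05), se_by),
                      "first_order")
  classic <- sum(bx * by / se_by^2) / sum(bx^2 / se_by^2)
  expect_equal(r$theta, classic, tolerance = 1e-12)
  expect_equal(r$se, sqrt(1 / sum(bx^2 / se_by^2)), tolerance = 1e-12)
})

test_that("correlated first-order IVW matches a brute-force GLS solve", {
  set.seed(2)
  m <- 5
  bx <- rnorm(m, 0.4, 0.1); by <- rnorm(m, 0.2, 0.05)
  se_by <- runif(m, 0.02, 0.08)
  A <- matrix(rnorm(m * m), m); S <- cov2cor(crossprod(A) + diag(m))
  r <- ivw_correlated(inst_set(bx, by, runif(m, 0.01, 0.05), se_by, rho = S),
                      "first_order")
  omega <- S * (se_by %o% se_by)
  oi <- solve(omega)
  theta_gls <- drop(t(bx) %*% oi %*% by) / drop(t(bx) %*% oi %*% bx)
  expect_equal(r$theta, theta_gls, tolerance = 1e-10)
  expect_equal(r$se, sqrt(1 / drop(t(bx) %*% oi %*% bx)), tolerance = 1e-10)
})

test_that("delta weights reduce exactly to first order when se_bx = 0 and psi = 0", {
  set.seed(3)
  m <- 4
  bx <- rnorm(m, 0.3, 0.1); by <- rnorm(m, 0.12, 0.03)
  se_by <- runif(m, 0.02, 0.06)
  A <- matrix(rnorm(m * m), m); S <- cov2cor(crossprod(A) + diag(m))
  i0 <- inst_set(bx, by, rep(0, m), se_by, rho = S, psi = 0)
  expect_equal(ivw_correlated(i0, "delta")$theta,
               ivw_correlated(i0, "first_order")$theta, tolerance = 1e-14)
  expect_equal(ivw_correlated(i0, "delta")$se,
               ivw_correlated(i0, "first_order")$se, tolerance = 1e-14)
  # with exposure uncertainty the delta SE is wider at psi = 0
  i1 <- inst_set(bx, by, rep(0.05, m), se_by, rho = S, psi = 0)
  expect_gt(ivw_correlated(i1, "delta")$se, ivw_correlated(i1, "first_order")$se)
})

test_that("delta-weight variance matches the delta-method ratio variance for one SNV", {
  bx <- 0.5; by <- 0.2; se_bx <- 0.08; se_by <- 0.05; psi <- 0.3
  r <- ivw_correlated(inst_set(bx, by, se_bx, se_by, psi = psi), "delta")
  theta0 <- by / bx
  var_ratio <- (se_by^2 + theta0^2 * se_bx^2 - 2 * theta0 * psi * se_bx * se_by) /
    bx^2
  expect_equal(r$se^2, var_ratio, tolerance = 1e-12)
})

test_that("delta SE tracks the parametric-bootstrap sampling SD on a fixed fixture", {
  # fixed genotypes and true parameters; regenerate expression and outcome
  # many times, each time computing the per-SNV summary statistics and the
  # delta-weight IVW estimate; the mean reported SE must match the
  # empirical SD of the estimates
  set.seed(9)
  n <- 1000; m <- 4; theta_true <- 0.3
  cfg <- sim_config(n_samples = n, n_genes = 1, n_snvs_per_gene = m,
                    maf_range = c(0.3, 0.3), ld_decay = 0.4, eqtl_r2 = 0.15,
                    n_causal_sat = 1, n_causal_ratio = 1, causal_overlap = 1,
                    seed = 9)
  g <- simulate_genotypes(cfg)
  G <- g$genotypes
  w_true <- rnorm(m); gen <- drop(crossprod(G, w_true))
  w_true <- w_true * sqrt(0.15 / var(gen))
  gen <- drop(crossprod(G, w_true))
  rho <- cor(t(G))
  X1 <- cbind(1, t(G))
  est <- ses <- numeric(400)
  for (b in seq_len(400)) {
    x <- gen + rnorm(n, sd = sqrt(0.85))
    y <- theta_true * x + rnorm(n, sd = 1)
    bx <- se_bx <- by <- se_by <- numeric(m)
    for (i in seq_len(m)) {
      Xi <- cbind(1, G[i, ])
      cs <- adipocop:::lm_coef(x, Xi, 2)
      bx[i] <- cs[1]; se_bx[i] <- cs[2]
      cs <- adipocop:::lm_coef(y, Xi, 2)
      by[i] <- cs[1]; se_by[i] <- cs[2]
    }
    inst <- inst_set(bx, by, se_bx, se_by, rho = rho, psi = cor(x, y))
    r <- ivw_correlated(inst, "delta")
    est[b] <- r$theta; ses[b] <- r$se
  }
  expect_equal(mean(est), theta_true, tolerance = 0.02)
  expect_equal(mean(ses), sd(est), tolerance = 0.15)
})

test_that("IVW is scale equivariant in the outcome", {
  set.seed(4)
  m <- 5
  bx <- rnorm(m, 0.3, 0.1); by <- rnorm(m, 0.2, 0.05)
  se_bx <- runif(m, 0.01, 0.05); se_by <- runif(m, 0.02, 0.06)
  A <- matrix(rnorm(m * m), m); S <- cov2cor(crossprod(A) + diag(m))
  for (w in c("first_order", "delta")) {
    r1 <- ivw_correlated(inst_set(bx, by, se_bx, se_by, rho = S, psi = 0.2), w)
    r2 <- ivw_correlated(inst_set(bx, 3 * by, se_bx, 3 * se_by, rho = S,
                                  psi = 0.2), w)
    expect_equal(r2$theta, 3 * r1$theta, tolerance = 1e-10)
    expect_equal(r2$p, r1$p, tolerance = 1e-10)
  }
})

test_that("instrument filters drop confounded and duplicated SNVs as designed", {
  # 3 eQTL SNVs: v2 engineered to determine a confounder (sex), v3 a copy
  # of v1 (Spearman rho = 1) -> survivors are exactly v1 (and not v2, v3)
  set.seed(5)
  n <- 400
  g1 <- rbinom(n, 2, 0.4)
  g3 <- g1
  sex <- factor(sample(c("woman", "man"), n, TRUE), levels = c("woman", "man"))
  g2 <- as.integer(sex == "man") + rbinom(n, 1, 0.05)
  covars <- data.frame(sex = sex, age = rnorm(n, 64, 8))
  expr <- 0.4 * g1 + rnorm(n)
  y1 <- 0.3 * expr + rnorm(n)
  geno <- rbind(v1 = g1, v2 = g2, v3 = g3)
  colnames(geno) <- sprintf("S%03d", 1:n)
  cohort <- list(
    genotypes = geno,
    expression_yj = matrix(expr, 1, dimnames = list("gene1", NULL)),
    analysis = data.frame(y1 = y1, y2 = rnorm(n)),
    covariates = covars)
  eqtl <- data.frame(variant_id = c("v1", "v2", "v3"), gene_id = "gene1",
                     pval_nominal = c(1e-8, 1e-3, 1e-8), pos = 1:3)
  inst <- select_instruments("gene1", eqtl, cohort, outcome = "sat")
  expect_identical(inst$snv_ids, "v1")
  # an SNV absent from the eQTL table never enters
  eqtl_v1 <- eqtl[eqtl$variant_id == "v1", ]
  inst2 <- select_instruments("gene1", eqtl_v1, cohort, outcome = "sat")
  expect_identical(inst2$snv_ids, "v1")
  # weakly correlated SNVs make pruning a no-op
  set.seed(6)
  geno3 <- rbind(v1 = rbinom(n, 2, 0.3), v2 = rbinom(n, 2, 0.4),
                 v3 = rbinom(n, 2, 0.2))
  cors <- cor(t(geno3), method = "spearman")
  expect_true(all(abs(cors[upper.tri(cors)]) < 0.9))
  cohort3 <- cohort
  cohort3$genotypes <- geno3
  cohort3$expression_yj[1, ] <- 0.3 * colSums(geno3) + rnorm(n)
  inst3 <- select_instruments("gene1", eqtl, cohort3, outcome = "sat")
  expect_identical(sort(inst3$snv_ids), c("v1", "v2", "v3"))
})

test_that("surviving sets never contain a pair above the pruning threshold", {
  set.seed(7)
  for (rep in 1:5) {
    co <- quick_cohort(n_samples = 150, n_genes = 3, n_snvs_per_gene = 8,
                       ld_decay = 0.97, seed = 100 + rep)
    pre <- preprocess_cohort(co, lengths = co$gene_meta$length)
    gene <- co$gene_meta$gene_id[1]
    inst <- select_instruments(gene, co$eqtl, pre, outcome = "sat")
    if (is.null(inst) || length(inst$snv_ids) < 2) next
    G <- co$genotypes[inst$snv_ids, ]
    sp <- cor(t(G), method = "spearman")
    expect_true(all(abs(sp[upper.tri(sp)]) <= 0.9))
    # determinism
    inst_b <- select_instruments(gene, co$eqtl, pre, outcome = "sat")
    expect_identical(inst$snv_ids, inst_b$snv_ids)
  }
})

test_that("mr_screen recovers an engineered causal effect and reports counts", {
  d <- sim_mr_dataset(2000, r2 = 0.2, theta_true = 0.4, seed = 8)
  assoc <- data.frame(gene = d$gene, significant_sat = TRUE,
                      significant_ratio = FALSE)
  mr <- mr_screen(assoc, d$eqtl, d$cohort)
  expect_identical(mr$gene, d$gene)
  expect_true(mr$causal[1])
  expect_equal(mr$theta[1], 0.4, tolerance = 3 * mr$se[1])
  cnt <- attr(mr, "counts")
  expect_identical(cnt$tested[cnt$outcome == "sat"], 1L)
  expect_identical(cnt$analyzable[cnt$outcome == "sat"], 1L)
  # empty association set
  mr0 <- mr_screen(assoc[0, ], d$eqtl, d$cohort)
  expect_identical(nrow(mr0), 0L)
  expect_identical(sum(attr(mr0, "counts")$tested), 0L)
})
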