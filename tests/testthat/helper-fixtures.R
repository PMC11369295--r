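# shared builders for small synthetic objects used across test files

quick_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_samples = 160, n_genes = 12, n_snvs_per_gene = 6,
                   n_causal_sat = 2, n_causal_ratio = 2, causal_overlap = 1,
                   frac_low_expressed = 0, seed = 42)
  merged <- utils::modifyList(defaults, args)
  # shrink the default causal sets for tiny gene panels
  if (!any(c("n_causal_sat", "n_causal_ratio", "causal_overlap") %in%
           names(args)) && merged$n_genes < 3) {
    merged$n_causal_sat <- merged$n_causal_ratio <- merged$causal_overlap <- 1
  }
  do.call(sim_config, merged)
}

quick_cohort <- function(...) simulate_cohort(quick_cfg(...))

# covariate-free bivariate data from the generative model; returns the
# pieces a fit needs
bb1_gaussian_data <- function(n, beta1 = 0, beta2 = 0, phi = 1.125,
                              theta = 1, s1 = 0.25, s2 = 0.06, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  e <- rnorm(n)
  uu <- sample_bb1(n, phi, theta)
  y1 <- 3 + beta1 * e + qnorm(uu[, 1]) * s1
  y2 <- 0.8 + beta2 * e + qnorm(uu[, 2]) * s2
  list(y1 = y1, y2 = y2, X = cbind(`(Intercept)` = 1, expr = e))
}

# 64-point tensor Gauss-Legendre nodes/weights on (0,1)
gauss_legendre_01 <- function(n = 64) {
  j <- seq_len(n - 1)
  b <- j / sqrt(4 * j^2 - 1)
  A <- matrix(0, n, n)
  A[cbind(j, j + 1)] <- b
  A[cbind(j + 1, j)] <- b
  e <- eigen(A, symmetric = TRUE)
  list(x = (e$values + 1) / 2, w = e$vectors[1, ]^2)
}

# minimal instrument_set builder for the IVW oracles
inst_set <- function(bx, by, se_bx, se_by, rho = NULL, psi = 0, gene = "g",
                     r2 = 0.1) {
  m <- length(bx)
  structure(list(gene = gene, outcome = "sat", snv_ids = sprintf("v%d", 1:m),
                 bx = bx, se_bx = se_bx, by = by, se_by = se_by,
                 rho = if (is.null(rho)) diag(m) else rho, psi_mr = psi,
                 r2 = r2, genotypes = NULL), class = "instrument_set")
}

# one-gene cohort for MR simulations: genotypes -> expression (share r2 of
# variance) -> outcome with causal effect theta_true; age is the only
# covariate so the instrument filters stay in the linear-regression path
sim_mr_dataset <- function(n, m_snvs = 5, r2 = 0.2, theta_true = 0.4,
                           maf = 0.3, ld = 0.3, seed = 1) {
  set.seed(seed)
  cfg <- sim_config(n_samples = n, n_genes = 1, n_snvs_per_gene = m_snvs,
                    maf_range = c(maf, maf), ld_decay = ld, eqtl_r2 = r2,
                    n_causal_sat = 1, n_causal_ratio = 1, causal_overlap = 1,
                    seed = seed)
  g <- simulate_genotypes(cfg)
  e <- simulate_expression(g$genotypes, g$snv_meta, cfg)
  expr <- e$latent[1, ]
  age <- rnorm(n, 64, 8)
  y1 <- 3 + theta_true * expr + 0.003 * (age - 64) + rnorm(n, sd = 1)
  cohort <- list(
    genotypes = g$genotypes,
    expression_yj = e$latent,
    analysis = data.frame(y1 = y1, y2 = rnorm(n, 0.8, 0.06)),
    covariates = data.frame(age = age))
  list(cohort = cohort, eqtl = e$eqtl, gene = rownames(e$latent)[1])
}

# independent two-sided Fisher p by full enumeration of the hypergeometric
# support (the oracle for fisher_enrichment)
fisher_p_enum <- function(a, b, c, d) {
  k <- a + b          # study size
  m <- a + c          # term size
  N <- a + b + c + d
  support <- max(0, k + m - N):min(k, m)
  probs <- dhyper(support, m, N - m, k)
  p_obs <- dhyper(a, m, N - m, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
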