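#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the discovery setting the pipeline is designed for: a
#' cohort of 160 adults with subcutaneous-adipose-tissue expression, RNA-seq
#' derived genotypes, and MRI fat phenotypes whose residual dependence has
#' Kendall's tau 0.36, with cis instruments explaining on average 10% of
#' expression variance.
#'
#' @param n_samples cohort size (default 160).
#' @param n_genes number of simulated genes.
#' @param n_snvs_per_gene cis SNVs per gene block.
#' @param maf_range minor-allele-frequency range, in (0, 0.5].
#' @param ld_decay adjacent-SNV haplotype correlation in `[0, 1)` (AR(1)
#'   style blocks).
#' @param eqtl_r2 expected fraction of expression variance explained by the
#'   gene's cis SNVs, in `[0, 1)`.
#' @param beta_sat effect of one causal gene's expression (per 1 SD of the
#'   latent expression) on log SAT (log-kg).
#' @param beta_ratio effect on SAT/TAT (ratio units per 1 SD).
#' @param tau target Kendall's tau of the phenotype residual dependence.
#' @param copula_theta Gumbel-like BB1 parameter theta >= 1; phi is solved
#'   from `tau` (which requires `tau > 1 - 1/theta`).
#' @param n_causal_sat,n_causal_ratio number of genes with a real effect on
#'   each phenotype.
#' @param causal_overlap how many causal genes affect both phenotypes.
#' @param frac_low_expressed fraction of genes simulated at very low
#'   abundance (removed by the 25% expression filter downstream).
#' @param sigma_sat residual SD of log SAT (log-kg scale).
#' @param sigma_ratio residual SD of SAT/TAT.
#' @param seed integer seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 160, n_genes = 200, n_snvs_per_gene = 12,
                       maf_range = c(0.1, 0.5), ld_decay = 0.5,
                       eqtl_r2 = 0.10, beta_sat = 0.12, beta_ratio = 0.02,
                       tau = 0.36, copula_theta = 1,
                       n_causal_sat = 8, n_causal_ratio = 8,
                       causal_overlap = 3, frac_low_expressed = 0.1,
                       sigma_sat = 0.25, sigma_ratio = 0.06, seed = 1) {
  stopifnot(n_samples >= 1, n_genes >= 0, n_snvs_per_gene >= 1)
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair in (0, 0.5]")
  if (ld_decay < 0 || ld_decay >= 1) stop("ld_decay must lie in [0, 1)")
  if (eqtl_r2 < 0 || eqtl_r2 >= 1) stop("eqtl_r2 must lie in [0, 1)")
  if (copula_theta < 1) stop("copula_theta must be >= 1")
  if (tau <= 1 - 1 / copula_theta || tau >= 1)
    stop(sprintf("tau must lie in (%g, 1) for copula_theta = %g so that phi > 0 exists",
                 1 - 1 / copula_theta, copula_theta))
  if (n_causal_sat + n_causal_ratio - causal_overlap > n_genes)
    stop("more causal genes than simulated genes")
  if (causal_overlap > min(n_causal_sat, n_causal_ratio))
    stop("causal_overlap exceeds a causal set size")
  structure(list(
    n_samples = n_samples, n_genes = n_genes,
    n_snvs_per_gene = n_snvs_per_gene, maf_range = maf_range,
    ld_decay = ld_decay, eqtl_r2 = eqtl_r2, beta_sat = beta_sat,
    beta_ratio = beta_ratio, tau = tau, copula_theta = copula_theta,
    n_causal_sat = n_causal_sat, n_causal_ratio = n_causal_ratio,
    causal_overlap = causal_overlap, frac_low_expressed = frac_low_expressed,
    sigma_sat = sigma_sat, sigma_ratio = sigma_ratio,
    seed = as.integer(seed)), class = "sim_config")
}

# one haplotype block: Markov chain on alleles with exact marginals maf[j]
# and adjacent-allele correlation r (clipped where the joint would leave
# the probability simplex)
sim_haplotypes <- function(n_hap, maf, r) {
  m <- length(maf)
  H <- matrix(0L, m, n_hap)
  H[1, ] <- as.integer(runif(n_hap) < maf[1])
  if (m > 1) for (j in 2:m) {
    p_prev <- maf[j - 1]; p <- maf[j]
    p11 <- p_prev * p + r * sqrt(p_prev * (1 - p_prev) * p * (1 - p))
    p11 <- min(max(p11, max(0, p_prev + p - 1)), min(p_prev, p))
    cond1 <- p11 / p_prev
    cond0 <- (p - p11) / (1 - p_prev)
    prev <- H[j - 1, ] == 1L
    H[j, ] <- as.integer(runif(n_hap) < ifelse(prev, cond1, cond0))
  }
  H
}

#' Simulate genotypes in cis blocks with AR(1)-style LD
#'
#' Each gene gets a block of `n_snvs_per_gene` SNVs. Haplotype alleles
#' follow a first-order Markov chain with adjacent-allele correlation
#' `ld_decay` and per-SNV frequencies drawn from `maf_range`; genotypes are
#' the sum of two independent haplotypes (Hardy-Weinberg sampling).
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` (SNVs x samples, values 0/1/2) and
#'   `snv_meta` (snv id, chrom, pos, ref, alt, maf, gene id).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  m <- cfg$n_snvs_per_gene
  bases <- c("A", "C", "G", "T")
  geno <- vector("list", cfg$n_genes)
  meta <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    G <- sim_haplotypes(2 * n, maf, cfg$ld_decay)
    G <- G[, seq_len(n), drop = FALSE] + G[, n + seq_len(n), drop = FALSE]
    chrom <- (g - 1L) %% 22L + 1L
    pos <- 1e6L * g + 100L * seq_len(m)
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    ids <- sprintf("chr%d_%d_%s_%s_b38", chrom, pos, ref, alt)
    rownames(G) <- ids
    geno[[g]] <- G
    meta[[g]] <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                            ref = ref, alt = alt, maf = maf,
                            gene_id = gene_name(g), row.names = NULL)
  }
  genotypes <- do.call(rbind, geno)
  colnames(genotypes) <- sprintf("S%04d", seq_len(n))
  list(genotypes = genotypes, snv_meta = do.call(rbind, meta))
}

gene_name <- function(g) sprintf("ENSG%011d", g)

#' Simulate cis-regulated expression
#'
#' Per gene, a latent (unit-variance) expression value is the sum of a
#' genetic component `sum_j w_j G_j`, rescaled so it explains `eqtl_r2` of
#' the variance, and Gaussian noise. The observed matrix is count-like:
#' `round(exp(mu_g + 0.4 * latent))` with gene-specific baselines, a
#' fraction of genes being near-silent so the low-expression filter has
#' work to do.
#'
#' @param genotypes,snv_meta output of [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @return list with `counts` (genes x samples, non-negative), `latent`
#'   (genes x samples generative scale), `weights` (per-gene named effect
#'   vectors on the latent scale) and `eqtl` (GTEx-layout effect table).
#' @export
simulate_expression <- function(genotypes, snv_meta, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$eqtl_r2 >= 1) stop("eqtl_r2 must be < 1")
  set.seed(cfg$seed + 1L)
  n <- ncol(genotypes)
  genes <- unique(snv_meta$gene_id)
  latent <- matrix(0, length(genes), n, dimnames = list(genes, colnames(genotypes)))
  weights <- vector("list", length(genes))
  names(weights) <- genes
  eqtl <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    rows <- which(snv_meta$gene_id == genes[gi])
    G <- genotypes[rows, , drop = FALSE]
    w <- rnorm(length(rows))
    gen <- drop(crossprod(G, w))
    v <- var(gen)
    if (cfg$eqtl_r2 > 0 && v > 0) {
      sc <- sqrt(cfg$eqtl_r2 / v)
      w <- w * sc
      gen <- gen * sc
    } else {
      w <- w * 0
      gen <- gen * 0
    }
    noise <- rnorm(n, sd = sqrt(1 - cfg$eqtl_r2))
    latent[gi, ] <- gen + noise
    names(w) <- rownames(G)
    weights[[gi]] <- w
    se <- rep(NA_real_, length(w))
    eqtl[[gi]] <- data.frame(
      variant_id = names(w), gene_id = genes[gi],
      tss_distance = snv_meta$pos[rows] - min(snv_meta$pos[rows]),
      ma_samples = as.integer(colSums(t(G) > 0)),
      ma_count = as.integer(rowSums(G)),
      maf = snv_meta$maf[rows],
      pval_nominal = NA_real_, slope = w, slope_se = se, row.names = NULL)
  }
  # nominal per-SNV slopes/p for the fixture table: marginal regressions,
  # computed in closed form per gene block
  eqtl <- do.call(rbind, eqtl)
  for (gi in seq_along(genes)) {
    rows <- which(eqtl$gene_id == genes[gi])
    G <- genotypes[eqtl$variant_id[rows], , drop = FALSE]
    y <- latent[genes[gi], ]
    Gc <- G - rowMeans(G)
    yc <- y - mean(y)
    sxx <- rowSums(Gc^2)
    sxy <- drop(Gc %*% yc)
    syy <- sum(yc^2)
    ok <- sxx > 0
    slope <- ifelse(ok, sxy / sxx, 0)
    s2 <- pmax(syy - slope * sxy, 0) / (n - 2)
    se <- ifelse(ok, sqrt(s2 / pmax(sxx, 1e-300)), NA_real_)
    tval <- ifelse(ok & se > 0, slope / se, 0)
    eqtl$slope[rows] <- slope
    eqtl$slope_se[rows] <- se
    eqtl$pval_nominal[rows] <- 2 * pt(-abs(tval), df = n - 2)
  }
  n_low <- round(cfg$frac_low_expressed * length(genes))
  mu <- runif(length(genes), log(50), log(500))
  if (n_low > 0) mu[sample.int(length(genes), n_low)] <- log(0.3)
  counts <- round(exp(mu + 0.4 * latent))
  dimnames(counts) <- dimnames(latent)
  list(counts = counts, latent = latent, weights = weights, eqtl = eqtl,
       baseline_log_mean = mu)
}

#' Simulate covariates matching the discovery cohort's profile
#'
#' Sex is Bernoulli with P(woman) = 88/160; age is Gaussian within sex
#' (women 62.7 +/- 8.4, men 66.9 +/- 8.3 years); smoking (never/former/
#' current), physical activity (four Cambridge index levels) and education
#' (three levels) are drawn from the sex-specific frequencies of the
#' cohort the generator emulates.
#'
#' @param n_samples number of rows to draw.
#' @param seed optional seed.
#' @return data.frame with factors `sex`, `smoking`, `physical_activity`,
#'   `education` and numeric `age`.
#' @export
simulate_covariates <- function(n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_samples >= 1)
  p_woman <- 88 / 160
  sex <- factor(ifelse(runif(n_samples) < p_woman, "woman", "man"),
                levels = c("woman", "man"))
  wm <- sex == "woman"
  age <- ifelse(wm, rnorm(n_samples, 62.7, 8.4), rnorm(n_samples, 66.9, 8.3))
  draw <- function(levels, pw, pm) {
    pw <- pw / sum(pw); pm <- pm / sum(pm)
    out <- character(n_samples)
    out[wm] <- sample(levels, sum(wm), TRUE, pw)
    out[!wm] <- sample(levels, sum(!wm), TRUE, pm)
    factor(out, levels = levels)
  }
  smoking <- draw(c("never", "former", "current"),
                  c(54.5, 31.8, 13.6), c(29.2, 55.6, 15.3))
  pa <- draw(c("inactive", "mod_inactive", "mod_active", "active"),
             c(8.0, 26.1, 35.2, 30.7), c(8.3, 29.1, 33.3, 29.2))
  edu <- draw(c("vocational", "technical_college", "university"),
              c(40.9, 26.1, 31.8), c(34.7, 11.1, 54.2))
  data.frame(sex = sex, age = age, smoking = smoking,
             physical_activity = pa, education = edu)
}

# modest fixed covariate effects on the linear predictors (log-kg / ratio)
cov_lp <- function(covariates, scale = 1) {
  age_c <- covariates$age - 64
  smoke <- c(never = 0, former = 0.02, current = -0.04)[as.character(covariates$smoking)]
  pa <- c(inactive = 0, mod_inactive = -0.02, mod_active = -0.04,
          active = -0.06)[as.character(covariates$physical_activity)]
  scale * (0.003 * age_c + smoke + pa)
}

#' Simulate copula-dependent fat phenotypes
#'
#' Residual pairs are drawn from the BB1 copula at `(phi, theta)` solved
#' from the target Kendall's tau, Gaussian-quantile-transformed, and added
#' to linear predictors: `log(SAT)` has sex-specific location (log 20.1 kg
#' for women, log 14.8 kg for men) plus causal-gene effects; SAT/TAT is
#' simulated on the raw ratio scale (0.848 women / 0.705 men) and clipped
#' into (0.01, 0.99) with the clip count recorded. TAT is derived as
#' SAT / (SAT/TAT), so SAT < TAT always holds.
#'
#' @param latent genes x samples latent expression (unit scale).
#' @param covariates data.frame from [simulate_covariates()].
#' @param cfg a [sim_config()].
#' @param causal_sat,causal_ratio row names of causal genes for each trait.
#' @param seed optional seed.
#' @return data.frame with `SAT`, `TAT` (kg) plus attributes `n_clipped`
#'   and `residuals` (the generative residual pairs).
#' @export
simulate_phenotypes <- function(latent, covariates, cfg,
                                causal_sat = character(),
                                causal_ratio = character(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(covariates)
  phi <- bb1_phi_from_tau(cfg$tau, cfg$copula_theta)
  uu <- sample_bb1(n, phi, cfg$copula_theta)
  eps1 <- qnorm(uu[, 1]) * cfg$sigma_sat
  eps2 <- qnorm(uu[, 2]) * cfg$sigma_ratio
  wm <- covariates$sex == "woman"
  zsum <- function(ids) {
    if (length(ids) == 0) return(rep(0, n))
    z <- latent[ids, , drop = FALSE]
    z <- (z - rowMeans(z)) / apply(z, 1, sd)
    colSums(z)
  }
  lp_sat <- ifelse(wm, log(20.1), log(14.8)) + cov_lp(covariates) +
    cfg$beta_sat * zsum(causal_sat)
  lp_ratio <- ifelse(wm, 20.1 / 23.7, 14.8 / 21.0) + cov_lp(covariates, 0.25) +
    cfg$beta_ratio * zsum(causal_ratio)
  log_sat <- lp_sat + eps1
  ratio <- lp_ratio + eps2
  clipped <- ratio <= 0.01 | ratio >= 0.99
  ratio <- pmin(pmax(ratio, 0.01), 0.99)
  if (mean(clipped) > 0.05)
    warning(sprintf("%.1f%% of SAT/TAT values clipped into (0.01, 0.99)",
                    100 * mean(clipped)))
  sat <- exp(log_sat)
  out <- data.frame(SAT = sat, TAT = sat / ratio)
  attr(out, "n_clipped") <- sum(clipped)
  attr(out, "residuals") <- cbind(eps1 = eps1, eps2 = eps2)
  out
}

#' Simulate a complete discovery cohort
#'
#' Chains [simulate_genotypes()], [simulate_expression()],
#' [simulate_covariates()] and [simulate_phenotypes()]. Causal genes are
#' the first `n_causal_sat` well-expressed genes for SAT and an
#' overlapping stretch for SAT/TAT.
#'
#' @param cfg a [sim_config()].
#' @return an `adipo_cohort` list: `sample_ids`, `expression` (counts),
#'   `expression_latent`, `genotypes`, `snv_meta`, `gene_meta` (gene id,
#'   symbol, length, causal flags), `phenotypes`, `covariates`, `eqtl`,
#'   `weights`, `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  g <- simulate_genotypes(cfg)
  e <- simulate_expression(g$genotypes, g$snv_meta, cfg)
  covars <- simulate_covariates(cfg$n_samples, seed = cfg$seed + 2L)
  genes <- rownames(e$counts)
  expressed <- rowMeans(e$counts > 0) >= 0.25
  pool <- genes[expressed]
  causal_sat <- head(pool, cfg$n_causal_sat)
  start <- cfg$n_causal_sat - cfg$causal_overlap
  causal_ratio <- pool[seq(start + 1, start + cfg$n_causal_ratio)]
  ph <- simulate_phenotypes(e$latent, covars, cfg, causal_sat, causal_ratio,
                            seed = cfg$seed + 3L)
  gene_meta <- data.frame(
    gene_id = genes,
    symbol = sprintf("GENE%d", seq_along(genes)),
    length = round(runif(length(genes), 500, 5000)),
    causal_sat = genes %in% causal_sat,
    causal_ratio = genes %in% causal_ratio)
  structure(list(
    sample_ids = colnames(g$genotypes),
    expression = e$counts, expression_latent = e$latent,
    genotypes = g$genotypes, snv_meta = g$snv_meta, gene_meta = gene_meta,
    phenotypes = ph, covariates = covars, eqtl = e$eqtl,
    weights = e$weights, config = cfg), class = "adipo_cohort")
}

#' Simulate a replication cohort sharing the discovery genetic architecture
#'
#' Regenerates genotypes from the same per-gene allele frequencies and LD,
#' rebuilds expression from the discovery eQTL weights, and produces
#' abdominal phenotypes (aSAT, VAT) driven by the same causal genes. An
#' exome-capture-style availability mask keeps each SNV with probability
#' `avail_prob`; unavailable SNVs are absent from the genotype matrix.
#'
#' @param cohort_a the discovery `adipo_cohort`.
#' @param n_samples replication size (default 4904).
#' @param avail_prob per-SNV availability probability.
#' @param seed integer seed.
#' @export
simulate_replication_cohort <- function(cohort_a, n_samples = 4904,
                                        avail_prob = 0.5, seed = NULL) {
  cfg <- cohort_a$config
  if (is.null(seed)) seed <- cfg$seed + 1000L
  cfg_b <- cfg
  cfg_b$n_samples <- n_samples
  cfg_b$seed <- as.integer(seed)
  set.seed(cfg_b$seed)
  meta <- cohort_a$snv_meta
  genes <- unique(meta$gene_id)
  geno <- vector("list", length(genes))
  for (gi in seq_along(genes)) {
    rows <- which(meta$gene_id == genes[gi])
    H <- sim_haplotypes(2 * n_samples, meta$maf[rows], cfg$ld_decay)
    G <- H[, seq_len(n_samples), drop = FALSE] +
      H[, n_samples + seq_len(n_samples), drop = FALSE]
    rownames(G) <- meta$variant_id[rows]
    geno[[gi]] <- G
  }
  genotypes <- do.call(rbind, geno)
  colnames(genotypes) <- sprintf("B%05d", seq_len(n_samples))
  latent <- matrix(0, length(genes), n_samples,
                   dimnames = list(genes, colnames(genotypes)))
  for (gi in seq_along(genes)) {
    w <- cohort_a$weights[[genes[gi]]]
    gen <- drop(crossprod(genotypes[names(w), , drop = FALSE], w))
    latent[gi, ] <- gen + rnorm(n_samples, sd = sqrt(max(1 - cfg$eqtl_r2, 0)))
  }
  covars <- simulate_covariates(n_samples, seed = cfg_b$seed + 1L)
  causal_sat <- cohort_a$gene_meta$gene_id[cohort_a$gene_meta$causal_sat]
  causal_ratio <- cohort_a$gene_meta$gene_id[cohort_a$gene_meta$causal_ratio]
  ph <- simulate_phenotypes(latent, covars, cfg_b, causal_sat, causal_ratio,
                            seed = cfg_b$seed + 2L)
  # abdominal phenotypes: aSAT is a fixed fraction of SAT on the log scale,
  # VAT derived so that aSAT/(aSAT+VAT) mirrors the simulated ratio
  aSAT <- 0.6 * ph$SAT
  ratio <- ph$SAT / ph$TAT
  VAT <- aSAT * (1 - ratio) / ratio
  avail <- runif(nrow(genotypes)) < avail_prob
  counts <- round(exp(log(150) + 0.4 * latent))
  structure(list(
    sample_ids = colnames(genotypes),
    expression = counts, expression_latent = latent,
    genotypes = genotypes[avail, , drop = FALSE],
    snv_meta = meta[avail, , drop = FALSE],
    gene_meta = cohort_a$gene_meta,
    phenotypes = data.frame(aSAT = aSAT, VAT = VAT),
    covariates = covars, config = cfg_b), class = "adipo_cohort")
}

#' @export
print.adipo_cohort <- function(x, ...) {
  cat("adipo_cohort:", length(x$sample_ids), "samples,",
      nrow(x$expression), "genes,", nrow(x$genotypes), "SNVs\n")
  cat("phenotypes:", paste(names(x$phenotypes), collapse = ", "), "\n")
  invisible(x)
}
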