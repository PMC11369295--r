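#' Select cis-eQTL instruments for one gene
#'
#' Applies the four instrument filters on individual-level data:
#' (i) the SNV is a cis-eQTL for the gene (member of the gene's rows in
#' the eQTL table) and present in the cohort genotypes; (ii) it is not
#' associated with any adjustment covariate at `p < p_thresh` (linear-
#' regression Wald test for age, Fisher's exact test on genotype-by-
#' category tables for sex, smoking, physical activity, education);
#' (iii) it is not associated with the outcome conditional on the gene's
#' expression and the covariates at `p < p_thresh`; (iv) correlated pairs
#' are pruned greedily at |Spearman rho| > `rho_max`, strongest eQTL
#' first (ties by genomic position). Missing genotypes are mean-imputed
#' per SNV beforehand.
#'
#' @param gene gene id.
#' @param eqtl_table data.frame in GTEx `signif_variant_gene_pairs` layout
#'   (needs `variant_id`, `gene_id`; uses `pval_nominal` for ordering when
#'   present).
#' @param cohort preprocessed cohort with genotypes, covariates and
#'   analysis-scale outcomes.
#' @param outcome `"sat"` (log SAT) or `"ratio"` (SAT/TAT).
#' @param p_thresh filter significance threshold (default 0.001).
#' @param rho_max pruning threshold on |Spearman correlation| (default 0.9).
#' @return an `instrument_set` (snv ids, per-SNV exposure and outcome
#'   effects with SEs, genotype correlation matrix, exposure-outcome
#'   correlation `psi_mr`, instrument R^2) or `NULL` when no SNV survives.
#' @export
select_instruments <- function(gene, eqtl_table, cohort,
                               outcome = c("sat", "ratio"),
                               p_thresh = 0.001, rho_max = 0.9) {
  outcome <- match.arg(outcome)
  y <- if (outcome == "sat") cohort$analysis$y1 else cohort$analysis$y2
  expr <- gene_expression(cohort, gene)
  if (is.null(expr)) return(NULL)
  cand <- eqtl_table[eqtl_table$gene_id == gene, , drop = FALSE]
  cand <- cand[cand$variant_id %in% rownames(cohort$genotypes), , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  G <- cohort$genotypes[cand$variant_id, , drop = FALSE]
  G <- mean_impute(G)
  poly <- apply(G, 1, var) > 0
  cand <- cand[poly, , drop = FALSE]
  G <- G[poly, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  covars <- cohort$covariates
  X0 <- build_design(covars)

  # (ii) confounder association
  keep <- vapply(seq_len(nrow(G)), function(i) {
    g <- G[i, ]
    if (lm_coef_p(covars$age, cbind(1, g), 2) < p_thresh) return(FALSE)
    for (v in c("sex", "smoking", "physical_activity", "education")) {
      if (!v %in% names(covars) || !is.factor(covars[[v]])) next
      if (length(unique(covars[[v]])) < 2) next
      tab <- table(round(g), covars[[v]])
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (any(dim(tab) < 2)) next
      # hybrid network algorithm for tables beyond 2x2: exact where cell
      # expectations are small, chi-square elsewhere; orders of magnitude
      # faster at cohort-scale counts and deterministic
      hybrid <- any(dim(tab) > 2)
      p <- tryCatch(fisher.test(tab, workspace = 2e7, hybrid = hybrid)$p.value,
                    error = function(e)
                      suppressWarnings(stats::chisq.test(tab)$p.value))
      if (is.finite(p) && p < p_thresh) return(FALSE)
    }
    TRUE
  }, TRUE)
  cand <- cand[keep, , drop = FALSE]
  G <- G[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)

  # (iii) outcome association conditional on expression + covariates
  keep <- vapply(seq_len(nrow(G)), function(i) {
    lm_coef_p(y, cbind(X0, expr = expr, snv = G[i, ]), "snv") >= p_thresh
  }, TRUE)
  cand <- cand[keep, , drop = FALSE]
  G <- G[keep, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)

  # (iv) greedy Spearman pruning, strongest eQTL evidence first
  ord <- order(if ("pval_nominal" %in% names(cand)) cand$pval_nominal
               else seq_len(nrow(cand)),
               eqtl_pos(cand))
  kept <- integer()
  for (i in ord) {
    if (all(abs(vapply(kept, function(j)
      suppressWarnings(cor(G[i, ], G[j, ], method = "spearman")), 0)) <= rho_max,
      na.rm = TRUE))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  cand <- cand[kept, , drop = FALSE]
  G <- G[kept, , drop = FALSE]

  m <- nrow(G)
  bx <- se_bx <- by <- se_by <- numeric(m)
  for (i in seq_len(m)) {
    Xi <- cbind(X0, snv = G[i, ])
    fx <- lm_coef(expr, Xi, "snv")
    fy <- lm_coef(y, Xi, "snv")
    bx[i] <- fx[1]; se_bx[i] <- fx[2]
    by[i] <- fy[1]; se_by[i] <- fy[2]
  }
  rho <- if (m == 1) matrix(1, 1, 1) else suppressWarnings(cor(t(G)))
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 1
  r2 <- summary(lm(expr ~ t(G)))$r.squared
  structure(list(
    gene = gene, outcome = outcome, snv_ids = cand$variant_id,
    bx = bx, se_bx = se_bx, by = by, se_by = se_by,
    rho = rho, psi_mr = cor(expr, y), r2 = r2,
    genotypes = G), class = "instrument_set")
}

gene_expression <- function(cohort, gene) {
  if (!is.null(cohort$expression_yj) && gene %in% rownames(cohort$expression_yj))
    return(cohort$expression_yj[gene, ])
  if (gene %in% rownames(cohort$expression))
    return(yeo_johnson(cohort$expression[gene, ])$x)
  NULL
}

mean_impute <- function(G) {
  for (i in seq_len(nrow(G))) {
    na <- is.na(G[i, ])
    if (any(na)) G[i, na] <- mean(G[i, !na])
  }
  G
}

eqtl_pos <- function(cand) {
  if ("pos" %in% names(cand)) return(cand$pos)
  # GTEx variant ids are chr_pos_ref_alt_build
  as.numeric(vapply(strsplit(cand$variant_id, "_"), `[`, "", 2))
}

lm_coef <- function(y, X, which) {
  fit <- lm.fit(as.matrix(X), y)
  rdf <- length(y) - ncol(X)
  s2 <- sum(fit$residuals^2) / rdf
  XtXi <- tryCatch(solve(crossprod(as.matrix(X))), error = function(e) NULL)
  if (is.null(XtXi)) return(c(NA_real_, NA_real_))
  j <- if (is.character(which)) match(which, colnames(X)) else which
  c(unname(fit$coefficients[j]), sqrt(s2 * XtXi[j, j]))
}

lm_coef_p <- function(y, X, which) {
  cs <- lm_coef(y, X, which)
  if (!all(is.finite(cs)) || cs[2] <= 0) return(1)
  2 * pt(-abs(cs[1] / cs[2]), df = length(y) - ncol(X))
}

#' Inverse-variance-weighted MR with correlated instruments
#'
#' Generalized weighted regression of the outcome effects on the exposure
#' effects without intercept: `theta = (bx' W bx)^-1 bx' W by` with
#' `W = Omega^-1`. First-order weights use
#' `Omega_ij = rho_ij se_by_i se_by_j`; delta weights add the second-order
#' exposure-uncertainty term `theta0^2 rho_ij se_bx_i se_bx_j` and the
#' exposure-outcome-correlation cross term
#' `- theta0 psi rho_ij (se_bx_i se_by_j + se_by_i se_bx_j)`, with
#' `theta0` the first-order estimate and `psi` the sample correlation
#' between expression and outcome. The diagonal of the delta Omega is the
#' published delta-method variance of the per-SNV Wald ratio
#' (`se_by^2 + theta0^2 se_bx^2 - 2 theta0 psi se_bx se_by`); off-diagonal
#' entries carry one power of `rho_ij` per pair of correlated slope
#' errors, which keeps Omega positive semi-definite. The SE is
#' `sqrt((bx' Omega^-1 bx)^-1)` and the p-value two-sided normal.
#'
#' @param inst an `instrument_set` from [select_instruments()].
#' @param weights `"delta"` (default) or `"first_order"`.
#' @return an `mr_result` data.frame row: gene, outcome, theta, se, p,
#'   n_var, r2.
#' @export
ivw_correlated <- function(inst, weights = c("delta", "first_order")) {
  weights <- match.arg(weights)
  stopifnot(inherits(inst, "instrument_set"))
  bx <- inst$bx; by <- inst$by
  se_bx <- inst$se_bx; se_by <- inst$se_by
  rho <- inst$rho
  m <- length(bx)
  stopifnot(length(by) == m, nrow(rho) == m)
  omega1 <- rho * tcrossprod(se_by)
  theta0 <- gls_theta(bx, by, omega1)
  if (weights == "first_order") {
    est <- theta0
  } else {
    psi <- inst$psi_mr
    omega <- omega1 +
      theta0$theta^2 * rho * tcrossprod(se_bx) -
      theta0$theta * psi * rho *
        (outer(se_bx, se_by) + outer(se_by, se_bx))
    est <- gls_theta(bx, by, omega)
  }
  data.frame(gene = inst$gene, outcome = inst$outcome,
             theta = est$theta, se = est$se,
             p = 2 * pnorm(-abs(est$theta / est$se)),
             n_var = m, r2 = inst$r2)
}

gls_theta <- function(bx, by, omega) {
  oi <- tryCatch(solve(omega), error = function(e) NULL)
  if (is.null(oi)) {
    omega <- omega + diag(1e-8, nrow(omega))
    oi <- tryCatch(solve(omega), error = function(e)
      stop("singular weight matrix in IVW even after ridge"))
  }
  denom <- drop(crossprod(bx, oi %*% bx))
  theta <- drop(crossprod(bx, oi %*% by)) / denom
  list(theta = theta, se = sqrt(1 / denom))
}

#' Per-gene Mendelian randomization screen
#'
#' For every associated gene and its relevant outcome(s), selects
#' instruments and runs the correlated-instrument IVW with delta weights;
#' genes with no surviving instrument are recorded as not analyzable.
#'
#' @param assoc association table from [transcriptome_screen()] (uses the
#'   significance flags), or a data.frame with `gene`, `significant_sat`,
#'   `significant_ratio`.
#' @param eqtl_table eQTL table (GTEx layout).
#' @param cohort preprocessed cohort.
#' @param alpha significance level for the causal call (default 0.05).
#' @param ... passed to [select_instruments()].
#' @return data.frame of MR results; attributes `counts` (genes tested /
#'   analyzable / causal per outcome) and `diagnostics` (mean n_var, mean
#'   r2 per outcome).
#' @export
mr_screen <- function(assoc, eqtl_table, cohort, alpha = 0.05, ...) {
  jobs <- rbind(
    if (any(assoc$significant_sat))
      data.frame(gene = assoc$gene[assoc$significant_sat], outcome = "sat"),
    if (any(assoc$significant_ratio))
      data.frame(gene = assoc$gene[assoc$significant_ratio], outcome = "ratio"))
  res <- list(); insts <- list()
  n_analyzable <- c(sat = 0L, ratio = 0L)
  n_tested <- c(sat = 0L, ratio = 0L)
  if (!is.null(jobs)) for (i in seq_len(nrow(jobs))) {
    oc <- jobs$outcome[i]
    n_tested[oc] <- n_tested[oc] + 1L
    inst <- select_instruments(jobs$gene[i], eqtl_table, cohort,
                               outcome = oc, ...)
    if (is.null(inst)) next
    n_analyzable[oc] <- n_analyzable[oc] + 1L
    res[[length(res) + 1L]] <- ivw_correlated(inst, "delta")
    insts[[paste(jobs$gene[i], oc, sep = ".")]] <- inst
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(gene = character(), outcome = character(), theta = numeric(),
               se = numeric(), p = numeric(), n_var = integer(), r2 = numeric())
  out$causal <- out$p < alpha
  counts <- data.frame(
    outcome = c("sat", "ratio"),
    tested = as.integer(n_tested),
    analyzable = as.integer(n_analyzable),
    causal = c(sum(out$causal[out$outcome == "sat"]),
               sum(out$causal[out$outcome == "ratio"])))
  diag_tab <- data.frame(
    outcome = c("sat", "ratio"),
    mean_n_var = c(mean(out$n_var[out$outcome == "sat"]),
                   mean(out$n_var[out$outcome == "ratio"])),
    mean_r2 = c(mean(out$r2[out$outcome == "sat"]),
                mean(out$r2[out$outcome == "ratio"])))
  attr(out, "counts") <- counts
  attr(out, "diagnostics") <- diag_tab
  attr(out, "instruments") <- insts
  out
}
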