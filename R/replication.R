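#' Learn per-gene SNV weights for expression imputation
#'
#' Multiple linear regression of the (transformed) expression on all
#' surviving instrument SNVs jointly; collinear SNVs are dropped to a
#' full-rank subset (recorded in `dropped`). The training data are kept
#' with the model so that the explained variance of any available SNV
#' subset can be recomputed when imputing into a cohort with partial
#' coverage.
#'
#' @param expr_gene per-sample (transformed) expression of one gene.
#' @param genotypes SNVs x samples matrix of the gene's surviving
#'   instruments.
#' @param gene gene id carried into the model.
#' @return an `imputation_model`: `weights` (named per-SNV), `intercept`,
#'   `r2` (training), `dropped`, plus the training data.
#' @export
learn_weights <- function(expr_gene, genotypes, gene = "gene") {
  G <- as.matrix(genotypes)
  if (nrow(G) == 0) stop("no SNVs to learn weights from")
  if (ncol(G) != length(expr_gene)) stop("sample axes disagree")
  if (length(expr_gene) <= nrow(G) + 1)
    stop("need more samples than SNVs to fit weights")
  X <- cbind(`(Intercept)` = 1, t(G))
  fit <- lm.fit(X, expr_gene)
  dropped <- character()
  if (any(is.na(fit$coefficients))) {
    dropped <- setdiff(names(fit$coefficients)[is.na(fit$coefficients)],
                       "(Intercept)")
    G <- G[setdiff(rownames(G), dropped), , drop = FALSE]
    X <- cbind(`(Intercept)` = 1, t(G))
    fit <- lm.fit(X, expr_gene)
  }
  r2 <- 1 - sum(fit$residuals^2) / sum((expr_gene - mean(expr_gene))^2)
  structure(list(
    gene = gene,
    weights = fit$coefficients[-1],
    intercept = unname(fit$coefficients[1]),
    r2 = r2,
    dropped = dropped,
    training_expr = expr_gene,
    training_geno = G), class = "imputation_model")
}

#' Impute genetically-determined expression in a second cohort
#'
#' Scores each sample as `intercept + sum(weight * genotype)` over the
#' model SNVs available in the cohort; the discovery weights are reused
#' as-is, never refit. Also reports how much expression variance the
#' available subset explained in the discovery cohort (`r2_available`,
#' from a restricted regression on the training data).
#'
#' @param model an [learn_weights()] model.
#' @param genotypes_b SNVs x samples genotype matrix of the target cohort.
#' @return list with `score` (per-sample), `n_var_available`,
#'   `r2_available`, `available` (snv ids); `NULL` when no model SNV is
#'   available.
#' @export
impute_expression <- function(model, genotypes_b) {
  stopifnot(inherits(model, "imputation_model"))
  avail <- intersect(names(model$weights), rownames(genotypes_b))
  if (length(avail) == 0) return(NULL)
  G <- mean_impute(as.matrix(genotypes_b[avail, , drop = FALSE]))
  score <- model$intercept + drop(crossprod(G, model$weights[avail]))
  r2_avail <- if (length(avail) == length(model$weights)) model$r2 else {
    Xr <- cbind(1, t(model$training_geno[avail, , drop = FALSE]))
    fr <- lm.fit(Xr, model$training_expr)
    1 - sum(fr$residuals^2) /
      sum((model$training_expr - mean(model$training_expr))^2)
  }
  list(score = score, n_var_available = length(avail),
       r2_available = r2_avail, available = avail)
}

#' Test an imputed expression score against an abdominal fat outcome
#'
#' Linear regression of the outcome on the score adjusting for age, sex,
#' smoking and education (no physical-activity term in the replication
#' model), with a two-sided t-test on the score coefficient.
#'
#' @param score per-sample imputed expression.
#' @param outcome per-sample outcome on the analysis scale (log aSAT or
#'   aSAT/(aSAT+VAT)).
#' @param covariates data.frame with `age`, `sex`, `smoking`, `education`.
#' @return list with `beta`, `se`, `p`, `n`.
#' @export
replication_test <- function(score, outcome, covariates) {
  if (var(score) == 0) stop("constant imputed score")
  if (var(outcome) == 0) stop("constant outcome")
  X <- build_design(covariates, include = c("sex", "age", "smoking", "education"))
  X <- cbind(X, score = score)
  cs <- lm_coef(outcome, X, "score")
  p <- 2 * pt(-abs(cs[1] / cs[2]), df = length(outcome) - ncol(X))
  list(beta = cs[1], se = cs[2], p = p, n = length(outcome))
}

#' Replicate causal genes in an independent cohort
#'
#' For each MR-causal gene: learn weights from the discovery instruments,
#' impute the expression score from the replication cohort's available
#' SNVs, and test the score against the matching abdominal outcome
#' (log aSAT for SAT genes, aSAT/(aSAT+VAT) for ratio genes).
#'
#' @param mr_results output of [mr_screen()] (uses rows with
#'   `causal == TRUE` and its `instruments` attribute).
#' @param cohort_a preprocessed discovery cohort.
#' @param cohort_b replication cohort with `aSAT`, `VAT` phenotypes.
#' @param alpha per-test replication significance level (default 0.05).
#' @return data.frame with gene, outcome, n_var_available, r2_available,
#'   beta, se, p, confirmed; attribute `counts` (investigated, confirmed).
#' @export
replication_pipeline <- function(mr_results, cohort_a, cohort_b, alpha = 0.05) {
  insts <- attr(mr_results, "instruments")
  causal <- mr_results[mr_results$causal, , drop = FALSE]
  ya <- log(cohort_b$phenotypes$aSAT)
  yr <- cohort_b$phenotypes$aSAT / (cohort_b$phenotypes$aSAT + cohort_b$phenotypes$VAT)
  rows <- list()
  for (i in seq_len(nrow(causal))) {
    gene <- causal$gene[i]; oc <- causal$outcome[i]
    inst <- insts[[paste(gene, oc, sep = ".")]]
    if (is.null(inst)) next
    expr <- gene_expression(cohort_a, gene)
    model <- learn_weights(expr, inst$genotypes, gene = gene)
    imp <- impute_expression(model, cohort_b$genotypes)
    if (is.null(imp)) next
    y <- if (oc == "sat") ya else yr
    tst <- tryCatch(replication_test(imp$score, y, cohort_b$covariates),
                    error = function(e) NULL)
    if (is.null(tst)) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, outcome = oc,
      n_var_available = imp$n_var_available,
      r2_available = imp$r2_available,
      beta = tst$beta, se = tst$se, p = tst$p)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), outcome = character(),
               n_var_available = integer(), r2_available = numeric(),
               beta = numeric(), se = numeric(), p = numeric())
  out$confirmed <- out$p < alpha
  attr(out, "counts") <- c(causal = nrow(causal), investigated = nrow(out),
                           confirmed = sum(out$confirmed))
  out
}
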