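#' Joint log-likelihood of the two-margin BB1 model
#'
#' The joint distribution of the two analysis-scale outcomes given the
#' design is built by coupling two Gaussian linear margins through the BB1
#' copula: the contribution of observation i is
#' `log c(u1, u2; phi, theta) + log N(y1; X gamma, sigma1) + log N(y2; X gamma', sigma2)`
#' with `u = Phi((y - X gamma)/sigma)`.
#'
#' @param y1 vector of log SAT values.
#' @param y2 vector of SAT/TAT values.
#' @param X design matrix (intercept, covariates, expression).
#' @param gamma1,gamma2 marginal coefficient vectors (length `ncol(X)`).
#' @param sigma1,sigma2 residual SDs (> 0).
#' @param phi,theta BB1 copula parameters.
#' @return the log-likelihood (a single number).
#' @export
joint_loglik <- function(y1, y2, X, gamma1, sigma1, gamma2, sigma2, phi, theta) {
  X <- as.matrix(X)
  stopifnot(length(y1) == nrow(X), length(y2) == nrow(X),
            length(gamma1) == ncol(X), length(gamma2) == ncol(X),
            sigma1 > 0, sigma2 > 0)
  check_bb1_params(phi, theta)
  par <- c(gamma1, log(sigma1), gamma2, log(sigma2), log(phi), log(theta - 1 + 1e-12))
  -cpp_joint_nll(par, y1, y2, X)
}

ols_margin <- function(y, X) {
  fit <- lm.fit(X, y)
  r <- fit$residuals
  list(coef = fit$coefficients, sigma = sqrt(mean(r^2)), resid = r)
}

#' Fit the joint copula model for one gene by maximum likelihood
#'
#' One-stage quasi-Newton maximization over all free parameters on the
#' unconstrained scale (`log sigma`, `log phi`, `log(theta - 1)`), started
#' from marginal OLS fits with the copula initialized by tau-inversion at
#' `theta = 1`. Standard errors come from the inverse of the numerically
#' differentiated observed information at the optimum; Wald p-values use
#' the N(0,1) reference, two-sided.
#'
#' @param y1,y2 analysis-scale outcomes (log SAT, SAT/TAT).
#' @param X design matrix whose column `test_coef` carries the expression
#'   coefficient under test (default: last column).
#' @param test_coef index of the coefficient tested by the Wald tests.
#' @param max_restarts restarts from perturbed starts on non-convergence.
#' @return a `copula_fit`: marginal models, copula parameters, log-lik,
#'   covariance of all free parameters, Wald p for the tested coefficient
#'   in each margin, convergence flag.
#' @export
fit_copula_model <- function(y1, y2, X, test_coef = ncol(X), max_restarts = 2L) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (n <= 2 * k + 4) stop("more free parameters than observations")
  if (qr(X)$rank < k) stop("design matrix is rank deficient")
  m1 <- ols_margin(y1, X)
  m2 <- ols_margin(y2, X)
  tau0 <- kendall_tau(m1$resid, m2$resid)
  phi0 <- max(2 * tau0 / (1 - tau0), 0.05)
  np <- 2 * k + 4
  start <- c(m1$coef, log(m1$sigma), m2$coef, log(m2$sigma), log(phi0),
             LT_BOUNDARY)
  # Stage 1 fixes theta at 1 (the Clayton limit of the family); stage 2
  # frees theta from the stage-1 optimum. The boundary theta -> 1 has no
  # interior zero-gradient point in log(theta - 1), so the reduced model
  # is reported (as theta = 1) unless freeing theta genuinely raises the
  # maximum with an interior, gradient-zero solution.
  red <- bfgs_newton(start, seq_len(np - 1L), y1, y2, X, max_restarts)
  full <- NULL
  if (!is.null(red)) {
    # free theta only if the profile likelihood actually increases away
    # from the boundary: sign of d(nll)/d log(theta-1) just inside
    st2 <- red$par
    st2[np] <- log(5e-2)
    g_lt <- cpp_joint_nll_grad(st2, y1, y2, X)[np]
    if (is.finite(g_lt) && g_lt < 0)
      full <- bfgs_newton(st2, seq_len(np), y1, y2, X, 0L)
  }
  use_full <- !is.null(full) && !is.null(red) &&
    full$value < red$value - 1e-6 && exp(full$par[np]) >= 1e-3 &&
    full$max_grad < 1e-4
  fit <- if (use_full) full else red
  if (is.null(fit))
    return(structure(list(converged = FALSE), class = "copula_fit"))
  p <- unname(fit$par)
  free <- fit$free
  cov <- matrix(NA_real_, np, np)
  cov_free <- tryCatch(solve(fit$H), error = function(e) NULL)
  if (!is.null(cov_free) && all(is.finite(diag(cov_free))))
    cov[free, free] <- cov_free
  converged <- fit$convergence == 0 &&
    !is.na(cov[test_coef, test_coef]) && cov[test_coef, test_coef] > 0 &&
    !is.na(cov[k + 1 + test_coef, k + 1 + test_coef]) &&
    cov[k + 1 + test_coef, k + 1 + test_coef] > 0
  idx2 <- k + 1 + seq_len(k)
  se1 <- se2 <- p1 <- p2 <- NA_real_
  if (converged) {
    se1 <- sqrt(cov[test_coef, test_coef])
    se2 <- sqrt(cov[idx2[test_coef], idx2[test_coef]])
    p1 <- 2 * pnorm(-abs(p[test_coef] / se1))
    p2 <- 2 * pnorm(-abs(p[idx2[test_coef]] / se2))
  }
  theta_hat <- 1 + exp(p[np])
  structure(list(
    marginal_sat = list(coef = setNames(p[seq_len(k)], colnames(X)),
                        sigma = exp(p[k + 1])),
    marginal_ratio = list(coef = setNames(p[idx2], colnames(X)),
                          sigma = exp(p[2 * k + 2])),
    copula = list(phi = unname(exp(p[2 * k + 3])),
                  theta = if (use_full) unname(theta_hat) else 1),
    loglik = -fit$value,
    covariance = cov,
    par = p,
    free = free,
    max_grad = fit$max_grad,
    test_coef = test_coef,
    beta_sat = unname(p[test_coef]), se_sat = se1, wald_p_sat = p1,
    beta_ratio = unname(p[idx2[test_coef]]), se_ratio = se2, wald_p_ratio = p2,
    converged = converged), class = "copula_fit")
}

# theta - 1 = 1e-8: numerically the Clayton limit on the log scale
LT_BOUNDARY <- log(1e-8)

# BFGS over par[free] (other entries held fixed) followed by damped Newton
# polishing; returns par (full length), value, free, H (free block),
# max_grad, convergence
bfgs_newton <- function(start, free, y1, y2, X, max_restarts = 0L) {
  np <- length(start)
  wrap_fn <- function(pf) {
    w <- start; w[free] <- pf
    cpp_joint_nll(w, y1, y2, X)
  }
  wrap_gr <- function(pf) {
    w <- start; w[free] <- pf
    cpp_joint_nll_grad(w, y1, y2, X)[free]
  }
  fit <- NULL
  for (attempt in 0:max_restarts) {
    st <- if (attempt == 0) start[free] else
      start[free] + rnorm(length(free), sd = 0.05 * attempt)
    res <- tryCatch(
      optim(st, fn = wrap_fn, gr = wrap_gr, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-9)),
      error = function(e) NULL)
    if (!is.null(res) && res$convergence == 0 && res$value < 1e9) { fit <- res; break }
    if (!is.null(res) && is.null(fit)) fit <- res
  }
  if (is.null(fit)) return(NULL)
  p <- start
  p[free] <- fit$par
  # chord-Newton polish: one observed-information evaluation drives the
  # steps; the information is refreshed once at the final point
  H <- cpp_joint_nll_hess(p, y1, y2, X)[free, free, drop = FALSE]
  stepped <- FALSE
  for (step in 1:10) {
    g <- cpp_joint_nll_grad(p, y1, y2, X)[free]
    if (max(abs(g)) < 1e-6) break
    dir <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(dir)) break
    f0 <- cpp_joint_nll(p, y1, y2, X)
    lam <- 1
    p_new <- p
    repeat {
      p_try <- p
      p_try[free] <- p[free] - lam * dir
      if (cpp_joint_nll(p_try, y1, y2, X) <= f0 + 1e-12) { p_new <- p_try; break }
      lam <- lam / 2
      if (lam < 1e-4) break
    }
    if (identical(p_new, p)) break
    if (max(abs(p_new[free] - p[free])) > 1e-7) stepped <- TRUE
    p <- p_new
  }
  if (stepped) H <- cpp_joint_nll_hess(p, y1, y2, X)[free, free, drop = FALSE]
  list(par = p, value = cpp_joint_nll(p, y1, y2, X), free = free, H = H,
       max_grad = max(abs(cpp_joint_nll_grad(p, y1, y2, X)[free])),
       convergence = fit$convergence)
}

#' @export
print.copula_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("copula_fit (not converged)\n")
    return(invisible(x))
  }
  cat(sprintf("copula_fit: phi = %.3f, theta = %.3f (tau = %.3f), loglik = %.2f\n",
              x$copula$phi, x$copula$theta,
              bb1_tau(x$copula$phi, x$copula$theta), x$loglik))
  cat(sprintf("  SAT margin:     beta = %8.4f  se = %.4f  p = %.3g\n",
              x$beta_sat, x$se_sat, x$wald_p_sat))
  cat(sprintf("  SAT/TAT margin: beta = %8.4f  se = %.4f  p = %.3g\n",
              x$beta_ratio, x$se_ratio, x$wald_p_ratio))
  invisible(x)
}

#' Design matrix for the adjustment covariates
#'
#' Dummy-codes sex, smoking, physical activity and education (first level
#' as reference) with age numeric, matching the marginal models of the
#' screen.
#'
#' @param covariates data.frame with `sex`, `age`, `smoking`,
#'   `physical_activity`, `education` (factors/numeric).
#' @param include optional character vector naming covariates to keep.
#' @return design matrix with intercept.
#' @export
build_design <- function(covariates,
                         include = c("sex", "age", "smoking",
                                     "physical_activity", "education")) {
  include <- include[include %in% names(covariates)]
  # drop factors with a single observed level (degenerate at tiny n)
  ok <- vapply(include, function(v) {
    x <- covariates[[v]]
    !is.factor(x) || length(unique(x[!is.na(x)])) > 1
  }, TRUE)
  include <- include[ok]
  f <- if (length(include))
    as.formula(paste("~", paste(include, collapse = " + "))) else ~1
  model.matrix(f, data = covariates)
}

bonferroni_cutoff <- function(alpha, n_tests) alpha / n_tests

screen_counts <- function(sig1, sig2) {
  c(sat_only = sum(sig1 & !sig2), ratio_only = sum(!sig1 & sig2),
    both = sum(sig1 & sig2), total = sum(sig1 | sig2))
}

#' Transcriptome-wide joint copula screen
#'
#' Fits the joint copula model per gene (expression Yeo-Johnson transformed
#' unless `yj = FALSE`) with the shared covariate design, Wald-tests the
#' expression coefficient in each margin, and flags significance at the
#' Bonferroni level `alpha / G` with `G` the number of genes attempted
#' (genes whose fit fails stay in the denominator with missing results).
#'
#' @param cohort a preprocessed cohort (see [preprocess_cohort()]); the
#'   screen uses `expression_yj` if present, else transforms `expression`.
#' @param alpha family-wise error level (default 0.05).
#' @param yj transform expression per gene before fitting.
#' @param genes optional subset of gene ids to screen.
#' @return data.frame (one row per gene): `gene`, `beta_sat`, `se_sat`,
#'   `p_sat`, `beta_ratio`, `se_ratio`, `p_ratio`, `converged`,
#'   `significant_sat`, `significant_ratio`; attributes `cutoff`,
#'   `n_genes`, `counts` (SAT-only / ratio-only / both / total).
#' @export
transcriptome_screen <- function(cohort, alpha = 0.05, yj = TRUE, genes = NULL) {
  expr <- if (!is.null(cohort$expression_yj)) cohort$expression_yj
          else as.matrix(cohort$expression)
  if (!is.null(genes)) expr <- expr[intersect(genes, rownames(expr)), , drop = FALSE]
  if (is.null(cohort$analysis))
    stop("cohort has no analysis-scale phenotypes; run preprocess_cohort() first")
  y1 <- cohort$analysis$y1
  y2 <- cohort$analysis$y2
  X0 <- build_design(cohort$covariates)
  G <- nrow(expr)
  out <- empty_screen_table(as.character(rownames(expr) %||% seq_len(G)))
  skipped <- character()
  for (g in seq_len(G)) {
    e <- expr[g, ]
    if (var(e) == 0) {
      skipped <- c(skipped, out$gene[g])
      next
    }
    if (yj && is.null(cohort$expression_yj)) e <- yeo_johnson(e)$x
    X <- cbind(X0, expr = e)
    f <- tryCatch(fit_copula_model(y1, y2, X), error = function(err) NULL)
    if (is.null(f) || !isTRUE(f$converged)) next
    out[g, c("beta_sat", "se_sat", "p_sat")] <- c(f$beta_sat, f$se_sat, f$wald_p_sat)
    out[g, c("beta_ratio", "se_ratio", "p_ratio")] <-
      c(f$beta_ratio, f$se_ratio, f$wald_p_ratio)
    out$converged[g] <- TRUE
  }
  cutoff <- bonferroni_cutoff(alpha, G)
  out$significant_sat <- !is.na(out$p_sat) & out$p_sat < cutoff
  out$significant_ratio <- !is.na(out$p_ratio) & out$p_ratio < cutoff
  attr(out, "cutoff") <- cutoff
  attr(out, "n_genes") <- G
  attr(out, "skipped") <- skipped
  attr(out, "counts") <- screen_counts(out$significant_sat, out$significant_ratio)
  out
}

#' Univariate linear-regression screen (sensitivity analysis)
#'
#' Ordinary least squares of each analysis-scale outcome on expression and
#' the same covariates, with two-sided t-tests on the expression
#' coefficient and the same Bonferroni flagging as the copula screen.
#'
#' @inheritParams transcriptome_screen
#' @return data.frame in the same layout as [transcriptome_screen()].
#' @export
linear_screen <- function(cohort, alpha = 0.05, yj = TRUE, genes = NULL) {
  expr <- if (!is.null(cohort$expression_yj)) cohort$expression_yj
          else as.matrix(cohort$expression)
  if (!is.null(genes)) expr <- expr[intersect(genes, rownames(expr)), , drop = FALSE]
  y1 <- cohort$analysis$y1
  y2 <- cohort$analysis$y2
  X0 <- build_design(cohort$covariates)
  if (qr(X0)$rank < ncol(X0)) stop("rank-deficient covariate design")
  G <- nrow(expr)
  out <- empty_screen_table(as.character(rownames(expr) %||% seq_len(G)))
  out$converged <- TRUE
  for (g in seq_len(G)) {
    e <- expr[g, ]
    if (var(e) == 0) { out$converged[g] <- FALSE; next }
    if (yj && is.null(cohort$expression_yj)) e <- yeo_johnson(e)$x
    X <- cbind(X0, expr = e)
    for (m in 1:2) {
      y <- if (m == 1) y1 else y2
      fit <- lm.fit(X, y)
      rdf <- length(y) - ncol(X)
      s2 <- sum(fit$residuals^2) / rdf
      XtXi <- solve(crossprod(X))
      se <- sqrt(s2 * XtXi[ncol(X), ncol(X)])
      b <- fit$coefficients["expr"]
      pv <- 2 * pt(-abs(b / se), df = rdf)
      cols <- if (m == 1) c("beta_sat", "se_sat", "p_sat")
              else c("beta_ratio", "se_ratio", "p_ratio")
      out[g, cols] <- c(b, se, pv)
    }
  }
  cutoff <- bonferroni_cutoff(alpha, G)
  out$significant_sat <- !is.na(out$p_sat) & out$p_sat < cutoff
  out$significant_ratio <- !is.na(out$p_ratio) & out$p_ratio < cutoff
  attr(out, "cutoff") <- cutoff
  attr(out, "n_genes") <- G
  attr(out, "counts") <- screen_counts(out$significant_sat, out$significant_ratio)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_screen_table <- function(genes) {
  n <- length(genes)
  data.frame(gene = genes, beta_sat = rep(NA_real_, n),
             se_sat = rep(NA_real_, n), p_sat = rep(NA_real_, n),
             beta_ratio = rep(NA_real_, n), se_ratio = rep(NA_real_, n),
             p_ratio = rep(NA_real_, n), converged = rep(FALSE, n))
}
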