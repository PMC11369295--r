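#' Transcripts-per-million normalization
#'
#' Length-normalizes counts to rates, then scales each sample so its rates
#' sum to one million: `TPM_g = (count_g/length_g) / sum_g(count_g/length_g) * 1e6`.
#'
#' @param counts non-negative genes x samples count matrix.
#' @param lengths per-gene effective length in bases (> 0), aligned to rows.
#' @return genes x samples TPM matrix; every sample column sums to 1e6.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    stop("lengths must have one entry per gene (row) of counts")
  if (any(!is.finite(lengths) | lengths <= 0)) stop("gene lengths must be > 0")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    bad <- colnames(counts)[tot == 0]
    if (is.null(bad)) bad <- which(tot == 0)
    stop("zero total rate in sample(s): ", paste(bad, collapse = ", "))
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Trimmed-mean-of-M-values scale factors
#'
#' Per-sample scale factors in the Robinson-Oshlack sense, absorbing both
#' sequencing depth and composition bias: the reference is the sample whose
#' upper quartile is closest to the mean upper quartile, each factor is the
#' weighted mean of gene-wise log ratios after trimming 30% of M-values and
#' 5% of A-values, and factors are rescaled to geometric mean 1. Dividing a
#' sample's counts by its factor puts samples on a common scale.
#'
#' @param counts non-negative genes x samples count matrix with >= 2 samples.
#' @return positive per-sample factors with geometric mean 1.
#' @export
tmm_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample(s) with zero counts")
  # reference by upper quartile of depth-scaled counts (edgeR's default rule)
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  shared <- counts[, ref] > 0
  for (j in seq_len(ncol(counts))) {
    if (j != ref && !any(counts[, j] > 0 & shared))
      stop("sample ", j, " shares no expressed gene with the reference sample")
  }
  # edgeR's TMM factor is composition-only; combine with depth so the factor
  # is the full between-sample scale, then rescale to geometric mean 1
  comp <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref,
                                 logratioTrim = 0.3, sumTrim = 0.05)
  f <- comp * lib
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Filter genes expressed in too few samples
#'
#' Keeps a gene iff the fraction of samples with value > 0 is at least
#' `min_fraction` (a gene expressed in exactly 25% of samples is kept; the
#' filter removes genes expressed in *less than* that fraction).
#'
#' @param expr non-negative genes x samples matrix.
#' @param min_fraction minimum expressed fraction, default 0.25.
#' @return character vector of kept gene ids (rownames), or row indices if
#'   the matrix has no rownames.
#' @export
filter_low_expressed <- function(expr, min_fraction = 0.25) {
  expr <- as.matrix(expr)
  if (any(expr < 0)) stop("expression must be non-negative")
  frac <- rowMeans(expr > 0)
  keep <- frac >= min_fraction
  if (!is.null(rownames(expr))) rownames(expr)[keep] else which(keep)
}

yj_transform <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-12) {
    out[!pos] <- -(((-x[!pos] + 1)^(2 - lambda) - 1) / (2 - lambda))
  } else {
    out[!pos] <- -log1p(-x[!pos])
  }
  out
}

yj_profile_loglik <- function(x, lambda) {
  z <- yj_transform(x, lambda)
  n <- length(x)
  s2 <- mean((z - mean(z))^2)
  if (s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

#' Yeo-Johnson power transformation
#'
#' Removes skewness towards a Gaussian shape. For `x >= 0` the transform is
#' `((x+1)^lambda - 1)/lambda` (`log(x+1)` at `lambda = 0`); for `x < 0` it
#' is `-(((-x+1)^(2-lambda) - 1)/(2-lambda))` (`-log(-x+1)` at `lambda = 2`).
#' When `lambda` is not supplied it is chosen by profile maximum likelihood
#' under a Gaussian model, via golden-section search on `[-5, 5]` to 1e-6.
#'
#' @param x numeric vector of finite values.
#' @param lambda optional fixed transformation parameter.
#' @return list with `x` (transformed values) and `lambda`.
#' @export
yeo_johnson <- function(x, lambda = NULL) {
  if (any(!is.finite(x))) stop("x must be finite")
  if (length(unique(x)) < 2L) {
    warning("constant input: returning values unchanged with lambda = 1")
    return(list(x = x, lambda = 1))
  }
  if (is.null(lambda)) {
    lambda <- golden_section(function(l) -yj_profile_loglik(x, l),
                             lower = -5, upper = 5, tol = 1e-6)
  }
  list(x = yj_transform(x, lambda), lambda = lambda)
}

golden_section <- function(f, lower, upper, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- f(c1); fd <- f(d1)
  while (b - a > tol) {
    if (fc < fd) {
      b <- d1; d1 <- c1; fd <- fc
      c1 <- b - gr * (b - a); fc <- f(c1)
    } else {
      a <- c1; c1 <- d1; fc <- fd
      d1 <- a + gr * (b - a); fd <- f(d1)
    }
  }
  (a + b) / 2
}

#' Put fat phenotypes on the analysis scale
#'
#' SAT mass is log-transformed (natural log); the distribution ratio
#' SAT/TAT is analyzed untransformed.
#'
#' @param sat,tat per-sample fat masses in kg, `sat > 0`, `tat > 0`.
#' @return data.frame with `log_sat` and `ratio = sat/tat`.
#' @export
transform_phenotypes <- function(sat, tat) {
  if (any(!is.finite(sat)) || any(sat <= 0)) stop("SAT must be finite and > 0")
  if (any(!is.finite(tat)) || any(tat <= 0)) stop("TAT must be finite and > 0")
  data.frame(log_sat = log(sat), ratio = sat / tat)
}

#' Normalize, filter and transform a cohort for analysis
#'
#' Runs the expression pipeline TPM -> TMM scaling -> low-expression filter
#' -> per-gene Yeo-Johnson, and puts phenotypes on the analysis scale
#' (log SAT, raw SAT/TAT). When `lengths` is `NULL` the expression matrix
#' is taken as already length/depth-normalized and only TMM scaling,
#' filtering and Yeo-Johnson are applied.
#'
#' @param cohort an `adipo_cohort` (see [simulate_cohort()]) or a list with
#'   `expression`, `phenotypes`, `covariates`.
#' @param lengths optional per-gene effective lengths for TPM.
#' @param min_fraction low-expression filter threshold (default 0.25).
#' @return the cohort with added elements `expression_norm` (normalized,
#'   filtered), `expression_yj` (Yeo-Johnson transformed, one row per kept
#'   gene), `yj_lambda`, `tmm` (per-sample factors) and `analysis`
#'   (data.frame with `y1 = log SAT`, `y2 = SAT/TAT`).
#' @export
preprocess_cohort <- function(cohort, lengths = NULL, min_fraction = 0.25) {
  expr <- as.matrix(cohort$expression)
  if (!is.null(lengths)) expr <- tpm(expr, lengths)
  fac <- tmm_factors(expr)
  norm <- sweep(expr, 2, fac, "/")
  keep <- filter_low_expressed(norm, min_fraction)
  norm <- norm[keep, , drop = FALSE]
  yj <- matrix(NA_real_, nrow(norm), ncol(norm), dimnames = dimnames(norm))
  lam <- setNames(numeric(nrow(norm)), rownames(norm))
  for (g in seq_len(nrow(norm))) {
    fit <- yeo_johnson(norm[g, ])
    yj[g, ] <- fit$x
    lam[g] <- fit$lambda
  }
  ph <- cohort$phenotypes
  if (!is.null(ph$SAT)) {
    an <- transform_phenotypes(ph$SAT, ph$TAT)
  } else {
    an <- transform_phenotypes(ph$aSAT, ph$aSAT + ph$VAT)
  }
  cohort$expression_norm <- norm
  cohort$expression_yj <- yj
  cohort$yj_lambda <- lam
  cohort$tmm <- fac
  cohort$analysis <- data.frame(y1 = an$log_sat, y2 = an$ratio)
  cohort$kept_genes <- keep
  cohort
}
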