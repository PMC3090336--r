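# The statistical machinery behind the pipeline's comparisons,
# implemented from first principles so every decision rule is explicit:
# Pearson 2x2 chi-square without continuity correction, Mann-Whitney U
# with midranks and exact small-sample enumeration, the two-sided exact
# binomial test, the normal-approximation sample size for MAF
# estimation, and logistic regression by IRLS. Base distribution
# functions (pbinom, pchisq, pnorm, qnorm) supply the tail areas.

#' Pearson chi-square test for a 2x2 table
#'
#' `sum((O - E)^2 / E)` with expectations from the margins and no
#' continuity correction (the uncorrected statistic is what the
#' pipeline's pooled filter-level comparisons report); p-value from the
#' upper tail of chi-square with one degree of freedom. A zero row or
#' column margin leaves the statistic undefined.
#'
#' @param table 2x2 numeric matrix of counts (rows = groups, columns =
#'   outcome yes/no).
#' @return List: `statistic`, `p_value` (both `NA` when undefined) and
#'   `note`.
#' @export
pearson_chi2_2x2 <- function(table) {
  o <- as.matrix(table)
  stopifnot(all(dim(o) == c(2L, 2L)), all(o >= 0))
  rs <- rowSums(o); cs <- colSums(o); n <- sum(o)
  if (any(rs == 0) || any(cs == 0)) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                note = "degenerate margin; statistic undefined"))
  }
  e <- outer(rs, cs) / n
  stat <- sum((o - e)^2 / e)
  list(statistic = stat, p_value = pchisq(stat, df = 1L,
                                          lower.tail = FALSE),
       note = NULL)
}

#' Mann-Whitney U test
#'
#' Rank-sum U with midranks for ties. For two samples of at most
#' `exact_max` observations each the two-sided p-value is computed by
#' full enumeration of all label assignments (permutation distribution
#' of U, measured as distance from its null mean); otherwise a normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction is used. Identical samples give p = 1.
#'
#' @param x,y Numeric samples (non-empty).
#' @param exact_max Largest per-sample size for exact enumeration.
#' @return List: `U` (for `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, exact_max = 8L) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u1 - mu) - 1e-12)
    return(list(U = u1, p_value = p, method = "exact enumeration"))
  }
  nt <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) /
                              (nt * (nt - 1)))
  if (sigma2 <= 0) {
    return(list(U = u1, p_value = 1, method = "normal approximation"))
  }
  z <- (u1 - mu - sign(u1 - mu) * 0.5) / sqrt(sigma2)
  list(U = u1, p_value = min(1, 2 * pnorm(-abs(z))),
       method = "normal approximation")
}

#' Two-sided exact binomial test
#'
#' Doubled smaller tail, capped at 1: `2 * min(P(X <= k), P(X >= k))`
#' for `X ~ Binomial(n, p0)`. With the symmetric null `p0 = 0.5` this
#' matches the minimum-likelihood two-sided test.
#'
#' @param k Observed count, `0 <= k <= n`.
#' @param n Number of trials (>= 1).
#' @param p0 Null success probability.
#' @return p-value in `(0, 1]`.
#' @export
exact_binomial_two_sided <- function(k, n, p0 = 0.5) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  stopifnot(k >= 0L, k <= n, p0 > 0, p0 < 1)
  lower <- pbinom(k, n, p0)
  upper <- 1 - pbinom(k - 1L, n, p0)
  min(1, 2 * min(lower, upper))
}

#' Sample size needed to estimate an allele frequency
#'
#' Normal-approximation sample size for estimating an allele of
#' frequency `freq` to within `halfwidth` with the given confidence:
#' `n_alleles = ceil(z^2 freq (1 - freq) / halfwidth^2)`, with `z` the
#' two-sided normal quantile; individuals are diploid, so half as many
#' (rounded up) are needed.
#'
#' @param freq Allele frequency in `(0, 1)`.
#' @param halfwidth Desired half-width of the interval (> 0).
#' @param confidence Coverage probability.
#' @return List: `n_alleles`, `n_individuals`.
#' @export
min_sample_size_for_maf <- function(freq, halfwidth,
                                    confidence = 0.95) {
  stopifnot(freq > 0, freq < 1, halfwidth > 0,
            confidence > 0, confidence < 1)
  z <- qnorm(1 - (1 - confidence) / 2)
  n_alleles <- ceiling(z^2 * freq * (1 - freq) / halfwidth^2)
  list(n_alleles = as.integer(n_alleles),
       n_individuals = as.integer(ceiling(n_alleles / 2)))
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit of a binary response on a covariate
#' matrix (an intercept is prepended). Convergence is declared when the
#' log-likelihood changes by less than `tol`; complete separation is
#' detected from diverging coefficients with perfectly split fitted
#' probabilities and reported as a warning with the `separated` flag
#' set. Standard errors come from the inverse Fisher information and
#' p-values from the Wald z statistic.
#'
#' @param response Numeric 0/1 vector.
#' @param covariates Numeric matrix or data.frame, one column per
#'   explanatory variable.
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @return List: `coefficients`, `se`, `z`, `p_value`, `deviance`,
#'   `converged`, `separated`, `n_iter`.
#' @export
logistic_fit <- function(response, covariates, tol = 1e-8,
                         max_iter = 100L) {
  y <- as.numeric(response)
  stopifnot(all(y %in% c(0, 1)))
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  design <- cbind(`(Intercept)` = 1, x)
  qd <- qr(design)
  if (qd$rank < ncol(design)) {
    bad <- colnames(design)[qd$pivot[(qd$rank + 1L):ncol(design)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- rep(0, ncol(design))
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  for (it in seq_len(max_iter)) {
    eta <- drop(design %*% beta)
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    wd <- design * w
    beta <- solve(crossprod(design, wd), crossprod(wd, z))
    beta <- drop(beta)
    ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  eta <- drop(design %*% beta)
  mu <- 1 / (1 + exp(-eta))
  separated <- max(abs(beta)) > 15 &&
    all(abs(y - mu) < 1e-4)
  if (separated) {
    warning("complete separation detected; coefficients diverge",
            call. = FALSE)
  }
  info <- crossprod(design, design * (mu * (1 - mu)))
  se <- tryCatch(sqrt(diag(solve(info))),
                 error = function(e) rep(NA_real_, length(beta)))
  zstat <- beta / se
  mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  list(coefficients = setNames(beta, colnames(design)),
       se = setNames(se, colnames(design)),
       z = setNames(zstat, colnames(design)),
       p_value = setNames(2 * pnorm(-abs(zstat)), colnames(design)),
       deviance = -2 * sum(y * log(mu_c) + (1 - y) * log(1 - mu_c)),
       converged = converged, separated = separated, n_iter = it)
}
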