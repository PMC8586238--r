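# Statistical primitives composed by every pipeline stage. Each returns a
# "test_result" recording the method actually used (exact enumeration,
# tie-corrected normal approximation, chi-squared approximation, Monte Carlo)
# so that downstream tables are auditable.

#' Construct a test result
#'
#' @param statistic test statistic.
#' @param p_value p-value in [0, 1].
#' @param alternative one of `"two_sided"`, `"greater"`, `"less"`.
#' @param method one of `"exact"`, `"normal_approx"`, `"chi2_approx"`,
#'   `"monte_carlo"`.
#' @return A list of class `"test_result"`.
#' @export
test_result <- function(statistic, p_value,
                        alternative = c("two_sided", "greater", "less"),
                        method = c("exact", "normal_approx", "chi2_approx",
                                   "monte_carlo")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(is.numeric(p_value), length(p_value) == 1L,
            !is.na(p_value), p_value >= 0, p_value <= 1)
  structure(list(statistic = as.numeric(statistic), p_value = p_value,
                 alternative = alternative, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("test_result: statistic = %.6g, p = %.4g (%s, %s)\n",
              x$statistic, x$p_value, x$alternative, x$method))
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum (Mann-Whitney) test. The exact null distribution is
#' used when the combined sample size is at most 12 and there are no ties;
#' otherwise a tie-corrected normal approximation with continuity correction
#' is applied. `alternative = "greater"` means the first-argument population
#' is stochastically larger.
#'
#' @param x,y numeric samples (each non-empty after NA removal).
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @return A `"test_result"`; the statistic is the Mann-Whitney U of `x`.
#' @export
rank_sum_test <- function(x, y, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 1L || length(y) < 1L)
    stop("rank_sum_test: both samples must be non-empty")
  n.x <- length(x); n.y <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n.x)]) - n.x * (n.x + 1) / 2
  ties <- length(r) != length(unique(r))
  if (n.x + n.y <= 12L && !ties) {
    p <- switch(alternative,
      two_sided = {
        pp <- if (U > n.x * n.y / 2)
          stats::pwilcox(U - 1, n.x, n.y, lower.tail = FALSE) * 2
        else
          stats::pwilcox(U, n.x, n.y) * 2
        min(pp, 1)
      },
      greater = stats::pwilcox(U - 1, n.x, n.y, lower.tail = FALSE),
      less = stats::pwilcox(U, n.x, n.y))
    return(test_result(U, p, alternative, "exact"))
  }
  p <- ranksum_normal_p(U, n.x, n.y, r, alternative)
  test_result(U, p, alternative, "normal_approx")
}

# Sum of t^3 - t over tie groups; 0 when all values are distinct (the
# common case for continuous scores, checked cheaply first).
tie_term <- function(r) {
  if (!anyDuplicated(r)) return(0)
  t <- rle(sort(r))$lengths
  sum(t^3 - t)
}

# Tie-corrected normal approximation with continuity correction, on the
# Mann-Whitney U scale. `r` is the pooled rank vector (for tie counts).
ranksum_normal_p <- function(U, n.x, n.y, r, alternative) {
  z <- U - n.x * n.y / 2
  sigma <- sqrt((n.x * n.y / 12) *
                ((n.x + n.y + 1) -
                 tie_term(r) / ((n.x + n.y) * (n.x + n.y - 1))))
  if (sigma == 0) return(1)
  corr <- switch(alternative,
                 two_sided = sign(z) * 0.5,
                 greater = 0.5,
                 less = -0.5)
  z <- (z - corr) / sigma
  switch(alternative,
         two_sided = min(2 * min(stats::pnorm(z),
                                 stats::pnorm(z, lower.tail = FALSE)), 1),
         greater = stats::pnorm(z, lower.tail = FALSE),
         less = stats::pnorm(z))
}

#' Wilcoxon signed-rank test
#'
#' One-sample signed-rank test on a vector of differences. Zero differences
#' are dropped (with a warning); the exact 2^n sign-pattern distribution is
#' used for n <= 15 without ties in |d|, a tie-corrected normal approximation
#' otherwise. `alternative = "greater"` tests for location above zero.
#'
#' @param d numeric differences.
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @return A `"test_result"`; statistic is the positive-rank sum V.
#' @export
signed_rank_test <- function(d, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- d[is.finite(d)]
  if (length(d) < 1L) stop("signed_rank_test: empty sample")
  nzero <- sum(d == 0)
  if (nzero > 0) {
    warning(sprintf("signed_rank_test: dropping %d zero difference(s)", nzero))
    d <- d[d != 0]
  }
  if (length(d) == 0L) {
    warning("signed_rank_test: all differences are zero; p = 1")
    return(test_result(0, 1, alternative, "exact"))
  }
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- length(r) != length(unique(r))
  if (n <= 15L && !ties) {
    p <- switch(alternative,
      two_sided = {
        pp <- if (V > n * (n + 1) / 4)
          stats::psignrank(V - 1, n, lower.tail = FALSE) * 2
        else
          stats::psignrank(V, n) * 2
        min(pp, 1)
      },
      greater = stats::psignrank(V - 1, n, lower.tail = FALSE),
      less = stats::psignrank(V, n))
    return(test_result(V, p, alternative, "exact"))
  }
  z <- V - n * (n + 1) / 4
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_term(r) / 48)
  p <- if (sigma == 0) 1 else {
    corr <- switch(alternative,
                   two_sided = sign(z) * 0.5,
                   greater = 0.5,
                   less = -0.5)
    zz <- (z - corr) / sigma
    switch(alternative,
           two_sided = min(2 * min(stats::pnorm(zz),
                                   stats::pnorm(zz, lower.tail = FALSE)), 1),
           greater = stats::pnorm(zz, lower.tail = FALSE),
           less = stats::pnorm(zz))
  }
  test_result(V, p, alternative, "normal_approx")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR correction; order-preserving with the input, q >= p
#' elementwise. NAs are propagated.
#'
#' @param p numeric p-values in [0, 1].
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("bh_fdr: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` items from a
#' universe of `N` containing `K` marked items.
#'
#' @param k observed overlap.
#' @param K marked items in the universe.
#' @param n draw size.
#' @param N universe size.
#' @return P(X >= k).
#' @export
hypergeom_tail <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= 0)
  if (K > N || n > N || k > min(K, n))
    stop("hypergeom_tail: inconsistent counts (need 0 <= k <= min(K, n) <= N)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fisher / chi-squared test for an r x c contingency table
#'
#' Follows the published rule: when every cell exceeds `chi2_min_cell`, the
#' Pearson chi-squared approximation of Fisher's exact test is used; otherwise
#' the exact test (full enumeration over fixed margins) when the table total
#' is at most 500, and a seeded Monte-Carlo p-value beyond that. Zero-margin
#' rows and columns are dropped with a warning before testing.
#'
#' @param table non-negative integer matrix with >= 2 rows and columns.
#' @param chi2_min_cell cell-count switch for the chi-squared approximation.
#' @param mc_draws Monte-Carlo draws for the large-table fallback.
#' @param seed seed for the Monte-Carlo fallback.
#' @return A `"test_result"` (two-sided); the statistic is the Pearson
#'   chi-squared statistic of the (margin-reduced) table.
#' @export
fisher_rxc <- function(table, chi2_min_cell = 30L, mc_draws = 1e5, seed = 1L) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("fisher_rxc: table must contain non-negative integers")
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("fisher_rxc: need at least 2 rows and 2 columns")
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("fisher_rxc: dropping zero-margin rows/columns")
    table <- table[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(table) < 2L || ncol(table) < 2L)
    return(test_result(0, 1, "two_sided", "exact"))
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  chi2 <- sum((table - expected)^2 / expected)
  if (all(table > chi2_min_cell)) {
    df <- (nrow(table) - 1L) * (ncol(table) - 1L)
    p <- stats::pchisq(chi2, df, lower.tail = FALSE)
    return(test_result(chi2, p, "two_sided", "chi2_approx"))
  }
  if (sum(table) <= 500) {
    p <- stats::fisher.test(table)$p.value
    return(test_result(chi2, min(p, 1), "two_sided", "exact"))
  }
  p <- withr::with_seed(seed,
    stats::fisher.test(table, simulate.p.value = TRUE, B = mc_draws)$p.value)
  test_result(chi2, p, "two_sided", "monte_carlo")
}

#' Average precision (area under the precision-recall curve)
#'
#' Mean of the precision at each positive, taken in score order. Ties are
#' broken by stable input order.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1/TRUE = positive).
#' @param higher_is_positive if `TRUE` (default) larger scores rank first.
#' @return The average precision in [0, 1].
#' @export
average_precision <- function(scores, labels, higher_is_positive = TRUE) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(as.logical(labels))
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (sum(labels) == 0L) stop("average_precision: no positive labels")
  ord <- order(if (higher_is_positive) -scores else scores)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  mean(prec[lab == 1L])
}

# Rank-based AUROC (probability a positive outranks a negative), used for
# screen QC reporting alongside average precision.
auroc <- function(scores, labels, higher_is_positive = TRUE) {
  labels <- as.integer(as.logical(labels))
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("auroc: need both classes")
  s <- if (higher_is_positive) scores else -scores
  r <- rank(s)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit a gaussian or binomial generalized linear model
#'
#' Thin wrapper around maximum-likelihood GLM fitting that drops aliased
#' design columns with a warning, records convergence, and flags probable
#' separation in the binomial case instead of returning silently unstable
#' estimates.
#'
#' @param design numeric design matrix (include an intercept column if one is
#'   wanted); column names label the coefficients.
#' @param response numeric response (0/1 for binomial).
#' @param family `"gaussian"` or `"binomial"`.
#' @return A list with `coefficients` (data.frame: term, estimate, se, z,
#'   p_value), `converged`, `dropped` (aliased column names).
#' @export
glm_fit <- function(design, response, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  design <- as.matrix(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  if (nrow(design) != length(response))
    stop("glm_fit: design rows must match response length")
  qrd <- qr(design)
  dropped <- character(0)
  if (qrd$rank < ncol(design)) {
    keep <- qrd$pivot[seq_len(qrd$rank)]
    dropped <- colnames(design)[-keep]
    warning("glm_fit: dropping aliased column(s): ",
            paste(dropped, collapse = ", "))
    design <- design[, sort(keep), drop = FALSE]
  }
  fam <- if (family == "gaussian") stats::gaussian() else stats::binomial()
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(design, response, family = fam,
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  converged <- isTRUE(fit$converged) && !sep_warn
  # Wald standard errors from the weighted cross-product at the MLE
  est <- fit$coefficients
  w <- fit$weights
  XtWX <- crossprod(design * sqrt(w))
  cov_unscaled <- tryCatch(solve(XtWX), error = function(e) {
    converged <<- FALSE
    matrix(NA_real_, ncol(design), ncol(design))
  })
  disp <- if (family == "gaussian") {
    rdf <- nrow(design) - ncol(design)
    if (rdf > 0) sum(fit$residuals^2 * w) / rdf else 0
  } else 1
  se <- sqrt(pmax(diag(cov_unscaled) * disp, 0))
  z <- est / se
  z[se == 0] <- ifelse(est[se == 0] == 0, 0, Inf * sign(est[se == 0]))
  p <- if (family == "gaussian") {
    rdf <- nrow(design) - ncol(design)
    2 * stats::pt(abs(z), df = max(rdf, 1), lower.tail = FALSE)
  } else {
    2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
  p[se == 0 & est == 0] <- 1
  list(coefficients = data.frame(term = colnames(design), estimate = est,
                                 se = se, z = z, p_value = p,
                                 row.names = NULL),
       converged = converged,
       dropped = dropped)
}
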