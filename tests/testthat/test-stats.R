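# Statistical primitives against independent enumeration oracles and
# hand-computed values.

test_that("rank-sum exact path matches enumeration and known values", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6), "less")$p_value, 0.05)
  expect_equal(rank_sum_test(5, 1:4, "greater")$p_value, 0.2)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3), "two_sided")$p_value, 1.0)

  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    for (alt in c("two_sided", "greater", "less")) {
      r <- rank_sum_test(x, y, alt)
      expect_equal(r$method, "exact")
      expect_equal(r$p_value, oracle_ranksum(x, y, alt), tolerance = 1e-12)
    }
  }
})

test_that("rank-sum approximation is close to a permutation oracle under ties", {
  set.seed(21)
  x <- sample(1:5, 12, replace = TRUE)
  y <- sample(2:6, 14, replace = TRUE)
  r <- rank_sum_test(x, y, "two_sided")
  expect_equal(r$method, "normal_approx")
  pooled <- c(x, y)
  perm <- replicate(1e4, {
    idx <- sample(length(pooled), length(x))
    abs(sum(rank(pooled)[idx]) - length(x) * (length(pooled) + 1) / 2)
  })
  obs <- abs(sum(rank(pooled)[seq_along(x)]) -
             length(x) * (length(pooled) + 1) / 2)
  expect_lt(abs(r$p_value - mean(perm >= obs)), 0.02)
})

test_that("signed-rank test matches enumeration, drops zeros, handles all-zero", {
  expect_equal(signed_rank_test(c(1, 2, 3), "greater")$p_value, 0.125)
  expect_equal(signed_rank_test(c(-1, 1), "two_sided")$p_value, 1.0)
  expect_warning(r <- signed_rank_test(c(0, 0, 2), "greater"), "zero")
  expect_equal(r$p_value, 0.5)
  expect_warning(
    expect_warning(r0 <- signed_rank_test(c(0, 0), "greater"), "zero"),
    "all differences")
  expect_equal(r0$p_value, 1.0)

  set.seed(31)
  for (rep in 1:20) {
    d <- round(rnorm(sample(3:8, 1)), 3)
    d <- d[d != 0]
    for (alt in c("two_sided", "greater", "less")) {
      r <- signed_rank_test(d, alt)
      expect_equal(r$p_value, oracle_signed_rank(d, alt), tolerance = 1e-12)
    }
  }
})

test_that("BH q-values match the step-up rule and control the null FDP", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- c(0.3, 0.01, 0.9, 0.04)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))

  # global-null calibration: families of independent uniforms
  set.seed(41)
  any_rej <- replicate(200, any(bh_fdr(runif(100)) <= 0.1))
  expect_lte(mean(any_rej), 0.1 + 0.05)
})

test_that("hypergeometric tail matches binomial-coefficient enumeration", {
  expect_equal(hypergeom_tail(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_tail(0, 5, 4, 10), 1.0)
  expect_equal(hypergeom_tail(3, 10, 3, 10), 1.0)  # target is the universe
  expect_error(hypergeom_tail(5, 4, 4, 10), "inconsistent")
  set.seed(51)
  for (rep in 1:20) {
    N <- sample(8:20, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_tail(k, K, n, N), oracle_hypergeom(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("fisher_rxc exact path equals full enumeration on small tables", {
  expect_equal(fisher_rxc(matrix(c(3, 1, 1, 3), 2, 2))$p_value, 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_rxc(matrix(2, 3, 2))$p_value, 1.0)
  set.seed(61)
  for (rep in 1:15) {
    dims <- if (rep %% 2 == 0) c(2, 2) else c(3, 2)
    tab <- matrix(rpois(prod(dims), 3), dims[1], dims[2])
    tab[tab == 0] <- 1  # keep margins positive
    if (sum(tab) > 30) tab <- pmin(tab, 3)
    r <- fisher_rxc(tab)
    expect_equal(r$method, "exact")
    expect_equal(r$p_value, oracle_fisher_rxc(tab), tolerance = 1e-10)
  }
})

test_that("fisher_rxc switches to chi-squared above the cell threshold", {
  tab <- matrix(c(200, 100, 100, 100), 2, 2)
  r <- fisher_rxc(tab, chi2_min_cell = 30)
  expect_equal(r$method, "chi2_approx")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  expect_equal(r$statistic, chi2)
  expect_equal(r$p_value, pchisq(chi2, 1, lower.tail = FALSE))
  # below-threshold cells keep the exact method
  expect_equal(fisher_rxc(matrix(c(31, 31, 31, 5), 2, 2))$method, "exact")
  expect_warning(fisher_rxc(matrix(c(0, 0, 3, 4), 2, 2)), "zero-margin")
})

test_that("average precision matches the hand definition", {
  expect_equal(average_precision(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1.0)
  expect_equal(average_precision(c(4, 3, 2, 1), c(1, 0, 1, 0)), (1 + 2 / 3) / 2)
  expect_equal(average_precision(c(1, 5, 2), c(1, 1, 1)), 1.0)
  expect_error(average_precision(c(1, 2), c(0, 0)), "no positive")
  set.seed(71)
  sc <- rnorm(30); lb <- rbinom(30, 1, 0.4)
  expect_equal(average_precision(sc, lb),
               oracle_average_precision(sc, lb), tolerance = 1e-12)
})

test_that("glm_fit recovers gaussian and binomial truths and flags pathology", {
  x <- 1:10
  f <- glm_fit(cbind(intercept = 1, x = x), 2 * x, "gaussian")
  expect_equal(f$coefficients$estimate[f$coefficients$term == "x"], 2.0)
  expect_lt(f$coefficients$se[f$coefficients$term == "x"], 1e-8)

  f0 <- glm_fit(cbind(intercept = rep(1, 10)), rep(c(0, 1), 5), "binomial")
  expect_equal(f0$coefficients$estimate[1], 0.0, tolerance = 1e-8)

  set.seed(81)
  n <- 2000
  xx <- rnorm(n)
  eta <- 0.5 - 1.0 * xx
  y <- rbinom(n, 1, plogis(eta))
  fb <- glm_fit(cbind(intercept = 1, x = xx), y, "binomial")
  co <- fb$coefficients
  expect_lt(abs(co$estimate[1] - 0.5), 3 * co$se[1])
  expect_lt(abs(co$estimate[2] - (-1.0)), 3 * co$se[2])
  # cross-check against stats::glm
  ref <- glm(y ~ xx, family = binomial())
  expect_equal(unname(co$estimate), unname(coef(ref)), tolerance = 1e-6)

  expect_warning(
    fa <- glm_fit(cbind(a = c(1, 1, 2, 2), b = c(2, 2, 4, 4)), c(1, 2, 3, 4),
                  "gaussian"),
    "aliased")
  expect_equal(fa$dropped, "b")

  # perfect separation flagged
  xs <- c(-2, -1, 1, 2); ys <- c(0, 0, 1, 1)
  fs <- glm_fit(cbind(intercept = 1, x = xs), ys, "binomial")
  expect_false(fs$converged)
})

test_that("binomial fit agrees with the logit closed form in the saturated balanced case", {
  g <- rep(c(0, 1), each = 50)
  y <- c(rep(c(0, 1), c(10, 40)), rep(c(0, 1), c(30, 20)))
  f <- glm_fit(cbind(intercept = 1, g = g), y, "binomial")
  expect_equal(f$coefficients$estimate[1], qlogis(0.8), tolerance = 1e-6)
  expect_equal(f$coefficients$estimate[2], qlogis(0.4) - qlogis(0.8),
               tolerance = 1e-6)
})
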