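# Independent enumeration oracles. These recompute exact p-values by brute
# force (label assignments, sign patterns, fixed-margin tables, binomial
# coefficients) without touching the package's code paths or the closed-form
# distribution functions it uses.

# Rank-sum: enumerate all C(n1+n2, n1) assignments of the pooled ranks to
# the first group; tail probability of the observed Mann-Whitney U.
oracle_ranksum <- function(x, y, alternative) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  U_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_greater <- mean(U_all >= U_obs)
  p_less <- mean(U_all <= U_obs)
  switch(alternative,
         greater = p_greater,
         less = p_less,
         two_sided = min(1, 2 * min(p_greater, p_less)))
}

# Signed-rank: enumerate all 2^n sign patterns of the |d| ranks.
oracle_signed_rank <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  V_all <- vapply(seq_len(2^n) - 1L, function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  p_greater <- mean(V_all >= V_obs)
  p_less <- mean(V_all <= V_obs)
  switch(alternative,
         greater = p_greater,
         less = p_less,
         two_sided = min(1, 2 * min(p_greater, p_less)))
}

# Hypergeometric upper tail from binomial coefficients only.
oracle_hypergeom <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Fisher r x c: enumerate every table with the observed margins; two-sided
# p sums the multivariate hypergeometric probabilities of tables no more
# probable than the observed one (relative tolerance 1e-7, the conventional
# definition).
oracle_fisher_rxc <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  logp_tab <- function(m) {
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N) -
      sum(lfactorial(m))
  }
  lp_obs <- logp_tab(tab)
  tables <- list()
  gen <- function(m, row, rrem, crem) {
    if (row > nrow(tab)) {
      if (all(crem == 0)) tables[[length(tables) + 1L]] <<- m
      return(invisible())
    }
    fill_row <- function(m, col, left, crem) {
      if (col == ncol(tab)) {
        if (left <= crem[col]) {
          m[row, col] <- left
          crem[col] <- crem[col] - left
          gen(m, row + 1L, rrem, crem)
        }
        return(invisible())
      }
      for (v in 0:min(left, crem[col])) {
        m[row, col] <- v
        crem2 <- crem; crem2[col] <- crem2[col] - v
        fill_row(m, col + 1L, left - v, crem2)
      }
      invisible()
    }
    fill_row(m, 1L, rrem[row], crem)
    invisible()
  }
  gen(matrix(0L, nrow(tab), ncol(tab)), 1L, rs, cs)
  lps <- vapply(tables, logp_tab, numeric(1))
  sum(exp(lps[lps <= lp_obs + log(1 + 1e-7)]))
}

# Average precision by direct definition at each positive rank.
oracle_average_precision <- function(scores, labels, higher_is_positive = TRUE) {
  ord <- order(if (higher_is_positive) -scores else scores)
  lab <- labels[ord]
  hits <- which(lab == 1)
  mean(vapply(seq_along(hits), function(i) i / hits[i], numeric(1)))
}

# Unweighted KS-style running-sum enrichment score computed position by
# position (O(N) reference for the weight = 0 case).
oracle_es_unweighted <- function(N, hit_idx) {
  m <- length(hit_idx)
  inc <- rep(-1 / (N - m), N)
  inc[hit_idx] <- 1 / m
  run <- cumsum(inc)
  run[which.max(abs(run))]
}
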