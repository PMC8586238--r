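# Per-gene differential essentiality between driver-mutant and driver-WT
# cell lines within one screen modality.

# Row-wise rank-sum p-values of a genes x lines matrix between two groups.
# Uses the same tie-corrected, continuity-corrected normal approximation as
# rank_sum_test's large-sample path (and its exact path for tiny tie-free
# rows), so per-gene results agree with the scalar primitive.
ranksum_rows <- function(values, is_mut, alternative = "two_sided") {
  n_genes <- nrow(values)
  p <- rep(NA_real_, n_genes)
  n_mut <- integer(n_genes); n_wt <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    v <- values[i, ]
    ok <- is.finite(v)
    g <- is_mut[ok]; v <- v[ok]
    n1 <- sum(g); n2 <- sum(!g)
    n_mut[i] <- n1; n_wt[i] <- n2
    if (n1 < 2L || n2 < 2L) next
    r <- rank(v)
    U <- sum(r[g]) - n1 * (n1 + 1) / 2
    if (n1 + n2 <= 12L && length(unique(r)) == length(r)) {
      p[i] <- rank_sum_test(v[g], v[!g], alternative)$p_value
    } else {
      p[i] <- ranksum_normal_p(U, n1, n2, r, alternative)
    }
  }
  list(p = p, n_mut = n_mut, n_wt = n_wt)
}

# Row-wise difference of medians (mutant - WT), missing values excluded
# per gene; NA when a group is empty for that gene.
delta_median_rows <- function(values, is_mut) {
  med <- function(x) if (any(is.finite(x))) stats::median(x[is.finite(x)]) else NA_real_
  m_mut <- apply(values[, is_mut, drop = FALSE], 1L, med)
  m_wt <- apply(values[, !is_mut, drop = FALSE], 1L, med)
  m_mut - m_wt
}

#' Per-gene selection score (difference of median viabilities)
#'
#' Median post-knockout viability over mutant lines minus the median over WT
#' lines, per gene. Positive scores mean the gene's knockout is better
#' tolerated by (selects for) driver-mutant cells.
#'
#' @param screen a `"viability_matrix"`.
#' @param profile a `"mutation_profile"` covering the screen's cell lines.
#' @return Named numeric vector of per-gene scores (NA when a group has no
#'   finite values for that gene).
#' @export
selection_score <- function(screen, profile) {
  is_mut <- align_profile(screen, profile)
  if (sum(is_mut) == 0 || sum(!is_mut) == 0)
    stop("selection_score: both mutant and WT groups must be non-empty")
  stats::setNames(delta_median_rows(screen$values, is_mut), screen_genes(screen))
}

# Match profile status onto the screen's cell-line order.
align_profile <- function(screen, profile) {
  lines <- screen_lines(screen)
  missing <- setdiff(lines, names(profile$status))
  if (length(missing) > 0)
    stop("profile does not cover cell line(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  profile$status[lines] == 1L
}

#' Classify differential essentiality per gene
#'
#' For every gene, tests whether post-knockout viability differs between
#' driver-mutant and driver-WT cell lines (rank-sum test), applies BH
#' correction across all tested genes of the modality, and classifies genes
#' as `pos` (q < alpha and mutants more viable), `neg` (q < alpha and WT more
#' viable) or `ns`. In the default two-sided mode direction is read off the
#' median difference; the one-sided mode computes per-direction p-values and
#' corrects within each direction. An optional copy-number covariate mode
#' regresses viability on copy number per gene first and tests the
#' residuals, controlling copy-number-driven artifacts.
#'
#' @param screen a `"viability_matrix"`.
#' @param profile a `"mutation_profile"`.
#' @param alpha FDR threshold for the pos/neg calls.
#' @param cn optional copy-number matrix (genes x cell lines, log-ratios)
#'   aligned with the screen.
#' @param sides `"two_sided"` (default) or `"one_sided"`.
#' @return data.frame of class `"de_result"`: gene, modality, p, q, class,
#'   delta_median, n_wt, n_mut.
#' @export
classify_differential <- function(screen, profile, alpha = 0.1, cn = NULL,
                                  sides = c("two_sided", "one_sided")) {
  sides <- match.arg(sides)
  stopifnot(alpha > 0, alpha <= 1)
  is_mut <- align_profile(screen, profile)
  if (sum(is_mut) < 2L || sum(!is_mut) < 2L)
    stop("classify_differential: need >= 2 cell lines in each group")
  values <- screen$values
  if (!is.null(cn)) {
    genes <- screen_genes(screen); lines <- screen_lines(screen)
    if (!all(genes %in% rownames(cn)) || !all(lines %in% colnames(cn)))
      stop("classify_differential: copy-number matrix does not cover the panel")
    cn <- cn[genes, lines, drop = FALSE]
    for (i in seq_len(nrow(values))) {
      ok <- is.finite(values[i, ]) & is.finite(cn[i, ])
      if (sum(ok) >= 3L && stats::sd(cn[i, ok]) > 0) {
        f <- stats::lm.fit(cbind(1, cn[i, ok]), values[i, ok])
        v <- values[i, ]; v[ok] <- f$residuals; v[!ok] <- NA_real_
        values[i, ] <- v
      }
    }
  }
  delta <- delta_median_rows(values, is_mut)
  if (sides == "two_sided") {
    rs <- ranksum_rows(values, is_mut, "two_sided")
    q <- bh_fdr(rs$p)
    cls <- ifelse(is.na(rs$p) | is.na(q) | q >= alpha | is.na(delta) | delta == 0,
                  "ns", ifelse(delta > 0, "pos", "neg"))
  } else {
    rs_g <- ranksum_rows(values, is_mut, "greater")
    rs_l <- ranksum_rows(values, is_mut, "less")
    rs <- rs_g
    rs$p <- pmin(rs_g$p, rs_l$p)
    q_g <- bh_fdr(rs_g$p); q_l <- bh_fdr(rs_l$p)
    q <- pmin(q_g, q_l)
    cls <- rep("ns", length(q))
    cls[!is.na(q_g) & q_g < alpha & !is.na(delta) & delta > 0] <- "pos"
    cls[!is.na(q_l) & q_l < alpha & !is.na(delta) & delta < 0] <- "neg"
  }
  out <- data.frame(gene = screen_genes(screen), modality = screen$modality,
                    p = rs$p, q = q, class = cls, delta_median = delta,
                    n_wt = rs$n_wt, n_mut = rs$n_mut,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("de_result", "data.frame")
  out
}
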