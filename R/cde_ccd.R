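# CDE+/CDE- identification with copy-number confound filtering, and the
# genome-wide scan ranking candidate CRISPR-selected cancer drivers (CCDs).

#' Copy-number association filter
#'
#' Genes whose copy number is itself associated with the driver's mutation
#' status can produce spurious differential-essentiality calls; this filter
#' flags them. Per gene, a two-sided rank-sum test of copy-number log-ratios
#' between mutant and WT lines, BH-corrected; genes with q < alpha are
#' returned for exclusion. Constant copy-number genes are retained (p = 1).
#'
#' @param cn genes x cell-lines numeric matrix of copy-number log-ratios.
#' @param profile a `"mutation_profile"` covering the columns of `cn`.
#' @param alpha FDR threshold.
#' @return Character vector of genes to drop.
#' @export
cn_association_filter <- function(cn, profile, alpha = 0.1) {
  cn <- as.matrix(cn)
  missing <- setdiff(colnames(cn), names(profile$status))
  if (length(missing) > 0)
    stop("cn_association_filter: profile does not cover cell line(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  is_mut <- profile$status[colnames(cn)] == 1L
  rs <- ranksum_rows(cn, is_mut, "two_sided")
  q <- bh_fdr(rs$p)
  rownames(cn)[!is.na(q) & q < alpha]
}

#' Identify CDE+ and CDE- genes
#'
#' CDE+ genes are significantly *more* viable after CRISPR knockout in
#' driver-mutant than WT lines while not showing that differential
#' essentiality in the shRNA screen; CDE- genes are the mirror image.
#' Genes failing the copy-number association filter are removed from both
#' sets. The shRNA exclusion is same-direction by default ("not significant
#' in the same direction"); `shrna_exclusion = "any_direction"` also excludes
#' opposite-direction shRNA hits.
#'
#' @param de_crispr,de_shrna `"de_result"` tables over the same gene universe.
#' @param drop genes excluded by [cn_association_filter()].
#' @param shrna_exclusion `"same_direction"` or `"any_direction"`.
#' @return list of class `"cde_set"`: `cde_pos`, `cde_neg`, `dropped_cn`,
#'   `shrna_exclusion`.
#' @export
identify_cde <- function(de_crispr, de_shrna, drop = character(0),
                         shrna_exclusion = c("same_direction", "any_direction")) {
  shrna_exclusion <- match.arg(shrna_exclusion)
  if (!identical(de_crispr$gene, de_shrna$gene))
    stop("identify_cde: DE tables must share an identical gene universe")
  sh_pos <- de_shrna$class == "pos"
  sh_neg <- de_shrna$class == "neg"
  excl_pos <- if (shrna_exclusion == "same_direction") sh_pos else sh_pos | sh_neg
  excl_neg <- if (shrna_exclusion == "same_direction") sh_neg else sh_pos | sh_neg
  dropped <- de_crispr$gene %in% drop
  cde_pos <- de_crispr$gene[de_crispr$class == "pos" & !excl_pos & !dropped]
  cde_neg <- de_crispr$gene[de_crispr$class == "neg" & !excl_neg & !dropped]
  structure(list(cde_pos = cde_pos, cde_neg = cde_neg,
                 dropped_cn = intersect(drop, de_crispr$gene),
                 shrna_exclusion = shrna_exclusion),
            class = "cde_set")
}

#' @export
print.cde_set <- function(x, ...) {
  cat(sprintf("cde_set: %d CDE+, %d CDE-, %d dropped by CN filter (%s)\n",
              length(x$cde_pos), length(x$cde_neg), length(x$dropped_cn),
              x$shrna_exclusion))
  invisible(x)
}

#' Build the 3 x 2 modality contingency table
#'
#' Counts of genes classified pos / neg / ns in the CRISPR and shRNA screens;
#' column sums equal the shared gene-universe size.
#'
#' @param de_crispr,de_shrna `"de_result"` tables over the same universe.
#' @return 3 x 2 integer matrix, rows pos/neg/ns, columns crispr/shrna.
#' @export
build_contingency <- function(de_crispr, de_shrna) {
  if (!identical(de_crispr$gene, de_shrna$gene))
    stop("build_contingency: DE tables must share an identical gene universe")
  lv <- c("pos", "neg", "ns")
  tab <- cbind(crispr = table(factor(de_crispr$class, levels = lv)),
               shrna = table(factor(de_shrna$class, levels = lv)))
  storage.mode(tab) <- "integer"
  tab
}

#' Test for skew between modalities
#'
#' Tests whether the pos/neg/ns composition in the CRISPR screen deviates
#' from the shRNA screen: Fisher's exact test, replaced by its chi-squared
#' approximation when every cell exceeds `chi2_min_cell`.
#'
#' @param table 3 x 2 contingency matrix from [build_contingency()].
#' @param chi2_min_cell cell-count switch.
#' @param seed seed for the Monte-Carlo fallback on very large exact tables.
#' @return A `"test_result"`.
#' @export
skew_test <- function(table, chi2_min_cell = 30L, seed = 1L) {
  fisher_rxc(table, chi2_min_cell = chi2_min_cell, seed = seed)
}

#' Genome-wide scan for CRISPR-selected cancer drivers
#'
#' For each candidate driver with at least `min_mutant_lines` mutant lines:
#' differential-essentiality classification in both modalities, the 3 x 2
#' contingency table, the modality skew test (BH-corrected across drivers),
#' the per-driver CDE sets after copy-number filtering, and a pairwise
#' Fisher independence test of the driver's mutation profile against the
#' reference driver's (p53 by default) to flag candidates that merely track
#' the reference. A driver is reported when its skew q-value is below
#' `alpha_fdr`, it has more than `ccd_min_cde_pos` CDE+ genes, and it is not
#' correlated with the reference profile. Drivers are ranked by skew q, then
#' number of CDE+ genes (descending), then gene id.
#'
#' @param drivers character vector of candidate driver genes.
#' @param crispr,shrna `"viability_matrix"` objects on a common panel.
#' @param muts a `"mutation_table"`.
#' @param cn optional copy-number matrix for the confound filter.
#' @param config an [analysis_config()].
#' @param reference_driver profile-independence reference (default
#'   `"TP53"`); if absent from `drivers`, the filter is skipped with a
#'   warning.
#' @param mode mutation-classification mode passed to
#'   [derive_mutation_profile()].
#' @return list of class `"ccd_result"`: `table` (per-driver data.frame
#'   with n_mutant_lines, skew statistic/p/q, n_cde_pos/neg, independence q,
#'   flags, rank) and `cde_sets` (named list of `"cde_set"` objects for
#'   tested drivers).
#' @export
ccd_scan <- function(drivers, crispr, shrna, muts, cn = NULL,
                     config = analysis_config(), reference_driver = "TP53",
                     mode = "any_nonsynonymous") {
  drivers <- sort(unique(drivers))
  aligned <- withCallingHandlers(intersect_panels(crispr, shrna, muts),
                                 message = function(m) invokeRestart("muffleMessage"))
  crispr <- aligned$v1; shrna <- aligned$v2; muts <- aligned$muts
  lines <- aligned$cell_lines
  alpha <- config$alpha_fdr

  profiles <- lapply(drivers, function(d)
    suppressWarnings(derive_mutation_profile(muts, d, lines, mode = mode)))
  names(profiles) <- drivers
  n_mut <- vapply(profiles, function(p) sum(p$status == 1L), integer(1))
  testable <- n_mut >= config$min_mutant_lines &
    (length(lines) - n_mut) >= 2L & n_mut >= 2L

  skew_stat <- skew_p <- rep(NA_real_, length(drivers))
  n_pos <- n_neg <- rep(NA_integer_, length(drivers))
  cde_sets <- list()
  for (i in seq_along(drivers)) {
    if (!testable[i]) next
    pr <- profiles[[i]]
    de_c <- classify_differential(crispr, pr, alpha, sides = config$sides)
    de_s <- classify_differential(shrna, pr, alpha, sides = config$sides)
    tab <- build_contingency(de_c, de_s)
    st <- skew_test(tab, config$chi2_min_cell, seed = config$seed)
    skew_stat[i] <- st$statistic
    skew_p[i] <- st$p_value
    drop <- if (is.null(cn)) character(0) else
      cn_association_filter(cn[, lines, drop = FALSE], pr, alpha)
    cs <- identify_cde(de_c, de_s, drop, config$shrna_exclusion)
    n_pos[i] <- length(cs$cde_pos)
    n_neg[i] <- length(cs$cde_neg)
    cde_sets[[drivers[i]]] <- cs
  }
  skew_q <- rep(NA_real_, length(drivers))
  skew_q[testable] <- bh_fdr(skew_p[testable])

  # pairwise independence of each candidate's profile against the reference
  indep_q <- rep(NA_real_, length(drivers))
  correlated <- rep(FALSE, length(drivers))
  if (reference_driver %in% drivers) {
    ref_status <- profiles[[reference_driver]]$status
    ip <- rep(NA_real_, length(drivers))
    for (i in seq_along(drivers)) {
      if (!testable[i] || drivers[i] == reference_driver) next
      tab2 <- table(factor(profiles[[i]]$status, levels = 0:1),
                    factor(ref_status, levels = 0:1))
      ip[i] <- fisher_rxc(tab2, chi2_min_cell = config$chi2_min_cell,
                          seed = config$seed)$p_value
    }
    indep_q[!is.na(ip)] <- bh_fdr(ip[!is.na(ip)])
    correlated <- !is.na(indep_q) & indep_q < alpha
  } else {
    warning("ccd_scan: reference driver '", reference_driver,
            "' not among candidates; independence filter skipped")
  }

  reported <- testable & !is.na(skew_q) & skew_q < alpha &
    !is.na(n_pos) & n_pos > config$ccd_min_cde_pos & !correlated
  ord <- order(skew_q, -ifelse(is.na(n_pos), -Inf, n_pos), drivers,
               na.last = TRUE)
  rank_out <- integer(length(drivers)); rank_out[ord] <- seq_along(drivers)
  tab <- data.frame(driver = drivers, n_mutant_lines = n_mut,
                    skew_stat = skew_stat, skew_p = skew_p, skew_q = skew_q,
                    n_cde_pos = n_pos, n_cde_neg = n_neg,
                    independence_q = indep_q,
                    insufficient_mutants = !testable,
                    reference_correlated = correlated,
                    reported = reported, rank = rank_out,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(tab$rank), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, cde_sets = cde_sets,
                 reference_driver = reference_driver),
            class = "ccd_result")
}

#' @export
print.ccd_result <- function(x, ...) {
  cat(sprintf("ccd_result: %d candidates, %d reported\n",
              nrow(x$table), sum(x$table$reported)))
  print(utils::head(x$table, 10))
  invisible(x)
}
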