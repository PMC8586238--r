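# Cas9-activity association with driver mutation status, and the
# parental-vs-Cas9 mutant-allele-frequency expansion analysis.

#' Scan drivers for Cas9-activity association
#'
#' For each driver, tests whether Cas9 activity (GFP-reporter fraction) is
#' higher in mutant than WT cell lines via a one-sided rank-sum test, with BH
#' correction across tested drivers. Drivers with fewer than
#' `min_mutant_lines` mutants among lines with activity data are flagged and
#' not tested. Ranking is by q, then median activity difference.
#'
#' @param activity named numeric vector of per-cell-line Cas9 activity in
#'   [0, 1].
#' @param profiles list of `"mutation_profile"` objects (one per driver).
#' @param min_mutant_lines minimum mutants required to test a driver.
#' @return data.frame: driver, n_mut, n_wt, delta (median mutant - WT
#'   activity), p, q, tested, rank.
#' @export
activity_scan <- function(activity, profiles, min_mutant_lines = 10L) {
  if (any(activity < 0 | activity > 1, na.rm = TRUE))
    stop("activity_scan: activity must lie in [0, 1]")
  lines <- names(activity)
  res <- lapply(profiles, function(pr) {
    st <- pr$status[intersect(lines, names(pr$status))]
    act <- activity[names(st)]
    ok <- is.finite(act)
    st <- st[ok]; act <- act[ok]
    n_mut <- sum(st == 1L); n_wt <- sum(st == 0L)
    if (n_mut < min_mutant_lines || n_wt < 2L)
      return(data.frame(driver = pr$driver, n_mut = n_mut, n_wt = n_wt,
                        delta = NA_real_, p = NA_real_, tested = FALSE))
    tr <- rank_sum_test(act[st == 1L], act[st == 0L], "greater")
    data.frame(driver = pr$driver, n_mut = n_mut, n_wt = n_wt,
               delta = stats::median(act[st == 1L]) - stats::median(act[st == 0L]),
               p = tr$p_value, tested = TRUE)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  out$q[out$tested] <- bh_fdr(out$p[out$tested])
  ord <- order(out$q, -out$delta, out$driver, na.last = TRUE)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  out[order(out$rank), , drop = FALSE]
}

#' Cas9 activity adjusted for a second driver's status
#'
#' Linear model of activity on the driver's status adjusting for the
#' reference driver's (e.g. p53) status; identical profiles trigger an
#' aliasing warning and the aliased column is dropped.
#'
#' @param activity named numeric activity vector.
#' @param driver_profile,reference_profile `"mutation_profile"` objects.
#' @return Coefficient data.frame from [glm_fit()] (gaussian), terms
#'   intercept / driver / reference.
#' @export
activity_adjusted <- function(activity, driver_profile, reference_profile) {
  lines <- intersect(names(activity),
                     intersect(names(driver_profile$status),
                               names(reference_profile$status)))
  act <- activity[lines]
  ok <- is.finite(act)
  X <- cbind(intercept = 1,
             driver = driver_profile$status[lines][ok],
             reference = reference_profile$status[lines][ok])
  glm_fit(X, act[ok], "gaussian")$coefficients
}

#' Construct a MAF pair table
#'
#' One record per (cell line, variant) with mutant allele frequencies in the
#' parental and the Cas9-expressing derivative.
#'
#' @param cell_line,gene,variant_id character vectors.
#' @param maf_parental,maf_cas9 numeric in [0, 1].
#' @param variant_region `"exonic"` or `"intronic"`.
#' @param activity per-record Cas9 activity of the cell line, in [0, 1].
#' @return data.frame of class `"maf_pair_table"`.
#' @export
maf_pair_table <- function(cell_line, gene, variant_id, maf_parental,
                           maf_cas9, variant_region = "exonic",
                           activity = NA_real_) {
  if (any(maf_parental < 0 | maf_parental > 1, na.rm = TRUE) ||
      any(maf_cas9 < 0 | maf_cas9 > 1, na.rm = TRUE))
    stop("maf_pair_table: allele frequencies must lie in [0, 1]")
  if (any(!variant_region %in% c("exonic", "intronic")))
    stop("maf_pair_table: variant_region must be 'exonic' or 'intronic'")
  df <- data.frame(cell_line = as.character(cell_line),
                   gene = as.character(gene),
                   variant_id = as.character(variant_id),
                   maf_parental = as.numeric(maf_parental),
                   maf_cas9 = as.numeric(maf_cas9),
                   variant_region = as.character(variant_region),
                   activity = as.numeric(activity),
                   stringsAsFactors = FALSE)
  class(df) <- c("maf_pair_table", "data.frame")
  df
}

#' Scan drivers for mutant-allele-frequency expansion
#'
#' Cell lines with Cas9 activity strictly below `min_activity` are discarded
#' (low DNA damage). Per driver, the allele-frequency deltas (Cas9 minus
#' parental) over retained cases are tested for positive shift with a
#' signed-rank test; zero deltas are removed by the signed-rank rule and
#' their count logged. Intronic variants are included by default, matching
#' the primary analysis; `include_intronic = FALSE` reruns the exonic-only
#' variant. Drivers are ranked by p ascending, ties by median delta
#' descending.
#'
#' @param pairs a `"maf_pair_table"` with per-record `activity`.
#' @param drivers driver genes to test.
#' @param min_activity activity gate (cases with activity < gate excluded;
#'   a case at exactly the gate is retained).
#' @param include_intronic include intronic variants.
#' @param alternative signed-rank alternative (default `"greater"`).
#' @return data.frame: driver, n_cases, n_zero_removed, n_increased,
#'   median_delta, p, tested, rank.
#' @export
maf_expansion_scan <- function(pairs, drivers, min_activity = 0.20,
                               include_intronic = TRUE,
                               alternative = "greater") {
  stopifnot(min_activity >= 0, min_activity <= 1)
  keep <- is.na(pairs$activity) | pairs$activity >= min_activity
  pairs <- pairs[keep, , drop = FALSE]
  if (!include_intronic)
    pairs <- pairs[pairs$variant_region != "intronic", , drop = FALSE]
  res <- lapply(drivers, function(d) {
    rec <- pairs[pairs$gene == d, , drop = FALSE]
    delta <- rec$maf_cas9 - rec$maf_parental
    delta <- delta[is.finite(delta)]
    n_cases <- length(delta)
    if (n_cases == 0)
      return(data.frame(driver = d, n_cases = 0L, n_zero_removed = 0L,
                        n_increased = 0L, median_delta = NA_real_,
                        p = NA_real_, tested = FALSE))
    tr <- suppressWarnings(signed_rank_test(delta, alternative))
    data.frame(driver = d, n_cases = n_cases,
               n_zero_removed = sum(delta == 0),
               n_increased = sum(delta > 0),
               median_delta = stats::median(delta),
               p = tr$p_value, tested = TRUE)
  })
  out <- do.call(rbind, res)
  ord <- order(out$p, -out$median_delta, out$driver, na.last = TRUE)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  out[order(out$rank), , drop = FALSE]
}
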