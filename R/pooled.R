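# Pooled isogenic CRISPR-KO / CRISPRi screen analysis: CPM normalization,
# day-0 count filtering, fold-change ranks, isogenic CDE calls, screen QC
# against gold-standard essential genes, and the competition-assay trend
# model.

#' Construct an sgRNA count table
#'
#' Long-format pooled-screen counts: one row per
#' (sgRNA, context, modality, timepoint, replicate).
#'
#' @param sgrna_id,gene character; `gene` may be a control class (`"ntc"`,
#'   `"nonessential_control"`), but each sgRNA must map to exactly one label.
#' @param context `"wt"` or `"mutant"` cell-line context.
#' @param modality `"crispr_ko"` or `"crispri"`.
#' @param timepoint `"day0"` or `"day30"`.
#' @param replicate integer replicate index.
#' @param raw_count non-negative integer read count.
#' @return data.frame of class `"sgrna_counts"`.
#' @export
sgrna_counts <- function(sgrna_id, gene, context, modality, timepoint,
                         replicate, raw_count) {
  stopifnot(all(context %in% c("wt", "mutant")),
            all(modality %in% c("crispr_ko", "crispri")),
            all(timepoint %in% c("day0", "day30")))
  if (any(raw_count < 0) || any(raw_count != round(raw_count)))
    stop("sgrna_counts: raw_count must be non-negative integers")
  map <- unique(data.frame(sgrna_id = sgrna_id, gene = gene))
  if (anyDuplicated(map$sgrna_id))
    stop("sgrna_counts: sgRNA(s) mapped to more than one gene")
  df <- data.frame(sgrna_id = as.character(sgrna_id), gene = as.character(gene),
                   context = context, modality = modality,
                   timepoint = timepoint, replicate = as.integer(replicate),
                   raw_count = as.integer(round(raw_count)),
                   stringsAsFactors = FALSE)
  class(df) <- c("sgrna_counts", "data.frame")
  df
}

#' Counts-per-million normalization
#'
#' Adds a `cpm` column scaled per (context, modality, timepoint, replicate)
#' sample; within-sample count ratios are preserved exactly and each
#' sample's CPM sums to 10^6.
#'
#' @param counts an `"sgrna_counts"` table.
#' @return The table with a `cpm` column.
#' @export
cpm_normalize <- function(counts) {
  key <- interaction(counts$context, counts$modality, counts$timepoint,
                     counts$replicate, drop = TRUE)
  libsize <- tapply(counts$raw_count, key, sum)
  if (any(libsize == 0)) stop("cpm_normalize: zero library size in a sample")
  counts$cpm <- counts$raw_count / as.numeric(libsize[key]) * 1e6
  counts
}

#' Remove sgRNAs with low day-0 counts
#'
#' An sgRNA is removed from all samples if its raw day-0 count falls below
#' `min_day0_count` in any replicate of any context (strict less-than: a
#' count exactly at the threshold is retained). The rule operates on raw
#' counts, so filtering commutes with CPM normalization.
#'
#' @param counts an `"sgrna_counts"` table.
#' @param min_day0_count threshold.
#' @return list(counts = filtered table, removed = sgRNA ids).
#' @export
filter_low_day0 <- function(counts, min_day0_count = 20L) {
  d0 <- counts[counts$timepoint == "day0", , drop = FALSE]
  if (nrow(d0) == 0) stop("filter_low_day0: no day-0 records")
  low <- unique(d0$sgrna_id[d0$raw_count < min_day0_count])
  message(sprintf(
    "filter_low_day0: removing %d sgRNA(s) with any day-0 raw count < %d",
    length(low), min_day0_count))
  list(counts = counts[!counts$sgrna_id %in% low, , drop = FALSE],
       removed = low)
}

#' Fold-change ranks per context
#'
#' Restricts to the shared sgRNA set, computes the replicate-averaged
#' day30/day0 fold change on the CPM scale with pseudocount 0.5, ranks
#' sgRNAs within each (modality, context) ascending (rank 1 = most
#' depleted), and forms the WT-minus-mutant rank difference per sgRNA.
#' sgRNAs missing a timepoint in some context are dropped with a warning.
#'
#' @param counts a CPM-normalized `"sgrna_counts"` table (run
#'   [cpm_normalize()] first).
#' @param shared_sgrnas sgRNA ids present in both libraries; `NULL` keeps
#'   all.
#' @param pseudocount added to both CPM values before the ratio.
#' @return data.frame of class `"fc_table"`: sgrna_id, gene, modality,
#'   fc_wt, fc_mut, rank_wt, rank_mut, rank_diff (wt - mutant).
#' @export
fold_change_ranks <- function(counts, shared_sgrnas = NULL, pseudocount = 0.5) {
  if (is.null(counts$cpm)) stop("fold_change_ranks: run cpm_normalize() first")
  if (!is.null(shared_sgrnas)) {
    if (length(shared_sgrnas) == 0) stop("fold_change_ranks: empty shared set")
    counts <- counts[counts$sgrna_id %in% shared_sgrnas, , drop = FALSE]
  }
  agg <- stats::aggregate(cpm ~ sgrna_id + gene + context + modality + timepoint,
                          data = counts, FUN = mean)
  wide <- stats::reshape(agg, idvar = c("sgrna_id", "gene", "context", "modality"),
                         timevar = "timepoint", direction = "wide")
  incomplete <- !stats::complete.cases(wide[c("cpm.day0", "cpm.day30")])
  if (any(incomplete)) {
    warning("fold_change_ranks: dropping ", sum(incomplete),
            " sgRNA/context record(s) missing a timepoint")
    wide <- wide[!incomplete, , drop = FALSE]
  }
  wide$fc <- (wide$cpm.day30 + pseudocount) / (wide$cpm.day0 + pseudocount)
  out <- NULL
  for (mod in unique(wide$modality)) {
    w <- wide[wide$modality == mod, , drop = FALSE]
    wt <- w[w$context == "wt", c("sgrna_id", "gene", "fc")]
    mu <- w[w$context == "mutant", c("sgrna_id", "fc")]
    m <- merge(wt, mu, by = "sgrna_id", suffixes = c("_wt", "_mut"))
    if (nrow(m) == 0) next
    m$rank_wt <- rank(m$fc_wt)
    m$rank_mut <- rank(m$fc_mut)
    m$rank_diff <- m$rank_wt - m$rank_mut
    m$modality <- mod
    out <- rbind(out, m[, c("sgrna_id", "gene", "modality", "fc_wt", "fc_mut",
                            "rank_wt", "rank_mut", "rank_diff")])
  }
  if (is.null(out))
    stop("fold_change_ranks: no sgRNA has both timepoints in both contexts")
  rownames(out) <- NULL
  class(out) <- c("fc_table", "data.frame")
  out
}

#' Isogenic CDE calls from paired CRISPR-KO and CRISPRi screens
#'
#' Per gene, aggregates the sgRNA-level WT-minus-mutant fold-change rank
#' differences (mean by default) in each modality; the screen-difference
#' score is the CRISPR-KO aggregate minus the CRISPRi aggregate. CDE+
#' behaviour - WT-specific depletion under knockout but not under
#' interference - yields strongly negative scores, so the k most negative
#' genes become `cde_pos_iso` and the k most positive `cde_neg_iso`. Genes
#' with fewer than two surviving sgRNAs are excluded from calls. Also emits
#' two-sided signed-rank tests comparing the gene-level WT and mutant ranks
#' within each called class and modality. Degenerate inputs (all scores
#' zero, e.g. identical KO and CRISPRi screens) are flagged.
#'
#' @param fc an `"fc_table"` containing both modalities.
#' @param k number of genes per call class.
#' @param aggregate `"mean"` or `"median"` sgRNA-to-gene aggregation.
#' @return list of class `"iso_cde"`: `cde_pos_iso`, `cde_neg_iso`,
#'   `scores` (per-gene data.frame), `class_tests` (data.frame of
#'   signed-rank p per class x modality), `degenerate`.
#' @export
isogenic_cde_call <- function(fc, k, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  fun <- if (aggregate == "mean") mean else stats::median
  need <- c("crispr_ko", "crispri")
  if (!all(need %in% fc$modality))
    stop("isogenic_cde_call: both crispr_ko and crispri modalities required")
  n_sg <- stats::aggregate(sgrna_id ~ gene + modality, data = fc,
                           FUN = function(x) length(unique(x)))
  per_gene <- function(mod, col) {
    w <- fc[fc$modality == mod, , drop = FALSE]
    a <- stats::aggregate(w[[col]], by = list(gene = w$gene), FUN = fun)
    stats::setNames(a$x, a$gene)
  }
  rd_ko <- per_gene("crispr_ko", "rank_diff")
  rd_i <- per_gene("crispri", "rank_diff")
  genes <- intersect(names(rd_ko), names(rd_i))
  min_sg <- tapply(n_sg$sgrna_id, n_sg$gene, min)[genes]
  eligible <- genes[min_sg >= 2L]
  excluded <- setdiff(genes, eligible)
  if (length(excluded) > 0)
    message("isogenic_cde_call: excluding ", length(excluded),
            " gene(s) with < 2 surviving sgRNAs")
  if (k > length(eligible))
    stop("isogenic_cde_call: k exceeds the eligible gene universe (",
         length(eligible), ")")
  score <- rd_ko[eligible] - rd_i[eligible]
  degenerate <- all(score == 0)
  if (degenerate)
    warning("isogenic_cde_call: all screen-difference scores are zero; ",
            "calls are tie-broken by gene id and flagged degenerate")
  ord <- order(score, names(score))  # most negative first = CDE+ behaviour
  cde_pos <- names(score)[ord][seq_len(k)]
  cde_neg <- rev(names(score)[ord])[seq_len(k)]
  # Fig-2-style class tests: gene-level WT vs mutant ranks, per modality
  rank_cols <- function(mod) {
    w <- fc[fc$modality == mod, , drop = FALSE]
    list(wt = stats::setNames(
           stats::aggregate(w$rank_wt, by = list(gene = w$gene), FUN = fun)$x,
           sort(unique(w$gene))),
         mut = stats::setNames(
           stats::aggregate(w$rank_mut, by = list(gene = w$gene), FUN = fun)$x,
           sort(unique(w$gene))))
  }
  class_tests <- NULL
  for (mod in need) {
    rc <- rank_cols(mod)
    for (cls in c("cde_pos_iso", "cde_neg_iso")) {
      members <- if (cls == "cde_pos_iso") cde_pos else cde_neg
      members <- intersect(members, intersect(names(rc$wt), names(rc$mut)))
      p <- if (length(members) >= 2) {
        d <- rc$wt[members] - rc$mut[members]
        suppressWarnings(signed_rank_test(d, "two_sided")$p_value)
      } else NA_real_
      class_tests <- rbind(class_tests,
                           data.frame(class = cls, modality = mod,
                                      n_genes = length(members), p = p))
    }
  }
  structure(list(cde_pos_iso = cde_pos, cde_neg_iso = cde_neg,
                 scores = data.frame(gene = names(score),
                                     rank_diff_ko = rd_ko[names(score)],
                                     rank_diff_i = rd_i[names(score)],
                                     score = unname(score), row.names = NULL),
                 class_tests = class_tests, degenerate = degenerate,
                 excluded = excluded),
            class = "iso_cde")
}

#' Screen quality control against gold-standard gene sets
#'
#' Ranks genes by ascending mean logFC (most depleted first = predicted
#' essential), restricts to gold-labeled genes, and computes the average
#' precision with essentials as positives; the screen passes when the AUPRC
#' exceeds `threshold`. AUROC is reported alongside.
#'
#' @param gene_scores named numeric vector of per-gene mean logFC.
#' @param gold list with elements `essential` and `nonessential` (character
#'   vectors).
#' @param threshold pass threshold on the AUPRC.
#' @return list: auprc, auroc, n_essential, n_nonessential, pass.
#' @export
screen_qc <- function(gene_scores, gold, threshold = 0.6) {
  ess <- intersect(gold$essential, names(gene_scores))
  non <- intersect(gold$nonessential, names(gene_scores))
  if (length(ess) == 0 || length(non) == 0)
    stop("screen_qc: gold sets do not intersect the scored universe")
  lab_genes <- c(ess, non)
  scores <- gene_scores[lab_genes]
  labels <- c(rep(1L, length(ess)), rep(0L, length(non)))
  ap <- average_precision(scores, labels, higher_is_positive = FALSE)
  au <- auroc(scores, labels, higher_is_positive = FALSE)
  list(auprc = ap, auroc = au, n_essential = length(ess),
       n_nonessential = length(non), pass = ap > threshold)
}

#' Competition-assay trend model
#'
#' Linear model of the percentage of mutant cells on day (continuous) with
#' sgRNA as a categorical covariate; returns the day coefficient and its
#' 15-day extrapolation (slope and standard error multiplied by 15).
#'
#' @param observations data.frame with columns `day`, `sgrna`, `pct_mutant`.
#' @return list: slope_per_day, se_per_day, slope_x15, se_x15, p.
#' @export
competition_trend <- function(observations) {
  stopifnot(all(c("day", "sgrna", "pct_mutant") %in% names(observations)))
  if (length(unique(observations$day)) < 2L)
    stop("competition_trend: need at least two distinct days")
  sg <- factor(observations$sgrna)
  X <- cbind(intercept = 1, day = observations$day)
  if (nlevels(sg) > 1) {
    D <- stats::model.matrix(~ sg)[, -1, drop = FALSE]
    X <- cbind(X, D)
  }
  fit <- glm_fit(X, observations$pct_mutant, "gaussian")
  co <- fit$coefficients
  i <- match("day", co$term)
  list(slope_per_day = co$estimate[i], se_per_day = co$se[i],
       slope_x15 = 15 * co$estimate[i], se_x15 = 15 * co$se[i],
       p = co$p_value[i])
}
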