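# Patient-cohort analyses: the per-sample copy-number alteration burden (GI)
# of a gene set, its comparison between CDE+ and control gene sets by driver
# stratum, and the per-gene logistic interaction model linking a gene's
# absolute SCNA level and tumor stage to driver-mutation accumulation.

#' Construct a tumor cohort
#'
#' @param scna samples x genes numeric matrix of SCNA log-ratios (signed;
#'   absolute values are taken internally where the model requires them).
#' @param cancer_type per-sample categorical.
#' @param stage_binary per-sample 0 (stage I/II) or 1 (stage III/IV).
#' @param mutation_load per-sample non-negative non-synonymous variant count.
#' @param driver_status per-sample 0 (WT) / 1 (mutant).
#' @return A list of class `"tumor_cohort"`.
#' @export
tumor_cohort <- function(scna, cancer_type, stage_binary, mutation_load,
                         driver_status) {
  scna <- as.matrix(scna)
  n <- nrow(scna)
  stopifnot(length(cancer_type) == n, length(stage_binary) == n,
            length(mutation_load) == n, length(driver_status) == n)
  if (is.null(colnames(scna))) stop("tumor_cohort: scna needs gene colnames")
  if (any(!stage_binary %in% c(0, 1)))
    stop("tumor_cohort: stage_binary must be 0 (I/II) or 1 (III/IV)")
  if (any(mutation_load < 0)) stop("tumor_cohort: mutation_load must be >= 0")
  if (any(!driver_status %in% c(0, 1)))
    stop("tumor_cohort: driver_status must be 0/1")
  structure(list(scna = scna, cancer_type = as.factor(cancer_type),
                 stage_binary = as.integer(stage_binary),
                 mutation_load = as.numeric(mutation_load),
                 driver_status = as.integer(driver_status)),
            class = "tumor_cohort")
}

#' Per-sample copy-number alteration burden of a gene set
#'
#' For each sample, the fraction of gene-set genes whose absolute SCNA
#' log-ratio strictly exceeds 1. Missing SCNA entries are excluded from both
#' the numerator and the denominator of that sample.
#'
#' @param cohort a `"tumor_cohort"`.
#' @param geneset character gene set (subset of the cohort's genes).
#' @return Numeric vector of per-sample scores in [0, 1] with attribute
#'   `geneset_size`.
#' @export
gi_score <- function(cohort, geneset) {
  geneset <- unique(geneset)
  if (length(geneset) == 0) stop("gi_score: empty gene set")
  missing <- setdiff(geneset, colnames(cohort$scna))
  if (length(missing) > 0)
    stop("gi_score: gene(s) absent from cohort: ",
         paste(utils::head(missing, 5), collapse = ", "))
  s <- abs(cohort$scna[, geneset, drop = FALSE])
  altered <- s > 1          # strict inequality
  n_obs <- rowSums(is.finite(s))
  if (any(n_obs == 0)) warning("gi_score: sample(s) with no observed gene")
  gi <- rowSums(altered & is.finite(s)) / n_obs
  attr(gi, "geneset_size") <- length(geneset)
  gi
}

#' Compare CDE+ and control gene-set alteration burden by driver stratum
#'
#' Within each driver stratum (WT, mutant), tests whether the per-sample GI
#' of the CDE+ gene set is lower than that of control gene sets via a
#' one-sided rank-sum test. If `control` is `NULL`, size-matched random gene
#' sets are drawn from the non-CDE genes (`n_control_draws` draws, seeded)
#' and the per-stratum p-values are combined by their median.
#'
#' @param cohort a `"tumor_cohort"`.
#' @param cde_pos CDE+ gene set.
#' @param control explicit control gene set, or `NULL` for size-matched
#'   random draws.
#' @param n_control_draws number of random control draws.
#' @param seed RNG seed for the draws.
#' @return data.frame: stratum ("wt", "mutant"), n_samples, p.
#' @export
compare_gi <- function(cohort, cde_pos, control = NULL,
                       n_control_draws = 100L, seed = 1L) {
  if (!is.null(control) && length(control) == 0)
    stop("compare_gi: empty control gene set")
  strata <- list(wt = cohort$driver_status == 0L,
                 mutant = cohort$driver_status == 1L)
  for (nm in names(strata))
    if (sum(strata[[nm]]) == 0) stop("compare_gi: empty stratum: ", nm)
  gi_cde <- gi_score(cohort, cde_pos)
  one_p <- function(ctrl, idx) {
    gi_ctrl <- gi_score(cohort, ctrl)
    rank_sum_test(gi_cde[idx], gi_ctrl[idx], alternative = "less")$p_value
  }
  p <- vapply(names(strata), function(nm) {
    idx <- strata[[nm]]
    if (!is.null(control)) return(one_p(control, idx))
    pool <- setdiff(colnames(cohort$scna), cde_pos)
    if (length(pool) < length(unique(cde_pos)))
      stop("compare_gi: not enough non-CDE genes for size-matched controls")
    draws <- withr::with_seed(seed, replicate(n_control_draws,
      sample(pool, length(unique(cde_pos))), simplify = FALSE))
    stats::median(vapply(draws, one_p, numeric(1), idx = idx))
  }, numeric(1))
  data.frame(stratum = names(strata),
             n_samples = vapply(strata, sum, integer(1)),
             p = p, row.names = NULL, stringsAsFactors = FALSE)
}

# Shared design builder for the interaction model: cancer-type dummies
# (reference = first level; block dropped when only one level), mutation
# load (optionally log10(x+1)), per-gene absolute SCNA level, binary stage
# and the SCNA-by-stage interaction.
interaction_design <- function(cohort, gene, log_mutation_load = FALSE) {
  gi <- abs(cohort$scna[, gene])
  load <- cohort$mutation_load
  if (log_mutation_load) load <- log10(load + 1)
  X <- cbind(intercept = rep(1, length(gi)))
  if (nlevels(cohort$cancer_type) > 1) {
    ct <- stats::model.matrix(~ cancer_type, data = list(cancer_type = cohort$cancer_type))
    X <- cbind(X, ct[, -1, drop = FALSE])
  }
  cbind(X, mutation_load = load, gi = gi, stage = cohort$stage_binary,
        gi_x_stage = gi * cohort$stage_binary)
}

#' Fit the per-gene SCNA-stage interaction logistic model
#'
#' Logistic regression of driver-mutation status on cancer-type dummies,
#' overall mutation load, the gene's absolute SCNA level, binary stage and
#' the SCNA-by-stage interaction. A significantly positive interaction
#' coefficient indicates that high absolute SCNA of the gene is associated
#' with faster driver-mutation accumulation with stage.
#'
#' @param cohort a `"tumor_cohort"`.
#' @param gene gene id (a column of the SCNA matrix).
#' @param log_mutation_load apply log10(x+1) to the mutation load.
#' @return One-row data.frame: gene, beta_gi, beta_stage, beta_interact,
#'   se_interact, p_interact, converged.
#' @export
fit_interaction_model <- function(cohort, gene, log_mutation_load = FALSE) {
  if (!gene %in% colnames(cohort$scna))
    stop("fit_interaction_model: gene absent from cohort: ", gene)
  X <- interaction_design(cohort, gene, log_mutation_load)
  ok <- rowSums(!is.finite(X)) == 0
  fit <- glm_fit(X[ok, , drop = FALSE], cohort$driver_status[ok], "binomial")
  co <- fit$coefficients
  grab <- function(term, col) {
    i <- match(term, co$term)
    if (is.na(i)) NA_real_ else co[[col]][i]
  }
  data.frame(gene = gene,
             beta_gi = grab("gi", "estimate"),
             beta_stage = grab("stage", "estimate"),
             beta_interact = grab("gi_x_stage", "estimate"),
             se_interact = grab("gi_x_stage", "se"),
             p_interact = grab("gi_x_stage", "p_value"),
             converged = fit$converged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fit the interaction model across many genes
#'
#' @param cohort a `"tumor_cohort"`.
#' @param genes genes to fit (default: every cohort gene).
#' @param log_mutation_load apply log10(x+1) to the mutation load.
#' @return data.frame with one [fit_interaction_model()] row per gene.
#' @export
fit_interaction_models <- function(cohort, genes = colnames(cohort$scna),
                                   log_mutation_load = FALSE) {
  do.call(rbind, lapply(genes, function(g)
    fit_interaction_model(cohort, g, log_mutation_load)))
}

#' Enrichment of CDE+ genes among significant positive interactions
#'
#' Defines the significant set as converged fits with a positive interaction
#' coefficient and BH q below `alpha`, then tests the hypergeometric
#' enrichment of CDE+ genes in that set within the universe of converged
#' fits.
#'
#' @param fits table from [fit_interaction_models()].
#' @param cde_pos CDE+ gene set.
#' @param alpha FDR threshold for the significant-positive set.
#' @return A `"test_result"` with attribute `significant_genes`.
#' @export
interaction_enrichment <- function(fits, cde_pos, alpha = 0.1) {
  conv <- fits[fits$converged & !is.na(fits$p_interact), , drop = FALSE]
  if (nrow(conv) == 0) stop("interaction_enrichment: no converged fits")
  q <- bh_fdr(conv$p_interact)
  sig <- conv$gene[conv$beta_interact > 0 & q < alpha]
  universe <- conv$gene
  if (length(sig) == 0) {
    warning("interaction_enrichment: empty significant set; p = 1")
    res <- test_result(0, 1, "greater", "exact")
  } else {
    res <- overlap_enrichment(intersect(cde_pos, universe), sig, universe)
  }
  attr(res, "significant_genes") <- sig
  res
}
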