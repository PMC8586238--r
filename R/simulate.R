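# Seeded generators producing every input class with known planted
# structure, so the whole pipeline is testable without external downloads.
# Each generator is a pure function of its parameters including the seed,
# and returns a truth ledger sufficient to score downstream callers.

#' Parameters for the paired-screen generator
#'
#' Defaults describe the reference desk-scale panel: 60 cell lines, 2000
#' genes, a driver mutated in half the lines, planted CRISPR-specific
#' differential essentiality of 1.5 viability units over unit Gaussian
#' noise, 2% missing values.
#'
#' @param n_lines,n_genes panel dimensions.
#' @param driver_mutation_rate Bernoulli rate of driver mutation per line.
#' @param n_cde_pos,n_cde_neg planted CRISPR-specific differential genes.
#' @param n_shared_de genes shifted in both modalities (excluded by the
#'   shRNA criterion, hence not true CDEs).
#' @param n_cn_confounded genes whose copy number tracks mutation status and
#'   leaks into CRISPR viability (removed by the copy-number filter).
#' @param effect_size viability shift added to mutant lines (units of the
#'   score; >= 0).
#' @param noise_sd Gaussian noise standard deviation.
#' @param missing_rate completely-at-random missingness rate.
#' @param n_null_drivers extra candidate drivers with random mutation status
#'   and no planted effect (for scan calibration studies).
#' @param heavy_tails use scaled t(5) noise instead of Gaussian to stress
#'   the rank tests.
#' @param seed integer seed.
#' @return A parameter list of class `"screen_sim_params"`.
#' @export
screen_sim_params <- function(n_lines = 60L, n_genes = 2000L,
                              driver_mutation_rate = 0.5,
                              n_cde_pos = 120L, n_cde_neg = 60L,
                              n_shared_de = 60L, n_cn_confounded = 30L,
                              effect_size = 1.5, noise_sd = 1,
                              missing_rate = 0.02, n_null_drivers = 0L,
                              heavy_tails = FALSE, seed = 1L) {
  stopifnot(effect_size >= 0, noise_sd > 0,
            missing_rate >= 0, missing_rate < 1,
            driver_mutation_rate > 0, driver_mutation_rate < 1)
  if (n_cde_pos + n_cde_neg + n_shared_de + n_cn_confounded > n_genes)
    stop("screen_sim_params: planted class counts exceed n_genes")
  structure(as.list(environment()), class = "screen_sim_params")
}

# t(5) scaled to unit variance, or standard normal
.sim_noise <- function(n, sd, heavy_tails) {
  if (heavy_tails) sd * stats::rt(n, df = 5) / sqrt(5 / 3) else stats::rnorm(n, 0, sd)
}

#' Simulate a paired CRISPR/shRNA screen panel with planted structure
#'
#' Baseline viability is noise around zero in both modalities. Planted CDE+
#' genes add `effect_size` to mutant-line viability in the CRISPR screen
#' only; CDE- genes subtract it; shared-DE genes shift in both modalities;
#' copy-number-confounded genes have their copy number raised in mutant
#' lines with viability coupled to copy number in the CRISPR screen. The
#' focal driver is `"DRIVER"`; a few WT lines carry silent driver variants
#' (which must not flip their status). Optional null drivers (`ND01`, ...)
#' have random mutation status and no effect.
#'
#' @param params a [screen_sim_params()].
#' @return list: `crispr`, `shrna` (`"viability_matrix"`), `muts`
#'   (`"mutation_table"`), `cn` (genes x lines matrix), `truth` (data.frame
#'   gene/class), `driver`, `null_drivers`, `params`.
#' @export
simulate_screen_pair <- function(params = screen_sim_params()) {
  stopifnot(inherits(params, "screen_sim_params"))
  withr::with_seed(params$seed, {
    p <- params
    genes <- sprintf("G%04d", seq_len(p$n_genes))
    lines <- sprintf("L%03d", seq_len(p$n_lines))
    classes <- rep("null", p$n_genes)
    idx <- seq_len(p$n_cde_pos + p$n_cde_neg + p$n_shared_de + p$n_cn_confounded)
    planted <- sample(p$n_genes, length(idx))
    cls_vec <- rep(c("cde_pos", "cde_neg", "shared_de", "cn_confounded"),
                   times = c(p$n_cde_pos, p$n_cde_neg, p$n_shared_de,
                             p$n_cn_confounded))
    classes[planted] <- cls_vec
    is_mut <- stats::rbinom(p$n_lines, 1L, p$driver_mutation_rate) == 1L

    crispr <- matrix(.sim_noise(p$n_genes * p$n_lines, p$noise_sd, p$heavy_tails),
                     p$n_genes, p$n_lines, dimnames = list(genes, lines))
    shrna <- matrix(.sim_noise(p$n_genes * p$n_lines, p$noise_sd, p$heavy_tails),
                    p$n_genes, p$n_lines, dimnames = list(genes, lines))
    cn <- matrix(stats::rnorm(p$n_genes * p$n_lines, 0, 0.3),
                 p$n_genes, p$n_lines, dimnames = list(genes, lines))

    eff <- p$effect_size
    crispr[classes == "cde_pos", is_mut] <-
      crispr[classes == "cde_pos", is_mut] + eff
    crispr[classes == "cde_neg", is_mut] <-
      crispr[classes == "cde_neg", is_mut] - eff
    crispr[classes == "shared_de", is_mut] <-
      crispr[classes == "shared_de", is_mut] + eff
    shrna[classes == "shared_de", is_mut] <-
      shrna[classes == "shared_de", is_mut] + eff
    conf <- classes == "cn_confounded"
    cn[conf, is_mut] <- cn[conf, is_mut] + 2 * sign(eff + 1e-9)
    crispr[conf, ] <- crispr[conf, ] + 0.6 * eff * cn[conf, ]

    if (p$missing_rate > 0) {
      na1 <- matrix(stats::runif(length(crispr)) < p$missing_rate, p$n_genes)
      na2 <- matrix(stats::runif(length(shrna)) < p$missing_rate, p$n_genes)
      # keep at least one finite value per row
      na1[rowSums(!na1) == 0, 1] <- FALSE
      na2[rowSums(!na2) == 0, 1] <- FALSE
      crispr[na1] <- NA_real_
      shrna[na2] <- NA_real_
    }

    mut_rows <- data.frame(cell_line = lines[is_mut], gene = "DRIVER",
                           variant_classification = "missense",
                           protein_change = "R111H",
                           allele_frequency = NA_real_)
    wt_lines <- lines[!is_mut]
    n_sil <- max(1L, round(0.05 * length(wt_lines)))
    sil_rows <- if (length(wt_lines) > 0)
      data.frame(cell_line = sample(wt_lines, min(n_sil, length(wt_lines))),
                 gene = "DRIVER", variant_classification = "silent",
                 protein_change = "L222L", allele_frequency = NA_real_)
    else NULL
    null_drivers <- character(0)
    nd_rows <- NULL
    if (p$n_null_drivers > 0) {
      null_drivers <- sprintf("ND%02d", seq_len(p$n_null_drivers))
      for (nd in null_drivers) {
        st <- stats::rbinom(p$n_lines, 1L, p$driver_mutation_rate) == 1L
        if (any(st))
          nd_rows <- rbind(nd_rows,
                           data.frame(cell_line = lines[st], gene = nd,
                                      variant_classification = "missense",
                                      protein_change = "A10V",
                                      allele_frequency = NA_real_))
      }
    }
    mt <- do.call(rbind, Filter(Negate(is.null),
                                list(mut_rows, sil_rows, nd_rows)))
    muts <- mutation_table(mt$cell_line, mt$gene, mt$variant_classification,
                           mt$protein_change, mt$allele_frequency)

    list(crispr = viability_matrix(crispr, "crispr_ko"),
         shrna = viability_matrix(shrna, "shrna"),
         muts = muts, cn = cn,
         truth = data.frame(gene = genes, class = classes,
                            stringsAsFactors = FALSE),
         driver = "DRIVER", null_drivers = null_drivers, params = params)
  })
}

#' Parameters for the tumor-cohort generator
#'
#' The forward model is the same logistic interaction model the fitting
#' stage estimates: driver-mutation probability depends on cancer type,
#' mutation load, the gene's absolute SCNA level, binary stage and the
#' SCNA-by-stage interaction.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param n_cancer_types number of cancer-type levels.
#' @param beta0 intercept.
#' @param beta_cancer_type length `n_cancer_types - 1` dummy effects.
#' @param beta_mutation_load,beta_gi,beta_stage,beta_interact model
#'   coefficients.
#' @param scna_sd SCNA log-ratio standard deviation.
#' @param stage_rate Bernoulli rate of late stage (III/IV).
#' @param mutation_load_mean Poisson mean of the per-sample load.
#' @param seed integer seed.
#' @return A parameter list of class `"cohort_sim_params"`.
#' @export
cohort_sim_params <- function(n_samples = 2000L, n_genes = 100L,
                              n_cancer_types = 3L, beta0 = -0.5,
                              beta_cancer_type = NULL,
                              beta_mutation_load = 0.02, beta_gi = 0.3,
                              beta_stage = 0.3, beta_interact = 0.5,
                              scna_sd = 1, stage_rate = 0.5,
                              mutation_load_mean = 10, seed = 1L) {
  if (is.null(beta_cancer_type))
    beta_cancer_type <- rep(c(0.3, -0.3), length.out = n_cancer_types - 1L)
  stopifnot(length(beta_cancer_type) == n_cancer_types - 1L,
            scna_sd > 0, stage_rate > 0, stage_rate < 1)
  structure(as.list(environment()), class = "cohort_sim_params")
}

#' Simulate a tumor cohort from the interaction model
#'
#' SCNA log-ratios are Gaussian; stage is Bernoulli; mutation load is
#' Poisson; driver status is drawn from the logistic interaction model using
#' the designated gene's absolute SCNA level. When `cde_pos` is supplied,
#' those genes share a latent copy-number-burden factor that enters the
#' model, so each of them individually carries a positive interaction
#' signal; optionally their alterations are damped in driver-WT samples
#' (`suppress_wt_factor`) for burden-comparison tests.
#'
#' @param params a [cohort_sim_params()].
#' @param cde_pos optional planted CDE+ gene set (subset of simulated
#'   genes by index or name `Gxxx`).
#' @param suppress_wt_factor optional multiplier (< 1) applied to the SCNA
#'   of `cde_pos` genes in driver-WT samples.
#' @return list: `cohort` (`"tumor_cohort"`), `truth` (designated gene,
#'   betas, cde_pos), `params`.
#' @export
simulate_cohort <- function(params = cohort_sim_params(), cde_pos = NULL,
                            suppress_wt_factor = NULL) {
  stopifnot(inherits(params, "cohort_sim_params"))
  withr::with_seed(params$seed, {
    p <- params
    genes <- sprintf("G%03d", seq_len(p$n_genes))
    if (!is.null(cde_pos)) cde_pos <- intersect(cde_pos, genes)
    scna <- matrix(stats::rnorm(p$n_samples * p$n_genes, 0, p$scna_sd),
                   p$n_samples, p$n_genes, dimnames = list(NULL, genes))
    ct <- factor(sample(paste0("T", seq_len(p$n_cancer_types)),
                        p$n_samples, replace = TRUE))
    stage <- stats::rbinom(p$n_samples, 1L, p$stage_rate)
    load <- stats::rpois(p$n_samples, p$mutation_load_mean)
    if (!is.null(cde_pos) && length(cde_pos) > 0) {
      burden <- abs(stats::rnorm(p$n_samples, 0, p$scna_sd))
      for (g in cde_pos)
        scna[, g] <- sample(c(-1, 1), p$n_samples, replace = TRUE) *
          (burden + abs(stats::rnorm(p$n_samples, 0, 0.3)))
      gi_term <- burden
      designated <- NA_character_
    } else {
      designated <- genes[1L]
      gi_term <- abs(scna[, designated])
    }
    ct_mm <- if (nlevels(ct) > 1)
      stats::model.matrix(~ ct)[, -1, drop = FALSE] %*% p$beta_cancer_type
    else 0
    eta <- p$beta0 + as.numeric(ct_mm) + p$beta_mutation_load * load +
      p$beta_gi * gi_term + p$beta_stage * stage +
      p$beta_interact * gi_term * stage
    prob <- stats::plogis(eta)
    if (all(prob > 1 - 1e-8) || all(prob < 1e-8))
      stop("simulate_cohort: degenerate mutation probabilities")
    status <- stats::rbinom(p$n_samples, 1L, prob)
    if (!is.null(suppress_wt_factor) && !is.null(cde_pos))
      scna[status == 0L, cde_pos] <- suppress_wt_factor *
        scna[status == 0L, cde_pos]
    cohort <- tumor_cohort(scna, ct, stage, load, status)
    list(cohort = cohort,
         truth = list(designated_gene = designated,
                      betas = list(beta0 = p$beta0,
                                   beta_cancer_type = p$beta_cancer_type,
                                   beta_mutation_load = p$beta_mutation_load,
                                   beta_gi = p$beta_gi,
                                   beta_stage = p$beta_stage,
                                   beta_interact = p$beta_interact),
                      cde_pos = cde_pos),
         params = params)
  })
}

#' Simulate paired parental/Cas9 allele-frequency tables
#'
#' Parental mutant allele frequencies are Uniform(0.05, 0.5); the Cas9
#' derivative adds `delta` plus noise for the planted driver (clipped to
#' [0, 1]) and noise only for null drivers. Per-line Cas9 activities are
#' Uniform over `activity_range`.
#'
#' @param n_lines number of cell lines.
#' @param n_drivers number of null drivers (`D01`, ...).
#' @param planted_driver name of the expanding driver.
#' @param delta mean allele-frequency increase for the planted driver, in
#'   [-1, 1].
#' @param activity_range length-2 activity range.
#' @param noise_sd frequency noise standard deviation.
#' @param seed integer seed.
#' @return list: `pairs` (`"maf_pair_table"` with joined activity),
#'   `activity` (named vector), `planted_driver`.
#' @export
simulate_maf_pairs <- function(n_lines = 20L, n_drivers = 10L,
                               planted_driver = "KRAS", delta = 0.1,
                               activity_range = c(0.2, 1), noise_sd = 0.03,
                               seed = 1L) {
  stopifnot(delta >= -1, delta <= 1)
  if (length(activity_range) != 2L || activity_range[1] > activity_range[2] ||
      activity_range[1] < 0 || activity_range[2] > 1)
    stop("simulate_maf_pairs: invalid activity range")
  withr::with_seed(seed, {
    lines <- sprintf("CL%02d", seq_len(n_lines))
    activity <- stats::setNames(
      stats::runif(n_lines, activity_range[1], activity_range[2]), lines)
    drivers <- c(planted_driver, sprintf("D%02d", seq_len(n_drivers)))
    rec <- expand.grid(cell_line = lines, gene = drivers,
                       stringsAsFactors = FALSE)
    rec$variant_id <- paste0(rec$gene, ":v1:", rec$cell_line)
    rec$maf_parental <- stats::runif(nrow(rec), 0.05, 0.5)
    shift <- ifelse(rec$gene == planted_driver, delta, 0)
    rec$maf_cas9 <- pmin(1, pmax(0, rec$maf_parental + shift +
                                   stats::rnorm(nrow(rec), 0, noise_sd)))
    pairs <- maf_pair_table(rec$cell_line, rec$gene, rec$variant_id,
                            rec$maf_parental, rec$maf_cas9, "exonic",
                            activity[rec$cell_line])
    list(pairs = pairs, activity = activity, planted_driver = planted_driver)
  })
}

#' Simulate a pooled isogenic sgRNA count table
#'
#' Day-0 counts are negative binomial around `depth`; day-30 counts are
#' resampled from the day-0 mean multiplied by `depletion_factor` for
#' planted genes in the WT context of the CRISPR-KO modality only (the
#' CDE+ signature), and unchanged elsewhere. Ten guides per gene by
#' default.
#'
#' @param n_genes,sgrnas_per_gene library dimensions.
#' @param n_planted planted CDE+-like genes.
#' @param depletion_factor day-30 mean multiplier for planted/WT/KO, in
#'   (0, 1].
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param depth mean day-0 reads per sgRNA.
#' @param n_replicates replicates per sample.
#' @param seed integer seed.
#' @return list: `counts` (`"sgrna_counts"`), `truth` (planted genes),
#'   `params`.
#' @export
simulate_counts <- function(n_genes = 200L, sgrnas_per_gene = 10L,
                            n_planted = 20L, depletion_factor = 0.3,
                            dispersion = 0.1, depth = 500,
                            n_replicates = 2L, seed = 1L) {
  stopifnot(depletion_factor > 0, depletion_factor <= 1, depth > 0,
            n_planted <= n_genes)
  withr::with_seed(seed, {
    genes <- sprintf("PG%03d", seq_len(n_genes))
    planted <- sample(genes, n_planted)
    sg <- data.frame(
      sgrna_id = sprintf("sg_%s_%02d", rep(genes, each = sgrnas_per_gene),
                         rep(seq_len(sgrnas_per_gene), n_genes)),
      gene = rep(genes, each = sgrnas_per_gene), stringsAsFactors = FALSE)
    size <- 1 / dispersion
    out <- NULL
    for (mod in c("crispr_ko", "crispri")) for (ctx in c("wt", "mutant")) {
      for (rep_i in seq_len(n_replicates)) {
        d0 <- stats::rnbinom(nrow(sg), mu = depth, size = size)
        dep <- ifelse(sg$gene %in% planted & ctx == "wt" & mod == "crispr_ko",
                      depletion_factor, 1)
        d30 <- stats::rnbinom(nrow(sg), mu = pmax(d0, 1) * dep, size = size)
        out <- rbind(out,
          data.frame(sgrna_id = sg$sgrna_id, gene = sg$gene, context = ctx,
                     modality = mod, timepoint = "day0", replicate = rep_i,
                     raw_count = d0, stringsAsFactors = FALSE),
          data.frame(sgrna_id = sg$sgrna_id, gene = sg$gene, context = ctx,
                     modality = mod, timepoint = "day30", replicate = rep_i,
                     raw_count = d30, stringsAsFactors = FALSE))
      }
    }
    counts <- sgrna_counts(out$sgrna_id, out$gene, out$context, out$modality,
                           out$timepoint, out$replicate, out$raw_count)
    list(counts = counts, truth = planted,
         params = list(n_genes = n_genes, sgrnas_per_gene = sgrnas_per_gene,
                       n_planted = n_planted,
                       depletion_factor = depletion_factor,
                       dispersion = dispersion, depth = depth,
                       n_replicates = n_replicates, seed = seed))
  })
}

#' Simulate a genomic annotation with planted positional structure
#'
#' Genes are placed on non-overlapping intervals along `n_chroms`
#' chromosomes. Common-fragile-site cytobands are placed exactly over the
#' planted CFS genes (plus decoy bands in intergenic gaps), so the CFS gene
#' set recovers the planted set exactly. Each gene gets `sgrnas_per_gene`
#' sgRNA sites inside its body; highly-accessible-chromatin intervals cover
#' the planted HAC genes (plus intergenic decoys).
#'
#' @param n_genes number of genes (`A0001`, ...).
#' @param n_chroms chromosomes.
#' @param planted_cfs_genes,planted_hac_genes planted subsets (character, or
#'   integer indices).
#' @param sgrnas_per_gene sgRNA sites per gene.
#' @param seed integer seed.
#' @return list: `annot` (`"genomic_annotation"`), `truth` (cfs/hac planted
#'   sets).
#' @export
simulate_annotation <- function(n_genes = 200L, n_chroms = 3L,
                                planted_cfs_genes = character(0),
                                planted_hac_genes = character(0),
                                sgrnas_per_gene = 4L, seed = 1L) {
  withr::with_seed(seed, {
    genes <- sprintf("A%04d", seq_len(n_genes))
    if (is.numeric(planted_cfs_genes)) planted_cfs_genes <- genes[planted_cfs_genes]
    if (is.numeric(planted_hac_genes)) planted_hac_genes <- genes[planted_hac_genes]
    if (!all(planted_cfs_genes %in% genes) || !all(planted_hac_genes %in% genes))
      stop("simulate_annotation: planted sets must be subsets of the genes")
    chrom <- paste0("chr", (seq_len(n_genes) - 1L) %% n_chroms + 1L)
    slot <- (seq_len(n_genes) - 1L) %/% n_chroms
    start <- slot * 30000L
    end <- start + 10000L
    gl <- data.frame(gene = genes, chrom = chrom, start = start, end = end,
                     stringsAsFactors = FALSE)
    is_cfs <- genes %in% planted_cfs_genes
    cfs_bands <- if (any(is_cfs)) paste0("q", seq_len(sum(is_cfs)), ".1")
                 else character(0)
    cb <- data.frame(chrom = chrom[is_cfs], start = start[is_cfs],
                     end = end[is_cfs], band = cfs_bands,
                     stringsAsFactors = FALSE)
    # decoy bands in intergenic gaps (overlap no gene)
    n_decoy <- min(10L, n_genes)
    di <- sample(n_genes, n_decoy)
    cb <- rbind(cb, data.frame(chrom = chrom[di], start = end[di] + 2000L,
                               end = end[di] + 8000L,
                               band = paste0("p", seq_len(n_decoy), ".2"),
                               stringsAsFactors = FALSE))
    sgr <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      pos <- sort(sample(seq(start[i], end[i] - 1L), sgrnas_per_gene))
      data.frame(chrom = chrom[i], position = pos,
                 sgrna_id = sprintf("%s_sg%d", genes[i], seq_len(sgrnas_per_gene)),
                 gene = genes[i], stringsAsFactors = FALSE)
    }))
    is_hac <- genes %in% planted_hac_genes
    hac <- data.frame(chrom = chrom[is_hac], start = start[is_hac],
                      end = end[is_hac], stringsAsFactors = FALSE)
    hi <- sample(n_genes, min(5L, n_genes))
    hac <- rbind(hac, data.frame(chrom = chrom[hi], start = end[hi] + 2000L,
                                 end = end[hi] + 8000L,
                                 stringsAsFactors = FALSE))
    annot <- genomic_annotation(gl, cb, cfs_bands, sgr, hac)
    list(annot = annot,
         truth = list(cfs = sort(planted_cfs_genes),
                      hac = sort(planted_hac_genes)))
  })
}
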