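# Hypergeometric gene-set overlap, permutation GSEA (weighted running-sum
# enrichment score with a gene-sampling null), fragile-site and
# open-chromatin positional gene sets, and the Cas9-response differential
# pathway comparison.

#' Build a ranked gene list
#'
#' Descending-score order with a deterministic tie-break (score, then gene
#' id), so downstream enrichment is reproducible.
#'
#' @param genes character vector.
#' @param scores numeric scores (e.g. difference of median post-knockout
#'   viability, or logFC).
#' @param semantics free-text tag describing the score.
#' @return data.frame of class `"ranked_list"`: gene, score (descending).
#' @export
ranked_list <- function(genes, scores, semantics = "delta_median") {
  stopifnot(length(genes) == length(scores))
  if (anyDuplicated(genes)) stop("ranked_list: duplicate genes")
  ok <- is.finite(scores)
  genes <- genes[ok]; scores <- scores[ok]
  ord <- order(-scores, genes)
  out <- data.frame(gene = genes[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  attr(out, "semantics") <- semantics
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Hypergeometric overlap enrichment
#'
#' Upper-tail hypergeometric probability of the observed overlap between a
#' query and a target gene set within a universe.
#'
#' @param query,target,universe character gene sets; query and target must be
#'   subsets of the universe.
#' @return A `"test_result"` whose statistic is the overlap count.
#' @export
overlap_enrichment <- function(query, target, universe) {
  if (length(query) == 0 || length(universe) == 0)
    stop("overlap_enrichment: empty query or universe")
  query <- unique(query); target <- unique(target); universe <- unique(universe)
  if (!all(query %in% universe) || !all(target %in% universe))
    stop("overlap_enrichment: query and target must be subsets of the universe")
  k <- length(intersect(query, target))
  p <- hypergeom_tail(k, length(target), length(query), length(universe))
  test_result(k, p, "greater", "exact")
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score. stats_sorted is
# the descending score vector of the ranked list; hit_idx are the (sorted)
# positions of the gene set within it. Returns the maximum-magnitude
# deviation of the running sum; 0 when the complement is empty.
calc_es <- function(stats_sorted, hit_idx, weight = 1) {
  N <- length(stats_sorted); m <- length(hit_idx)
  if (m == 0) return(0)
  if (m == N) return(0)  # complement empty: running sum ends at 0
  hit_idx <- sort(hit_idx)
  w <- abs(stats_sorted[hit_idx])^weight
  sw <- sum(w)
  if (sw == 0) { w <- rep(1, m); sw <- m }  # all-zero weights: unweighted
  hits <- cumsum(w) / sw
  miss_step <- 1 / (N - m)
  miss_before <- (hit_idx - seq_len(m)) * miss_step
  tops <- hits - miss_before                 # running sum just after each hit
  bottoms <- tops - w / sw                   # just before each hit
  max_p <- max(tops); min_p <- min(c(bottoms, 0))
  if (max_p > -min_p) max_p else min_p
}

#' Gene-set enrichment analysis with a gene-sampling permutation null
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score (ES) for each
#' gene set against a ranked list. The null distribution is generated by
#' sampling same-size gene sets from the ranked list; NES = ES divided by the
#' mean |null ES| of matching sign, the p-value is empirical within the
#' matching-sign null, and BH correction is applied separately per sign.
#' Gene sets with fewer than `min_size` members in the list are skipped with
#' a warning, as are sets disjoint from the list.
#'
#' @param ranked a `"ranked_list"`.
#' @param genesets named list of character vectors.
#' @param weight running-sum weight exponent (1 = classic weighted; 0 =
#'   unweighted KS statistic).
#' @param permutations number of sampled null gene sets per set size.
#' @param seed RNG seed.
#' @param min_size minimum in-list gene-set size.
#' @return data.frame of class `"gsea_result"`: geneset, n_genes_in_list,
#'   es, nes, p, q.
#' @export
gsea <- function(ranked, genesets, weight = 1, permutations = 1000L,
                 seed = 1L, min_size = 3L) {
  stopifnot(inherits(ranked, "ranked_list"))
  stats_sorted <- ranked$score
  gene_pos <- stats::setNames(seq_len(nrow(ranked)), ranked$gene)
  N <- length(stats_sorted)
  sizes <- integer(0)
  idx_list <- vector("list", length(genesets))
  names(idx_list) <- names(genesets)
  for (nm in names(genesets)) {
    idx <- unname(gene_pos[intersect(genesets[[nm]], names(gene_pos))])
    if (length(idx) == 0) {
      warning("gsea: gene set '", nm, "' disjoint from the ranked list; skipped")
      idx_list[[nm]] <- NULL
    } else if (length(idx) < min_size) {
      warning("gsea: gene set '", nm, "' has fewer than ", min_size,
              " members in the list; skipped")
      idx_list[[nm]] <- NULL
    } else idx_list[[nm]] <- idx
  }
  idx_list <- Filter(Negate(is.null), idx_list)
  if (length(idx_list) == 0)
    return(structure(data.frame(geneset = character(0),
                                n_genes_in_list = integer(0), es = numeric(0),
                                nes = numeric(0), p = numeric(0), q = numeric(0)),
                     class = c("gsea_result", "data.frame")))
  es <- vapply(idx_list, function(idx) calc_es(stats_sorted, idx, weight),
               numeric(1))
  sizes <- lengths(idx_list)
  # one shared null per distinct set size
  null_by_size <- withr::with_seed(seed, {
    out <- list()
    for (m in sort(unique(sizes))) {
      out[[as.character(m)]] <- vapply(seq_len(permutations), function(b)
        calc_es(stats_sorted, sample.int(N, m), weight), numeric(1))
    }
    out
  })
  nes <- p <- rep(NA_real_, length(es))
  for (i in seq_along(es)) {
    null_es <- null_by_size[[as.character(sizes[i])]]
    same <- if (es[i] >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    if (length(same) == 0) { nes[i] <- NA_real_; p[i] <- 1 / (permutations + 1); next }
    nes[i] <- es[i] / mean(abs(same))
    p[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
  }
  q <- rep(NA_real_, length(es))
  q[es >= 0] <- bh_fdr(p[es >= 0])
  q[es < 0] <- bh_fdr(p[es < 0])
  out <- data.frame(geneset = names(idx_list), n_genes_in_list = sizes,
                    es = es, nes = nes, p = p, q = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Common fragile site gene set
#'
#' All genes whose interval overlaps any common-fragile-site cytoband
#' (any-overlap rule, 0-based half-open arithmetic).
#'
#' @param annot a `"genomic_annotation"` with cytobands, `cfs_bands` names
#'   and gene locations.
#' @return Character vector of CFS genes.
#' @export
cfs_geneset <- function(annot) {
  if (is.null(annot$cytobands) || length(annot$cfs_bands) == 0)
    stop("cfs_geneset: annotation lacks cytobands or CFS band names")
  cb <- annot$cytobands
  missing <- setdiff(annot$cfs_bands, cb$band)
  if (length(missing) > 0)
    stop("cfs_geneset: CFS band name(s) absent from the cytoband table: ",
         paste(missing, collapse = ", "))
  bands <- cb[cb$band %in% annot$cfs_bands, , drop = FALSE]
  gl <- annot$gene_locations
  gr_genes <- .granges_from_halfopen(gl$chrom, gl$start, gl$end)
  gr_bands <- .granges_from_halfopen(bands$chrom, bands$start, bands$end)
  hits <- GenomicRanges::findOverlaps(gr_genes, gr_bands)
  sort(unique(gl$gene[S4Vectors::queryHits(hits)]))
}

#' Highly-accessible-chromatin sgRNA ranking enrichment
#'
#' Counts, per gene, the sgRNA sites falling inside any highly accessible
#' chromatin (HAC) interval (position in [start, end), half-open), ranks
#' genes by that count (ties broken by total sgRNA count, then gene id), takes
#' the top k = |cde_pos| genes, and tests the hypergeometric overlap of the
#' CDE+ set with that top set.
#'
#' @param annot a `"genomic_annotation"` with `sgrna_sites` and
#'   `hac_intervals`.
#' @param cde_pos CDE+ gene set.
#' @param universe gene universe for the test.
#' @return A `"test_result"` with attributes `top_genes` and `hac_counts`.
#' @export
hac_rank_enrichment <- function(annot, cde_pos, universe) {
  if (is.null(annot$sgrna_sites) || is.null(annot$hac_intervals))
    stop("hac_rank_enrichment: annotation lacks sgRNA sites or HAC intervals")
  sg <- annot$sgrna_sites
  gr_sites <- .granges_from_halfopen(sg$chrom, sg$position, sg$position + 1L)
  gr_hac <- .granges_from_halfopen(annot$hac_intervals$chrom,
                                   annot$hac_intervals$start,
                                   annot$hac_intervals$end)
  in_hac <- GenomicRanges::countOverlaps(gr_sites, gr_hac) > 0
  counts <- stats::setNames(rep(0L, length(universe)), universe)
  tot <- stats::setNames(rep(0L, length(universe)), universe)
  tab_hac <- table(sg$gene[in_hac])
  tab_all <- table(sg$gene)
  counts[intersect(names(tab_hac), universe)] <-
    as.integer(tab_hac[intersect(names(tab_hac), universe)])
  tot[intersect(names(tab_all), universe)] <-
    as.integer(tab_all[intersect(names(tab_all), universe)])
  if (all(counts == 0)) {
    warning("hac_rank_enrichment: no sgRNA site overlaps any HAC interval")
    res <- test_result(0, 1, "greater", "exact")
    attr(res, "top_genes") <- character(0)
    attr(res, "hac_counts") <- counts
    return(res)
  }
  ord <- order(-counts, -tot, names(counts))
  k <- length(unique(cde_pos))
  top <- names(counts)[ord][seq_len(min(k, length(counts)))]
  res <- overlap_enrichment(cde_pos, top, universe)
  attr(res, "top_genes") <- top
  attr(res, "hac_counts") <- counts
  res
}

#' Differential pathway response to Cas9 induction
#'
#' Runs GSEA on the WT and mutant expression-response ranked lists separately
#' and classifies pathways as differentially regulated when significantly up
#' in one group while down-or-not-significant in the other. Output is ranked
#' by |NES difference|.
#'
#' @param logfc_wt,logfc_mut `"ranked_list"` objects over a shared universe.
#' @param genesets named list of gene sets.
#' @param config an [analysis_config()] (uses `alpha_fdr`, `permutations`,
#'   `seed`).
#' @param permutations override for the permutation count (defaults to
#'   `config$permutations`).
#' @return data.frame: geneset, nes_wt, nes_mut, nes_diff, classification;
#'   rows ordered by |nes_diff| descending.
#' @export
cas9_response_pathways <- function(logfc_wt, logfc_mut, genesets,
                                   config = analysis_config(),
                                   permutations = config$permutations) {
  g_wt <- gsea(logfc_wt, genesets, permutations = permutations,
               seed = config$seed)
  g_mut <- gsea(logfc_mut, genesets, permutations = permutations,
                seed = config$seed)
  common <- intersect(g_wt$geneset, g_mut$geneset)
  g_wt <- g_wt[match(common, g_wt$geneset), ]
  g_mut <- g_mut[match(common, g_mut$geneset), ]
  alpha <- config$alpha_fdr
  state <- function(g) ifelse(!is.na(g$q) & g$q < alpha,
                              ifelse(g$es > 0, "up", "down"), "ns")
  s_wt <- state(g_wt); s_mut <- state(g_mut)
  classification <- rep("ns", length(common))
  classification[s_mut == "up" & s_wt != "up"] <- "mut-up/wt-down-or-ns"
  classification[s_wt == "up" & s_mut != "up"] <- "wt-up/mut-down-or-ns"
  out <- data.frame(geneset = common, nes_wt = g_wt$nes, nes_mut = g_mut$nes,
                    nes_diff = g_mut$nes - g_wt$nes,
                    q_wt = g_wt$q, q_mut = g_mut$q,
                    classification = classification,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-abs(out$nes_diff)), , drop = FALSE]
}

#' Pairwise Jaccard matrix of gene sets
#'
#' Emitted for external pathway-cluster visualization.
#' @param sets named list of character vectors.
#' @return Symmetric numeric matrix of Jaccard indices.
#' @export
jaccard_matrix <- function(sets) {
  n <- length(sets)
  m <- matrix(1, n, n, dimnames = list(names(sets), names(sets)))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- unique(sets[[i]]); b <- unique(sets[[j]])
    m[i, j] <- m[j, i] <- length(intersect(a, b)) / length(union(a, b))
  }
  m
}
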