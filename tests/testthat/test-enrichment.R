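# Overlap enrichment, GSEA, positional gene sets and the Cas9-response
# pathway comparison.

test_that("overlap_enrichment reduces to the hypergeometric tail", {
  universe <- paste0("U", 1:10)
  target <- universe[1:5]
  query <- universe[c(1:4)]
  r <- overlap_enrichment(query, target, universe)
  expect_equal(r$statistic, 4)
  expect_equal(r$p_value, oracle_hypergeom(4, 5, 4, 10), tolerance = 1e-12)
  expect_equal(overlap_enrichment(target, target, universe)$p_value,
               1 / choose(10, 5), tolerance = 1e-12)
  big_u <- paste0("U", 1:1000)
  expect_gt(overlap_enrichment(big_u[1:3], big_u[900:999], big_u)$p_value, 0.7)
  expect_error(overlap_enrichment(character(0), target, universe), "empty")
  # monotone in overlap at fixed margins
  ps <- sapply(0:4, function(k)
    hypergeom_tail(k, 5, 4, 10))
  expect_true(all(diff(ps) < 0))
})

test_that("gsea ES is bounded, matches fgsea, and hits boundary cases", {
  set.seed(111)
  scores <- sort(rnorm(200), decreasing = TRUE)
  rl <- ranked_list(sprintf("g%03d", 1:200), scores)
  sets <- list(s1 = sample(rl$gene, 12), s2 = sample(rl$gene, 25),
               whole = rl$gene)
  res <- suppressWarnings(gsea(rl, sets, permutations = 100, seed = 2))
  expect_true(all(res$es >= -1 & res$es <= 1))
  expect_true(all(sign(res$nes) == sign(res$es) | res$es == 0, na.rm = TRUE))
  for (nm in c("s1", "s2")) {
    ref <- fgsea::calcGseaStat(
      stats::setNames(rl$score, rl$gene),
      selectedStats = match(sets[[nm]], rl$gene))
    expect_equal(res$es[res$geneset == nm], ref, tolerance = 1e-12)
  }
  # geneset = entire list: complement empty, running sum ends at 0
  expect_equal(res$es[res$geneset == "whole"], 0)
})

test_that("gsea with weight 0 equals the unweighted KS running-sum oracle", {
  set.seed(112)
  for (rep in 1:5) {
    rl <- ranked_list(sprintf("g%02d", 1:20), sort(rnorm(20), decreasing = TRUE))
    hit <- sort(sample(20, 6))
    res <- gsea(rl, list(s = rl$gene[hit]), weight = 0, permutations = 50,
                seed = 3)
    expect_equal(res$es, oracle_es_unweighted(20, hit), tolerance = 1e-12)
  }
})

test_that("gsea detects a planted top-of-list set and skips tiny/disjoint sets", {
  set.seed(113)
  rl <- ranked_list(sprintf("g%04d", 1:1000),
                    sort(rnorm(1000), decreasing = TRUE))
  res <- gsea(rl, list(top = rl$gene[1:10]), permutations = 500, seed = 4)
  expect_gt(res$es, 0.9)
  # empirical p is computed within the matching-sign half of the null, so
  # its floor is 1/(n_same_sign + 1) — bounded by ~2/permutations here
  expect_lte(res$p, 2.5 / 500)
  expect_warning(gsea(rl, list(tiny = rl$gene[1:2]), permutations = 10,
                      seed = 1), "fewer than")
  expect_warning(gsea(rl, list(out = c("zz1", "zz2", "zz3")),
                      permutations = 10, seed = 1), "disjoint")
})

test_that("cfs_geneset uses half-open overlap and validates band names", {
  gl <- data.frame(gene = c("A", "B", "C"), chrom = "chr1",
                   start = c(0L, 100L, 200L), end = c(50L, 150L, 250L))
  cb <- data.frame(chrom = "chr1", start = c(10L, 150L), end = c(40L, 180L),
                   band = c("q1", "q2"))
  an <- genomic_annotation(gl, cb, cfs_bands = c("q1", "q2"))
  # A overlaps q1; B abuts q2 (gene.end = band.start would overlap; here
  # band q2 starts exactly at B's end=150 -> no overlap in half-open)
  expect_equal(cfs_geneset(an), "A")
  an2 <- genomic_annotation(gl, cb, cfs_bands = "q9")
  expect_error(cfs_geneset(an2), "q9")
})

test_that("planted CFS annotation is recovered exactly and order-invariantly", {
  sim <- simulate_annotation(n_genes = 100L, planted_cfs_genes = 1:15,
                             planted_hac_genes = 16:40, seed = 8L)
  expect_equal(cfs_geneset(sim$annot), sim$truth$cfs)
  an_shuf <- sim$annot
  set.seed(1)
  an_shuf$gene_locations <- an_shuf$gene_locations[sample(100), ]
  an_shuf$cytobands <- an_shuf$cytobands[sample(nrow(an_shuf$cytobands)), ]
  expect_equal(cfs_geneset(an_shuf), sim$truth$cfs)
})

test_that("hac counting respects half-open boundaries and finds planted signal", {
  gl <- data.frame(gene = c("A", "B"), chrom = "chr1",
                   start = c(0L, 1000L), end = c(500L, 1500L))
  sg <- data.frame(chrom = "chr1", position = c(100L, 200L, 1100L, 1200L),
                   sgrna_id = paste0("s", 1:4), gene = c("A", "A", "B", "B"))
  hac <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  an <- genomic_annotation(gl, sgrna_sites = sg, hac_intervals = hac)
  r <- hac_rank_enrichment(an, "A", c("A", "B"))
  cnt <- attr(r, "hac_counts")
  expect_equal(unname(cnt["A"]), 1L)  # site at 100 in, site at 200 (=end) out
  expect_equal(unname(cnt["B"]), 0L)

  sim <- simulate_annotation(n_genes = 120L, planted_hac_genes = 1:25,
                             seed = 9L)
  rr <- hac_rank_enrichment(sim$annot, sim$truth$hac,
                            sim$annot$gene_locations$gene)
  expect_lt(rr$p_value, 1e-6)
})

test_that("cas9 response comparison is null on identical lists and finds planted pathways", {
  set.seed(114)
  genes <- sprintf("g%03d", 1:300)
  base <- rnorm(300)
  rl <- ranked_list(genes, base, "logFC")
  sets <- list(p1 = sample(genes, 20), p2 = sample(genes, 20))
  cfg <- analysis_config(seed = 5)
  same <- cas9_response_pathways(rl, rl, sets, cfg, permutations = 200)
  expect_equal(same$nes_diff, rep(0, nrow(same)))
  expect_true(all(same$classification == "ns"))

  up_mut <- base; names(up_mut) <- genes
  up_mut[sets$p1] <- up_mut[sets$p1] + 3
  down_wt <- base; names(down_wt) <- genes
  down_wt[sets$p1] <- down_wt[sets$p1] - 3
  res <- cas9_response_pathways(ranked_list(genes, down_wt, "logFC"),
                                ranked_list(genes, up_mut, "logFC"),
                                sets, cfg, permutations = 200)
  expect_equal(res$geneset[1], "p1")
  expect_equal(res$classification[1], "mut-up/wt-down-or-ns")
  expect_equal(res$classification[res$geneset == "p2"], "ns")
})

test_that("jaccard matrix is symmetric with unit diagonal", {
  m <- jaccard_matrix(list(a = c("x", "y"), b = c("y", "z"), c = c("q")))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m["a", "b"], 1 / 3)
  expect_equal(m, t(m))
})
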