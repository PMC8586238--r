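# Generator contracts: determinism, truth-ledger bookkeeping, parameter
# validation.

test_that("screen-pair generator is a pure function of its seed", {
  p <- screen_sim_params(n_lines = 20L, n_genes = 100L, n_cde_pos = 10L,
                         n_cde_neg = 5L, n_shared_de = 5L,
                         n_cn_confounded = 5L, seed = 42L)
  a <- simulate_screen_pair(p)
  b <- simulate_screen_pair(p)
  expect_identical(a$crispr$values, b$crispr$values)
  expect_identical(a$shrna$values, b$shrna$values)
  expect_identical(a$cn, b$cn)
  expect_identical(a$muts, b$muts)
  c2 <- simulate_screen_pair(screen_sim_params(n_lines = 20L, n_genes = 100L,
                                               n_cde_pos = 10L, n_cde_neg = 5L,
                                               n_shared_de = 5L,
                                               n_cn_confounded = 5L,
                                               seed = 43L))
  expect_false(identical(a$crispr$values, c2$crispr$values))
})

test_that("truth ledger matches the planted class counts and classes are disjoint", {
  p <- screen_sim_params(n_lines = 24L, n_genes = 200L, n_cde_pos = 20L,
                         n_cde_neg = 10L, n_shared_de = 8L,
                         n_cn_confounded = 6L, seed = 5L)
  sim <- simulate_screen_pair(p)
  tab <- table(sim$truth$class)
  expect_equal(unname(tab["cde_pos"]), 20L)
  expect_equal(unname(tab["cde_neg"]), 10L)
  expect_equal(unname(tab["shared_de"]), 8L)
  expect_equal(unname(tab["cn_confounded"]), 6L)
  expect_equal(sum(tab), 200L)
  expect_error(screen_sim_params(n_genes = 10L, n_cde_pos = 8L,
                                 n_cde_neg = 8L),
               "exceed")
})

test_that("silent driver variants never flip a WT line", {
  sim <- simulate_screen_pair(screen_sim_params(n_lines = 30L, n_genes = 50L,
                                                n_cde_pos = 5L, n_cde_neg = 0L,
                                                n_shared_de = 0L,
                                                n_cn_confounded = 0L,
                                                seed = 12L))
  pr <- derive_mutation_profile(sim$muts, "DRIVER", screen_lines(sim$crispr))
  silent_lines <- sim$muts$cell_line[sim$muts$gene == "DRIVER" &
                                     sim$muts$variant_classification == "silent"]
  true_mut <- unique(sim$muts$cell_line[sim$muts$gene == "DRIVER" &
                                        sim$muts$variant_classification ==
                                          "missense"])
  expect_true(all(pr$status[setdiff(silent_lines, true_mut)] == 0L))
})

test_that("null screen produces few CDE discoveries", {
  sim <- simulate_screen_pair(screen_sim_params(
    n_lines = 40L, n_genes = 400L, n_cde_pos = 0L, n_cde_neg = 0L,
    n_shared_de = 0L, n_cn_confounded = 0L, effect_size = 0, seed = 51L))
  pr <- derive_mutation_profile(sim$muts, "DRIVER", screen_lines(sim$crispr))
  de_c <- classify_differential(sim$crispr, pr, 0.1)
  de_s <- classify_differential(sim$shrna, pr, 0.1)
  cs <- identify_cde(de_c, de_s)
  expect_lte(length(cs$cde_pos) + length(cs$cde_neg), 5L)
})

test_that("cohort generator is deterministic and rejects degenerate settings", {
  p <- cohort_sim_params(n_samples = 200L, n_genes = 20L, seed = 31L)
  a <- simulate_cohort(p); b <- simulate_cohort(p)
  expect_identical(a$cohort$scna, b$cohort$scna)
  expect_identical(a$cohort$driver_status, b$cohort$driver_status)
  expect_error(simulate_cohort(cohort_sim_params(beta0 = 60, seed = 1L)),
               "degenerate")
})

test_that("maf-pair generator respects ranges and the activity gate path", {
  sim <- simulate_maf_pairs(n_lines = 10L, n_drivers = 4L, delta = 0.1,
                            seed = 3L)
  expect_true(all(sim$pairs$maf_parental >= 0.05 &
                  sim$pairs$maf_parental <= 0.5))
  expect_true(all(sim$pairs$maf_cas9 >= 0 & sim$pairs$maf_cas9 <= 1))
  expect_error(simulate_maf_pairs(activity_range = c(0.5, 0.2)), "range")

  low <- simulate_maf_pairs(n_lines = 8L, n_drivers = 2L,
                            activity_range = c(0, 0.19), seed = 4L)
  r <- maf_expansion_scan(low$pairs, low$planted_driver, min_activity = 0.20)
  expect_false(r$tested)
})

test_that("count generator is deterministic with correct library structure", {
  a <- simulate_counts(n_genes = 20L, sgrnas_per_gene = 4L, n_planted = 3L,
                       seed = 9L)
  b <- simulate_counts(n_genes = 20L, sgrnas_per_gene = 4L, n_planted = 3L,
                       seed = 9L)
  expect_identical(a$counts, b$counts)
  expect_equal(length(unique(a$counts$sgrna_id)), 80L)
  expect_equal(length(a$truth), 3L)
  # every sgRNA appears in all 2x2x2x2 samples
  expect_equal(nrow(a$counts), 80L * 16L)
})

test_that("annotation generator plants CFS and HAC memberships exactly", {
  sim <- simulate_annotation(n_genes = 60L, planted_cfs_genes = 1:10,
                             planted_hac_genes = 11:25, seed = 21L)
  expect_equal(cfs_geneset(sim$annot), sim$truth$cfs)
  counts <- attr(hac_rank_enrichment(sim$annot, sim$truth$hac,
                                     sim$annot$gene_locations$gene),
                 "hac_counts")
  expect_true(all(counts[sim$truth$hac] > 0))
  expect_error(simulate_annotation(n_genes = 10L,
                                   planted_cfs_genes = c("NOPE")),
               "subsets")
})
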