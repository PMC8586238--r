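# Pooled isogenic screen analysis: normalization, filtering, ranks, calls,
# QC and the competition trend model.

small_counts <- function() {
  sgrna_counts(
    sgrna_id = rep(c("s1", "s2"), times = 4),
    gene = rep(c("gA", "gB"), times = 4),
    context = "wt", modality = "crispr_ko",
    timepoint = rep(c("day0", "day0", "day30", "day30"), 2),
    replicate = rep(1:2, each = 4),
    raw_count = c(250000, 750000, 100, 300, 250000, 750000, 100, 300))
}

test_that("cpm preserves ratios and sums to one million per sample", {
  cc <- cpm_normalize(small_counts())
  d0r1 <- cc[cc$timepoint == "day0" & cc$replicate == 1, ]
  expect_equal(d0r1$cpm, c(250000, 750000))
  key <- interaction(cc$context, cc$modality, cc$timepoint, cc$replicate,
                     drop = TRUE)
  expect_true(all(abs(tapply(cc$cpm, key, sum) - 1e6) < 1e-6))
  one <- sgrna_counts("s1", "gA", "wt", "crispr_ko", "day0", 1L, 5L)
  expect_equal(cpm_normalize(one)$cpm, 1e6)
  zero <- sgrna_counts("s1", "gA", "wt", "crispr_ko", "day0", 1L, 0L)
  expect_error(cpm_normalize(zero), "zero library")
})

test_that("day-0 filter is strict-less and removes across all samples", {
  cnt <- sgrna_counts(
    sgrna_id = rep(c("s1", "s2", "s3"), 2),
    gene = rep(c("gA", "gB", "gC"), 2),
    context = "wt", modality = "crispr_ko",
    timepoint = rep(c("day0", "day30"), each = 3),
    replicate = 1L, raw_count = c(10, 20, 30, 500, 500, 500))
  fl <- suppressMessages(filter_low_day0(cnt, 20))
  expect_equal(fl$removed, "s1")
  expect_true(all(fl$counts$sgrna_id != "s1"))  # removed from day30 too
  expect_true("s2" %in% fl$counts$sgrna_id)     # exactly 20 retained
  all_ok <- suppressMessages(filter_low_day0(cnt, 5))
  expect_equal(nrow(all_ok$counts), nrow(cnt))
})

test_that("filtering commutes with normalization", {
  sim <- simulate_counts(n_genes = 30L, sgrnas_per_gene = 3L, n_planted = 5L,
                         depth = 40, seed = 6L)
  a <- suppressMessages(filter_low_day0(cpm_normalize(sim$counts), 20))
  b <- suppressMessages(filter_low_day0(sim$counts, 20))
  expect_setequal(unique(a$counts$sgrna_id), unique(b$counts$sgrna_id))
})

test_that("fold-change ranks order sgRNAs and difference out identical contexts", {
  cnt <- sgrna_counts(
    sgrna_id = rep(c("s1", "s2"), 4),
    gene = rep(c("gA", "gB"), 4),
    context = rep(c("wt", "mutant"), each = 4),
    modality = "crispr_ko",
    timepoint = rep(rep(c("day0", "day30"), each = 2), 2),
    replicate = 1L,
    raw_count = c(500, 500, 250, 1000,   # wt: s1 fc 0.5, s2 fc 2
                  500, 500, 250, 1000))  # mutant identical
  cc <- cpm_normalize(cnt)
  fc <- fold_change_ranks(cc)
  expect_equal(fc$rank_wt[match(c("s1", "s2"), fc$sgrna_id)], c(1, 2))
  expect_equal(fc$rank_diff, c(0, 0))
})

test_that("isogenic calls recover planted genes and flag degeneracy", {
  sim <- simulate_counts(seed = 2L)
  fc <- fold_change_ranks(
    suppressMessages(filter_low_day0(cpm_normalize(sim$counts), 20))$counts)
  call <- suppressMessages(isogenic_cde_call(fc, k = 20))
  sens <- length(intersect(call$cde_pos_iso, sim$truth)) / 20
  expect_gte(sens, 0.7)
  expect_false(call$degenerate)
  expect_equal(nrow(call$class_tests), 4L)
  # KO screen shows the WT-vs-mutant signal in the called CDE+ class
  ko_pos <- call$class_tests$p[call$class_tests$class == "cde_pos_iso" &
                               call$class_tests$modality == "crispr_ko"]
  expect_lt(ko_pos, 0.05)
  expect_error(suppressMessages(isogenic_cde_call(fc, k = 10000)),
               "exceeds the eligible")

  # record order invariance
  fc_shuf <- fc[sample(nrow(fc)), ]
  call2 <- suppressMessages(isogenic_cde_call(fc_shuf, k = 20))
  expect_setequal(call$cde_pos_iso, call2$cde_pos_iso)

  # identical KO and CRISPRi screens: degenerate
  fci <- fc[fc$modality == "crispr_ko", ]
  fci$modality <- "crispri"
  deg <- suppressMessages(suppressWarnings(
    isogenic_cde_call(rbind(fc[fc$modality == "crispr_ko", ], fci), k = 5)))
  expect_true(deg$degenerate)
})

test_that("screen_qc behaves at the extremes and near 0.5 on random input", {
  gold <- list(essential = sprintf("E%02d", 1:40),
               nonessential = sprintf("N%02d", 1:40))
  perfect <- stats::setNames(c(rep(-3, 40), rep(0, 40)),
                             c(gold$essential, gold$nonessential))
  qc <- screen_qc(perfect, gold, threshold = 0.6)
  expect_equal(qc$auprc, 1.0)
  expect_equal(qc$auroc, 1.0)
  expect_true(qc$pass)

  inverted <- stats::setNames(c(rep(0, 40), rep(-3, 40)),
                              c(gold$essential, gold$nonessential))
  qc_inv <- screen_qc(inverted, gold, threshold = 0.6)
  expect_lt(qc_inv$auprc, 0.5)
  expect_false(qc_inv$pass)

  set.seed(141)
  ap <- replicate(100, screen_qc(stats::setNames(rnorm(80),
                                                 c(gold$essential,
                                                   gold$nonessential)),
                                 gold)$auprc)
  expect_lt(abs(mean(ap) - 0.5), 0.05)
  expect_error(screen_qc(c(x = 1), gold), "gold sets")
})

test_that("competition trend recovers slopes with sgRNA offsets", {
  obs1 <- data.frame(day = c(0, 5, 10, 15), sgrna = "a",
                     pct_mutant = 5 + 1 * c(0, 5, 10, 15))
  t1 <- competition_trend(obs1)
  expect_equal(t1$slope_x15, 15.0)
  expect_lt(t1$se_x15, 1e-8)

  flat <- data.frame(day = c(0, 5, 10), sgrna = "a", pct_mutant = c(7, 7, 7))
  expect_equal(competition_trend(flat)$slope_x15, 0)

  obs2 <- data.frame(day = rep(c(0, 5, 10, 15), 2),
                     sgrna = rep(c("a", "b"), each = 4),
                     pct_mutant = c(5 + 0.4 * c(0, 5, 10, 15),
                                    9 + 0.4 * c(0, 5, 10, 15)))
  expect_equal(competition_trend(obs2)$slope_x15, 6.0)
  expect_error(competition_trend(data.frame(day = 1, sgrna = "a",
                                            pct_mutant = 2)),
               "two distinct days")
})
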