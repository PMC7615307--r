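test_that("TSS-covering regions target the gene; boundary cases are half-open", {
  ann <- data.frame(gene = "g1", chrom = "chr1", strand = "+", tss = 10000,
                    stringsAsFactors = FALSE)
  w <- 3000
  covers <- data.frame(chrom = "chr1", start = 9990, end = 10010)
  expect_identical(assign_targets(covers, ann, w)$targets, "g1")
  at_edge <- data.frame(chrom = "chr1", start = 13000, end = 13200)
  expect_length(assign_targets(at_edge, ann, w)$targets, 0)
  just_in <- data.frame(chrom = "chr1", start = 12999, end = 13200)
  expect_identical(assign_targets(just_in, ann, w)$targets, "g1")
  left_out <- data.frame(chrom = "chr1", start = 6800, end = 7000)
  expect_length(assign_targets(left_out, ann, w)$targets, 0)
  left_in <- data.frame(chrom = "chr1", start = 6800, end = 7001)
  expect_identical(assign_targets(left_in, ann, w)$targets, "g1")
  beyond <- data.frame(chrom = "chr1", start = 13001, end = 13100)
  expect_length(assign_targets(beyond, ann, w)$targets, 0)
})

test_that("assignment equals the all-pairs oracle on random fixtures", {
  set.seed(3)
  for (i in 1:5) {
    ann <- make_gene_annotation(80, n_chrom = 2, spacing_bp = 9000,
                                seed = i)
    n <- 150
    regions <- data.frame(
      chrom = sample(unique(ann$chrom), n, TRUE),
      start = sample.int(max(ann$tss) + 5000, n))
    regions$end <- regions$start + sample.int(800, n)
    for (w in c(500, 3000)) {
      tm <- assign_targets(regions, ann, w)
      expect_identical(tm$targets, oracle_targets(regions, ann, w))
    }
  }
})

test_that("enlarging the window never shrinks the target set", {
  ann <- make_gene_annotation(60, seed = 11)
  rs <- simulate_regions(ann, sample(ann$gene, 20), n_decoys = 40,
                         seed = 12)
  t1 <- assign_targets(rs$regions, ann, 1000)$targets
  t2 <- assign_targets(rs$regions, ann, 3000)$targets
  t3 <- assign_targets(rs$regions, ann, 6000)$targets
  expect_true(all(t1 %in% t2))
  expect_true(all(t2 %in% t3))
})

test_that("regions on unknown chromosomes are skipped with a count", {
  ann <- data.frame(gene = "g1", chrom = "chr1", strand = "+", tss = 5000,
                    stringsAsFactors = FALSE)
  regions <- data.frame(chrom = c("chr1", "chrX"), start = c(4000, 4000),
                        end = c(4500, 4500))
  expect_message(tm <- assign_targets(regions, ann, 3000), "skipped")
  expect_equal(tm$skipped_regions, 1)
  expect_identical(tm$targets, "g1")
})

test_that("the constructed 60/20 design gives an odds ratio of exactly 6", {
  universe <- sprintf("g%04d", 1:1000)
  bias <- universe[1:200]
  rest <- universe[201:1000]
  targets <- c(bias[1:120], rest[1:160])    # 60% of bias, 20% of non-bias
  enr <- target_enrichment(bias, list(tf = targets), universe)
  expect_equal(enr$per_set$odds_ratio, 6, tolerance = 1e-12)
  expect_lt(enr$per_set$p.value, 1e-10)
  expect_equal(enr$coverage$bias_fraction, 0.6)
  expect_equal(enr$coverage$nonbias_fraction, 0.2)
})

test_that("target enrichment is calibrated for random target sets", {
  set.seed(13)
  universe <- sprintf("g%04d", 1:500)
  bias <- universe[1:80]
  p <- replicate(200, {
    tg <- sample(universe, 150)
    target_enrichment(bias, list(tf = tg), universe)$per_set$p.value
  })
  expect_gt(mean(p <= 0.05), 0.01)
  expect_lt(mean(p <= 0.11), 0.2)
})

test_that("the directional grid is symmetric for identical strata", {
  universe <- sprintf("g%04d", 1:400)
  male <- universe[1:50]; female <- universe[51:100]
  tg <- universe[c(1:30, 51:80, 101:140)]
  grid <- directional_enrichment(male, female,
                                 list(m_sites = tg, f_sites = tg), universe)
  expect_equal(grid$odds_ratio[grid$bias_set == "male"][1],
               grid$odds_ratio[grid$bias_set == "male"][2])
  expect_equal(nrow(grid), 4)
  expect_warning(
    g2 <- directional_enrichment(male, character(0),
                                 list(m = tg, f = tg), universe),
    "empty female")
  expect_equal(nrow(g2), 2)
})

test_that("concordant wiring lights up the diagonal of the grid", {
  set.seed(14)
  hits <- 0L
  for (s in 1:5) {
    universe <- sprintf("g%04d", 1:600)
    male <- universe[1:60]; female <- universe[61:120]
    # each gene targeted at a 15% background rate, boosted to 70% for the
    # concordant bias set, so off-diagonal cells are exactly null
    m_sites <- universe[runif(600) < 0.15 + 0.55 * (universe %in% male)]
    f_sites <- universe[runif(600) < 0.15 + 0.55 * (universe %in% female)]
    grid <- directional_enrichment(male, female,
                                   list(m = m_sites, f = f_sites), universe)
    diag_sig <- grid$padj[grid$bias_set == "male" & grid$region_set == "m"] <= 0.05 &&
      grid$padj[grid$bias_set == "female" & grid$region_set == "f"] <= 0.05
    off_ns <- grid$padj[grid$bias_set == "male" & grid$region_set == "f"] > 0.05 &&
      grid$padj[grid$bias_set == "female" & grid$region_set == "m"] > 0.05
    if (diag_sig && off_ns) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
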