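test_that("simulation is deterministic given the seed and varies across seeds", {
  d <- timeseries_design(n_genes = 60, seed = 3)
  s1 <- simulate_timeseries(d, list(spike_spec(1, "male", 1, "always")))
  s2 <- simulate_timeseries(d, list(spike_spec(1, "male", 1, "always")))
  expect_identical(s1$ts$counts, s2$ts$counts)
  d2 <- timeseries_design(n_genes = 60, seed = 4)
  s3 <- simulate_timeseries(d2, list())
  expect_false(identical(s1$ts$counts, s3$ts$counts))
})

test_that("with no spikes the sexes are exchangeable", {
  d <- timeseries_design(n_genes = 300, seed = 8)
  sim <- simulate_timeseries(d, list())
  ts <- sim$ts
  sexM <- ts$samples$sex == "M"
  p <- apply(ts$counts, 1, function(y)
    wilcox.test(y[sexM], y[!sexM], exact = FALSE)$p.value)
  expect_gt(mean(p <= 0.05, na.rm = TRUE), 0.005)
  expect_lt(mean(p <= 0.05, na.rm = TRUE), 0.12)
})

test_that("thinning halves the lower sex's expected counts at lfc = 1", {
  d <- timeseries_design(n_genes = 40, reps_per_sex_stage = 3,
                         base_log_mean = log(800), base_log_sd = 0.2,
                         seed = 9)
  sim <- simulate_timeseries(d, list(spike_spec(1, "male", 1, "always")))
  ts <- sim$ts
  m <- mean(ts$counts[1, ts$samples$sex == "M"])
  f <- mean(ts$counts[1, ts$samples$sex == "F"])
  expect_equal(f / m, 0.5, tolerance = 0.25)
  # the effect is confined to the spiked gene's window in onset spikes
  sim2 <- simulate_timeseries(d, list(spike_spec(2, "female", 2, "post_SM")))
  pre <- sim2$ts$samples$stage_ordinal < d$maturity_stage
  mm <- mean(sim2$ts$counts[2, pre & sim2$ts$samples$sex == "M"])
  ff <- mean(sim2$ts$counts[2, pre & sim2$ts$samples$sex == "F"])
  expect_equal(log2(ff / mm), 0, tolerance = 0.6)
})

test_that("invalid spikes are rejected", {
  d <- timeseries_design(n_genes = 20, seed = 1)
  expect_error(spike_spec(1, "male", -1), "lfc")
  expect_error(simulate_timeseries(d, list(
    spike_spec(1, "male", 1, "always"),
    spike_spec(1, "female", 1, "always"))), "overlapping")
  expect_error(simulate_timeseries(d, list(
    spike_spec(30, "male", 1, "always"))), "out of range")
  expect_error(simulate_timeseries(d, list(
    spike_spec(1, "male", 1, "pre_SM", onset_stage = 1,
               offset_stage = 8))), "inconsistent")
  expect_error(timeseries_design(n_genes = 10, n_stages = 8,
                                 maturity_stage = 8), "maturity")
})

test_that("simulation truth round-trips losslessly through JSON", {
  d <- timeseries_design(n_genes = 30, seed = 5)
  sim <- simulate_timeseries(d, list(spike_spec(3, "female", 2, "post_SM"),
                                     spike_spec(7, "male", 1.5, "always")))
  f <- tempfile(fileext = ".json")
  write_truth(sim$truth, f)
  back <- read_truth(f)
  expect_equal(back$spikes, sim$truth$spikes)
  expect_identical(back$chromosomes, sim$truth$chromosomes)
  expect_identical(back$schema_version, sim$truth$schema_version)
})

test_that("cell simulation puts the sex effect only in the dimorphic type", {
  spec <- cell_sim_spec(n_genes = 400, n_cells_per_type_sex = 60,
                        n_bias = 20, lfc = 2, seed = 6)
  sim <- simulate_cells(spec)
  cm <- sim$cells
  male_set <- sim$truth$male_set
  mn <- function(type, sex) {
    sub <- cm$counts[male_set, cm$meta$type == type & cm$meta$sex == sex]
    sum(sub) / length(sub)
  }
  expect_gt(mn("proximal_tubule", "M"), 2 * mn("proximal_tubule", "F"))
  # another type stays exchangeable
  expect_equal(mn("immune", "M"), mn("immune", "F"), tolerance = 0.5)
  expect_error(cell_sim_spec(n_cells_per_type_sex = 0), "empty")
})

test_that("ortholog simulation honours the conserved fraction", {
  # full conservation: biased genes shared through 1:1 families everywhere
  orth <- simulate_orthologs(conserved_fraction = 1, n_families = 800,
                             n_bias = 50, seed = 2)
  f1 <- match(orth$bias_sets$sp1, orth$map$sp1_gene)
  f2 <- match(orth$bias_sets$sp2, orth$map$sp2_gene)
  expect_identical(sort(f1), sort(f2))
  expect_true(all(orth$map$relation[f1] == "1:1"))
  # zero conservation: overlap near the hypergeometric chance expectation
  ov <- vapply(1:20, function(s) {
    o <- simulate_orthologs(conserved_fraction = 0, n_families = 800,
                            n_bias = 50, seed = s)
    g1 <- match(o$bias_sets$sp1, o$map$sp1_gene)
    g2 <- match(o$bias_sets$sp2, o$map$sp2_gene)
    length(intersect(g1, g2))
  }, numeric(1))
  expect_lt(abs(mean(ov) - 50 * 50 / 800), 3)
})

test_that("region simulation round-trips and marks targets exactly", {
  ann <- make_gene_annotation(120, seed = 7)
  tg <- sort(sample(ann$gene, 40))
  rs <- simulate_regions(ann, tg, n_decoys = 50, window_bp = 3000, seed = 8)
  f <- tempfile(fileext = ".bed")
  write_bed(rs$regions, f)
  gr <- read_bed(f)
  expect_equal(length(gr), nrow(rs$regions))
  expect_setequal(paste(GenomicRanges::seqnames(gr),
                        GenomicRanges::start(gr) - 1,
                        GenomicRanges::end(gr)),
                  paste(rs$regions$chrom, rs$regions$start, rs$regions$end))
  tm <- assign_targets(gr, ann, window_bp = 3000)
  expect_identical(tm$targets, rs$truth$targets)
  # all-decoy set recovers nothing
  rs0 <- simulate_regions(ann, character(0), n_decoys = 30, seed = 9)
  tm0 <- assign_targets(rs0$regions, ann, window_bp = 3000)
  expect_length(tm0$targets, 0)
  expect_error(simulate_regions(ann, tg, window_bp = 1e7), "window larger")
})
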