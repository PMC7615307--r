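# One moderately sized spiked simulation shared across caller tests.
sim_env <- local({
  d <- timeseries_design(n_genes = 250, n_stages = 8, seed = 21)
  spikes <- list(spike_spec(1, "male", 3, "always"),
                 spike_spec(2, "female", 3, "always"),
                 spike_spec(3, "male", 3, "post_SM"),
                 spike_spec(4, "female", 2, "pre_SM"))
  sim <- simulate_timeseries(d, spikes)
  list(d = d, sim = sim, ts = normalize_counts(sim$ts))
})

test_that("constant genes give p = 1 (or no call) in every caller", {
  ts <- constant_ts(values = c(10, 20, 50, 100, 200, 400), n_stages = 5,
                    reps = 2)
  for (r in list(caller_spline_lrt(ts), caller_factor_lrt(ts))) {
    expect_true(all(r$table$pvalue[r$table$tested] > 0.99))
    expect_true(all(r$table$direction == "none"))
  }
  rp <- caller_poly2step(ts)
  expect_true(all(rp$table$direction == "none"))
  rw <- caller_window_perm(ts, n_perm = 200, seed = 1)
  expect_true(all(rw$table$pvalue[rw$table$tested] == 1))
})

test_that("strong always-on spikes are recovered with correct direction", {
  ts <- sim_env$ts
  for (r in list(caller_spline_lrt(ts), caller_factor_lrt(ts),
                 caller_poly2step(ts))) {
    expect_identical(r$table$direction[1], "male")
    expect_identical(r$table$direction[2], "female")
    expect_gt(r$table$lfc[1], 1)
    expect_lt(r$table$lfc[2], -1)
  }
})

test_that("the window caller detects late-onset effects", {
  # post-maturity windows (4 of 10 stages); several spiked genes so the BH
  # ranks of the tied empirical p-values rise together
  d <- timeseries_design(n_genes = 150, n_stages = 10, seed = 31)
  spikes <- lapply(1:20, function(g) spike_spec(g, "male", 3, "post_SM"))
  sim <- simulate_timeseries(d, spikes)
  ts <- normalize_counts(sim$ts)
  r <- caller_window_perm(ts, n_perm = 2000, seed = 2)
  expect_gt(mean(r$table$direction[1:20] == "male"), 0.8)
  expect_true(all(r$table$lfc[1:20] > 1))
  expect_true(all(r$table$pvalue[1:20] < 0.01))
})

test_that("singular designs are rejected with a message", {
  ts <- sim_env$ts
  ts2 <- ts
  ts2$samples$sex <- "M"
  ts2$samples$sex[1] <- "F"   # single female sample at one stage
  expect_error(caller_spline_lrt(ts2), "2 distinct stages|singular")
})

test_that("the expression filter marks low genes untested", {
  d <- timeseries_design(n_genes = 50, library_size_range = c(150, 250),
                         base_log_sd = 1.5, seed = 41)
  sim <- simulate_timeseries(d, list())
  ts <- normalize_counts(sim$ts)
  r <- caller_spline_lrt(ts)
  expect_true(sum(r$table$tested) < nrow(r$table))
  expect_true(all(is.na(r$table$pvalue[!r$table$tested])))
  expect_true(all(r$table$direction[!r$table$tested] == "none"))
})

test_that("adjusted p-values dominate raw p-values in every caller", {
  ts <- sim_env$ts
  for (r in list(caller_spline_lrt(ts), caller_poly2step(ts),
                 caller_window_perm(ts, n_perm = 200, seed = 3))) {
    ok <- r$table$tested
    expect_true(all(r$table$padj[ok] >= r$table$pvalue[ok] - 1e-12))
  }
})

test_that("size-factor rescaling of one sample leaves calls unchanged", {
  ts <- sim_env$ts
  scaled <- ts$counts
  scaled[, 5] <- scaled[, 5] * 3L
  ts3 <- normalize_counts(expression_time_series(scaled, ts$samples))
  expect_equal(ts3$size_factors[5] / ts$size_factors[5], 3, tolerance = 0.05)
  r0 <- caller_factor_lrt(ts)
  r1 <- caller_factor_lrt(ts3)
  well <- rowMeans(sexbiasdev:::norm_counts(ts)) > 50
  expect_gt(mean((r0$table$direction == r1$table$direction)[well]), 0.95)
})

test_that("BH matches the textbook step-up procedure on a worked list", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.36)
  # independent oracle: direct enumeration of the step-up definition
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(m * p[o[i:m]] / seq(i, m)))
  }
  expect_equal(p.adjust(p, method = "BH"), adj, tolerance = 1e-12)
})

test_that("stage-wise calls respect the effect window", {
  d <- timeseries_design(n_genes = 120, n_stages = 8, seed = 51)
  sim <- simulate_timeseries(d, list(spike_spec(1, "male", 3, "post_SM")))
  ts <- normalize_counts(sim$ts)
  adult <- stagewise_de(ts, stages = 7:8)
  prenatal <- stagewise_de(ts, stages = 1:4, name = "prenatal")
  expect_identical(adult$table$direction[1], "male")
  expect_identical(prenatal$table$direction[1], "none")
  expect_error(stagewise_de(ts, stages = 99), "no samples")
})

test_that("spline and factor callers agree on strongly spiked genes", {
  d <- timeseries_design(n_genes = 400, seed = 61)
  spikes <- lapply(1:40, function(g)
    spike_spec(g, if (g %% 2) "male" else "female", 3, "always"))
  sim <- simulate_timeseries(d, spikes)
  ts <- normalize_counts(sim$ts)
  called <- function(r) r$table$gene[r$table$direction != "none"]
  a <- called(caller_spline_lrt(ts))
  b <- called(caller_factor_lrt(ts))
  spiked <- sim$truth$spikes$gene
  expect_gte(length(intersect(intersect(a, spiked), intersect(b, spiked))) /
               max(1, length(union(intersect(a, spiked),
                                   intersect(b, spiked)))), 0.8)
})

test_that("factor caller calls agree with an independent NB-GLM implementation", {
  skip_if_not_installed("DESeq2")
  d <- timeseries_design(n_genes = 300, seed = 71)
  spikes <- lapply(1:30, function(g)
    spike_spec(g, if (g %% 2) "male" else "female", 3, "always"))
  sim <- simulate_timeseries(d, spikes)
  ts <- normalize_counts(sim$ts)
  ours <- caller_factor_lrt(ts)
  cd <- data.frame(sex = factor(ts$samples$sex),
                   stage = factor(ts$samples$stage_ordinal))
  dds <- DESeq2::DESeqDataSetFromMatrix(ts$counts, cd, ~ sex + stage + sex:stage)
  dds <- suppressMessages(DESeq2::DESeq(dds, test = "LRT", reduced = ~ stage,
                                        quiet = TRUE))
  res <- DESeq2::results(dds)
  ref <- rownames(res)[!is.na(res$padj) & res$padj <= 0.05]
  mine <- ours$table$gene[ours$table$direction != "none"]
  spiked <- sim$truth$spikes$gene
  both <- intersect(intersect(mine, spiked), intersect(ref, spiked))
  either <- union(intersect(mine, spiked), intersect(ref, spiked))
  expect_gte(length(both) / max(1, length(either)), 0.8)
})
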