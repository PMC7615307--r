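test_that("permutation overlap matches the exact hypergeometric tail", {
  u <- paste0("g", 1:20)
  A <- u[1:5]
  B <- c(u[1:4], u[6])          # overlap 4
  res <- permutation_overlap(A, B, u, n_perm = 9999, seed = 1)
  exact <- 76 / 15504
  se <- sqrt(exact * (1 - exact) / 9999)
  expect_lt(abs(res$p.value - exact), 3 * se + 2 / 10000)
  expect_equal(res$observed, 4)
})

test_that("degenerate overlaps give p = 1", {
  u <- paste0("g", 1:12)
  expect_equal(permutation_overlap(u, u, u, 999, seed = 2)$p.value, 1)
  expect_equal(permutation_overlap(u[1:3], u[10:12], u, 999,
                                   seed = 3)$p.value, 1)
  expect_error(permutation_overlap(c(u, "zz"), u, u, 999), "subsets")
  expect_error(permutation_overlap(u[1], u[2], u, 10), "999")
})

test_that("permutation p-values are uniform for independent random sets", {
  set.seed(4)
  u <- paste0("g", 1:60)
  p <- replicate(120, {
    permutation_overlap(sample(u, 12), sample(u, 12), u, n_perm = 999,
                        seed = sample.int(1e6, 1))$p.value
  })
  ks <- suppressWarnings(ks.test(p, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(p <= 0.1), 0.03)
})

test_that("ortholog mapping strata partition each species' call set", {
  orth <- simulate_orthologs(conserved_fraction = 0.4, n_families = 600,
                             n_bias = 60, lineage_specific_fraction = 0.3,
                             seed = 5)
  mk <- function(sp) {
    genes <- orth$map[[paste0(sp, "_gene")]]
    genes <- genes[!is.na(genes)]
    make_callset(genes, ifelse(genes %in% orth$bias_sets[[sp]],
                               "male-biased", "unbiased"))
  }
  call_sets <- list(sp1 = mk("sp1"), sp2 = mk("sp2"))
  mo <- map_orthologs(call_sets, orth$map)
  expect_equal(mo$biased_both + mo$only1_with_11 + mo$only1_without_11, 60)
  expect_equal(mo$biased_both + mo$only2_with_11 + mo$only2_without_11, 60)
  expect_equal(mo$concordance, 1)   # all bias labels are male-biased here
  # identical call sets under a fully conserved map overlap completely
  orth1 <- simulate_orthologs(conserved_fraction = 1, n_families = 400,
                              n_bias = 40, lineage_specific_fraction = 0,
                              duplicated_fraction = 0, seed = 6)
  mk1 <- function(sp) {
    genes <- orth1$map[[paste0(sp, "_gene")]]
    make_callset(genes, ifelse(genes %in% orth1$bias_sets[[sp]],
                               "female-biased", "unbiased"))
  }
  mo1 <- map_orthologs(list(sp1 = mk1("sp1"), sp2 = mk1("sp2")), orth1$map)
  expect_equal(mo1$biased_both, 40)
  expect_equal(mo1$only1_with_11, 0)
  expect_equal(mo1$only1_without_11, 0)
})

test_that("effect-size comparison matches exact enumeration", {
  # {1,2,3} vs {4,5,6}: most extreme assignment of ranks; two-sided p
  # equals 2 / choose(6,3) * 1 = 0.1 by direct enumeration
  res <- effect_size_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p.value, 0.1, tolerance = 1e-12)
  expect_identical(res$method, "exact")
  same <- effect_size_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1, tolerance = 1e-9)
  expect_warning(tied <- effect_size_compare(rep(2, 5), rep(2, 4)), "tied")
  expect_equal(tied$p.value, 1)
  expect_error(effect_size_compare(numeric(0), 1), "non-empty")
  # large shifted samples reject decisively
  set.seed(7)
  big <- effect_size_compare(rnorm(60, 2), rnorm(60, 0.5))
  expect_lt(big$p.value, 1e-4)
  expect_identical(big$method, "normal approximation")
})

test_that("functional enrichment equals the direct hypergeometric tail sum", {
  u <- paste0("g", 1:100)
  categories <- list(catA = u[1:10], catB = u[51:70])
  gset <- c(u[1:5], u[90:94])     # overlap 5 with catA, 0 with catB
  res <- functional_enrichment(gset, categories, u)
  # oracle: direct tail summation over the hypergeometric pmf
  direct <- sum(vapply(5:10, function(k)
    choose(10, k) * choose(90, 10 - k), numeric(1))) / choose(100, 10)
  expect_equal(res$p.value[res$category == "catA"], direct,
               tolerance = 1e-12)
  expect_true(is.na(res$p.value[res$category == "catB"]))  # < 3 members
  res0 <- functional_enrichment(gset, categories, u, min_members = 0)
  expect_equal(res0$p.value[res0$category == "catB"], 1)
  # set equal to the category is maximally enriched for the margins
  resx <- functional_enrichment(u[1:10], list(catA = u[1:10]), u)
  expect_equal(resx$p.value, 1 / choose(100, 10), tolerance = 1e-12)
  expect_error(functional_enrichment(gset, categories, character(0)),
               "empty universe")
})

test_that("adjust_overlaps applies BH across a family of comparisons", {
  u <- paste0("g", 1:30)
  rs <- list(a = permutation_overlap(u[1:5], u[1:5], u, 999, seed = 8),
             b = permutation_overlap(u[1:5], u[20:24], u, 999, seed = 9))
  adj <- adjust_overlaps(rs)
  expect_equal(adj$padj, p.adjust(adj$p.value, "BH"))
  expect_lt(adj$p.value[1], adj$p.value[2])
})
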