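genes <- sprintf("g%02d", 1:6)

test_that("two concordant significant callers make a call; one does not", {
  r1 <- make_caller(genes, padj = c(0.01, 0.01, 0.20, 0.01, 0.01, 0.5),
                    direction = c("male", "female", "none", "male",
                                  "male", "none"),
                    lfc = c(2, -2, 0.1, 1, 1.5, 0), name = "spline")
  r2 <- make_caller(genes, padj = c(0.02, 0.30, 0.01, 0.01, 0.6, 0.7),
                    direction = c("male", "none", "male", "female",
                                  "none", "none"),
                    lfc = c(1.6, -0.1, 1, -1, 0.2, 0), name = "window")
  cs <- suppressMessages(consensus(list(r1, r2)))
  tab <- cs$table
  expect_identical(tab$status[1], "male-biased")     # both male
  expect_identical(tab$status[2], "unbiased")        # only one significant
  expect_identical(tab$status[3], "unbiased")        # only one significant
  expect_identical(tab$status[4], "unbiased")        # opposite directions
  expect_identical(tab$status[5], "unbiased")        # quorum not met
  expect_identical(tab$callers[1], "spline,window")
  expect_equal(tab$lfc[1], median(c(2, 1.6)))
  expect_identical(tab$provenance[1], "time_series")
})

test_that("consensus is monotone: adding a caller never removes a call", {
  set.seed(5)
  mk <- function(nm) {
    padj <- runif(6)
    dir <- ifelse(padj <= 0.05, sample(c("male", "female"), 6, TRUE), "none")
    make_caller(genes, padj, dir, ifelse(dir == "male", 1,
                                         ifelse(dir == "female", -1, 0)),
                name = nm)
  }
  for (i in 1:20) {
    rs <- lapply(letters[1:3], function(x) mk(x))
    c2 <- suppressMessages(consensus(rs[1:2]))
    c3 <- suppressMessages(consensus(rs))
    was_called <- c2$table$status != "unbiased"
    expect_true(all(c3$table$status[was_called] != "unbiased"))
    # consensus set is inside the union of caller calls
    union_called <- Reduce(`|`, lapply(rs, function(r)
      r$table$direction != "none"))
    expect_true(all(union_called[c3$table$status != "unbiased"]))
  }
})

test_that("extended set unions adult calls and tracks provenance", {
  ts_calls <- make_callset(genes,
                           c("male-biased", "unbiased", "unbiased",
                             "female-biased", "unbiased", "unbiased"))
  adult <- make_caller(genes, padj = c(0.01, 0.01, 0.5, 0.01, 0.6, 0.9),
                       direction = c("female", "male", "none", "female",
                                     "none", "none"),
                       lfc = c(-1, 0.5, 0, -0.8, 0, 0), name = "adult")
  ext <- suppressMessages(extended_set(ts_calls, adult))
  tab <- ext$table
  expect_identical(tab$status[1], "male-biased")   # conflict: time series wins
  expect_identical(tab$provenance[1], "both")
  expect_identical(tab$status[2], "male-biased")
  expect_identical(tab$provenance[2], "adult_only")
  expect_identical(tab$provenance[4], "both")
  expect_identical(tab$status[3], "unbiased")
  # empty adult set leaves the time-series calls untouched
  none <- make_caller(genes, padj = rep(0.9, 6), direction = rep("none", 6),
                      lfc = rep(0, 6), name = "adult")
  ext0 <- extended_set(ts_calls, none)
  expect_identical(ext0$table$status, ts_calls$table$status)
  # disjoint sets: sizes add
  expect_equal(sum(ext$table$status != "unbiased"), 3)
})

test_that("evaluation counts the worked confusion example correctly", {
  g <- sprintf("g%02d", 1:10)
  truth <- simulation_truth(
    list(spike_spec(1, "male", 2, "always"),
         spike_spec(2, "male", 2, "always"),
         spike_spec(3, "female", 2, "always"),
         spike_spec(4, "female", 2, "always")),
    chromosomes = setNames(rep("A", 10), g), gene_ids = g)
  calls <- make_callset(g, c("male-biased", "male-biased", "female-biased",
                             "unbiased", "male-biased", rep("unbiased", 5)))
  ev <- evaluate_calls(calls, truth)
  expect_equal(ev$tp, 3); expect_equal(ev$fp, 1); expect_equal(ev$fn, 1)
  expect_equal(ev$sensitivity, 0.75)
  expect_equal(ev$fdp, 0.25)
  expect_equal(ev$specificity, 5 / 6)
  # wrong-direction calls are false positives, not true positives
  wrong <- make_callset(g, c("female-biased", rep("unbiased", 9)))
  ev2 <- evaluate_calls(wrong, truth)
  expect_equal(ev2$tp, 0); expect_equal(ev2$fp, 1)
  # perfect and empty call sets hit the boundary values
  perfect <- make_callset(g, c("male-biased", "male-biased",
                               "female-biased", "female-biased",
                               rep("unbiased", 6)))
  evp <- evaluate_calls(perfect, truth)
  expect_equal(evp$sensitivity, 1); expect_equal(evp$specificity, 1)
  expect_equal(evp$fdp, 0)
  empty <- make_callset(g, rep("unbiased", 10))
  eve <- evaluate_calls(empty, truth)
  expect_equal(eve$sensitivity, 0); expect_equal(eve$specificity, 1)
})
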