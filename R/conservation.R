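#' Map sex-bias call sets across species through an ortholog map
#'
#' For every pair of species, restricts to the pairwise 1:1 universe and
#' counts genes biased in both species, biased in one with a 1:1 ortholog,
#' and biased in one without a 1:1 ortholog (lineage-specific or
#' duplicated), plus direction concordance among the shared genes.
#'
#' @param call_sets named list (by species) of `SexBiasCallSet`s.
#' @param map ortholog map data.frame: one `<species>_gene` column per
#'   species plus a `relation` column.
#' @return data.frame, one row per species pair, with overlap counts and
#'   the concordance fraction.
#' @export
map_orthologs <- function(call_sets, map) {
  species <- sub("_gene$", "", grep("_gene$", names(map), value = TRUE))
  stopifnot(all(names(call_sets) %in% species))
  use <- names(call_sets)
  pairs <- utils::combn(use, 2, simplify = FALSE)
  biased_genes <- lapply(call_sets, function(cs)
    cs$table[cs$table$status != "unbiased",
             c("gene", "status"), drop = FALSE])
  out <- lapply(pairs, function(pr) {
    c1 <- map[[paste0(pr[1], "_gene")]]
    c2 <- map[[paste0(pr[2], "_gene")]]
    one2one <- map$relation == "1:1" & !is.na(c1) & !is.na(c2)
    b1 <- biased_genes[[pr[1]]]; b2 <- biased_genes[[pr[2]]]
    m1 <- match(b1$gene, c1); m2 <- match(b2$gene, c2)
    in11_1 <- !is.na(m1) & one2one[pmax(m1, 1)]
    in11_2 <- !is.na(m2) & one2one[pmax(m2, 1)]
    fam1 <- m1[in11_1]; fam2 <- m2[in11_2]
    shared <- intersect(fam1, fam2)
    conc <- if (length(shared)) {
      s1 <- b1$status[in11_1][match(shared, fam1)]
      s2 <- b2$status[in11_2][match(shared, fam2)]
      mean(s1 == s2)
    } else NA_real_
    data.frame(species1 = pr[1], species2 = pr[2],
               biased_both = length(shared),
               only1_with_11 = length(fam1) - length(shared),
               only1_without_11 = nrow(b1) - length(fam1),
               only2_with_11 = length(fam2) - length(shared),
               only2_without_11 = nrow(b2) - length(fam2),
               universe_11 = sum(one2one),
               concordance = conc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Permutation test of gene-set overlap
#'
#' Null draws are random subsets of the universe preserving both set
#' sizes; the empirical p-value uses add-one smoothing,
#' `p = (1 + #[overlap_perm >= overlap_obs]) / (1 + n_perm)`, so it is
#' never zero.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of eligible genes.
#' @param n_perm number of permutations (>= 999).
#' @param seed integer seed.
#' @return an `OverlapResult` list: `observed`, `expected` (permutation
#'   mean), `perm_sd`, `p.value`, `n_perm`.
#' @export
permutation_overlap <- function(setA, setB, universe, n_perm = 9999,
                                seed = 1) {
  if (n_perm < 999) stop("need at least 999 permutations")
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("sets must be subsets of the universe")
  nU <- length(universe); nA <- length(setA); nB <- length(setB)
  obs <- length(intersect(setA, setB))
  set.seed(derive_seed(seed, 8L))
  perm <- integer(n_perm)
  inB <- logical(nU)
  for (i in seq_len(n_perm)) {
    a <- sample.int(nU, nA)
    b <- sample.int(nU, nB)
    inB[b] <- TRUE
    perm[i] <- sum(inB[a])
    inB[b] <- FALSE
  }
  structure(list(observed = obs, expected = mean(perm), perm_sd = sd(perm),
                 p.value = (1 + sum(perm >= obs)) / (1 + n_perm),
                 n_perm = n_perm),
            class = "OverlapResult")
}

#' @method print OverlapResult
#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("OverlapResult: observed %d (null %.2f +/- %.2f), p = %.4g\n",
              x$observed, x$expected, x$perm_sd, x$p.value))
  invisible(x)
}

#' BH adjustment across a family of overlap results
#'
#' @param results list of `OverlapResult`s run together.
#' @return data.frame with observed overlaps, p-values and BH-adjusted
#'   p-values.
#' @export
adjust_overlaps <- function(results) {
  p <- vapply(results, function(r) r$p.value, numeric(1))
  data.frame(comparison = names(results) %||% seq_along(results),
             observed = vapply(results, function(r) r$observed, numeric(1)),
             expected = vapply(results, function(r) r$expected, numeric(1)),
             p.value = p, padj = bh_adjust(p), stringsAsFactors = FALSE)
}

#' Compare two log2-fold-change distributions
#'
#' Two-sided Wilcoxon rank-sum test: exact when both groups have <= 25
#' values and no ties, normal approximation with tie correction otherwise.
#'
#' @param lfc1,lfc2 numeric vectors (absolute log2 fold changes are a
#'   typical input).
#' @return list with `statistic`, `p.value`, `method`.
#' @export
effect_size_compare <- function(lfc1, lfc2) {
  if (!length(lfc1) || !length(lfc2)) stop("both sets must be non-empty")
  if (length(unique(c(lfc1, lfc2))) == 1) {
    warning("all values tied; p = 1")
    return(list(statistic = NA_real_, p.value = 1, method = "degenerate"))
  }
  ties <- any(duplicated(c(lfc1, lfc2)))
  exact <- length(lfc1) <= 25 && length(lfc2) <= 25 && !ties
  ht <- suppressWarnings(wilcox.test(lfc1, lfc2, exact = exact,
                                     correct = !exact))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Hypergeometric functional enrichment of a gene set
#'
#' Upper-tail hypergeometric test per category, BH-adjusted across
#' categories; categories with fewer than `min_members` genes in the set
#' are skipped.
#'
#' @param gene_set character vector (subset of `universe`).
#' @param categories named list of character vectors (each a subset of
#'   `universe`).
#' @param universe character vector of tested genes.
#' @param min_members minimum set members for a category to be tested.
#' @return data.frame with per-category overlap, p-value and BH-adjusted
#'   p-value (`NA` for skipped categories).
#' @export
functional_enrichment <- function(gene_set, categories, universe,
                                  min_members = 3) {
  if (!length(universe)) stop("empty universe")
  gene_set <- intersect(gene_set, universe)
  n <- length(gene_set); N <- length(universe)
  rows <- lapply(names(categories), function(nm) {
    cat_genes <- intersect(categories[[nm]], universe)
    K <- length(cat_genes)
    k <- length(intersect(gene_set, cat_genes))
    p <- if (k >= min_members)
      phyper(k - 1, K, N - K, n, lower.tail = FALSE) else NA_real_
    data.frame(category = nm, category_size = K, overlap = k,
               p.value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- NA_real_
  tested <- !is.na(out$p.value)
  out$padj[tested] <- bh_adjust(out$p.value[tested])
  out
}
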