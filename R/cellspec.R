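#' Control-bin module score of a gene set per cell
#'
#' Genes are binned by their average normalized expression into `n_bins`
#' equal-size bins; for each set gene, `n_ctrl` control genes are sampled
#' from its bin (seeded, without replacement within one draw, with
#' replacement across draws).  The score of a cell is the mean normalized
#' expression over the set genes minus the mean over the pooled control
#' genes (with multiplicity), the usual expression-matched module score.
#'
#' @param cells a [cell_matrix()].
#' @param gene_set character vector of gene ids; absent genes are dropped
#'   with a warning.
#' @param n_bins number of expression bins (>= 2).
#' @param n_ctrl controls per set gene (>= 10); bins smaller than `n_ctrl`
#'   are sampled with replacement (logged).
#' @param seed integer seed.
#' @return numeric vector of per-cell scores (named by cell).
#' @export
module_score <- function(cells, gene_set, n_bins = 24, n_ctrl = 100,
                         seed = 1) {
  stopifnot(inherits(cells, "CellMatrix"), n_bins >= 2, n_ctrl >= 10)
  genes <- rownames(cells$norm)
  missing <- setdiff(gene_set, genes)
  if (length(missing)) {
    warning(length(missing), " set gene(s) absent from the matrix; dropped")
    gene_set <- intersect(gene_set, genes)
  }
  if (!length(gene_set)) stop("no set genes present in the matrix")
  avg <- Matrix::rowMeans(cells$norm)
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins / length(avg))
  bin_members <- split(seq_along(avg), bin)

  set.seed(derive_seed(seed, 9L))
  set_idx <- match(gene_set, genes)
  ctrl_idx <- integer(0)
  small_bins <- 0L
  for (g in gene_set) {
    members <- bin_members[[as.character(bin[match(g, genes)])]]
    members <- setdiff(members, set_idx)   # controls never overlap the set
    if (!length(members))
      members <- bin_members[[as.character(bin[match(g, genes)])]]
    if (length(members) < n_ctrl) {
      small_bins <- small_bins + 1L
      draw <- sample(members, n_ctrl, replace = TRUE)
    } else {
      draw <- sample(members, n_ctrl, replace = FALSE)
    }
    ctrl_idx <- c(ctrl_idx, draw)
  }
  if (small_bins > 0)
    message(small_bins, " set gene(s) in bins smaller than n_ctrl; ",
            "sampled with replacement")
  set_mean <- Matrix::colMeans(cells$norm[gene_set, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(cells$norm[ctrl_idx, , drop = FALSE])
  score <- as.numeric(set_mean - ctrl_mean)
  # summation noise below 1e-12 is reported as an exact zero, so a constant
  # matrix scores 0 for any gene set
  score[abs(score) < 1e-12] <- 0
  setNames(score, colnames(cells$norm))
}

#' Per-cell-type male-vs-female comparison of module scores
#'
#' Two-sided Wilcoxon rank-sum test of male vs female scores within each
#' cell type with at least `min_cells` cells of each sex; p-values are
#' BH-adjusted across the tested types.
#'
#' @param scores per-cell score vector from [module_score()].
#' @param cell_meta data.frame with columns `cell`, `type`, `sex`.
#' @param min_cells minimum cells per sex per type.
#' @return a `ModuleScoreResult` data.frame: per tested type, the group
#'   sizes, mean scores, Wilcoxon statistic, p-value, BH-adjusted p-value
#'   and direction (`"male"`/`"female"`, the higher-scoring sex).
#' @export
compare_by_sex <- function(scores, cell_meta, min_cells = 20) {
  stopifnot(all(cell_meta$cell %in% names(scores)))
  s <- scores[cell_meta$cell]
  types <- unique(cell_meta$type)
  rows <- lapply(types, function(ct) {
    m <- s[cell_meta$type == ct & cell_meta$sex == "M"]
    f <- s[cell_meta$type == ct & cell_meta$sex == "F"]
    if (length(m) < min_cells || length(f) < min_cells) {
      message("skipping cell type '", ct, "' (fewer than ", min_cells,
              " cells in one sex)")
      return(NULL)
    }
    ht <- suppressWarnings(wilcox.test(m, f, exact = FALSE, correct = TRUE))
    data.frame(type = ct, n_male = length(m), n_female = length(f),
               mean_male = mean(m), mean_female = mean(f),
               statistic = unname(ht$statistic), p.value = ht$p.value,
               direction = if (median(m) >= median(f)) "male" else "female",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no cell type passed the min_cells filter")
  out$padj <- bh_adjust(out$p.value)
  class(out) <- c("ModuleScoreResult", "data.frame")
  out
}

#' Rank cell types by mean module score and flag a specific top type
#'
#' Types are ranked by mean score; the top type is flagged as specific
#' when its mean is positive and at least `ratio` times the second-ranked
#' mean (a negative or near-zero runner-up also flags the top type),
#' separating "expressed specifically in one type" from "broadly
#' expressed".
#'
#' @param scores per-cell score vector.
#' @param cell_meta data.frame with `cell`, `type`.
#' @param ratio top-to-second mean ratio required for the flag.
#' @return data.frame of types ranked by mean score with a `top_specific`
#'   flag on the first row.
#' @export
setwise_specificity <- function(scores, cell_meta, ratio = 2) {
  stopifnot(length(unique(cell_meta$type)) >= 2)
  s <- scores[cell_meta$cell]
  mu <- tapply(s, cell_meta$type, mean)
  ord <- order(mu, decreasing = TRUE)
  mu <- mu[ord]
  flag <- mu[1] > 0 && (mu[2] <= 0 || mu[1] >= ratio * mu[2])
  data.frame(type = names(mu), mean_score = as.numeric(mu),
             rank = seq_along(mu),
             top_specific = c(flag, rep(FALSE, length(mu) - 1)),
             stringsAsFactors = FALSE)
}
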