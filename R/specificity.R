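#' Organ-specificity index tau
#'
#' `tau = sum(1 - x_i / max(x)) / (N - 1)` over N organs: 0 for uniform
#' positive expression, 1 for expression confined to a single organ.  By
#' default the per-organ means are `log2(x + 1)`-transformed first, which
#' damps dynamic-range dominance; pass `transform = "none"` for raw values.
#'
#' @param expr non-negative numeric vector of per-organ mean expression
#'   (length >= 2).
#' @param transform `"log2"` (default) or `"none"`.
#' @return tau in `[0, 1]`, or `NA` (with a warning) for an all-zero
#'   vector.
#' @export
tau <- function(expr, transform = c("log2", "none")) {
  transform <- match.arg(transform)
  if (length(expr) < 2) stop("tau needs at least 2 organs")
  if (any(expr < 0) || any(!is.finite(expr)))
    stop("expression values must be finite and non-negative")
  x <- if (transform == "log2") log2(expr + 1) else expr
  mx <- max(x)
  if (mx == 0) {
    warning("tau undefined for an all-zero vector")
    return(NA_real_)
  }
  sum(1 - x / mx) / (length(x) - 1)
}

#' Specificity profiles for a per-organ mean expression matrix
#'
#' @param organ_means numeric matrix, genes x organs.
#' @param tau_cutoff threshold above which a gene is flagged
#'   organ-specific.
#' @param transform passed to [tau()].
#' @return data.frame with columns `gene`, `tau`, `organ_specific`.
#' @export
specificity_profile <- function(organ_means, tau_cutoff = 0.8,
                                transform = "log2") {
  organ_means <- as.matrix(organ_means)
  taus <- apply(organ_means, 1, function(x)
    suppressWarnings(tau(x, transform)))
  data.frame(gene = rownames(organ_means) %||%
               as.character(seq_len(nrow(organ_means))),
             tau = taus,
             organ_specific = !is.na(taus) & taus > tau_cutoff,
             stringsAsFactors = FALSE)
}

#' Multi-organ bias summary
#'
#' Tallies, per gene, the number of organs where it is sex-biased and
#' whether the direction of bias is the same in every biased organ.
#'
#' @param calls_per_organ named list of `SexBiasCallSet`s, one per organ
#'   (>= 2 organs).
#' @return data.frame with columns `gene`, `n_organs_biased`, `consistent`
#'   (`NA` for genes biased nowhere).
#' @export
multiorgan_summary <- function(calls_per_organ) {
  stopifnot(length(calls_per_organ) >= 2)
  genes <- unique(unlist(lapply(calls_per_organ,
                                function(cs) cs$table$gene)))
  status <- sapply(calls_per_organ, function(cs) {
    cs$table$status[match(genes, cs$table$gene)]
  })
  if (is.null(dim(status))) status <- matrix(status, nrow = length(genes))
  biased <- status %in% c("male-biased", "female-biased")
  dim(biased) <- dim(status)
  n_biased <- rowSums(biased, na.rm = TRUE)
  consistent <- rep(NA, length(genes))
  for (i in which(n_biased >= 1)) {
    dirs <- unique(status[i, biased[i, ]])
    consistent[i] <- length(dirs) == 1
  }
  data.frame(gene = genes, n_organs_biased = n_biased,
             consistent = consistent, stringsAsFactors = FALSE)
}

#' Sex-chromosome enrichment of a gene set
#'
#' 2x2 test of sex-chromosome membership inside vs outside the gene set,
#' Pearson chi-square without continuity correction when all expected
#' counts reach 5, Fisher's exact test otherwise.  The odds ratio is the
#' sample cross-product ratio (with an `Inf` sentinel for degenerate
#' margins).
#'
#' @param gene_set character vector of genes (subset of `universe`).
#' @param universe character vector of tested genes.
#' @param chrom_labels named character vector gene -> chromosome label,
#'   covering the universe.
#' @param sex_chroms labels counted as sex chromosomes.
#' @return list with `table` (2x2), `statistic`, `p.value`, `odds_ratio`,
#'   `method`.
#' @export
chromosome_enrichment <- function(gene_set, universe, chrom_labels,
                                  sex_chroms = c("X", "Y", "Z", "W")) {
  if (length(gene_set) == 0) stop("empty gene set")
  if (!all(gene_set %in% universe)) stop("gene set must be inside universe")
  if (!all(universe %in% names(chrom_labels)))
    stop("chromosome labels must cover the universe")
  sexed <- chrom_labels[universe] %in% sex_chroms
  inset <- universe %in% gene_set
  tab <- table(in_set = factor(inset, c(TRUE, FALSE)),
               sex_chrom = factor(sexed, c(TRUE, FALSE)))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  or <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    method <- "chisq"
  } else {
    ht <- fisher.test(tab)
    method <- "fisher"
  }
  list(table = tab, statistic = unname(ht$statistic %||% NA_real_),
       p.value = ht$p.value, odds_ratio = or, method = method)
}
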