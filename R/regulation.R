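#' Assign regulatory regions to target genes through TSS windows
#'
#' A gene is a target of a region set when some region overlaps the
#' half-open window `[tss - window_bp, tss + window_bp)` around its TSS
#' (0-based coordinates; strand is used only to locate the TSS upstream of
#' the annotation — the window itself is symmetric and strand-agnostic).
#' Overlap is resolved with sorted interval trees, linear in regions plus
#' genes.  Regions on chromosomes absent from the annotation are skipped
#' with a logged count.
#'
#' @param regions a `GRanges` (e.g. from [read_bed()]) or a data.frame with
#'   0-based half-open `chrom`, `start`, `end`.
#' @param annotation data.frame with columns `gene`, `chrom`, `strand`,
#'   `tss` (0-based TSS position).
#' @param window_bp half-window size in bp (> 0).
#' @return a `RegionTargetMap` list: `targets` (character vector of target
#'   genes), `window_bp`, `distance` (named per-gene distance to the
#'   nearest region, `NA` when the chromosome has none) and
#'   `skipped_regions`.
#' @export
assign_targets <- function(regions, annotation, window_bp = 3000) {
  stopifnot(window_bp > 0,
            all(c("gene", "chrom", "strand", "tss") %in% names(annotation)))
  if (!methods::is(regions, "GRanges")) {
    regions <- GenomicRanges::GRanges(
      regions$chrom,
      IRanges::IRanges(start = regions$start + 1, end = regions$end))
  }
  ann_chroms <- unique(annotation$chrom)
  reg_chroms <- as.character(GenomicRanges::seqnames(regions))
  skipped <- sum(!reg_chroms %in% ann_chroms)
  if (skipped > 0)
    message(skipped, " region(s) on chromosomes absent from the ",
            "annotation; skipped")
  regions <- regions[reg_chroms %in% ann_chroms]

  # gene windows [tss - w, tss + w) in 0-based half-open coordinates =
  # [tss - w + 1, tss + w] in 1-based closed GRanges coordinates
  win <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(start = pmax(annotation$tss - window_bp + 1, 1),
                     end = annotation$tss + window_bp))
  hits <- GenomicRanges::findOverlaps(win, regions)
  targets <- sort(unique(annotation$gene[S4Vectors::queryHits(hits)]))

  dist <- rep(NA_real_, nrow(annotation))
  if (length(regions)) {
    tss_gr <- GenomicRanges::GRanges(
      annotation$chrom,
      IRanges::IRanges(start = annotation$tss + 1, width = 1))
    dn <- GenomicRanges::distanceToNearest(tss_gr, regions)
    dist[S4Vectors::queryHits(dn)] <- S4Vectors::mcols(dn)$distance
  }
  names(dist) <- annotation$gene
  structure(list(targets = targets, window_bp = window_bp,
                 distance = dist, skipped_regions = skipped),
            class = "RegionTargetMap")
}

#' Enrichment of a bias set among region-set targets
#'
#' For each region set, a 2x2 test (bias vs non-bias universe, targeted vs
#' not): Pearson chi-square without continuity correction when all
#' expected counts reach 5, Fisher's exact test otherwise; BH adjustment
#' across region sets.  Additionally, a coverage summary tests the
#' fraction of bias genes targeted by at least one region set against the
#' rest of the expressed universe.
#'
#' @param bias_set character vector (subset of `universe`).
#' @param target_maps named list of `RegionTargetMap`s (or plain character
#'   vectors of target genes).
#' @param universe expressed-gene universe.
#' @return list with `per_set` (data.frame: per region set, counts, odds
#'   ratio, p-value, BH-adjusted p-value) and `coverage` (fractions and
#'   the combined test).
#' @export
target_enrichment <- function(bias_set, target_maps, universe) {
  if (!all(bias_set %in% universe))
    stop("bias set must be inside the universe")
  get_targets <- function(tm)
    if (inherits(tm, "RegionTargetMap")) tm$targets else tm
  rows <- lapply(names(target_maps), function(nm) {
    tg <- intersect(get_targets(target_maps[[nm]]), universe)
    if (!length(tg)) {
      message("region set '", nm, "' has no targets in the universe; skipped")
      return(NULL)
    }
    tt <- twoby2_test(bias_set, tg, universe)
    data.frame(region_set = nm, n_targets = length(tg),
               bias_targeted = tt$a, odds_ratio = tt$or,
               p.value = tt$p, method = tt$method,
               stringsAsFactors = FALSE)
  })
  per_set <- do.call(rbind, rows)
  if (!is.null(per_set)) per_set$padj <- bh_adjust(per_set$p.value)

  any_target <- unique(unlist(lapply(target_maps, get_targets)))
  any_target <- intersect(any_target, universe)
  ctt <- twoby2_test(bias_set, any_target, universe)
  coverage <- list(
    bias_fraction = ctt$a / length(bias_set),
    universe_fraction = length(any_target) / length(universe),
    nonbias_fraction = (length(any_target) - ctt$a) /
      (length(universe) - length(bias_set)),
    odds_ratio = ctt$or, p.value = ctt$p, method = ctt$method)
  list(per_set = per_set, coverage = coverage)
}

# 2x2 membership test: bias vs rest of universe, target vs not.
twoby2_test <- function(bias_set, targets, universe) {
  inb <- universe %in% bias_set
  int <- universe %in% targets
  a <- sum(inb & int); b <- sum(inb & !int)
  c_ <- sum(!inb & int); d <- sum(!inb & !int)
  tab <- matrix(c(a, c_, b, d), 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    method <- "chisq"
  } else {
    ht <- fisher.test(tab)
    method <- "fisher"
  }
  or <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
  list(a = a, b = b, c = c_, d = d, or = or, p = ht$p.value,
       method = method)
}

#' Directional enrichment grid: bias sex by region stratum
#'
#' Crosses male- and female-bias sets with sex-stratified region sets
#' (e.g. male- and female-enriched binding sites of one factor), producing
#' the full grid of enrichment tests so concordant wiring (diagonal
#' significant, off-diagonal not) can be read off.
#'
#' @param male_set,female_set bias gene sets (either may be empty; an
#'   empty set's row is skipped with a warning).
#' @param region_sets named list (>= 2) of `RegionTargetMap`s or target
#'   gene vectors, typically one per sex stratum.
#' @param universe expressed-gene universe.
#' @return data.frame, one row per (bias set x region set), with counts,
#'   odds ratio, p-value and BH-adjusted p-value across the grid.
#' @export
directional_enrichment <- function(male_set, female_set, region_sets,
                                   universe) {
  stopifnot(length(region_sets) >= 2)
  bias_sets <- list(male = male_set, female = female_set)
  rows <- list()
  for (bs in names(bias_sets)) {
    if (!length(bias_sets[[bs]])) {
      warning("empty ", bs, " set; row skipped")
      next
    }
    for (rs in names(region_sets)) {
      tg <- region_sets[[rs]]
      if (inherits(tg, "RegionTargetMap")) tg <- tg$targets
      tt <- twoby2_test(bias_sets[[bs]], intersect(tg, universe), universe)
      rows[[length(rows) + 1]] <-
        data.frame(bias_set = bs, region_set = rs, bias_targeted = tt$a,
                   odds_ratio = tt$or, p.value = tt$p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("both bias sets empty")
  out$padj <- bh_adjust(out$p.value)
  out
}
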