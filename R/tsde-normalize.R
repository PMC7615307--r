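#' Median-of-ratios size factors
#'
#' Computes per-sample size factors against a geometric-mean pseudo-reference
#' built from genes with all-positive counts, and attaches them to the
#' series; counts themselves are untouched.  When no gene is positive in all
#' samples the function falls back to upper-quartile factors (scaled to
#' geometric mean 1) with a warning.
#'
#' @param ts an [expression_time_series()].
#' @return the same object with `size_factors` filled.
#' @export
normalize_counts <- function(ts) {
  stopifnot(inherits(ts, "ExpressionTimeSeries"))
  counts <- ts$counts
  if (ncol(counts) < 2) stop("need at least 2 samples")
  allpos <- rowSums(counts == 0) == 0
  if (any(allpos)) {
    lg <- log(counts[allpos, , drop = FALSE])
    ref <- rowMeans(lg)                       # log geometric means
    sf <- apply(exp(lg - ref), 2, median)
  } else {
    warning("no gene positive in all samples; using upper-quartile factors")
    uq <- apply(counts, 2, quantile, probs = 0.75)
    if (any(uq == 0)) stop("upper-quartile fallback failed: zero quartiles")
    sf <- uq / exp(mean(log(uq)))
  }
  ts$size_factors <- unname(sf)
  ts
}

# Attach size factors if missing.
ensure_normalized <- function(ts) {
  if (is.null(ts$size_factors)) normalize_counts(ts) else ts
}

# Normalized counts (counts / size factor).
norm_counts <- function(ts) {
  ts <- ensure_normalized(ts)
  sweep(ts$counts, 2, ts$size_factors, `/`)
}
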