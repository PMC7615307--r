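#' Per-gene male-minus-female difference trajectories
#'
#' For each gene and stage with both sexes observed, the mean of
#' `log2(normalized count + 0.5)` in males minus females.  The standardized
#' copy divides each gene's trajectory by its maximum absolute value, so
#' trajectories of different effect sizes become comparable shapes while
#' signs are preserved.
#'
#' @param ts an [expression_time_series()].
#' @param genes optional character vector restricting to a gene subset
#'   (typically the sex-biased set).
#' @return list with `d` (genes x stages raw difference matrix), `z` (the
#'   standardized copy) and `stages` (stage ordinals used).
#' @export
difference_trajectories <- function(ts, genes = NULL) {
  nc <- norm_counts(ts)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(nc))
    if (length(missing)) stop("unknown genes: ", paste(head(missing), collapse = ", "))
    nc <- nc[genes, , drop = FALSE]
  }
  Z <- log2p5(nc)
  sx <- ts$samples$sex
  st <- ts$samples$stage_ordinal
  both <- vapply(split(sx, st), function(s) all(c("M", "F") %in% s),
                 logical(1))
  stages <- as.integer(names(both))[both]
  d <- sapply(stages, function(s) {
    rowMeans(Z[, sx == "M" & st == s, drop = FALSE]) -
      rowMeans(Z[, sx == "F" & st == s, drop = FALSE])
  })
  if (is.null(dim(d))) d <- matrix(d, nrow = nrow(Z))
  dimnames(d) <- list(rownames(Z), stages)
  mx <- apply(abs(d), 1, max)
  z <- d / ifelse(mx > 0, mx, 1)
  list(d = d, z = z, stages = stages)
}

#' Fuzzy c-means soft clustering of trajectories
#'
#' Fuzzy c-means (fuzzifier m = 2, Euclidean distance) on standardized
#' trajectories with 20 seeded restarts, keeping the solution with the
#' smallest objective.  Memberships are recomputed analytically from the
#' final centers so the degenerate limits are exact: a trajectory at zero
#' distance from a center gets membership 1 for it, and identical
#' trajectories yield uniform memberships `1/K`.
#'
#' @param z numeric matrix, genes x stages (standardized trajectories).
#' @param K number of clusters (2 <= K <= number of genes).
#' @param seed integer seed.
#' @param m fuzzifier.
#' @param restarts number of random restarts.
#' @return list with `centers` (K x stages), `membership` (genes x K) and
#'   `K`.
#' @export
soft_cluster <- function(z, K, seed = 1, m = 2, restarts = 20) {
  z <- as.matrix(z)
  if (K < 2) stop("K must be >= 2")
  if (K > nrow(z)) stop("K exceeds the number of trajectories")
  set.seed(derive_seed(seed, 7L))
  if (all(abs(sweep(z, 2, z[1, ])) < 1e-12)) {
    centers <- matrix(rep(z[1, ], K), K, ncol(z), byrow = TRUE)
    membership <- matrix(1 / K, nrow(z), K,
                         dimnames = list(rownames(z), NULL))
    return(list(centers = centers, membership = membership, K = K))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- tryCatch(
      e1071::cmeans(z, centers = K, m = m, iter.max = 200,
                    method = "cmeans"),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || min(fit$withinerror) < min(best$withinerror)))
      best <- fit
  }
  if (is.null(best)) stop("fuzzy c-means failed on all restarts")
  centers <- unname(as.matrix(best$centers))
  membership <- fcm_membership(z, centers, m)
  rownames(membership) <- rownames(z)
  list(centers = centers, membership = membership, K = K)
}

# Analytic fuzzy c-means membership with exact zero-distance limits.
fcm_membership <- function(z, centers, m = 2) {
  d2 <- outer(rowSums(z^2), rep(1, nrow(centers))) -
    2 * z %*% t(centers) +
    outer(rep(1, nrow(z)), rowSums(centers^2))
  d2 <- pmax(d2, 0)
  u <- matrix(0, nrow(z), nrow(centers))
  for (i in seq_len(nrow(z))) {
    zero <- d2[i, ] < 1e-15
    if (any(zero)) {
      u[i, zero] <- 1 / sum(zero)
    } else {
      w <- d2[i, ]^(-1 / (m - 1))
      u[i, ] <- w / sum(w)
    }
  }
  u
}

#' Choose the number of clusters by the fuzzy partition coefficient elbow
#'
#' Scans `k_range`, computes the fuzzy partition coefficient (mean squared
#' membership) of each solution, and picks the elbow as the K with the
#' largest distance to the chord joining the endpoints of the FPC curve.
#'
#' @param z standardized trajectory matrix.
#' @param k_range candidate K values.
#' @param seed integer seed.
#' @return the chosen K (integer).
#' @export
choose_k <- function(z, k_range = 2:8, seed = 1) {
  k_range <- k_range[k_range <= nrow(z)]
  if (length(k_range) < 2) return(min(k_range))
  fpc <- vapply(k_range, function(k) {
    cl <- soft_cluster(z, k, seed = seed, restarts = 5)
    mean(rowSums(cl$membership^2))
  }, numeric(1))
  x <- as.numeric(k_range); y <- fpc
  x0 <- x - x[1]; y0 <- y - y[1]
  dx <- x[length(x)] - x[1]; dy <- y[length(y)] - y[1]
  dist <- abs(dx * y0 - dy * x0) / sqrt(dx^2 + dy^2)
  as.integer(k_range[which.max(dist)])
}

#' Classify cluster centers (and their genes) into onset classes
#'
#' Each center is rescaled to its own peak and the stages where the scaled
#' absolute effect reaches `effect_threshold` form the active window.
#' Active at every stage gives `always_SB`; a first active stage at or
#' after `maturity_stage - tol_stages` gives `post_SM` (the tolerance
#' captures onsets "around" maturity); an earlier first active stage gives
#' `pre_SM`.  A cluster with an empty active window leaves its genes
#' unassigned.  Each gene inherits the class of its maximum-membership
#' cluster when that membership reaches `min_membership`, otherwise it is
#' unassigned.
#'
#' @param clust result of [soft_cluster()].
#' @param stages stage ordinals corresponding to the trajectory columns.
#' @param maturity_stage sexual-maturity stage ordinal.
#' @param effect_threshold active-window threshold on the peak-scaled
#'   center, in `(0, 1)`.
#' @param min_membership membership required to inherit the cluster class.
#' @param tol_stages tolerance (in stages) for "around" sexual maturity.
#' @return data.frame with columns `gene`, `class`, `cluster`,
#'   `membership`; attribute `cluster_classes` maps cluster -> class.
#' @export
classify_onset <- function(clust, stages, maturity_stage,
                           effect_threshold = 0.5, min_membership = 0.5,
                           tol_stages = 1L) {
  stopifnot(effect_threshold > 0, effect_threshold < 1)
  centers <- clust$centers
  stopifnot(ncol(centers) == length(stages))
  cl_class <- character(nrow(centers))
  for (k in seq_len(nrow(centers))) {
    cc <- abs(centers[k, ])
    if (max(cc) <= 0) { cl_class[k] <- "unassigned"; next }
    active <- cc / max(cc) >= effect_threshold
    if (!any(active)) { cl_class[k] <- "unassigned"; next }
    first_active <- stages[which(active)[1]]
    cl_class[k] <-
      if (all(active)) "always_SB"
      else if (first_active >= maturity_stage - tol_stages) "post_SM"
      else "pre_SM"
  }
  u <- clust$membership
  best <- max.col(u, ties.method = "first")
  best_u <- u[cbind(seq_len(nrow(u)), best)]
  cls <- ifelse(best_u >= min_membership, cl_class[best], "unassigned")
  out <- data.frame(gene = rownames(u) %||% seq_len(nrow(u)),
                    class = cls, cluster = best, membership = best_u,
                    stringsAsFactors = FALSE)
  attr(out, "cluster_classes") <- cl_class
  out
}

#' One-call onset classification for a call set
#'
#' Convenience wrapper: builds difference trajectories for the sex-biased
#' genes, picks K by [choose_k()] (unless given), soft-clusters, and
#' classifies onsets.
#'
#' @param ts an [expression_time_series()].
#' @param calls a `SexBiasCallSet`.
#' @param maturity_stage sexual-maturity stage ordinal.
#' @param K number of clusters; `NULL` to scan 2..8.
#' @param seed integer seed.
#' @param ... passed to [classify_onset()].
#' @return the [classify_onset()] data.frame.
#' @export
onset_classes <- function(ts, calls, maturity_stage, K = NULL, seed = 1,
                          ...) {
  genes <- calls$table$gene[calls$table$status != "unbiased"]
  if (length(genes) < 3) stop("too few sex-biased genes to cluster")
  tr <- difference_trajectories(ts, genes)
  if (is.null(K)) K <- choose_k(tr$z, seed = seed)
  cl <- soft_cluster(tr$z, K, seed = seed)
  classify_onset(cl, tr$stages, maturity_stage, ...)
}
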