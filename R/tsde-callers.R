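#' Spline likelihood-ratio caller
#'
#' Per gene, a negative-binomial GLM with a natural cubic spline of the
#' stage ordinal is fitted with and without sex terms:
#' full `log mu = offset(log sf) + b0 + bs*sex + spline(stage, df) +
#' sex:spline(stage, df)`, reduced without `sex` and the interaction.  The
#' likelihood-ratio statistic, scaled by its `df + 1` degrees of freedom,
#' is referred to an F distribution whose denominator adds the dispersion
#' prior df to the residual df (a quasi-likelihood-style small-sample
#' correction of the chi-square reference, which is anticonservative at
#' 1-3 replicates per sex per stage); p-values are BH-adjusted across
#' tested genes.
#' Direction is the sign of the average fitted male-minus-female log2
#' difference over stages.
#'
#' @param ts an [expression_time_series()] (normalized; size factors are
#'   computed if missing).
#' @param df spline degrees of freedom.
#' @param alpha BH significance threshold used to set per-gene direction.
#' @param min_mean expression filter: mean normalized count required in at
#'   least one sex.
#' @return a `CallerResult`.
#' @export
caller_spline_lrt <- function(ts, df = 3, alpha = 0.05, min_mean = 5) {
  st <- ts$samples$stage_ordinal
  if (length(unique(st[ts$samples$sex == "M"])) < 2 ||
      length(unique(st[ts$samples$sex == "F"])) < 2)
    stop("need at least 2 distinct stages per sex")
  B <- splines::ns(st, df = df)
  sexM <- as.numeric(ts$samples$sex == "M")
  X_full <- cbind(1, sexM, B, B * sexM)
  X_red <- cbind(1, B)
  grid <- sort(unique(st))
  B_grid <- predict(B, grid)
  idx_int <- (2 + df + 1):(2 + 2 * df)
  lfc_fun <- function(beta) beta[2] + drop(B_grid %*% beta[idx_int])
  nb_lrt_engine(ts, X_full, X_red, lrt_df = df + 1, lfc_fun,
                name = "spline", alpha = alpha, min_mean = min_mean)
}

#' Factor likelihood-ratio caller
#'
#' Per gene, a negative-binomial GLM with stage as a categorical factor:
#' full `~ sex + stage + sex:stage`, reduced `~ stage`.  Gene-wise
#' dispersions are estimated by Cox-Reid adjusted maximum likelihood and
#' shrunk toward a mean-dispersion trend before the likelihood-ratio test
#' (`n_stages` numerator degrees of freedom, F reference as in
#' [caller_spline_lrt()]).
#'
#' @inheritParams caller_spline_lrt
#' @return a `CallerResult`.
#' @export
caller_factor_lrt <- function(ts, alpha = 0.05, min_mean = 5) {
  st <- factor(ts$samples$stage_ordinal)
  S <- nlevels(st)
  if (S < 2) stop("need at least 2 stages")
  D <- model.matrix(~ st)[, -1, drop = FALSE]
  sexM <- as.numeric(ts$samples$sex == "M")
  X_full <- cbind(1, sexM, D, D * sexM)
  X_red <- cbind(1, D)
  idx_int <- (2 + (S - 1) + 1):(2 + 2 * (S - 1))
  lfc_fun <- function(beta) beta[2] + c(0, beta[idx_int])
  nb_lrt_engine(ts, X_full, X_red, lrt_df = S, lfc_fun,
                name = "factor", alpha = alpha, min_mean = min_mean)
}

#' Two-step polynomial regression caller
#'
#' Step 1: per gene, least squares of `log2(normalized count + 0.5)` on a
#' centred polynomial of the stage ordinal plus sex and sex-by-stage-power
#' interactions; an overall F-test compares against the stage-only model.
#' Step 2: among step-1 significant genes (BH <= `alpha`), sex-block terms
#' are removed by backward elimination at `elim_alpha`, and survivors must
#' keep at least one sex term and reach `r2_min` goodness of fit.  Direction
#' comes from the average fitted male-minus-female difference over the
#' stage grid of the final model.
#'
#' @inheritParams caller_spline_lrt
#' @param degree polynomial degree; auto-reduced (with a warning) when the
#'   series has too few stages.
#' @param elim_alpha per-term threshold of the backward elimination.
#' @param r2_min goodness-of-fit filter on the final model.
#' @return a `CallerResult` (p-values are the step-1 F-test p-values;
#'   direction is set only for step-2 survivors).
#' @export
caller_poly2step <- function(ts, degree = 3, alpha = 0.05, min_mean = 5,
                             elim_alpha = 0.05, r2_min = 0.6) {
  ts <- ensure_normalized(ts)
  st <- ts$samples$stage_ordinal
  S <- length(unique(st))
  if (degree > S - 2) {
    degree <- max(1, S - 2)
    warning("polynomial degree reduced to ", degree,
            " for a series with ", S, " stages")
  }
  tc <- st - mean(sort(unique(st)))
  P <- sapply(seq_len(degree), function(k) tc^k)
  sexM <- as.numeric(ts$samples$sex == "M")
  X_red <- cbind(1, P)
  X_sex <- cbind(sexM, P * sexM)
  X_full <- cbind(X_red, X_sex)
  sex_cols <- ncol(X_red) + seq_len(ncol(X_sex))
  q <- length(sex_cols)
  n <- nrow(X_full)
  dfree <- n - ncol(X_full)
  grid <- sort(unique(tc))
  grid_pow <- cbind(1, sapply(seq_len(degree), function(k) grid^k))

  nc <- norm_counts(ts)
  tested <- expressed_filter(nc, ts$samples$sex, min_mean)
  Z <- log2p5(nc)
  G <- nrow(Z)
  pvalue <- rep(NA_real_, G); lfc <- rep(NA_real_, G)
  called <- rep(FALSE, G)

  rss <- function(X, z) {
    f <- lm.fit(X, z); sum(f$residuals^2)
  }
  for (g in which(tested)) {
    z <- Z[g, ]
    r1 <- lm.fit(X_full, z); rss1 <- sum(r1$residuals^2)
    rss0 <- rss(X_red, z)
    Fstat <- ((rss0 - rss1) / q) / (rss1 / dfree)
    pvalue[g] <- pf(Fstat, q, dfree, lower.tail = FALSE)
  }
  padj <- rep(NA_real_, G)
  padj[tested] <- bh_adjust(pvalue[tested])

  for (g in which(tested & !is.na(padj) & padj <= alpha)) {
    z <- Z[g, ]
    keep <- sex_cols
    repeat {
      X <- X_full[, c(seq_len(ncol(X_red)), keep), drop = FALSE]
      f <- lm.fit(X, z)
      res_df <- n - ncol(X)
      sigma2 <- sum(f$residuals^2) / res_df
      XtXi <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
      if (is.null(XtXi)) { keep <- integer(0); break }
      se <- sqrt(diag(XtXi) * sigma2)
      tt <- f$coefficients / se
      pv <- 2 * pt(abs(tt), res_df, lower.tail = FALSE)
      sex_in_X <- ncol(X_red) + seq_len(length(keep))
      worst <- which.max(pv[sex_in_X])
      if (length(keep) == 0 || pv[sex_in_X][worst] <= elim_alpha) break
      keep <- keep[-worst]
      if (length(keep) == 0) break
    }
    if (length(keep) == 0) next
    X <- X_full[, c(seq_len(ncol(X_red)), keep), drop = FALSE]
    f <- lm.fit(X, z)
    r2 <- 1 - sum(f$residuals^2) / sum((z - mean(z))^2)
    if (r2 < r2_min) next
    # fitted male-minus-female difference averaged over the stage grid
    beta_sex <- setNames(rep(0, q), c("sexM", paste0("sexP", seq_len(degree))))
    beta_sex[match(keep, sex_cols)] <- f$coefficients[ncol(X_red) +
                                                      seq_len(length(keep))]
    dbar <- mean(grid_pow %*% beta_sex)
    if (dbar == 0) next
    called[g] <- TRUE
    lfc[g] <- dbar
  }
  res <- caller_result("poly", rownames(Z), tested, pvalue, lfc, alpha)
  # direction only for step-2 survivors
  res$table$direction[!called] <- "none"
  res$table$lfc[!called] <- NA_real_
  res
}

#' Stage-window permutation caller
#'
#' Per gene, the statistic is the maximum over all contiguous stage windows
#' of length >= 2 of `|mean stage-wise male-minus-female log2 difference| *
#' sqrt(window length)`.  The null distribution is obtained by permuting
#' sex labels within each stage; the empirical p-value uses add-one
#' smoothing, `p = (1 + #[T_perm >= T_obs]) / (1 + n_perm)`.  The window
#' form makes the test sensitive to effects confined to part of the series,
#' such as post-maturity onsets.
#'
#' @inheritParams caller_spline_lrt
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @return a `CallerResult`; `lfc` is the mean log2 difference over the
#'   maximizing window.
#' @export
caller_window_perm <- function(ts, n_perm = 1000, seed = 1, alpha = 0.05,
                               min_mean = 5) {
  if (n_perm < 100) stop("need at least 100 permutations")
  ts <- ensure_normalized(ts)
  sx <- ts$samples$sex
  st <- ts$samples$stage_ordinal
  both <- vapply(split(sx, st), function(s) all(c("M", "F") %in% s),
                 logical(1))
  stages <- as.integer(names(both))[both]
  if (length(stages) < length(both))
    message("excluding ", sum(!both), " stage(s) with a single sex")
  if (length(stages) < 2) stop("both sexes must be present at >= 2 stages")
  keep <- st %in% stages
  sx <- sx[keep]; st <- st[keep]
  nc <- norm_counts(ts)[, keep, drop = FALSE]
  tested <- expressed_filter(nc, sx, min_mean)
  Z <- log2p5(nc[tested, , drop = FALSE])
  S <- length(stages)
  stage_idx <- match(st, stages)

  # windows [i, j], length >= 2
  win <- which(upper.tri(matrix(TRUE, S, S)), arr.ind = TRUE)
  win <- win[win[, 2] > win[, 1] | TRUE, , drop = FALSE]
  win <- win[win[, 2] - win[, 1] >= 1, , drop = FALSE]
  wlen <- win[, 2] - win[, 1] + 1

  diff_matrix <- function(sex_vec) {
    A <- matrix(0, length(sex_vec), S)
    for (s in seq_len(S)) {
      m <- sex_vec == "M" & stage_idx == s
      f <- sex_vec == "F" & stage_idx == s
      A[m, s] <- 1 / sum(m)
      A[f, s] <- -1 / sum(f)
    }
    Z %*% A                                  # genes x stages
  }
  window_stats <- function(D) {
    C <- cbind(0, t(apply(D, 1, cumsum)))
    W <- matrix(NA_real_, nrow(D), nrow(win))
    for (k in seq_len(nrow(win))) {
      W[, k] <- abs(C[, win[k, 2] + 1] - C[, win[k, 1]]) / sqrt(wlen[k])
    }
    W
  }

  D_obs <- diff_matrix(sx)
  W_obs <- window_stats(D_obs)
  T_obs <- apply(W_obs, 1, max)
  k_max <- apply(W_obs, 1, which.max)
  # signed mean difference over the maximizing window
  lfc_sub <- vapply(seq_len(nrow(D_obs)), function(i) {
    k <- k_max[i]
    mean(D_obs[i, win[k, 1]:win[k, 2]])
  }, numeric(1))

  set.seed(derive_seed(seed, 6L))
  exceed <- rep(0L, nrow(Z))
  groups <- split(seq_along(sx), stage_idx)
  for (p in seq_len(n_perm)) {
    perm_sex <- sx
    for (g in groups) perm_sex[g] <- sx[sample(g)]
    Tp <- apply(window_stats(diff_matrix(perm_sex)), 1, max)
    exceed <- exceed + (Tp >= T_obs)
  }
  pv_sub <- (1 + exceed) / (1 + n_perm)

  G <- nrow(nc)
  pvalue <- rep(NA_real_, G); lfc <- rep(NA_real_, G)
  pvalue[tested] <- pv_sub
  lfc[tested] <- lfc_sub
  caller_result("window", rownames(nc), tested, pvalue, lfc, alpha)
}

#' Stage-wise (classical) differential expression on a stage subset
#'
#' Negative-binomial Wald test of the sex coefficient on a subset of stages
#' only (adding a stage factor when the subset spans more than one stage),
#' the classical single-snapshot analysis used for adult-only or
#' prenatal-only calls.
#'
#' @inheritParams caller_spline_lrt
#' @param stages integer vector of stage ordinals to keep.
#' @return a `CallerResult` named `"adult"` (or `"stagewise"` for multi-use).
#' @param name caller name recorded in the result.
#' @export
stagewise_de <- function(ts, stages, alpha = 0.05, min_mean = 5,
                         name = "adult") {
  stopifnot(length(stages) >= 1)
  keep <- ts$samples$stage_ordinal %in% stages
  if (!any(keep)) stop("no samples in the requested stages")
  sub <- expression_time_series(ts$counts[, keep, drop = FALSE],
                                ts$samples[keep, , drop = FALSE])
  if (length(unique(sub$samples$sex)) < 2)
    stop("both sexes must be present in the stage subset")
  sub <- normalize_counts(sub)
  sexM <- as.numeric(sub$samples$sex == "M")
  stf <- factor(sub$samples$stage_ordinal)
  X <- if (nlevels(stf) > 1) {
    cbind(1, sexM, model.matrix(~ stf)[, -1, drop = FALSE])
  } else cbind(1, sexM)
  if (qr(X)$rank < ncol(X)) stop("singular design in stage subset")
  offset <- log(sub$size_factors)
  nc <- norm_counts(sub)
  tested <- expressed_filter(nc, sub$samples$sex, min_mean)
  base_mean <- rowMeans(nc)
  resid_df <- ncol(sub$counts) - ncol(X)
  G <- nrow(sub$counts)

  alpha_hat <- rep(NA_real_, G)
  for (g in which(tested)) {
    alpha_hat[g] <- estimate_alpha(sub$counts[g, ], X, offset)
  }
  trend <- fit_dispersion_trend(alpha_hat[tested], base_mean[tested])
  alpha_use <- shrink_alpha(alpha_hat, base_mean, trend,
                            max(resid_df, 1))

  zval <- rep(NA_real_, G); lfc <- rep(NA_real_, G)
  prior_df <- 10
  for (g in which(tested)) {
    y <- sub$counts[g, ]
    f <- fit_nb(y, X, offset, alpha_use[g])
    if (is.null(f)) { tested[g] <- FALSE; next }
    cv <- tryCatch(nb_wald_cov(X, f$mu, alpha_use[g]),
                   error = function(e) NULL)
    if (is.null(cv)) { tested[g] <- FALSE; next }
    zval[g] <- f$beta[2] / sqrt(cv[2, 2])
    lfc[g] <- f$beta[2] / log(2)
  }
  # t reference with moderated df plus a clamped median-based scale factor:
  # with the handful of samples a single-stage subset carries, the plain
  # normal Wald reference is substantially liberal
  denom_df <- max(resid_df, 1) + prior_df
  lam <- 1
  if (sum(tested) >= 50) {
    lam <- max(1, median(zval[tested]^2, na.rm = TRUE) /
                 qf(0.5, 1, denom_df))
  }
  pvalue <- rep(NA_real_, G)
  pvalue[tested] <- 2 * pt(-abs(zval[tested]) / sqrt(lam), df = denom_df)
  caller_result(name, rownames(sub$counts), tested, pvalue, lfc, alpha)
}
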