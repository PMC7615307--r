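# Negative-binomial GLM internals shared by the likelihood-ratio callers
# and the stage-wise Wald test.  Dispersion is parameterised as alpha with
# Var(Y) = mu + alpha * mu^2 (theta = 1/alpha).

nb_loglik <- function(y, mu, alpha) {
  sum(dnbinom(y, size = 1 / alpha, mu = pmax(mu, 1e-10), log = TRUE))
}

# Cox-Reid adjustment term 0.5 * log det(X' W X); counteracts the downward
# bias of ML dispersion estimates when the mean model has many coefficients.
cr_term <- function(X, mu, alpha) {
  w <- mu / (1 + alpha * mu)
  d <- determinant(crossprod(X * sqrt(w)), logarithm = TRUE)
  0.5 * as.numeric(d$modulus)
}

# CR-adjusted profile ML estimate of alpha.  The coefficients are refitted
# for every candidate alpha (a true profile likelihood); fixing the fitted
# means instead biases alpha low and inflates the LRT statistic.
estimate_alpha <- function(y, X, offset, lower = 1e-8, upper = 30) {
  obj <- function(la) {
    a <- exp(la)
    f <- fit_nb(y, X, offset, a)
    if (is.null(f)) return(1e10)
    -(f$ll - cr_term(X, f$mu, a))
  }
  opt <- optimize(obj, c(log(lower), log(upper)), tol = 0.02)
  exp(opt$minimum)
}

# NB GLM with fixed dispersion via IRLS (glm.fit).  Returns NULL on failure.
fit_nb <- function(y, X, offset, alpha) {
  fam <- MASS::negative.binomial(theta = 1 / max(alpha, 1e-8), link = "log")
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = fam, offset = offset,
                             control = list(maxit = 50))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(beta = beta, mu = fit$fitted.values,
       ll = nb_loglik(y, fit$fitted.values, alpha))
}

fit_poisson_mu <- function(y, X, offset) {
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = poisson(), offset = offset,
                             control = list(maxit = 50))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  fit$fitted.values
}

# Robust trend alpha(mu) = a0/mu + a1 across genes, and empirical-Bayes
# shrinkage of per-gene estimates toward it on the log scale with weight
# resid_df / (resid_df + prior_df).
fit_dispersion_trend <- function(alpha, mu) {
  ok <- is.finite(alpha) & is.finite(mu) & mu > 0
  alpha <- alpha[ok]; mu <- mu[ok]
  if (length(alpha) < 10) {
    a1 <- max(median(alpha), 1e-4); a0 <- 1e-3
  } else {
    hi <- mu >= quantile(mu, 0.7)
    a1 <- max(median(alpha[hi]), 1e-4)
    a0 <- max(median((alpha - a1) * mu), 1e-3)
  }
  list(a0 = a0, a1 = a1, fun = function(m) a0 / pmax(m, 1e-8) + a1)
}

shrink_alpha <- function(alpha, mu, trend, resid_df, prior_df = 10) {
  w <- resid_df / (resid_df + prior_df)
  exp(w * log(pmax(alpha, 1e-8)) +
      (1 - w) * log(pmax(trend$fun(mu), 1e-8)))
}

# Expression filter: a gene is tested when its mean normalized count
# reaches min_mean in at least one sex.
expressed_filter <- function(nc, sex, min_mean = 5) {
  mM <- rowMeans(nc[, sex == "M", drop = FALSE])
  mF <- rowMeans(nc[, sex == "F", drop = FALSE])
  pmax(mM, mF) >= min_mean
}

caller_result <- function(name, gene, tested, pvalue, lfc, alpha) {
  padj <- rep(NA_real_, length(gene))
  padj[tested] <- bh_adjust(pvalue[tested])
  direction <- rep("none", length(gene))
  sig <- tested & !is.na(padj) & padj <= alpha & !is.na(lfc) & lfc != 0
  direction[sig] <- ifelse(lfc[sig] > 0, "male", "female")
  structure(list(name = name, alpha = alpha,
                 table = data.frame(gene = gene, tested = tested,
                                    pvalue = pvalue, padj = padj, lfc = lfc,
                                    direction = direction,
                                    stringsAsFactors = FALSE)),
            class = "CallerResult")
}

#' @method print CallerResult
#' @export
print.CallerResult <- function(x, ...) {
  tab <- x$table
  cat(sprintf("CallerResult '%s': %d/%d genes tested, %d called at BH %.3g\n",
              x$name, sum(tab$tested), nrow(tab),
              sum(tab$direction != "none"), x$alpha))
  invisible(x)
}

# Shared engine for the two NB LRT callers.  X_full / X_red are fixed design
# matrices; lrt_df the chi-square degrees of freedom; lfc_fun maps the full
# coefficient vector to a per-stage male-minus-female log2 difference whose
# mean is the summary lfc.
nb_lrt_engine <- function(ts, X_full, X_red, lrt_df, lfc_fun, name,
                          alpha = 0.05, min_mean = 5, prior_df = 10) {
  ts <- ensure_normalized(ts)
  if (qr(X_full)$rank < ncol(X_full))
    stop("singular design: full model matrix is rank deficient")
  counts <- ts$counts
  offset <- log(ts$size_factors)
  nc <- norm_counts(ts)
  tested <- expressed_filter(nc, ts$samples$sex, min_mean)
  G <- nrow(counts)
  base_mean <- rowMeans(nc)
  resid_df <- ncol(counts) - ncol(X_full)

  alpha_hat <- rep(NA_real_, G)
  for (g in which(tested)) {
    alpha_hat[g] <- estimate_alpha(counts[g, ], X_full, offset)
  }
  trend <- fit_dispersion_trend(alpha_hat[tested], base_mean[tested])
  alpha_use <- shrink_alpha(alpha_hat, base_mean, trend, resid_df, prior_df)

  stat <- rep(NA_real_, G); lfc <- rep(NA_real_, G)
  for (g in which(tested)) {
    y <- counts[g, ]
    f1 <- fit_nb(y, X_full, offset, alpha_use[g])
    f0 <- fit_nb(y, X_red, offset, alpha_use[g])
    if (is.null(f1) || is.null(f0)) { tested[g] <- FALSE; next }
    stat[g] <- max(0, 2 * (f1$ll - f0$ll))
    lfc[g] <- mean(lfc_fun(f1$beta)) / log(2)
  }
  # Small-sample reference: the LRT statistic divided by its degrees of
  # freedom is referred to an F distribution whose denominator df adds the
  # dispersion-moderation prior df to the residual df (the quasi-likelihood
  # convention); a plain chi-square reference is anticonservative at 1-3
  # replicates per sex per stage.  A residual scale inflation of the
  # statistic is absorbed by a median-based (genomic-control style) factor,
  # clamped at 1 so it can only ever make the test more conservative; it is
  # robust as long as most genes are not sex-biased.
  denom_df <- resid_df + prior_df
  lam <- 1
  if (sum(tested) >= 50) {
    lam <- max(1, median(stat[tested], na.rm = TRUE) /
                 (lrt_df * qf(0.5, lrt_df, denom_df)))
  }
  pvalue <- rep(NA_real_, G)
  pvalue[tested] <- pf(stat[tested] / (lam * lrt_df), lrt_df, denom_df,
                       lower.tail = FALSE)
  caller_result(name, rownames(counts), tested, pvalue, lfc, alpha)
}

# Wald covariance for an NB GLM fit with fixed alpha.
nb_wald_cov <- function(X, mu, alpha) {
  w <- mu / (1 + alpha * mu)
  solve(crossprod(X * sqrt(w)))
}
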