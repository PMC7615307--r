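#' Consensus sex-bias calls from multiple callers
#'
#' A gene is called sex-biased when at least two callers are BH-significant
#' at `alpha` AND agree in direction; pairs of significant callers with
#' opposite directions do not count toward the quorum.  The consensus log2
#' fold change is the median of the supporting callers' estimates.
#'
#' @param results list of `CallerResult` objects sharing one gene universe
#'   (fewer than four is allowed, with a message; the quorum stays 2).
#' @param alpha BH significance threshold.
#' @return a `SexBiasCallSet`: list with `table` (columns `gene`, `status`,
#'   `n_supporting`, `callers`, `lfc`, `provenance`) and `alpha`.
#' @export
consensus <- function(results, alpha = 0.05) {
  stopifnot(length(results) >= 1)
  genes <- results[[1]]$table$gene
  for (r in results) {
    if (!identical(r$table$gene, genes))
      stop("caller results must share the gene universe")
  }
  if (length(results) < 4)
    message("consensus over ", length(results),
            " callers (quorum stays 2)")
  nm <- vapply(results, function(r) r$name, character(1))
  sig_dir <- sapply(results, function(r) {
    ifelse(r$table$tested & !is.na(r$table$padj) & r$table$padj <= alpha,
           r$table$direction, "none")
  })
  lfcs <- sapply(results, function(r) r$table$lfc)
  if (is.null(dim(sig_dir))) {
    sig_dir <- matrix(sig_dir, ncol = length(results))
    lfcs <- matrix(lfcs, ncol = length(results))
  }

  n_male <- rowSums(sig_dir == "male")
  n_female <- rowSums(sig_dir == "female")
  status <- rep("unbiased", length(genes))
  status[n_male >= 2 & n_male > n_female] <- "male-biased"
  status[n_female >= 2 & n_female > n_male] <- "female-biased"

  n_supporting <- integer(length(genes))
  callers <- character(length(genes))
  lfc <- rep(NA_real_, length(genes))
  for (i in which(status != "unbiased")) {
    dir <- if (status[i] == "male-biased") "male" else "female"
    sup <- which(sig_dir[i, ] == dir)
    n_supporting[i] <- length(sup)
    callers[i] <- paste(nm[sup], collapse = ",")
    lfc[i] <- median(lfcs[i, sup], na.rm = TRUE)
  }
  structure(list(table = data.frame(gene = genes, status = status,
                                    n_supporting = n_supporting,
                                    callers = callers, lfc = lfc,
                                    provenance = ifelse(status == "unbiased",
                                                        "", "time_series"),
                                    stringsAsFactors = FALSE),
                 alpha = alpha),
            class = "SexBiasCallSet")
}

#' @method print SexBiasCallSet
#' @export
print.SexBiasCallSet <- function(x, ...) {
  tab <- x$table
  cat(sprintf("SexBiasCallSet: %d genes, %d male-biased, %d female-biased\n",
              nrow(tab), sum(tab$status == "male-biased"),
              sum(tab$status == "female-biased")))
  invisible(x)
}

#' Extend time-series calls with adult-only (stage-wise) calls
#'
#' Union of the time-series consensus set and the adult stage-wise calls;
#' genes found only by the adult test get provenance `adult_only`, genes in
#' both get `both`.  Direction conflicts are resolved in favour of the
#' time-series call (with a message).
#'
#' @param ts_calls a `SexBiasCallSet` from [consensus()].
#' @param adult_calls a `CallerResult` from [stagewise_de()].
#' @param alpha BH threshold applied to the adult calls.
#' @return a `SexBiasCallSet`.
#' @export
extended_set <- function(ts_calls, adult_calls, alpha = ts_calls$alpha) {
  tab <- ts_calls$table
  at <- adult_calls$table
  if (!identical(tab$gene, at$gene))
    stop("time-series and adult calls must share the gene universe")
  adult_sig <- at$tested & !is.na(at$padj) & at$padj <= alpha &
    at$direction != "none"
  adult_status <- ifelse(at$direction == "male", "male-biased",
                         "female-biased")
  conflicts <- 0L
  for (i in which(adult_sig)) {
    if (tab$status[i] == "unbiased") {
      tab$status[i] <- adult_status[i]
      tab$n_supporting[i] <- 1L
      tab$callers[i] <- adult_calls$name
      tab$lfc[i] <- at$lfc[i]
      tab$provenance[i] <- "adult_only"
    } else {
      if (tab$status[i] != adult_status[i]) conflicts <- conflicts + 1L
      tab$provenance[i] <- "both"
    }
  }
  if (conflicts > 0)
    message(conflicts, " direction conflict(s) resolved in favour of the ",
            "time-series call")
  structure(list(table = tab, alpha = ts_calls$alpha),
            class = "SexBiasCallSet")
}

#' Evaluate calls against simulation truth
#'
#' A true positive requires the called direction to match the spiked
#' direction; calls with the wrong direction count as false positives.
#' Specificity is the fraction of unspiked genes left uncalled.
#'
#' @param calls a `SexBiasCallSet`.
#' @param truth a `SimulationTruth`.
#' @return an `EvaluationReport` list: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `fdp`, and `per_lfc` (stratified
#'   sensitivity by spiked lfc).
#' @export
evaluate_calls <- function(calls, truth) {
  tab <- calls$table
  sp <- truth$spikes
  if (nrow(sp) && !all(sp$gene %in% tab$gene))
    stop("truth and calls must share the gene universe")
  called <- tab$status != "unbiased"
  call_dir <- ifelse(tab$status == "male-biased", "male",
                     ifelse(tab$status == "female-biased", "female", "none"))
  truth_dir <- setNames(sp$direction, sp$gene)
  is_spiked <- tab$gene %in% sp$gene

  tp_mask <- called & is_spiked &
    call_dir == truth_dir[tab$gene]
  tp_mask[is.na(tp_mask)] <- FALSE
  tp <- sum(tp_mask)
  fp <- sum(called) - tp                   # unspiked calls + wrong direction
  fn <- nrow(sp) - tp
  tn <- sum(!is_spiked & !called)

  per_lfc <- NULL
  if (nrow(sp)) {
    per_lfc <- vapply(split(sp$gene, sp$lfc), function(gs) {
      mean(tp_mask[match(gs, tab$gene)])
    }, numeric(1))
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = if (nrow(sp)) tp / nrow(sp) else NA_real_,
                 specificity = if (sum(!is_spiked)) tn / sum(!is_spiked)
                               else NA_real_,
                 fdp = fp / max(1, tp + fp),
                 per_lfc = per_lfc),
            class = "EvaluationReport")
}

#' @method print EvaluationReport
#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf(paste0("EvaluationReport: TP=%d FP=%d TN=%d FN=%d | ",
                     "sens=%.3f spec=%.3f FDP=%.3f\n"),
              x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity, x$fdp))
  if (!is.null(x$per_lfc)) {
    cat("per-lfc sensitivity:",
        paste(sprintf("lfc %s: %.3f", names(x$per_lfc), x$per_lfc),
              collapse = ", "), "\n")
  }
  invisible(x)
}
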