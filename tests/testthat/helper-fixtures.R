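# Shared fixture builders; everything is generated in code at test time.

# A minimal ExpressionTimeSeries from an explicit count matrix.
ts_from_counts <- function(counts, stages = NULL, sexes = NULL) {
  n <- ncol(counts)
  if (is.null(stages)) stages <- rep(1L, n)
  if (is.null(sexes)) sexes <- rep(c("M", "F"), length.out = n)
  if (is.null(colnames(counts))) colnames(counts) <- paste0("smp", seq_len(n))
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  samples <- data.frame(sample = colnames(counts), species = "sp",
                        organ = "org", stage = paste0("s", stages),
                        stage_ordinal = stages, sex = sexes,
                        replicate = seq_len(n), stringsAsFactors = FALSE)
  expression_time_series(counts, samples)
}

# A series where every gene is constant across samples (size factors 1).
constant_ts <- function(values = c(10, 20, 50, 100, 200), n_stages = 4,
                        reps = 2) {
  n <- n_stages * 2 * reps
  counts <- matrix(rep(values, each = n), nrow = length(values),
                   byrow = TRUE)
  stages <- rep(seq_len(n_stages), each = 2 * reps)
  sexes <- rep(rep(c("M", "F"), each = reps), n_stages)
  ts_from_counts(counts, stages, sexes)
}

# A SexBiasCallSet built by hand (for evaluation tests).
make_callset <- function(genes, status, lfc = NULL, alpha = 0.05) {
  stopifnot(length(genes) == length(status))
  if (is.null(lfc))
    lfc <- ifelse(status == "male-biased", 1,
                  ifelse(status == "female-biased", -1, NA_real_))
  structure(list(table = data.frame(
    gene = genes, status = status,
    n_supporting = ifelse(status == "unbiased", 0L, 2L),
    callers = ifelse(status == "unbiased", "", "a,b"),
    lfc = lfc,
    provenance = ifelse(status == "unbiased", "", "time_series"),
    stringsAsFactors = FALSE), alpha = alpha), class = "SexBiasCallSet")
}

# A CallerResult built by hand.
make_caller <- function(genes, padj, direction, lfc, name = "x",
                        alpha = 0.05) {
  structure(list(name = name, alpha = alpha,
                 table = data.frame(gene = genes, tested = TRUE,
                                    pvalue = padj, padj = padj, lfc = lfc,
                                    direction = direction,
                                    stringsAsFactors = FALSE)),
            class = "CallerResult")
}

# Small dense CellMatrix from a value matrix (counts).
cells_from_counts <- function(counts, types, sexes) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  meta <- data.frame(cell = colnames(counts), type = types, sex = sexes,
                     stringsAsFactors = FALSE)
  cell_matrix(counts, meta)
}

# Brute-force all-pairs interval oracle in 0-based half-open coordinates:
# a gene is a target iff some region satisfies s < tss + w and e > tss - w.
oracle_targets <- function(regions, annotation, w) {
  hits <- vapply(seq_len(nrow(annotation)), function(i) {
    same <- regions$chrom == annotation$chrom[i]
    any(same & regions$start < annotation$tss[i] + w &
          regions$end > annotation$tss[i] - w)
  }, logical(1))
  sort(annotation$gene[hits])
}
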