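#' Construct an ExpressionTimeSeries
#'
#' The central bulk container: an integer count matrix (genes x samples)
#' plus the per-sample design metadata, and, once [normalize_counts()] has
#' run, median-of-ratios size factors.
#'
#' @param counts non-negative integer matrix, genes in rows, samples in
#'   columns; row and column names required.
#' @param samples data.frame with columns `sample`, `species`, `organ`,
#'   `stage`, `stage_ordinal`, `sex` (`"M"`/`"F"`), `replicate`; rows must
#'   match `colnames(counts)`.
#' @param size_factors optional positive numeric vector, one per sample.
#' @return object of class `ExpressionTimeSeries`.
#' @export
expression_time_series <- function(counts, samples, size_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts))) stop("duplicated gene IDs")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  need <- c("sample", "species", "organ", "stage", "stage_ordinal", "sex",
            "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample metadata missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(samples$sex %in% c("M", "F")))
    stop("sex labels must be 'M' or 'F'")
  if (any(is.na(samples$stage_ordinal)))
    stop("every sample needs a stage ordinal")
  if (!identical(as.character(samples$sample), colnames(counts)))
    stop("sample metadata rows must match count matrix columns")
  if (!is.null(size_factors)) {
    stopifnot(length(size_factors) == ncol(counts), all(size_factors > 0))
  }
  structure(list(counts = counts, samples = samples,
                 size_factors = size_factors),
            class = "ExpressionTimeSeries")
}

#' @method print ExpressionTimeSeries
#' @export
print.ExpressionTimeSeries <- function(x, ...) {
  cat(sprintf("ExpressionTimeSeries: %d genes x %d samples (%d stages, %s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$stage_ordinal)),
              if (is.null(x$size_factors)) "unnormalized" else "normalized"))
  invisible(x)
}

#' Construct a CellMatrix
#'
#' Sparse single-cell container (genes x cells) with cell type and sex
#' labels.  The normalized layer is `log1p(count / library_size * 1e4)`,
#' computed once and cached.
#'
#' @param counts sparse or dense non-negative matrix, genes x cells, with
#'   dimnames.
#' @param cell_meta data.frame with columns `cell`, `type`, `sex`.
#' @return object of class `CellMatrix` with elements `counts`, `meta`,
#'   `norm` (normalized layer) and `library_size`.
#' @export
cell_matrix <- function(counts, cell_meta) {
  if (!methods::is(counts, "sparseMatrix"))
    counts <- Matrix::Matrix(as.matrix(counts) * 1.0, sparse = TRUE)
  counts <- methods::as(counts, "CsparseMatrix")
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  need <- c("cell", "type", "sex")
  if (!all(need %in% names(cell_meta)))
    stop("cell metadata needs columns cell, type, sex")
  if (!all(cell_meta$sex %in% c("M", "F")))
    stop("sex labels must be 'M' or 'F'")
  if (any(!nzchar(cell_meta$type))) stop("cell types must be non-empty")
  if (!identical(as.character(cell_meta$cell), colnames(counts)))
    stop("cell metadata rows must match count matrix columns")
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) stop("cells with zero total counts are not allowed")
  norm <- counts
  norm@x <- log1p(counts@x / rep.int(lib, diff(counts@p)) * 1e4)
  structure(list(counts = counts, meta = cell_meta, norm = norm,
                 library_size = lib),
            class = "CellMatrix")
}

#' @method print CellMatrix
#' @export
print.CellMatrix <- function(x, ...) {
  cat(sprintf("CellMatrix: %d genes x %d cells, %d cell types\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$meta$type))))
  invisible(x)
}

#' Read a count matrix and sample metadata into an ExpressionTimeSeries
#'
#' @param counts_file TSV, genes in rows, first column the gene ID, one
#'   column per sample.
#' @param meta_file TSV of sample metadata (see
#'   [expression_time_series()]).
#' @return an `ExpressionTimeSeries`.
#' @export
read_counts <- function(counts_file, meta_file) {
  tab <- read.table(counts_file, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1]])) stop("duplicated gene IDs in ", counts_file)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  meta <- read.table(meta_file, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expression_time_series(counts, meta)
}

#' Write an ExpressionTimeSeries to TSV files
#'
#' @param ts an `ExpressionTimeSeries`.
#' @param counts_file,meta_file output paths.
#' @return invisibly, the paths written.
#' @export
write_counts <- function(ts, counts_file, meta_file) {
  tab <- data.frame(gene = rownames(ts$counts), ts$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, counts_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ts$samples, meta_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_file, meta_file))
}

#' Write / read a sex-bias call table
#'
#' Columns: `gene`, `status`, `n_supporting`, `callers`, `lfc`,
#' `provenance`.
#'
#' @param calls a `SexBiasCallSet` (see [consensus()]).
#' @param file path.
#' @return `write_calls()` the path invisibly; `read_calls()` a
#'   `SexBiasCallSet`.
#' @export
write_calls <- function(calls, file) {
  write.table(calls$table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_calls
#' @export
read_calls <- function(file) {
  tab <- read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  tab$callers[is.na(tab$callers)] <- ""
  structure(list(table = tab, alpha = NA_real_), class = "SexBiasCallSet")
}

#' Write / read simulation truth as versioned JSON
#'
#' @param truth a `SimulationTruth`.
#' @param file path.
#' @return `write_truth()` the path invisibly; `read_truth()` a
#'   `SimulationTruth`.
#' @export
write_truth <- function(truth, file) {
  stopifnot(inherits(truth, "SimulationTruth"))
  obj <- list(schema_version = truth$schema_version,
              spikes = truth$spikes,
              chromosomes = list(gene = names(truth$chromosomes),
                                 chrom = unname(truth$chromosomes)))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_truth
#' @export
read_truth <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  spikes <- as.data.frame(obj$spikes, stringsAsFactors = FALSE)
  if (nrow(spikes)) {
    spikes$gene <- as.character(spikes$gene)
    spikes$lfc <- as.numeric(spikes$lfc)
    spikes$onset_stage <- as.integer(spikes$onset_stage)
    spikes$offset_stage <- as.integer(spikes$offset_stage)
  }
  chrom <- setNames(obj$chromosomes$chrom, obj$chromosomes$gene)
  structure(list(schema_version = obj$schema_version, spikes = spikes,
                 chromosomes = chrom),
            class = "SimulationTruth")
}

#' Read a BED file into a GRanges
#'
#' BED is 0-based half-open; the returned `GRanges` follows the usual
#' 1-based closed convention (`start + 1`, `end`).  Malformed lines are
#' reported with their line numbers.
#'
#' @param file BED path (>= 3 whitespace-separated columns).
#' @return a [GenomicRanges::GRanges] with an `mcols` column `name` when a
#'   4th column is present.
#' @export
read_bed <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "[ \t]+")
  nfield <- lengths(fields)
  bad <- which(nfield < 3)
  if (length(bad))
    stop("BED parse error at line ", bad[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("BED parse error at line ", bad[1], ": non-numeric coordinates")
  bad <- which(start >= end)
  if (length(bad))
    stop("BED parse error at line ", bad[1], ": start >= end")
  gr <- GenomicRanges::GRanges(factor(chrom, levels = sort(unique(chrom))),
                               IRanges::IRanges(start = start + 1, end = end))
  if (all(nfield >= 4)) gr$name <- vapply(fields, `[[`, "", 4)
  GenomicRanges::sort(gr)
}

#' Write a GRanges or region data.frame as BED (0-based half-open)
#'
#' @param regions a `GRanges` or a data.frame with `chrom`, `start`, `end`
#'   already in 0-based half-open coordinates.
#' @param file path.
#' @return the path, invisibly.
#' @export
write_bed <- function(regions, file) {
  if (methods::is(regions, "GRanges")) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                     start = GenomicRanges::start(regions) - 1,
                     end = GenomicRanges::end(regions))
  } else {
    df <- regions[, c("chrom", "start", "end")]
  }
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Read / write a cells directory (MTX triplet + metadata)
#'
#' The directory holds `matrix.mtx` (genes x cells), `features.tsv`,
#' `barcodes.tsv` and `cell_metadata.tsv` (columns `cell`, `type`, `sex`).
#'
#' @param dir directory path.
#' @return `read_mtx_dir()` a [cell_matrix()]; `write_mtx_dir()` the
#'   directory invisibly.
#' @export
read_mtx_dir <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  feats <- readLines(file.path(dir, "features.tsv"))
  bcs <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(m) != length(feats) || ncol(m) != length(bcs))
    stop("MTX dimensions do not match features/barcodes")
  dimnames(m) <- list(feats, bcs)
  meta <- read.table(file.path(dir, "cell_metadata.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  cell_matrix(m, meta)
}

#' @rdname read_mtx_dir
#' @param cells a `CellMatrix`.
#' @export
write_mtx_dir <- function(cells, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cells$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(cells$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(cells$counts), file.path(dir, "barcodes.tsv"))
  write.table(cells$meta, file.path(dir, "cell_metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read an ortholog map TSV
#'
#' Expected columns: one `<species>_gene` column per species (NA where the
#' family is absent) and a `relation` column (`1:1`, `1:many`, `many:many`,
#' `none`).
#'
#' @param file path.
#' @return data.frame as described.
#' @export
read_ortholog_map <- function(file) {
  map <- read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"relation" %in% names(map)) stop("ortholog map needs a relation column")
  if (sum(grepl("_gene$", names(map))) < 2)
    stop("ortholog map needs at least two <species>_gene columns")
  map
}
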