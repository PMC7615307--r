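#' Construct a time-series simulation design
#'
#' Describes a two-sex developmental RNA-seq experiment: how many genes and
#' stages, the replicate structure, the sequencing-depth target, and the
#' mean-dispersion model for the negative-binomial counts.  The defaults
#' emulate a well-powered rodent organ series: 8 stages spanning
#' organogenesis to adulthood with 2 replicates per sex per stage and sexual
#' maturity declared at an ordinal strictly inside the series.
#'
#' @param n_genes number of genes.
#' @param n_stages number of developmental stages (>= 4).
#' @param stages optional character vector of stage labels (length
#'   `n_stages`); defaults to `"s1" ... "sN"`.
#' @param maturity_stage stage ordinal of sexual maturity; must be strictly
#'   inside `(1, n_stages)`.
#' @param reps_per_sex_stage replicates per sex per stage (1-3).
#' @param library_size_range length-2 positive numeric; expected total counts
#'   per sample are centred on the geometric midpoint of this range, with an
#'   additional per-sample log-uniform factor in `[0.7, 1.3]`.
#' @param dispersion named vector `c(a0=, a1=)` of the mean-dispersion trend
#'   `alpha(mu) = a0/mu + a1` from which gene dispersions are drawn
#'   (log-normal noise, sdlog 0.3).
#' @param base_log_mean,base_log_sd natural-log mean and sd of the gene
#'   baseline expression distribution.
#' @param traj_sd sd of the Gaussian spline coefficients that shape each
#'   gene's stage trajectory (natural-log scale).
#' @param x_fraction,y_fraction fractions of genes labelled X / Y-analog for
#'   chromosome bookkeeping; the rest are autosomal.
#' @param seed integer seed making the simulation deterministic.
#' @return object of class `TimeSeriesDesign`.
#' @export
timeseries_design <- function(n_genes = 2000L, n_stages = 8L, stages = NULL,
                              maturity_stage = ceiling(0.7 * n_stages),
                              reps_per_sex_stage = 2L,
                              library_size_range = c(5e5, 1e6),
                              dispersion = c(a0 = 3, a1 = 0.05),
                              base_log_mean = 4, base_log_sd = 1.5,
                              traj_sd = 0.35,
                              x_fraction = 0.05, y_fraction = 0.01,
                              seed = 1L) {
  stopifnot(n_genes >= 1, n_stages >= 4,
            reps_per_sex_stage >= 1, reps_per_sex_stage <= 3,
            length(library_size_range) == 2, all(library_size_range > 0),
            all(c("a0", "a1") %in% names(dispersion)))
  if (maturity_stage <= 1 || maturity_stage >= n_stages)
    stop("maturity_stage must lie strictly inside the stage range")
  if (is.null(stages)) stages <- paste0("s", seq_len(n_stages))
  stopifnot(length(stages) == n_stages)
  structure(list(n_genes = as.integer(n_genes),
                 n_stages = as.integer(n_stages),
                 stages = as.character(stages),
                 maturity_stage = as.integer(maturity_stage),
                 reps_per_sex_stage = as.integer(reps_per_sex_stage),
                 library_size_range = as.numeric(library_size_range),
                 dispersion = dispersion,
                 base_log_mean = base_log_mean, base_log_sd = base_log_sd,
                 traj_sd = traj_sd,
                 x_fraction = x_fraction, y_fraction = y_fraction,
                 seed = as.integer(seed)),
            class = "TimeSeriesDesign")
}

#' Specify one spiked (truly sex-biased) gene
#'
#' @param gene gene index (1-based) within the design.
#' @param direction `"male"` or `"female"`: which sex has the higher
#'   expression.
#' @param lfc target log2 fold change, >= 0.  Counts of the lower sex are
#'   binomially thinned with success probability `2^-lfc`, so the realized
#'   expected fold change equals `2^lfc` exactly.
#' @param onset_class `"always"`, `"pre_SM"` or `"post_SM"` relative to the
#'   design's sexual-maturity stage.
#' @param onset_stage,offset_stage stage ordinals bounding the effect window
#'   (inclusive).  Defaults: the whole series for `"always"`, everything
#'   before maturity for `"pre_SM"`, maturity onward for `"post_SM"`.
#' @return object of class `SpikeSpec`.
#' @export
spike_spec <- function(gene, direction = c("male", "female"), lfc = 2,
                       onset_class = c("always", "pre_SM", "post_SM"),
                       onset_stage = NA_integer_, offset_stage = NA_integer_) {
  direction <- match.arg(direction)
  onset_class <- match.arg(onset_class)
  if (lfc < 0) stop("lfc must be >= 0")
  structure(list(gene = as.integer(gene), direction = direction,
                 lfc = as.numeric(lfc), onset_class = onset_class,
                 onset_stage = as.integer(onset_stage),
                 offset_stage = as.integer(offset_stage)),
            class = "SpikeSpec")
}

# Fill default effect windows and validate a spike against a design.
resolve_spike <- function(sp, design) {
  m <- design$maturity_stage; S <- design$n_stages
  if (is.na(sp$onset_stage)) {
    sp$onset_stage <- switch(sp$onset_class, always = 1L, pre_SM = 1L,
                             post_SM = m)
  }
  if (is.na(sp$offset_stage)) {
    sp$offset_stage <- switch(sp$onset_class, always = S,
                              pre_SM = m - 1L, post_SM = S)
  }
  if (sp$gene < 1 || sp$gene > design$n_genes)
    stop("spiked gene index out of range")
  if (sp$onset_stage > sp$offset_stage) stop("empty spike window")
  ok <- switch(sp$onset_class,
    always = sp$onset_stage == 1L && sp$offset_stage == S,
    pre_SM = sp$offset_stage < m,
    post_SM = sp$onset_stage >= m)
  if (!ok) stop("spike window inconsistent with onset class ", sp$onset_class)
  sp
}

#' Generate a random set of spikes for a design
#'
#' Convenience generator producing spiked genes of mixed direction, log2
#' fold change and onset class, with default effect windows per class.
#'
#' @param design a [timeseries_design()].
#' @param n_spiked number of spiked genes.
#' @param lfc_values candidate log2 fold changes, recycled across spikes.
#' @param classes candidate onset classes, sampled with `class_weights`.
#' @param class_weights sampling weights for `classes`.
#' @param seed integer seed.
#' @return list of [spike_spec()] objects.
#' @export
random_spikes <- function(design, n_spiked, lfc_values = c(1, 2, 3),
                          classes = c("always", "pre_SM", "post_SM"),
                          class_weights = c(0.4, 0.2, 0.4), seed = 1L) {
  stopifnot(n_spiked <= design$n_genes)
  set.seed(derive_seed(seed, 11L))
  genes <- sample.int(design$n_genes, n_spiked)
  dirs <- sample(c("male", "female"), n_spiked, replace = TRUE)
  lfcs <- rep_len(lfc_values, n_spiked)
  cls <- sample(classes, n_spiked, replace = TRUE, prob = class_weights)
  mapply(function(g, d, l, cl) spike_spec(g, d, l, cl),
         genes, dirs, lfcs, cls, SIMPLIFY = FALSE)
}

#' Simulate a two-sex developmental count series with spiked sex effects
#'
#' Baseline counts are negative-binomial draws around smooth per-gene stage
#' trajectories: each gene's log mean is a cubic B-spline of the stage
#' ordinal (3 interior knots) with zero-mean Gaussian coefficients, shared
#' between the sexes.  Sex effects are injected by binomial thinning: for a
#' gene spiked male-biased with log2 fold change L, every count of the
#' female samples inside the effect window is replaced by a
#' `Binomial(count, 2^-L)` draw (and symmetrically for female bias), so the
#' realized expected fold change is exactly `2^L` and no reads are invented.
#'
#' @param design a [timeseries_design()].
#' @param spikes list of [spike_spec()] objects; may be empty.
#' @return list with components `ts` (an [expression_time_series()]) and
#'   `truth` (a `SimulationTruth`: spike table plus gene chromosome labels).
#' @export
simulate_timeseries <- function(design, spikes = list()) {
  stopifnot(inherits(design, "TimeSeriesDesign"))
  spikes <- lapply(spikes, resolve_spike, design = design)
  sg <- vapply(spikes, function(s) s$gene, integer(1))
  if (anyDuplicated(sg))
    stop("overlapping spike windows on the same gene are not supported")

  G <- design$n_genes; S <- design$n_stages; R <- design$reps_per_sex_stage
  set.seed(derive_seed(design$seed, 1L))

  # sample sheet: stages x sexes x replicates
  samples <- expand.grid(replicate = seq_len(R), sex = c("F", "M"),
                         stage_ordinal = seq_len(S),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples$stage <- design$stages[samples$stage_ordinal]
  samples$species <- "simulated"
  samples$organ <- "simulated"
  samples$sample <- sprintf("%s_%s_r%d", samples$stage, samples$sex,
                            samples$replicate)
  samples <- samples[, c("sample", "species", "organ", "stage",
                         "stage_ordinal", "sex", "replicate")]
  N <- nrow(samples)

  # per-gene smooth log-mean trajectories (natural log)
  B <- splines::bs(seq_len(S), degree = 3,
                   knots = quantile(seq_len(S), c(0.25, 0.5, 0.75)),
                   Boundary.knots = c(1, S))
  coefs <- matrix(rnorm(G * ncol(B), sd = design$traj_sd), G, ncol(B))
  traj <- coefs %*% t(B)                       # G x S
  traj <- traj - rowMeans(traj)
  base <- rlnorm(G, meanlog = design$base_log_mean, sdlog = design$base_log_sd)
  mu_stage <- base * exp(traj)                 # G x S expected counts, unit depth

  # depth scaling: expected totals centred on the geometric midpoint of the
  # library size range, times a per-sample log-uniform factor in [0.7, 1.3]
  target <- exp(mean(log(design$library_size_range)))
  global <- target / mean(colSums(mu_stage))
  samp_factor <- exp(runif(N, log(0.7), log(1.3)))

  mean_per_gene <- rowMeans(mu_stage) * global
  a0 <- design$dispersion[["a0"]]; a1 <- design$dispersion[["a1"]]
  alpha <- (a0 / pmax(mean_per_gene, 1e-8) + a1) *
    rlnorm(G, meanlog = 0, sdlog = 0.3)

  MU <- mu_stage[, samples$stage_ordinal, drop = FALSE] * global
  MU <- sweep(MU, 2, samp_factor, `*`)
  counts <- matrix(rnbinom(G * N, mu = MU, size = rep(1 / alpha, N)), G, N)
  dimnames(counts) <- list(sprintf("g%05d", seq_len(G)), samples$sample)

  # chromosome bookkeeping
  chrom <- sample(c("A", "X", "Y"), G, replace = TRUE,
                  prob = c(1 - design$x_fraction - design$y_fraction,
                           design$x_fraction, design$y_fraction))
  names(chrom) <- rownames(counts)

  # binomial thinning of the lower sex inside each spike window
  for (sp in spikes) {
    lower_sex <- if (sp$direction == "male") "F" else "M"
    idx <- which(samples$sex == lower_sex &
                 samples$stage_ordinal >= sp$onset_stage &
                 samples$stage_ordinal <= sp$offset_stage)
    y <- counts[sp$gene, idx]
    counts[sp$gene, idx] <- rbinom(length(y), y, 2^(-sp$lfc))
  }

  truth <- simulation_truth(spikes, chrom, gene_ids = rownames(counts))
  list(ts = expression_time_series(counts, samples), truth = truth)
}

#' Bundle spike specifications and chromosome labels into a truth object
#'
#' @param spikes list of resolved [spike_spec()] objects.
#' @param chromosomes named character vector gene -> chromosome label.
#' @param gene_ids character vector of gene identifiers (index order).
#' @return object of class `SimulationTruth` with a `spikes` data.frame
#'   (gene, direction, lfc, onset_class, onset_stage, offset_stage) and the
#'   chromosome map.
#' @export
simulation_truth <- function(spikes, chromosomes, gene_ids) {
  sp <- if (length(spikes)) {
    data.frame(
      gene = gene_ids[vapply(spikes, function(s) s$gene, integer(1))],
      direction = vapply(spikes, function(s) s$direction, character(1)),
      lfc = vapply(spikes, function(s) s$lfc, numeric(1)),
      onset_class = vapply(spikes, function(s) s$onset_class, character(1)),
      onset_stage = vapply(spikes, function(s) s$onset_stage, integer(1)),
      offset_stage = vapply(spikes, function(s) s$offset_stage, integer(1)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(), direction = character(), lfc = numeric(),
               onset_class = character(), onset_stage = integer(),
               offset_stage = integer(), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(sp$gene)) stop("spiked gene ids must be unique")
  structure(list(schema_version = "1.0", spikes = sp,
                 chromosomes = chromosomes),
            class = "SimulationTruth")
}

#' Construct a single-cell simulation specification
#'
#' Describes a cells-by-genes experiment with several cell types, one of
#' which is sexually dimorphic: inside that type only, genes of the male
#' bias set are shifted up `2^lfc`-fold in male cells and genes of the
#' female set in female cells.  All other genes and cell types are
#' sex-exchangeable by construction.  By default the bias-set genes are
#' expressed in a cell-type-restricted way (high in the dimorphic type, low
#' elsewhere), mirroring dimorphic expression confined to one cell type.
#'
#' @param n_genes number of genes.
#' @param cell_types character vector of cell type labels.
#' @param dimorphic_type which cell type carries the sex effect.
#' @param n_cells_per_type_sex cells per (type x sex); scalar or named by type.
#' @param n_bias number of genes in each of the male and female bias sets
#'   (sets are disjoint).
#' @param lfc within-type log2 fold change of bias-set genes in the
#'   corresponding sex.
#' @param restricted_sets logical; if `TRUE` bias-set genes are lowly
#'   expressed outside the dimorphic type (restriction factor 0.05).
#' @param female_set_broad logical; if `TRUE` the female set stays broadly
#'   expressed across types even when `restricted_sets = TRUE` (the kidney
#'   pattern: male set cell-type specific, female set broad).
#' @param base_log_mean,base_log_sd log-normal parameters of per-gene mean
#'   counts per cell.
#' @param phi negative-binomial dispersion per gene (counts per cell).
#' @param seed integer seed.
#' @return object of class `CellSimSpec`.
#' @export
cell_sim_spec <- function(n_genes = 1500L,
                          cell_types = c("proximal_tubule", "distal_tubule",
                                         "endothelial", "immune"),
                          dimorphic_type = "proximal_tubule",
                          n_cells_per_type_sex = 200L,
                          n_bias = 40L, lfc = 2,
                          restricted_sets = TRUE, female_set_broad = FALSE,
                          base_log_mean = log(0.3), base_log_sd = 1.1,
                          phi = 0.5, seed = 1L) {
  stopifnot(length(cell_types) >= 2, dimorphic_type %in% cell_types,
            n_bias * 2 <= n_genes, lfc >= 0)
  if (any(n_cells_per_type_sex < 1)) stop("empty cell type")
  structure(list(n_genes = as.integer(n_genes),
                 cell_types = as.character(cell_types),
                 dimorphic_type = dimorphic_type,
                 n_cells_per_type_sex = n_cells_per_type_sex,
                 n_bias = as.integer(n_bias), lfc = as.numeric(lfc),
                 restricted_sets = restricted_sets,
                 female_set_broad = female_set_broad,
                 base_log_mean = base_log_mean, base_log_sd = base_log_sd,
                 phi = phi, seed = as.integer(seed)),
            class = "CellSimSpec")
}

#' Simulate a single-cell count matrix with one dimorphic cell type
#'
#' @param spec a [cell_sim_spec()].
#' @return list with `cells` (a [cell_matrix()]) and `truth` (bias gene
#'   sets, the dimorphic type, and the spec parameters).
#' @export
simulate_cells <- function(spec) {
  stopifnot(inherits(spec, "CellSimSpec"))
  set.seed(derive_seed(spec$seed, 2L))
  G <- spec$n_genes
  types <- spec$cell_types
  ncl <- spec$n_cells_per_type_sex
  if (length(ncl) == 1) ncl <- setNames(rep(ncl, length(types)), types)

  gene_ids <- sprintf("g%05d", seq_len(G))
  male_set <- gene_ids[seq_len(spec$n_bias)]
  female_set <- gene_ids[spec$n_bias + seq_len(spec$n_bias)]

  base <- rlnorm(G, spec$base_log_mean, spec$base_log_sd)
  # per-type mean matrix; bias sets optionally restricted to dimorphic type
  mu_type <- matrix(base, G, length(types),
                    dimnames = list(gene_ids, types))
  if (spec$restricted_sets) {
    other <- setdiff(types, spec$dimorphic_type)
    mu_type[male_set, other] <- mu_type[male_set, other] * 0.05
    if (!spec$female_set_broad)
      mu_type[female_set, other] <- mu_type[female_set, other] * 0.05
  }

  meta <- do.call(rbind, lapply(types, function(ct)
    expand.grid(type = ct, sex = c("F", "M"), idx = seq_len(ncl[[ct]]),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  meta$cell <- sprintf("c%05d", seq_len(nrow(meta)))
  n_cells <- nrow(meta)

  cell_factor <- rlnorm(n_cells, 0, 0.3)
  blocks <- vector("list", n_cells)
  for (j in seq_len(n_cells)) {
    mu <- mu_type[, meta$type[j]] * cell_factor[j]
    if (meta$type[j] == spec$dimorphic_type) {
      if (meta$sex[j] == "M") mu[male_set] <- mu[male_set] * 2^spec$lfc
      else mu[female_set] <- mu[female_set] * 2^spec$lfc
    }
    blocks[[j]] <- rnbinom(G, mu = mu, size = 1 / spec$phi)
  }
  counts <- Matrix::Matrix(do.call(cbind, blocks), sparse = TRUE)
  dimnames(counts) <- list(gene_ids, meta$cell)

  cells <- cell_matrix(counts, meta[, c("cell", "type", "sex")])
  truth <- list(male_set = male_set, female_set = female_set,
                dimorphic_type = spec$dimorphic_type, lfc = spec$lfc)
  list(cells = cells, truth = truth)
}

#' Simulate a multi-species ortholog map with tunable conservation
#'
#' Builds gene families across `n_species` species: most are strict 1:1
#' orthologs, a fraction are lineage-specific (present in a single species,
#' no ortholog) and a fraction are duplicated (1:many).  Sex-bias truth sets
#' are drawn per species; a `conserved_fraction` of each set is shared
#' across all species (through 1:1 families), the remainder is
#' species-independent.
#'
#' @param n_species number of species (>= 2).
#' @param n_families number of gene families.
#' @param conserved_fraction fraction of each species' bias set shared
#'   across all species, in `[0, 1]`.
#' @param n_bias bias-set size per species.
#' @param lineage_specific_fraction,duplicated_fraction fractions of
#'   families that are lineage-specific / 1:many.
#' @param seed integer seed.
#' @return list with `map` (data.frame: one gene column per species, `NA`
#'   where absent, plus `relation`), `bias_sets` (list per species of biased
#'   gene ids) and `universes` (per species, genes present in 1:1 families).
#' @export
simulate_orthologs <- function(n_species = 2L, n_families = 5000L,
                               conserved_fraction = 0.5, n_bias = 100L,
                               lineage_specific_fraction = 0.1,
                               duplicated_fraction = 0.05, seed = 1L) {
  stopifnot(n_species >= 2, conserved_fraction >= 0, conserved_fraction <= 1,
            n_bias <= n_families)
  set.seed(derive_seed(seed, 3L))
  sp_names <- paste0("sp", seq_len(n_species))
  rel <- sample(c("1:1", "none", "1:many"), n_families, replace = TRUE,
                prob = c(1 - lineage_specific_fraction - duplicated_fraction,
                         lineage_specific_fraction, duplicated_fraction))
  owner <- sample.int(n_species, n_families, replace = TRUE)  # for "none"
  map <- data.frame(matrix(NA_character_, n_families, n_species,
                           dimnames = list(NULL, paste0(sp_names, "_gene"))),
                    stringsAsFactors = FALSE)
  for (s in seq_len(n_species)) {
    ids <- sprintf("%s_g%05d", sp_names[s], seq_len(n_families))
    present <- rel != "none" | owner == s
    map[[s]][present] <- ids[present]
  }
  map$relation <- rel

  one2one <- which(rel == "1:1")
  n_cons <- round(conserved_fraction * n_bias)
  cons_fam <- sample(one2one, n_cons)
  bias_sets <- vector("list", n_species); names(bias_sets) <- sp_names
  for (s in seq_len(n_species)) {
    pool <- setdiff(which(!is.na(map[[s]])), cons_fam)
    own <- sample(pool, n_bias - n_cons)
    bias_sets[[s]] <- map[[s]][sort(c(cons_fam, own))]
  }
  universes <- lapply(seq_len(n_species), function(s) map[[s]][one2one])
  names(universes) <- sp_names
  list(map = map, bias_sets = bias_sets, universes = universes)
}

#' Generate a gene annotation table of TSS positions
#'
#' Genes are laid out on `n_chrom` chromosomes with spacing wide enough that
#' promoter windows of neighbouring genes never touch, which makes decoy
#' placement in [simulate_regions()] well defined.
#'
#' @param n_genes number of genes.
#' @param n_chrom number of chromosomes.
#' @param spacing_bp distance between consecutive TSS (0-based positions).
#' @param seed integer seed (strands are random).
#' @return data.frame with columns `gene`, `chrom`, `strand`, `tss`
#'   (0-based position).
#' @export
make_gene_annotation <- function(n_genes = 200L, n_chrom = 3L,
                                 spacing_bp = 20000L, seed = 1L) {
  set.seed(derive_seed(seed, 4L))
  chrom <- rep(paste0("chr", seq_len(n_chrom)), length.out = n_genes)
  pos_in_chrom <- unlist(lapply(split(seq_len(n_genes), chrom),
                                seq_along), use.names = FALSE)
  ord <- order(chrom, pos_in_chrom)
  data.frame(gene = sprintf("g%05d", seq_len(n_genes)),
             chrom = sort(chrom),
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             tss = as.integer(unlist(lapply(table(chrom), seq_len)) *
                              spacing_bp),
             stringsAsFactors = FALSE)
}

#' Simulate a regulatory region set with known targets and decoys
#'
#' Places one region inside the TSS assignment window `[tss - window_bp,
#' tss + window_bp)` of every designated target gene, and `n_decoys` regions
#' outside every gene's window, so that [assign_targets()] must recover
#' exactly the designated set.
#'
#' @param annotation a [make_gene_annotation()] table.
#' @param target_genes character vector of target gene ids.
#' @param n_decoys number of decoy regions.
#' @param window_bp assignment half-window in bp.
#' @param region_len region length in bp.
#' @param seed integer seed.
#' @return list with `regions` (data.frame `chrom`, `start`, `end`, 0-based
#'   half-open, sorted) and `truth` (`targets`, `window_bp`).
#' @export
simulate_regions <- function(annotation, target_genes, n_decoys = 50L,
                             window_bp = 3000L, region_len = 200L, seed = 1L) {
  stopifnot(all(target_genes %in% annotation$gene), window_bp > 0)
  set.seed(derive_seed(seed, 5L))
  spacing <- min(diff(sort(annotation$tss[annotation$chrom ==
                                          annotation$chrom[1]])))
  if (2 * window_bp + region_len >= spacing)
    stop("window larger than the inter-gene spacing of the annotation")
  rows <- annotation[match(target_genes, annotation$gene), ]
  # region start uniform in [tss - window, tss + window - 1] guarantees overlap
  start <- rows$tss + sample(seq(-window_bp, window_bp - 1L),
                             nrow(rows), replace = TRUE)
  start <- pmax(start, 0L)
  target_regions <- data.frame(chrom = rows$chrom, start = start,
                               end = start + region_len)
  # decoys: midway between consecutive windows, beyond every window
  decoy <- NULL
  if (n_decoys > 0) {
    rows2 <- annotation[sample.int(nrow(annotation), n_decoys, replace = TRUE), ]
    dstart <- rows2$tss + window_bp + region_len +
      sample(seq_len(max(1L, spacing - 2L * window_bp - 3L * region_len)),
             n_decoys, replace = TRUE)
    decoy <- data.frame(chrom = rows2$chrom, start = dstart,
                        end = dstart + region_len)
  }
  regions <- rbind(target_regions, decoy)
  regions <- regions[order(regions$chrom, regions$start), ]
  rownames(regions) <- NULL
  list(regions = regions,
       truth = list(targets = sort(unique(target_genes)),
                    window_bp = window_bp))
}
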