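# Synthetic scRNA-seq generator with planted aging and senescence effects.
#
# The generator emulates the structure the downstream analysis assumes:
# multiple donors in two age groups spread over batches, several cell types
# with very unequal abundances, negative-binomial counts with per-gene
# dispersion, per-cell log-normal size factors, gene-by-batch mean shifts,
# age effects planted per cell type with controlled cross-cell-type sharing,
# and a senescence gene set up-shifted in aged cells of selected cell types.

#' Default donor design: 12 samples, 6 young / 6 aged, two batches
#'
#' @return A data.frame with columns `sample`, `age_group`, `batch`.
#' @export
default_samples <- function() {
  data.frame(
    sample = sprintf("S%02d", 1:12),
    age_group = rep(c("YOUNG", "AGED"), each = 6),
    batch = rep(c("B1", "B2"), 6),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic single-cell dataset generator
#'
#' Defaults describe the bundled desk-scale fixture: 3,000 genes, 12 donors
#' (6 young, 6 aged) in two batches, five cell types with 40:25:15:12:8
#' relative abundance (roughly 690 cells per donor, so even the rarest type
#' comfortably clears the 500-cell cluster rule), 60 up- and 30
#' down-planted aging genes at |log2FC| 1 with roughly half of planted genes
#' shared by two or more cell types, and a 20-gene senescence set up-shifted
#' in aged immune/progenitor cell types.
#'
#' @param n_genes Number of genes.
#' @param cell_types Named numeric vector: mean cells per sample per cell type.
#' @param samples Data.frame with `sample`, `age_group` (YOUNG/AGED), `batch`.
#' @param baseline_logmean_range Range (natural-log scale) of per-gene baseline
#'   mean expression per cell; baselines are drawn uniformly on this interval.
#' @param dispersion_shape Shape of the gamma law for per-gene NB dispersion
#'   alpha (Var = mu + alpha mu^2); scale is set so E\[alpha\] = 0.5.
#' @param libsize_sigma Log-normal sd of per-cell size factors.
#' @param batch_logfc_sigma Sd (log2 scale) of gene-by-batch mean shifts.
#' @param n_up_planted,n_down_planted Numbers of planted aging DEGs.
#' @param planted_log2fc Planted |log2 fold change| (aged vs young).
#' @param sharing_profile Probability vector over "number of cell types a
#'   planted gene affects" (index k = probability of affecting k cell types).
#' @param min_planted_logmean Planted and senescence genes are drawn only from
#'   genes whose baseline log-mean exceeds this, so planted truth lies in the
#'   expressed stratum and stays identifiable at desk scale.
#' @param senescence_set_size Number of senescence genes.
#' @param senescence_log2fc Log2 shift of senescence genes in aged cells of
#'   target cell types.
#' @param senescence_target_celltypes Cell types receiving the senescence shift.
#' @param mito_fraction_beta Beta(a, b) parameters for per-cell mitochondrial
#'   fraction (independent of counts; exercises the QC filter).
#' @param seed Integer seed; the generator is deterministic given the config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 3000,
                         cell_types = c(FABP4_Macro = 275, AT2 = 172,
                                        Monocyte = 103, NK = 82, Fibroblast = 55),
                         samples = default_samples(),
                         baseline_logmean_range = c(-4, 1),
                         dispersion_shape = 2,
                         libsize_sigma = 0.3,
                         batch_logfc_sigma = 0.2,
                         n_up_planted = 60,
                         n_down_planted = 30,
                         planted_log2fc = 1,
                         sharing_profile = c(0.5, 0.2, 0.15, 0.1, 0.05),
                         min_planted_logmean = -2,
                         senescence_set_size = 20,
                         senescence_log2fc = 1,
                         senescence_target_celltypes = c("FABP4_Macro", "Monocyte", "AT2"),
                         mito_fraction_beta = c(2, 18),
                         seed = 1L) {
  cfg <- list(
    n_genes = n_genes, cell_types = cell_types, samples = samples,
    baseline_logmean_range = baseline_logmean_range,
    dispersion_shape = dispersion_shape, libsize_sigma = libsize_sigma,
    batch_logfc_sigma = batch_logfc_sigma,
    n_up_planted = n_up_planted, n_down_planted = n_down_planted,
    planted_log2fc = planted_log2fc, sharing_profile = sharing_profile,
    min_planted_logmean = min_planted_logmean,
    senescence_set_size = senescence_set_size,
    senescence_log2fc = senescence_log2fc,
    senescence_target_celltypes = senescence_target_celltypes,
    mito_fraction_beta = mito_fraction_beta, seed = seed
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  if (!is.numeric(cfg$n_genes) || cfg$n_genes < 1)
    abort_field("n_genes", "must be a positive integer")
  if (is.null(names(cfg$cell_types)) || any(cfg$cell_types <= 0))
    abort_field("cell_types", "must be a named vector of positive mean cell counts")
  s <- cfg$samples
  if (!is.data.frame(s) || !all(c("sample", "age_group", "batch") %in% names(s)))
    abort_field("samples", "needs columns sample, age_group, batch")
  if (anyDuplicated(s$sample)) abort_field("samples", "duplicate sample IDs")
  if (!all(s$age_group %in% c("YOUNG", "AGED")))
    abort_field("samples", "age_group must be YOUNG or AGED")
  if (length(unique(s$age_group)) < 2)
    abort_field("samples", "need at least one sample per age group")
  for (f in c("n_up_planted", "n_down_planted", "senescence_set_size"))
    if (cfg[[f]] < 0) abort_field(f, "must be >= 0")
  if (cfg$n_up_planted + cfg$n_down_planted + cfg$senescence_set_size > cfg$n_genes)
    abort_field("n_genes", "fewer genes than planted + senescence genes")
  if (cfg$planted_log2fc <= 0) abort_field("planted_log2fc", "must be > 0")
  if (cfg$senescence_log2fc < 0) abort_field("senescence_log2fc", "must be >= 0")
  if (length(cfg$sharing_profile) > length(cfg$cell_types) ||
      any(cfg$sharing_profile < 0) || sum(cfg$sharing_profile) <= 0)
    abort_field("sharing_profile", "must be nonnegative with support in 1..n_cell_types")
  if (!all(cfg$senescence_target_celltypes %in% names(cfg$cell_types)))
    abort_field("senescence_target_celltypes", "unknown cell type")
  if (cfg$libsize_sigma < 0) abort_field("libsize_sigma", "must be >= 0")
  if (cfg$batch_logfc_sigma < 0) abort_field("batch_logfc_sigma", "must be >= 0")
  if (cfg$dispersion_shape <= 0) abort_field("dispersion_shape", "must be > 0")
  if (length(cfg$mito_fraction_beta) != 2 || any(cfg$mito_fraction_beta <= 0))
    abort_field("mito_fraction_beta", "must be two positive reals")
  if (diff(cfg$baseline_logmean_range) < 0)
    abort_field("baseline_logmean_range", "must be an increasing pair")
  cfg
}

#' Generate a synthetic labeled scRNA-seq dataset with planted ground truth
#'
#' Counts for gene g in cell c are negative-binomial with mean
#' `sizefactor(c) * basemean(g) * 2^batchshift(g, batch) * 2^effect(g, celltype, age)`
#' and per-gene dispersion; `effect` is +/- `planted_log2fc` for planted aging
#' genes in aged cells of their assigned cell types, plus `senescence_log2fc`
#' for senescence genes in aged cells of target cell types. Cell counts per
#' (sample, cell type) are Poisson around the configured mean. Deterministic
#' given the config (including its seed).
#'
#' @param config A [synth_config()].
#' @return A list with `counts` (sparse genes x cells dgCMatrix), `meta`
#'   (per-cell data.frame: cell, sample, cell_type, age_group, batch,
#'   n_features, mito_fraction) and `truth` (planted_up / planted_down maps
#'   gene -> affected cell types, senescence_genes, base_mean, dispersion,
#'   batch_shift, seed).
#' @export
#' @examples
#' d <- generate_dataset(synth_config(n_genes = 200,
#'   cell_types = c(A = 30, B = 20), n_up_planted = 5, n_down_planted = 3,
#'   sharing_profile = c(0.5, 0.5), senescence_set_size = 4,
#'   senescence_target_celltypes = "A"))
#' dim(d$counts)
generate_dataset <- function(config) {
  cfg <- validate_synth_config(config)
  set.seed(stage_seed(cfg$seed, "simulate"))
  n_genes <- cfg$n_genes
  ct_names <- names(cfg$cell_types)
  genes <- sprintf("G%05d", seq_len(n_genes))

  base_logmean <- stats::runif(n_genes, cfg$baseline_logmean_range[1],
                               cfg$baseline_logmean_range[2])
  alpha <- stats::rgamma(n_genes, shape = cfg$dispersion_shape,
                         scale = 0.5 / cfg$dispersion_shape)
  batches <- unique(cfg$samples$batch)
  batch_shift <- matrix(stats::rnorm(n_genes * length(batches), 0, cfg$batch_logfc_sigma),
                        n_genes, length(batches), dimnames = list(genes, batches))

  # planted truth: disjoint up / down / senescence genes from the expressed stratum
  eligible <- which(base_logmean >= cfg$min_planted_logmean)
  n_need <- cfg$n_up_planted + cfg$n_down_planted + cfg$senescence_set_size
  if (length(eligible) < n_need)
    abort_field("min_planted_logmean", "too few expressed genes to plant effects in")
  picks <- if (n_need > 0) sample(eligible, n_need) else integer(0)
  up_idx <- utils::head(picks, cfg$n_up_planted)
  down_idx <- picks[seq_len(cfg$n_down_planted) + cfg$n_up_planted]
  sen_idx <- utils::tail(picks, cfg$senescence_set_size)

  assign_celltypes <- function(idx) {
    out <- stats::setNames(vector("list", length(idx)), genes[idx])
    for (i in seq_along(idx)) {
      k <- sample.int(length(cfg$sharing_profile), 1, prob = cfg$sharing_profile)
      out[[i]] <- sort(sample(ct_names, k))
    }
    out
  }
  planted_up <- assign_celltypes(up_idx)
  planted_down <- assign_celltypes(down_idx)

  # log2 effect of age per gene x cell type
  effect <- matrix(0, n_genes, length(ct_names), dimnames = list(genes, ct_names))
  for (g in names(planted_up)) effect[g, planted_up[[g]]] <- cfg$planted_log2fc
  for (g in names(planted_down)) effect[g, planted_down[[g]]] <- -cfg$planted_log2fc
  if (length(sen_idx) > 0 && length(cfg$senescence_target_celltypes) > 0)
    effect[genes[sen_idx], cfg$senescence_target_celltypes] <-
      effect[genes[sen_idx], cfg$senescence_target_celltypes] + cfg$senescence_log2fc

  base_mean <- exp(base_logmean)
  ii <- jj <- xx <- vector("list", nrow(cfg$samples) * length(ct_names))
  cell_ids <- character(0)
  meta_rows <- vector("list", length(ii))
  blk <- 0L
  col_off <- 0L
  for (s in seq_len(nrow(cfg$samples))) {
    samp <- cfg$samples$sample[s]
    aged <- cfg$samples$age_group[s] == "AGED"
    bshift <- batch_shift[, cfg$samples$batch[s]]
    for (ct in ct_names) {
      blk <- blk + 1L
      nc <- stats::rpois(1, cfg$cell_types[[ct]])
      if (nc == 0) next
      ids <- sprintf("%s_%s_%03d", samp, ct, seq_len(nc))
      mu_g <- base_mean * 2^bshift
      if (aged) mu_g <- mu_g * 2^effect[, ct]
      sf <- stats::rlnorm(nc, 0, cfg$libsize_sigma)
      mu <- outer(mu_g, sf)
      y <- stats::rnbinom(length(mu), size = rep(1 / alpha, nc), mu = as.vector(mu))
      nz <- which(y > 0)
      ii[[blk]] <- ((nz - 1L) %% n_genes) + 1L
      jj[[blk]] <- ((nz - 1L) %/% n_genes) + 1L + col_off
      xx[[blk]] <- y[nz]
      meta_rows[[blk]] <- data.frame(
        cell = ids, sample = samp, cell_type = ct,
        age_group = cfg$samples$age_group[s], batch = cfg$samples$batch[s],
        stringsAsFactors = FALSE
      )
      cell_ids <- c(cell_ids, ids)
      col_off <- col_off + nc
    }
  }
  counts <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(n_genes, col_off), dimnames = list(genes, cell_ids)
  )
  meta <- do.call(rbind, meta_rows[!vapply(meta_rows, is.null, logical(1))])
  rownames(meta) <- NULL
  meta$n_features <- Matrix::colSums(counts > 0)
  meta$mito_fraction <- stats::rbeta(nrow(meta), cfg$mito_fraction_beta[1],
                                     cfg$mito_fraction_beta[2])

  truth <- list(
    planted_up = planted_up, planted_down = planted_down,
    senescence_genes = genes[sen_idx],
    base_mean = stats::setNames(base_mean, genes),
    dispersion = stats::setNames(alpha, genes),
    batch_shift = batch_shift, seed = cfg$seed
  )
  list(counts = counts, meta = meta, truth = truth)
}

#' Summarize a labeled count matrix
#'
#' Sanity panel over a dataset: per cell type the number of cells and the
#' median detected features and library size; per gene the mean and variance
#' of counts across cells.
#'
#' @param counts Genes x cells count matrix (sparse or dense).
#' @param meta Per-cell metadata matching `counts` columns.
#' @return A list with data.frames `cell_types` and `genes`.
#' @export
empirical_summary <- function(counts, meta) {
  meta <- align_meta(counts, meta)
  lib <- Matrix::colSums(counts)
  nfeat <- Matrix::colSums(counts > 0)
  ct <- split(seq_len(ncol(counts)), meta$cell_type)
  cell_types <- data.frame(
    cell_type = names(ct),
    n_cells = vapply(ct, length, integer(1)),
    median_features = vapply(ct, function(i) stats::median(nfeat[i]), numeric(1)),
    median_libsize = vapply(ct, function(i) stats::median(lib[i]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  m <- Matrix::rowMeans(counts)
  v <- Matrix::rowMeans(counts^2) - m^2
  v <- v * ncol(counts) / max(1L, ncol(counts) - 1L)
  genes <- data.frame(gene = rownames(counts), mean = as.numeric(m),
                      variance = as.numeric(v), stringsAsFactors = FALSE)
  list(cell_types = cell_types, genes = genes)
}
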