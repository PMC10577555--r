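# Pseudobulk aggregation: sum single-cell counts to sample x cell-type level
# so donors, not cells, are the units of replication in differential testing.

#' Aggregate single-cell counts to per-sample pseudobulk, per cell type
#'
#' Cells from the MIDDLE age group are excluded before aggregation; the
#' young-vs-aged contrast is the only one tested downstream. Aggregation is
#' a plain sum over the cells of each (sample, cell type) stratum and is
#' invariant to cell order.
#'
#' @param counts Genes x cells count matrix.
#' @param meta Per-cell metadata with `sample`, `cell_type`, `age_group`,
#'   `batch`.
#' @return A named list of `pseudobulk` objects, one per cell type, each with
#'   `cell_type`, `counts` (dense genes x samples), and `samples`
#'   (data.frame: sample, age_group, batch, n_cells).
#' @export
aggregate_pseudobulk <- function(counts, meta) {
  meta <- align_meta(counts, meta)
  if (!all(meta$age_group %in% AGE_LEVELS))
    stop("unknown age_group token in metadata", call. = FALSE)
  use <- meta$age_group %in% c("YOUNG", "AGED")
  counts <- counts[, use, drop = FALSE]
  meta <- meta[use, , drop = FALSE]
  out <- list()
  for (ct in sort(unique(meta$cell_type))) {
    sel <- which(meta$cell_type == ct)
    f <- factor(meta$sample[sel])
    ind <- Matrix::fac2sparse(f)                       # samples x cells
    pb <- as.matrix(counts[, sel, drop = FALSE] %*% Matrix::t(ind))
    samp <- data.frame(
      sample = levels(f),
      age_group = meta$age_group[sel][match(levels(f), meta$sample[sel])],
      batch = meta$batch[sel][match(levels(f), meta$sample[sel])],
      n_cells = as.integer(table(f)),
      stringsAsFactors = FALSE
    )
    out[[ct]] <- structure(
      list(cell_type = ct, counts = pb, samples = samp),
      class = "pseudobulk"
    )
  }
  out
}

#' Drop cell types too small or unbalanced to test
#'
#' Keeps cell types with at least `min_cells_per_cluster` total cells (the
#' analysis excludes clusters with fewer than 500 cells to ensure statistical
#' power) and at least `min_samples_per_group` samples in each age group.
#'
#' @param pbs List of pseudobulk objects from [aggregate_pseudobulk()].
#' @param cfg A [deg_config()].
#' @return The retained sublist; errors if nothing survives.
#' @export
exclude_small_clusters <- function(pbs, cfg = deg_config()) {
  keep <- vapply(pbs, function(pb) {
    tab <- table(pb$samples$age_group)
    sum(pb$samples$n_cells) >= cfg$min_cells_per_cluster &&
      all(c("YOUNG", "AGED") %in% names(tab)) &&
      all(tab[c("YOUNG", "AGED")] >= cfg$min_samples_per_group)
  }, logical(1))
  if (!any(keep))
    stop("all cell types excluded by the cluster-size/balance rule", call. = FALSE)
  pbs[keep]
}

#' Median-of-ratios size factors for a pseudobulk matrix
#'
#' DESeq-style: per-sample median of count ratios to the gene-wise geometric
#' mean, over genes with all-positive counts. When fewer than `min_ref_genes`
#' genes have a finite geometric mean the estimator is degenerate and the
#' documented fallback is used: total counts, rescaled to geometric mean 1.
#'
#' @param mat Genes x samples count matrix.
#' @param min_ref_genes Minimum usable reference genes (default 10).
#' @return Positive size factors with geometric mean 1; attribute `method`
#'   records `"median-of-ratios"` or `"total-count"`.
#' @export
compute_size_factors <- function(mat, min_ref_genes = 10) {
  lg <- rowMeans(log(mat))
  use <- is.finite(lg)
  sf <- NULL
  if (sum(use) >= min_ref_genes) {
    # median taken on the log scale (the DESeq convention)
    sf <- apply(mat[use, , drop = FALSE], 2,
                function(col) exp(stats::median(log(col) - lg[use])))
    if (any(!is.finite(sf)) || any(sf <= 0)) sf <- NULL
  }
  method <- "median-of-ratios"
  if (is.null(sf)) {
    sf <- colSums(mat)
    if (any(sf <= 0)) stop("sample with zero total count", call. = FALSE)
    method <- "total-count"
  }
  sf <- sf / exp(mean(log(sf)))
  attr(sf, "method") <- method
  sf
}
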