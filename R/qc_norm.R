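# Cell-level QC filters and log-normalization.

#' QC filter configuration
#'
#' Cells are kept when the number of detected gene features is strictly
#' greater than `min_features` and the mitochondrial fraction is strictly
#' below `max_mito_fraction` (both inequalities strict by design).
#'
#' @param min_features Minimum detected features, exclusive (default 200).
#' @param max_mito_fraction Maximum mitochondrial fraction, exclusive
#'   (default 0.35).
#' @param lognorm_scale Scale factor for log-normalization (default 1e4,
#'   i.e. log-CP10K).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_features = 200, max_mito_fraction = 0.35,
                      lognorm_scale = 1e4) {
  if (min_features < 0) abort_field("min_features", "must be >= 0")
  if (max_mito_fraction <= 0 || max_mito_fraction > 1)
    abort_field("max_mito_fraction", "must be in (0, 1]")
  if (lognorm_scale <= 0) abort_field("lognorm_scale", "must be > 0")
  structure(list(min_features = min_features,
                 max_mito_fraction = max_mito_fraction,
                 lognorm_scale = lognorm_scale), class = "qc_config")
}

#' Filter cells on detected features and mitochondrial fraction
#'
#' @param counts Genes x cells count matrix.
#' @param meta Per-cell metadata with `n_features` and `mito_fraction`.
#' @param cfg A [qc_config()].
#' @return List with filtered `counts`, `meta`, and a `report` giving the
#'   number of cells removed per criterion. The gene set is unchanged, and
#'   the operation is idempotent.
#' @export
filter_cells <- function(counts, meta, cfg = qc_config()) {
  meta <- align_meta(counts, meta)
  low_feat <- !(meta$n_features > cfg$min_features)
  high_mito <- !(meta$mito_fraction < cfg$max_mito_fraction)
  keep <- !low_feat & !high_mito
  if (!any(keep)) stop("no cells survive QC", call. = FALSE)
  report <- list(
    n_input = nrow(meta), n_kept = sum(keep),
    n_low_features = sum(low_feat), n_high_mito = sum(high_mito),
    min_features = cfg$min_features, max_mito_fraction = cfg$max_mito_fraction
  )
  list(counts = counts[, keep, drop = FALSE],
       meta = meta[keep, , drop = FALSE], report = report)
}

#' Log-normalize counts to log-CP10K
#'
#' Per-cell transformation `ln(1 + count / cell_total * scale)`. A column
#' operation only: invariant to rescaling a cell's counts and monotone in a
#' gene's within-cell count share; zeros map to zero.
#'
#' @param counts Genes x cells count matrix (sparse or dense).
#' @param scale Scale factor (default 1e4).
#' @return Matrix of the same shape and class family (sparse stays sparse),
#'   with attribute `lognorm_scale`.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[which(totals <= 0)[1]]
    stop(sprintf("cell '%s' has zero total count; cannot normalize", bad),
         call. = FALSE)
  }
  if (inherits(counts, "sparseMatrix")) {
    out <- methods::as(counts, "CsparseMatrix")
    out@x <- log1p(out@x * scale / rep.int(totals, diff(out@p)))
  } else {
    out <- log1p(sweep(counts, 2, totals, "/") * scale)
  }
  attr(out, "lognorm_scale") <- scale
  out
}
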