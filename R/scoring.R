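# Control-gene-subtracted module scores: per-cell mean expression of a gene
# set minus the mean expression of randomly drawn, expression-bin-matched
# control genes, so random sets center at zero regardless of depth.

#' Module scoring configuration
#'
#' @param n_bins Number of equal-frequency expression bins (default 24).
#' @param n_ctrl_per_gene Control genes drawn per set gene (default 100).
#' @param seed Seed for the control draws.
#' @param min_set_genes_present Minimum set genes present in the matrix
#'   (default 2).
#' @return A list of class `score_config`.
#' @export
score_config <- function(n_bins = 24, n_ctrl_per_gene = 100, seed = 0L,
                         min_set_genes_present = 2) {
  if (n_bins < 1) abort_field("n_bins", "must be >= 1")
  if (n_ctrl_per_gene < 1) abort_field("n_ctrl_per_gene", "must be >= 1")
  structure(list(n_bins = n_bins, n_ctrl_per_gene = n_ctrl_per_gene,
                 seed = as.integer(seed),
                 min_set_genes_present = min_set_genes_present),
            class = "score_config")
}

#' Expression-bin-matched module score per cell
#'
#' Genes are ranked by dataset-wide mean log-normalized expression (ties
#' broken by stable gene order) and cut into `n_bins` equal-frequency bins.
#' For each set gene, `n_ctrl_per_gene` control genes are sampled uniformly
#' with replacement from its bin, excluding all set genes. The score of a
#' cell is the mean expression of the set genes minus the mean expression of
#' the pooled control draws (with multiplicity). Deterministic given the
#' config seed; adding a constant to every set gene in one cell shifts that
#' cell's score by exactly that constant.
#'
#' @param lognorm Genes x cells log-normalized matrix ([lognormalize()]).
#' @param gene_set Character vector of gene identifiers.
#' @param cfg A [score_config()].
#' @param set_name Name recorded in the output (default "set").
#' @return Data.frame: `cell`, `set`, `score`.
#' @export
module_score <- function(lognorm, gene_set, cfg = score_config(),
                         set_name = "set") {
  n_genes <- nrow(lognorm)
  if (cfg$n_bins > n_genes)
    stop("n_bins exceeds the number of genes", call. = FALSE)
  present <- intersect(gene_set, rownames(lognorm))
  if (length(present) < length(unique(gene_set)))
    warning(sprintf("%d gene(s) of set '%s' absent from the matrix",
                    length(unique(gene_set)) - length(present), set_name))
  if (length(present) < cfg$min_set_genes_present)
    stop(sprintf("fewer than %d genes of set '%s' present",
                 cfg$min_set_genes_present, set_name), call. = FALSE)
  gene_means <- Matrix::rowMeans(lognorm)
  # equal-frequency bins on mean expression; ties and pool order resolved by
  # gene name so results do not depend on row order
  ord <- order(gene_means, rownames(lognorm))
  r <- integer(n_genes)
  r[ord] <- seq_len(n_genes)
  bin <- ceiling(r * cfg$n_bins / n_genes)
  set_idx <- match(present, rownames(lognorm))
  is_set <- logical(n_genes)
  is_set[set_idx] <- TRUE
  set.seed(cfg$seed)
  ctrl_idx <- integer(0)
  for (gi in set_idx) {
    pool <- which(bin == bin[gi] & !is_set)
    pool <- pool[order(rownames(lognorm)[pool])]
    if (length(pool) == 0)
      stop("empty control pool for an expression bin; lower n_bins",
           call. = FALSE)
    ctrl_idx <- c(ctrl_idx, pool[sample.int(length(pool), cfg$n_ctrl_per_gene,
                                            replace = TRUE)])
  }
  set_mean <- Matrix::colMeans(lognorm[set_idx, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(lognorm[ctrl_idx, , drop = FALSE])
  data.frame(cell = colnames(lognorm), set = set_name,
             score = as.numeric(set_mean - ctrl_mean),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact enumeration when both groups have at most 10 observations and no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction. Two-sided.
#'
#' @param x,y Numeric vectors.
#' @return List with `statistic` (rank-sum W of `x`), `pvalue`, `exact`.
#' @export
rank_sum_test <- function(x, y) {
  exact <- length(x) <= 10 && length(y) <= 10 &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), pvalue = wt$p.value, exact = exact)
}

#' Compare module scores between age groups
#'
#' Two-sided Wilcoxon rank-sum test of AGED vs YOUNG scores, per cell type
#' (or pooled), per score set. `unit = "cell"` uses cells as units (as in the
#' figure-level comparisons); `unit = "sample"` first averages scores per
#' sample, avoiding pseudo-replication of donors.
#'
#' @param scores Score table from [module_score()].
#' @param meta Per-cell metadata with `age_group` (and `cell_type`, `sample`).
#' @param by_celltype Compare within each cell type (default TRUE).
#' @param unit `"cell"` or `"sample"`.
#' @return Data.frame: set, cell_type, n_young, n_aged, statistic, pvalue,
#'   median_diff (aged - young). Cell types missing a group are skipped with
#'   a warning.
#' @export
compare_groups <- function(scores, meta, by_celltype = TRUE,
                           unit = c("cell", "sample")) {
  unit <- match.arg(unit)
  d <- merge(scores, meta, by = "cell")
  d <- d[d$age_group %in% c("YOUNG", "AGED"), , drop = FALSE]
  d$cell_type_key <- if (by_celltype) d$cell_type else "all"
  out <- list()
  for (grp in split(d, list(d$set, d$cell_type_key), drop = TRUE)) {
    if (unit == "sample") {
      agg <- stats::aggregate(score ~ sample + age_group, grp, mean)
      aged <- agg$score[agg$age_group == "AGED"]
      young <- agg$score[agg$age_group == "YOUNG"]
    } else {
      aged <- grp$score[grp$age_group == "AGED"]
      young <- grp$score[grp$age_group == "YOUNG"]
    }
    if (length(aged) == 0 || length(young) == 0) {
      warning(sprintf("cell type '%s' lacks one age group; skipped",
                      grp$cell_type_key[1]))
      next
    }
    wt <- rank_sum_test(aged, young)
    out[[length(out) + 1]] <- data.frame(
      set = grp$set[1], cell_type = grp$cell_type_key[1],
      n_young = length(young), n_aged = length(aged),
      statistic = wt$statistic, pvalue = wt$pvalue,
      median_diff = stats::median(aged) - stats::median(young),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$set, res$cell_type), , drop = FALSE]
}

#' Senescence scores from pluggable gene sets
#'
#' Applies [module_score()] to each supplied gene set (e.g. an 11-gene
#' consensus senescence list and a top-20 senescence gene list) and to their
#' deduplicated union.
#'
#' @param lognorm Genes x cells log-normalized matrix.
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param cfg A [score_config()].
#' @return Score table rows for every set plus `"union"`.
#' @export
senescence_scores <- function(lognorm, gene_sets, cfg = score_config()) {
  stopifnot(length(gene_sets) >= 1, !is.null(names(gene_sets)))
  tabs <- lapply(names(gene_sets), function(nm) {
    module_score(lognorm, gene_sets[[nm]], cfg, set_name = nm)
  })
  if (length(gene_sets) > 1) {
    union_set <- unique(unlist(gene_sets, use.names = FALSE))
    tabs <- c(tabs, list(module_score(lognorm, union_set, cfg, set_name = "union")))
  }
  do.call(rbind, tabs)
}

#' Exact overlap between two gene lists
#'
#' @param a,b Character vectors.
#' @return List with `size` and `members`.
#' @export
set_overlap <- function(a, b) {
  members <- sort(intersect(unique(a), unique(b)))
  list(size = length(members), members = members)
}
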