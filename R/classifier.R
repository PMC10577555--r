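# Age-state classifier: signature genes as features, stratified 90:10 split,
# repeated stratified 10-fold cross-validation of a random forest, AUROC
# evaluation and variable importance.

#' Train/test split specification
#'
#' @param test_fraction Fraction of each stratum sent to the test set
#'   (default 0.10).
#' @param seed Split seed.
#' @param min_cells_per_celltype Cell types with fewer cells are removed
#'   before splitting (default 200; only sufficiently abundant clusters are
#'   used for age-state prediction).
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.10, seed = 0L,
                       min_cells_per_celltype = 200) {
  if (test_fraction <= 0 || test_fraction >= 1)
    abort_field("test_fraction", "must be in (0, 1)")
  structure(list(test_fraction = test_fraction, seed = as.integer(seed),
                 min_cells_per_celltype = min_cells_per_celltype),
            class = "split_spec")
}

#' Cross-validation specification
#'
#' Defaults mirror a three-time repeated 10-fold cross-validation with a
#' 500-tree forest.
#'
#' @param n_repeats Number of CV repeats (default 3).
#' @param n_folds Number of folds (default 10).
#' @param n_trees Trees per forest (default 500).
#' @param seed CV seed.
#' @return A list of class `cv_spec`.
#' @export
cv_spec <- function(n_repeats = 3, n_folds = 10, n_trees = 500, seed = 0L) {
  if (n_folds < 2) abort_field("n_folds", "must be >= 2")
  structure(list(n_repeats = n_repeats, n_folds = n_folds,
                 n_trees = n_trees, seed = as.integer(seed)),
            class = "cv_spec")
}

#' Build the feature matrix from signature genes
#'
#' Cells x genes matrix of log-normalized expression of the up, down, or
#' combined signature genes; genes absent from the matrix are dropped and
#' recorded in attribute `missing`.
#'
#' @param lognorm Genes x cells log-normalized matrix.
#' @param signature A `signature_set` from [consensus_signature()].
#' @param subset `"all"`, `"up"`, or `"down"`.
#' @return Numeric matrix (cells x genes).
#' @export
make_features <- function(lognorm, signature, subset = c("all", "up", "down")) {
  subset <- match.arg(subset)
  genes <- switch(subset,
    up = signature$up_genes,
    down = signature$down_genes,
    all = union(signature$up_genes, signature$down_genes)
  )
  present <- intersect(genes, rownames(lognorm))
  if (length(present) == 0)
    stop("no signature genes present in the matrix", call. = FALSE)
  x <- t(as.matrix(lognorm[present, , drop = FALSE]))
  attr(x, "missing") <- setdiff(genes, present)
  x
}

#' Stratified train/test split of cells
#'
#' Cell types with fewer than `min_cells_per_celltype` cells are removed
#' entirely; within each remaining (sample, cell_type, age_group) stratum,
#' `ceiling(test_fraction * n)` cells go to the test set (uniformly, seeded).
#' Singleton strata go to training with a warning. Train and test are
#' disjoint and together exhaust the retained cells.
#'
#' @param meta Per-cell metadata with `cell`, `sample`, `cell_type`,
#'   `age_group`.
#' @param spec A [split_spec()].
#' @return List with `train`, `test` (cell identifiers) and
#'   `dropped_celltypes`.
#' @export
stratified_split <- function(meta, spec = split_spec()) {
  ct_n <- table(meta$cell_type)
  dropped <- names(ct_n)[ct_n < spec$min_cells_per_celltype]
  meta <- meta[!(meta$cell_type %in% dropped), , drop = FALSE]
  if (nrow(meta) == 0) stop("no cells left after cell-type filter", call. = FALSE)
  set.seed(stage_seed(spec$seed, "split"))
  test <- character(0)
  strata <- split(meta$cell, list(meta$sample, meta$cell_type, meta$age_group),
                  drop = TRUE)
  singletons <- 0L
  for (cells in strata) {
    n <- length(cells)
    if (n == 1) {
      singletons <- singletons + 1L
      next
    }
    n_test <- ceiling(spec$test_fraction * n)
    test <- c(test, cells[sample.int(n, n_test)])
  }
  if (singletons > 0)
    warning(sprintf("%d singleton stratum(s) assigned to training", singletons))
  list(train = setdiff(meta$cell, test), test = test,
       dropped_celltypes = dropped)
}

#' Train the random-forest age-state classifier
#'
#' Fits a random forest (bagged trees, Gini splits, sqrt(p) features per
#' split) on the training cells and, when `cv` is supplied, reports the mean
#' and sd of the AUROC over repeated stratified k-fold cross-validation.
#' Deterministic given the seed.
#'
#' @param x Cells x genes feature matrix (training cells).
#' @param y Labels, factor or character in YOUNG/AGED.
#' @param cv Optional [cv_spec()]; `NULL` skips cross-validation.
#' @param n_trees Trees for the final forest (default 500).
#' @param seed Training seed.
#' @return A `lungage_rf`: list with `model`, `cv_auroc_mean`, `cv_auroc_sd`,
#'   `cv_aurocs`, `genes`.
#' @export
train_rf <- function(x, y, cv = NULL, n_trees = 500, seed = 0L) {
  y <- factor(as.character(y), levels = c("YOUNG", "AGED"))
  if (any(is.na(y))) stop("labels must be YOUNG or AGED", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("training data contain a single class", call. = FALSE)
  cv_aurocs <- NULL
  if (!is.null(cv)) {
    set.seed(stage_seed(cv$seed, "cv"))
    cv_aurocs <- numeric(0)
    for (r in seq_len(cv$n_repeats)) {
      fold <- integer(length(y))
      for (lev in levels(y)) {           # stratified fold assignment
        idx <- which(y == lev)
        fold[idx] <- sample(rep_len(seq_len(cv$n_folds), length(idx)))
      }
      for (k in seq_len(cv$n_folds)) {
        tr <- fold != k
        if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
        fit <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                          ntree = cv$n_trees)
        p <- stats::predict(fit, x[!tr, , drop = FALSE], type = "prob")[, "AGED"]
        cv_aurocs <- c(cv_aurocs, auroc(p, y[!tr] == "AGED"))
      }
    }
  }
  set.seed(stage_seed(seed, "rf"))
  model <- randomForest::randomForest(x, y, ntree = n_trees, importance = FALSE)
  structure(list(
    model = model,
    cv_auroc_mean = if (length(cv_aurocs)) mean(cv_aurocs) else NA_real_,
    cv_auroc_sd = if (length(cv_aurocs) > 1) stats::sd(cv_aurocs) else NA_real_,
    cv_aurocs = cv_aurocs,
    genes = colnames(x)
  ), class = "lungage_rf")
}

#' Area under the ROC curve via the rank statistic
#'
#' Probability that a random positive scores above a random negative, with
#' ties counted half (midranks).
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical (or 0/1) positives.
#' @return AUROC in `[0, 1]`; NA if either class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a trained classifier on held-out cells
#'
#' AUROC from the vote fraction for AGED (midranks for ties), accuracy at the
#' 0.5 majority-vote threshold, confusion counts, and a per-cell-type accuracy
#' breakdown. A one-class test set yields `auroc = NA` with accuracy only.
#'
#' @param fit A `lungage_rf` from [train_rf()].
#' @param x Cells x genes feature matrix (test cells).
#' @param y True labels (YOUNG/AGED).
#' @param cell_type Optional per-cell cell-type labels for the breakdown.
#' @return A `classifier_report`: list with `auroc`, `accuracy`, `confusion`,
#'   `per_celltype`, `scores`.
#' @export
evaluate_classifier <- function(fit, x, y, cell_type = NULL) {
  if (nrow(x) == 0) stop("empty test set", call. = FALSE)
  y <- factor(as.character(y), levels = c("YOUNG", "AGED"))
  prob <- stats::predict(fit$model, x, type = "prob")[, "AGED"]
  pred <- factor(ifelse(prob > 0.5, "AGED", "YOUNG"), levels = c("YOUNG", "AGED"))
  per_ct <- NULL
  if (!is.null(cell_type)) {
    acc <- tapply(pred == y, cell_type, mean)
    per_ct <- data.frame(cell_type = names(acc), accuracy = as.numeric(acc),
                         n = as.integer(table(cell_type)[names(acc)]),
                         stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(
    auroc = auroc(prob, y == "AGED"),
    accuracy = mean(pred == y),
    confusion = table(truth = y, predicted = pred),
    per_celltype = per_ct,
    scores = prob
  ), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("AUROC %.3f | accuracy %.3f (n = %d)\n",
              x$auroc, x$accuracy, length(x$scores)))
  invisible(x)
}

#' Ranked variable importance with DEG annotation
#'
#' Mean-decrease-in-impurity (Gini) importance, normalized to sum 1, in
#' descending order with ties broken lexicographically. When a `DegTable` is
#' supplied, each gene is annotated with the cell types where it was called a
#' DEG.
#'
#' @param fit A `lungage_rf`.
#' @param top_k Number of genes to return (default 20; the full list if
#'   fewer features).
#' @param degs Optional `DegTable` with directions called.
#' @return Data.frame: gene, importance, rank, celltypes (comma-separated).
#' @export
variable_importance <- function(fit, top_k = 20, degs = NULL) {
  imp <- randomForest::importance(fit$model, type = 2)[, 1]
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  ord <- order(-imp, names(imp))
  out <- data.frame(gene = names(imp)[ord], importance = as.numeric(imp[ord]),
                    rank = seq_along(imp), stringsAsFactors = FALSE)
  if (!is.null(degs)) {
    sig <- degs[degs$direction != "ns", , drop = FALSE]
    ann <- tapply(sig$cell_type, sig$gene, function(ct) paste(sort(ct), collapse = ","))
    out$celltypes <- as.character(ann[out$gene])
    out$celltypes[is.na(out$celltypes)] <- ""
  }
  utils::head(out, top_k)
}
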