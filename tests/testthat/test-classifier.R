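test_that("feature matrices select the right signature genes", {
  sig <- structure(list(name = "s", up_genes = c("g1", "g2", "gX"),
                        down_genes = c("g3", "g4"), min_celltypes = 2,
                        conflicts = character(0)), class = "signature_set")
  mat <- matrix(rexp(50), 10, 5,
                dimnames = list(sprintf("g%d", 1:10), sprintf("c%d", 1:5)))
  x_up <- make_features(mat, sig, "up")
  expect_equal(colnames(x_up), c("g1", "g2"))
  expect_equal(attr(x_up, "missing"), "gX")
  x_all <- make_features(mat, sig, "all")
  expect_setequal(colnames(x_all), c("g1", "g2", "g3", "g4"))
  expect_equal(nrow(x_all), 5)
  expect_equal(x_all["c2", "g3"], mat["g3", "c2"])
  sig$up_genes <- "gX"
  sig$down_genes <- character(0)
  expect_error(make_features(mat, sig, "all"), "no signature genes")
})

test_that("stratified split is disjoint, exhaustive, and near the test fraction", {
  dd <- default_data()
  sp <- stratified_split(dd$meta, split_spec(seed = 13))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), dd$meta$cell)
  expect_length(sp$dropped_celltypes, 0)

  strata <- split(dd$meta$cell, list(dd$meta$sample, dd$meta$cell_type,
                                     dd$meta$age_group), drop = TRUE)
  for (cells in strata) {
    n <- length(cells)
    n_test <- sum(cells %in% sp$test)
    expect_equal(n_test, ceiling(0.10 * n))
    if (n >= 20) {
      expect_gte(n_test / n, 0.05)
      expect_lte(n_test / n, 0.2)
    }
  }

  # stratum of exactly 10 -> exactly 1 test cell; singleton goes to train
  meta <- toy_meta(sprintf("c%d", 1:11), c(rep("s1", 10), "s2"), "A",
                   c(rep("YOUNG", 10), "AGED"))
  expect_warning(sp2 <- stratified_split(meta, split_spec(seed = 1,
                                                          min_cells_per_celltype = 0)),
                 "singleton")
  expect_length(sp2$test, 1)
  expect_true(sp2$test %in% sprintf("c%d", 1:10))
  expect_true("c11" %in% sp2$train)

  # cell types below the abundance threshold are removed entirely
  meta2 <- rbind(meta, toy_meta(sprintf("d%d", 1:30), "s1", "B", "YOUNG"))
  sp3 <- suppressWarnings(stratified_split(meta2, split_spec(min_cells_per_celltype = 20)))
  expect_equal(sp3$dropped_celltypes, "A")
  expect_true(all(grepl("^d", c(sp3$train, sp3$test))))
})

test_that("AUROC equals the brute-force pairwise statistic", {
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)), 0.5)
  expect_true(is.na(auroc(1:3, c(TRUE, TRUE, TRUE))))
  set.seed(14)
  for (i in 1:10) {
    scores <- sample(seq(0, 1, 0.05), 50, replace = TRUE)   # with ties
    labels <- runif(50) < 0.4
    if (!any(labels) || all(labels)) next
    pairs <- outer(scores[labels], scores[!labels], function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(auroc(scores, labels), mean(pairs))
  }
})

test_that("random forest training separates a toy problem and is deterministic", {
  set.seed(15)
  n <- 120
  x <- cbind(f1 = c(seq(-3, -1, length.out = n / 2), seq(1, 3, length.out = n / 2)),
             f2 = rnorm(n))
  y <- rep(c("YOUNG", "AGED"), each = n / 2)
  fit <- train_rf(x, y, cv = cv_spec(n_repeats = 1, n_folds = 5, n_trees = 50,
                                     seed = 3), n_trees = 50, seed = 3)
  expect_equal(fit$cv_auroc_mean, 1.0)
  fit2 <- train_rf(x, y, n_trees = 50, seed = 3)
  expect_identical(randomForest::importance(fit$model, type = 2),
                   randomForest::importance(fit2$model, type = 2))
  expect_error(train_rf(x, rep("AGED", n)), "single class")
  expect_error(train_rf(x, rep(c("old", "young"), n / 2)), "YOUNG or AGED")
})

test_that("evaluation reports accuracy-only for one-class test sets", {
  set.seed(16)
  n <- 80
  x <- cbind(f1 = c(rnorm(n / 2, -2), rnorm(n / 2, 2)), f2 = rnorm(n))
  y <- rep(c("YOUNG", "AGED"), each = n / 2)
  fit <- train_rf(x, y, n_trees = 50, seed = 4)
  x_test <- cbind(f1 = rnorm(10, 2), f2 = rnorm(10))
  rep1 <- evaluate_classifier(fit, x_test, rep("AGED", 10),
                              cell_type = rep(c("A", "B"), 5))
  expect_true(is.na(rep1$auroc))
  expect_gte(rep1$accuracy, 0.8)
  expect_equal(nrow(rep1$per_celltype), 2)
  expect_error(evaluate_classifier(fit, x_test[0, , drop = FALSE], character(0)),
               "empty")
})

test_that("variable importance is normalized, ranked, and annotated", {
  set.seed(17)
  n <- 100
  x <- cbind(sig1 = c(rnorm(n / 2, -1.5), rnorm(n / 2, 1.5)), noise1 = rnorm(n),
             noise2 = rnorm(n))
  y <- rep(c("YOUNG", "AGED"), each = n / 2)
  fit <- train_rf(x, y, n_trees = 100, seed = 5)
  degs <- data.frame(cell_type = c("A", "B"), gene = "sig1", log2fc = 1,
                     lrt_stat = 1, pvalue = 0.001, fdr = 0.01,
                     direction = "up", mean_expr = 1, flag = "",
                     stringsAsFactors = FALSE)
  imp <- variable_importance(fit, top_k = 10, degs = degs)
  expect_equal(nrow(imp), 3)                      # top_k > p gives full list
  expect_true(all(imp$importance >= 0))
  expect_equal(sum(variable_importance(fit, top_k = 3)$importance), 1)
  expect_equal(imp$gene[1], "sig1")
  expect_equal(imp$celltypes[imp$gene == "sig1"], "A,B")
  expect_equal(imp$celltypes[imp$gene == "noise1"], "")
})
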