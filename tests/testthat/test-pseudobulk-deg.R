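test_that("pseudobulk aggregation sums cells, drops MIDDLE, matches brute force", {
  cells <- c("c1", "c2", "c3", "c4", "c5")
  counts <- Matrix::Matrix(
    matrix(c(1, 3, 2, 7, 4,
             0, 1, 1, 0, 2), 2, 5, byrow = TRUE,
           dimnames = list(c("g1", "g2"), cells)), sparse = TRUE)
  meta <- toy_meta(cells, c("s1", "s1", "s2", "s3", "s3"), "A",
                   c("YOUNG", "YOUNG", "MIDDLE", "AGED", "AGED"))
  pbs <- aggregate_pseudobulk(counts, meta)
  pb <- pbs[["A"]]
  expect_equal(pb$counts["g1", "s1"], 4)              # 1 + 3
  expect_false("s2" %in% colnames(pb$counts))          # MIDDLE dropped
  expect_equal(pb$samples$n_cells[pb$samples$sample == "s3"], 2L)

  # random fixture vs independent group-by-sum
  set.seed(1)
  n <- 200
  rc <- Matrix::Matrix(matrix(rpois(30 * n, 2), 30, n,
                              dimnames = list(sprintf("g%02d", 1:30),
                                              sprintf("c%03d", 1:n))),
                       sparse = TRUE)
  rmeta <- toy_meta(colnames(rc), sample(c("sA", "sB", "sC"), n, TRUE),
                    sample(c("T1", "T2"), n, TRUE),
                    sample(c("YOUNG", "AGED"), n, TRUE))
  pbs <- aggregate_pseudobulk(rc, rmeta)
  for (ct in names(pbs)) {
    for (s in pbs[[ct]]$samples$sample) {
      idx <- rmeta$cell[rmeta$cell_type == ct & rmeta$sample == s]
      brute <- rowSums(as.matrix(rc[, idx, drop = FALSE]))
      expect_equal(pbs[[ct]]$counts[, s], brute)
    }
  }

  # cell-order invariance
  perm <- sample(n)
  pbs2 <- aggregate_pseudobulk(rc[, perm], rmeta[perm, ])
  expect_equal(pbs[["T1"]]$counts, pbs2[["T1"]]$counts)
})

test_that("small or unbalanced cell types are excluded at the 500-cell boundary", {
  mk <- function(n_cells, ages) {
    pb <- make_pb(matrix(5, 3, length(ages)), ages)
    pb$samples$n_cells <- n_cells
    pb
  }
  pbs <- list(
    a = mk(c(250, 249), c("YOUNG", "AGED")),     # 499 total
    b = mk(c(250, 250), c("YOUNG", "AGED")),     # 500 total but 1 per group
    c = mk(c(200, 200, 200, 200), c("YOUNG", "YOUNG", "AGED", "AGED")),
    d = mk(c(300, 300), c("AGED", "AGED"))       # one age group only
  )
  kept <- exclude_small_clusters(pbs, deg_config())
  expect_identical(names(kept), "c")
  kept2 <- exclude_small_clusters(pbs, deg_config(min_cells_per_cluster = 0,
                                                  min_samples_per_group = 1))
  expect_setequal(names(kept2), c("a", "b", "c"))
  expect_error(exclude_small_clusters(pbs["d"], deg_config()), "excluded")
})

test_that("median-of-ratios size factors match DESeq2 and fall back cleanly", {
  set.seed(2)
  mat <- matrix(rnbinom(200 * 8, mu = 50, size = 2), 200, 8)
  mat <- sweep(mat, 2, c(0.5, 0.8, 1, 1.2, 1.5, 2, 0.7, 1.1), "*")
  storage.mode(mat) <- "integer"
  mat[mat == 0] <- 1                      # all-positive: pure median-of-ratios
  sf <- compute_size_factors(mat)
  expect_equal(attr(sf, "method"), "median-of-ratios")
  ref <- DESeq2::estimateSizeFactorsForMatrix(mat)
  ref <- ref / exp(mean(log(ref)))         # same geometric-mean-1 convention
  expect_equal(unname(sf), unname(ref), tolerance = 1e-10, ignore_attr = TRUE)

  sparse_mat <- matrix(0L, 50, 4)
  sparse_mat[cbind(1:50, sample(4, 50, TRUE))] <- 10L   # every gene has zeros
  sf2 <- compute_size_factors(sparse_mat)
  expect_equal(attr(sf2, "method"), "total-count")
  expect_equal(exp(mean(log(sf2))), 1)
})

test_that("dispersion estimates hit the floor for constants and recover truth", {
  const <- make_pb(matrix(7, 50, 8), rep(c("YOUNG", "AGED"), each = 4))
  a <- estimate_dispersions(const, deg_config(shrink_weight = 0))
  expect_true(all(a == deg_config()$dispersion_floor))

  set.seed(3)
  pois <- make_pb(matrix(rpois(200 * 20, 100), 200, 20),
                  rep(c("YOUNG", "AGED"), each = 10))
  ap <- estimate_dispersions(pois, deg_config(shrink_weight = 0))
  expect_lte(stats::median(ap), 0.05)

  nb <- make_pb(matrix(rnbinom(200 * 50, mu = 50, size = 2), 200, 50),
                rep(c("YOUNG", "AGED"), each = 25))
  an <- estimate_dispersions(nb, deg_config(shrink_weight = 0))
  expect_gte(stats::median(an), 0.3)
  expect_lte(stats::median(an), 0.7)

  zg <- rbind(matrix(5, 3, 6), 0)
  rownames(zg) <- sprintf("g%d", 1:4)
  zero_gene <- make_pb(zg, rep(c("YOUNG", "AGED"), each = 3))
  az <- estimate_dispersions(zero_gene, deg_config())
  expect_identical(attr(az, "flagged"), "g4")
  expect_equal(unname(az[["g4"]]), deg_config()$dispersion_floor)
})

test_that("nb_lrt agrees with an independent fixed-dispersion GLM fit", {
  set.seed(4)
  n_genes <- 10
  ages <- rep(c("YOUNG", "AGED"), each = 6)
  batch <- rep(c("B1", "B2"), 6)
  mu <- outer(exp(runif(n_genes, 2, 5)), rep(1, 12))
  mu[, ages == "AGED"] <- mu[, ages == "AGED"] * rep(2^runif(n_genes, -1, 1), 6)
  y <- matrix(rnbinom(length(mu), mu = mu, size = 5), n_genes,
              dimnames = list(sprintf("g%02d", 1:n_genes), NULL))
  pb <- make_pb(y, ages, batch)
  disp <- setNames(rep(0.2, n_genes), rownames(y))
  res <- nb_lrt(pb, disp, deg_config(min_total_count = 0))
  sf <- compute_size_factors(y)
  for (g in seq_len(n_genes)) {
    df <- data.frame(y = y[g, ], age = factor(ages, c("YOUNG", "AGED")),
                     batch = factor(batch), sf = sf)
    fam <- MASS::negative.binomial(theta = 1 / 0.2)
    full <- glm(y ~ batch + age + offset(log(sf)), family = fam, data = df,
                control = list(epsilon = 1e-12, maxit = 100))
    red <- glm(y ~ batch + offset(log(sf)), family = fam, data = df,
               control = list(epsilon = 1e-12, maxit = 100))
    ll <- function(fit) sum(dnbinom(df$y, size = 5, mu = fitted(fit), log = TRUE))
    expect_equal(res$lrt_stat[g], 2 * (ll(full) - ll(red)), tolerance = 1e-5)
    expect_equal(res$log2fc[g], unname(coef(full)["ageAGED"]) / log(2),
                 tolerance = 1e-5)
  }
  expect_true(all(res$lrt_stat >= 0))
})

test_that("degenerate contrasts and low-count genes are handled", {
  y <- matrix(rpois(20, 10), 5, 4,
              dimnames = list(sprintf("g%d", 1:5), NULL))
  pb_const <- make_pb(y, rep("AGED", 4))
  expect_error(nb_lrt(pb_const, setNames(rep(0.1, 5), rownames(y))),
               "contrast not estimable")
  pb_conf <- make_pb(y, c("YOUNG", "YOUNG", "AGED", "AGED"),
                     batch = c("B1", "B1", "B2", "B2"))
  expect_error(nb_lrt(pb_conf, setNames(rep(0.1, 5), rownames(y))),
               "confounded")

  y2 <- y
  y2[1, ] <- c(0, 0, 1, 0)                      # below min_total_count
  pb <- make_pb(y2, c("YOUNG", "AGED", "YOUNG", "AGED"))
  res <- nb_lrt(pb, setNames(rep(0.1, 5), rownames(y2)), deg_config())
  expect_true(is.na(res$pvalue[1]))
  expect_equal(res$flag[1], "lowcount")
})

test_that("BH adjustment matches the step-up formula and passes NAs through", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.7), 0.7)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  p <- c(0.001, NA, 0.03, 0.5, NA, 0.2)
  q <- bh_adjust(p)
  expect_true(all(is.na(q[is.na(p)])))
  expect_equal(q[!is.na(p)], bh_stepup(p[!is.na(p)]))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_stepup(p))
    expect_true(all(bh_adjust(p) >= p & bh_adjust(p) <= 1))
  }
})

test_that("direction calls respect the strict FDR threshold per cell type", {
  tab <- data.frame(
    cell_type = "A", gene = c("g1", "g2", "g3", "g4"),
    log2fc = c(0.5, -0.5, 2, 0.1),
    lrt_stat = 1, pvalue = c(0.001, 0.002, 0.5, NA), fdr = NA_real_,
    direction = "ns", mean_expr = 10, flag = "",
    stringsAsFactors = FALSE
  )
  out <- call_degs(tab, deg_config())
  expect_equal(out$direction[out$gene == "g1"], "up")
  expect_equal(out$direction[out$gene == "g2"], "down")
  expect_equal(out$direction[out$gene == "g3"], "ns")
  expect_equal(out$direction[out$gene == "g4"], "ns")      # NA pvalue

  # boundary: fdr exactly at the threshold is not significant
  tab2 <- data.frame(cell_type = "A", gene = c("g1", "g2"),
                     log2fc = c(1, 1), lrt_stat = 1,
                     pvalue = c(0.09, 0.10), fdr = NA_real_, direction = "ns",
                     mean_expr = 1, flag = "", stringsAsFactors = FALSE)
  out2 <- call_degs(tab2, deg_config())
  expect_equal(out2$fdr, c(0.10, 0.10))
  expect_equal(out2$direction, c("ns", "ns"))
})

test_that("full DEG pipeline matches a straight-line reimplementation on a small fixture", {
  set.seed(6)
  cfg <- synth_config(
    n_genes = 50, cell_types = c(A = 60),
    samples = data.frame(sample = sprintf("s%d", 1:8),
                         age_group = rep(c("YOUNG", "AGED"), each = 4),
                         batch = rep(c("B1", "B2"), 4)),
    sharing_profile = 1, baseline_logmean_range = c(-1, 1),
    n_up_planted = 5, n_down_planted = 3, senescence_set_size = 0,
    senescence_target_celltypes = character(0), seed = 7
  )
  d <- generate_dataset(cfg)
  degs <- run_deg(d$counts, d$meta,
                  deg_config(min_cells_per_cluster = 0))

  # independent straight-line path: loops + MASS glm + formulas only
  meta <- d$meta
  samples <- sort(unique(meta$sample))
  pb <- sapply(samples, function(s) {
    rowSums(as.matrix(d$counts[, meta$cell[meta$sample == s], drop = FALSE]))
  })
  lg <- rowMeans(log(pb))
  use <- is.finite(lg)
  sf <- apply(pb, 2, function(col) exp(median(log(col[use]) - lg[use])))
  sf <- sf / exp(mean(log(sf)))
  ages <- cfg$samples$age_group[match(samples, cfg$samples$sample)]
  batches <- cfg$samples$batch[match(samples, cfg$samples$sample)]
  norm <- sweep(pb, 2, sf, "/")
  strat <- paste(batches, ages)
  ss <- 0; df <- 0
  for (st in unique(strat)) {
    idx <- which(strat == st)
    gm <- rowMeans(norm[, idx, drop = FALSE])
    ss <- ss + rowSums((norm[, idx, drop = FALSE] - gm)^2)
    df <- df + length(idx) - 1
  }
  m <- rowMeans(norm)
  raw <- pmax(1e-6, (ss / df - m) / pmax(m, 1e-12)^2)
  alpha <- pmax(1e-6, 0.7 * raw + 0.3 * median(raw), median(raw))
  pvals <- rep(NA_real_, nrow(pb))
  for (g in seq_len(nrow(pb))) {
    if (sum(pb[g, ]) < 10) next
    dat <- data.frame(y = pb[g, ], age = factor(ages, c("YOUNG", "AGED")),
                      batch = factor(batches), sf = sf)
    fam <- MASS::negative.binomial(theta = 1 / alpha[g])
    ll <- function(fit) sum(dnbinom(dat$y, size = 1 / alpha[g],
                                    mu = fitted(fit), log = TRUE))
    full <- glm(y ~ batch + age + offset(log(sf)), family = fam, data = dat,
                control = list(epsilon = 1e-12, maxit = 100))
    red <- glm(y ~ batch + offset(log(sf)), family = fam, data = dat,
               control = list(epsilon = 1e-12, maxit = 100))
    pvals[g] <- pchisq(max(0, 2 * (ll(full) - ll(red))), 1, lower.tail = FALSE)
  }
  q <- rep(NA_real_, length(pvals))
  q[!is.na(pvals)] <- bh_stepup(pvals[!is.na(pvals)])
  calls <- ifelse(!is.na(q) & q < 0.1, "sig", "ns")
  pkg_calls <- ifelse(degs$direction == "ns", "ns", "sig")
  expect_equal(unname(pkg_calls), unname(calls))
})
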