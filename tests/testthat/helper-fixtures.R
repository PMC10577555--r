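# Shared fixtures, memoized so expensive simulations run once per suite.

fx <- local({
  cache <- new.env(parent = emptyenv())
  function(name, fn) {
    if (!exists(name, envir = cache)) assign(name, fn(), envir = cache)
    get(name, envir = cache)
  }
})

sen_target_celltypes <- c("FABP4_Macro", "Monocyte", "AT2")

# default planted fixture: 60 up / 30 down at |log2FC| 1, 20 senescence genes
default_data <- function() fx("default_data", function() {
  d <- generate_dataset(synth_config(seed = 20260101))
  q <- filter_cells(d$counts, d$meta)
  list(counts = q$counts, meta = q$meta, lognorm = lognormalize(q$counts),
       truth = d$truth)
})

default_degs <- function() fx("default_degs", function() {
  dd <- default_data()
  run_deg(dd$counts, dd$meta)
})

default_signature <- function() fx("default_signature", function() {
  degs <- default_degs()
  consensus_signature(build_membership(degs, "up"),
                      build_membership(degs, "down"), min_celltypes = 2)
})

# null fixture: 12 samples 6v6, 2 batches, 3 cell types, 2,000 genes,
# nothing planted
null_config <- function() synth_config(
  n_genes = 2000, cell_types = c(A = 200, B = 170, C = 130),
  sharing_profile = c(0.6, 0.3, 0.1),
  n_up_planted = 0, n_down_planted = 0, senescence_set_size = 0,
  senescence_target_celltypes = character(0), seed = 20260102
)

null_data <- function() fx("null_data", function() {
  d <- generate_dataset(null_config())
  list(counts = d$counts, meta = d$meta, lognorm = lognormalize(d$counts),
       truth = d$truth)
})

null_degs <- function() fx("null_degs", function() {
  nd <- null_data()
  run_deg(nd$counts, nd$meta)
})

# genes planted for one cell type
planted_for <- function(map, ct) {
  names(map)[vapply(map, function(v) ct %in% v, logical(1))]
}

# planted truth at >= k supporting cell types
planted_at_least <- function(map, k) {
  names(map)[vapply(map, length, integer(1)) >= k]
}

jaccard <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

# tiny dense count fixture with hand-set metadata
toy_counts <- function(n_genes = 6, cells) {
  m <- matrix(seq_len(n_genes * length(cells)) %% 5, n_genes, length(cells),
              dimnames = list(sprintf("g%02d", seq_len(n_genes)), cells))
  Matrix::Matrix(m, sparse = TRUE)
}

toy_meta <- function(cells, sample, cell_type, age_group, batch = "B1",
                     n_features = 300, mito = 0.05) {
  data.frame(cell = cells, sample = sample, cell_type = cell_type,
             age_group = age_group, batch = batch, n_features = n_features,
             mito_fraction = mito, stringsAsFactors = FALSE)
}

# manual pseudobulk object for direct nb_lrt/dispersion tests
make_pb <- function(counts, age_group, batch = NULL, cell_type = "T") {
  n <- ncol(counts)
  if (is.null(batch)) batch <- rep("B1", n)
  colnames(counts) <- sprintf("S%02d", seq_len(n))
  structure(list(
    cell_type = cell_type, counts = counts,
    samples = data.frame(sample = colnames(counts), age_group = age_group,
                         batch = batch, n_cells = rep(100L, n),
                         stringsAsFactors = FALSE)
  ), class = "pseudobulk")
}

# direct BH step-up formula, independent of bh_adjust
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rep(NA_real_, m)
  prev <- Inf
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[o[i]] / i, 1)
    q[o[i]] <- prev
  }
  q
}

# independent loop-based recomputation of the module score (same seeded
# sampling procedure, none of the package's vectorized code)
brute_module_score <- function(lognorm, gene_set, cfg) {
  mat <- as.matrix(lognorm)
  means <- apply(mat, 1, mean)
  ord <- order(means, rownames(mat))
  r <- integer(nrow(mat))
  r[ord] <- seq_len(nrow(mat))
  bin <- ceiling(r * cfg$n_bins / nrow(mat))
  present <- intersect(gene_set, rownames(mat))
  set.seed(cfg$seed)
  ctrl <- c()
  for (g in present) {
    pool <- setdiff(which(bin == bin[[match(g, rownames(mat))]]),
                    match(present, rownames(mat)))
    pool <- pool[order(rownames(mat)[pool])]
    ctrl <- c(ctrl, pool[sample.int(length(pool), cfg$n_ctrl_per_gene,
                                    replace = TRUE)])
  }
  sapply(seq_len(ncol(mat)), function(j) {
    mean(mat[match(present, rownames(mat)), j]) - mean(mat[ctrl, j])
  })
}

# brute-force NB log-likelihood maximization over coefficients (oracle)
nb_ll_max <- function(y, X, offset, alpha) {
  nll <- function(beta) {
    mu <- exp(drop(X %*% beta) + offset)
    -sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  }
  start <- rep(0, ncol(X))
  start[1] <- log(mean(y) + 0.5)
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  -opt$value
}
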