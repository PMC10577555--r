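# Young-vs-aged differential expression on pseudobulk counts: per-gene
# negative-binomial log-linear models with a batch covariate, compared by a
# likelihood-ratio test (full: ~ batch + age; reduced: ~ batch) with the
# dispersion fixed at a method-of-moments estimate, then BH adjustment per
# cell type at FDR < 0.1.

#' DEG testing configuration
#'
#' @param min_cells_per_cluster Cell types with fewer total cells are excluded
#'   (default 500).
#' @param min_samples_per_group Minimum samples per age group (default 2).
#' @param fdr_threshold BH-adjusted significance threshold, strict
#'   (default 0.1).
#' @param min_total_count Gene prefilter: genes with a smaller total pseudobulk
#'   count get `pvalue = NA` and are excluded from the multiplicity (default 10).
#' @param dispersion_floor Lower bound for the per-gene NB dispersion
#'   (default 1e-6).
#' @param shrink_weight Weight of shrinkage of gene-wise dispersions toward
#'   their median (default 0.3).
#' @return A list of class `deg_config`.
#' @export
deg_config <- function(min_cells_per_cluster = 500, min_samples_per_group = 2,
                       fdr_threshold = 0.1, min_total_count = 10,
                       dispersion_floor = 1e-6, shrink_weight = 0.3) {
  if (fdr_threshold <= 0) abort_field("fdr_threshold", "must be > 0")
  if (dispersion_floor <= 0) abort_field("dispersion_floor", "must be > 0")
  if (shrink_weight < 0 || shrink_weight > 1)
    abort_field("shrink_weight", "must be in [0, 1]")
  structure(list(min_cells_per_cluster = min_cells_per_cluster,
                 min_samples_per_group = min_samples_per_group,
                 fdr_threshold = fdr_threshold,
                 min_total_count = min_total_count,
                 dispersion_floor = dispersion_floor,
                 shrink_weight = shrink_weight), class = "deg_config")
}

#' Method-of-moments NB dispersion estimates for a pseudobulk matrix
#'
#' For each gene, `alpha = max(floor, (s2 - m) / m^2)` on size-factor
#' normalized counts, where `s2` is the pooled within-stratum variance
#' (strata = batch x age combinations, so design-driven mean shifts do not
#' inflate the dispersion) and `m` the overall normalized mean. Estimates are
#' then shrunk toward their median with weight `shrink_weight` and floored at
#' the median, so no gene is tested with a below-typical dispersion.
#'
#' @param pb A `pseudobulk` object.
#' @param cfg A [deg_config()].
#' @param size_factors Optional precomputed size factors.
#' @return Named per-gene dispersion vector (>= floor); all-zero genes sit at
#'   the floor and are listed in attribute `flagged`.
#' @export
estimate_dispersions <- function(pb, cfg = deg_config(), size_factors = NULL) {
  mat <- pb$counts
  if (ncol(mat) < 3) stop("need at least 3 samples to estimate dispersion", call. = FALSE)
  sf <- size_factors
  if (is.null(sf)) sf <- compute_size_factors(mat)
  norm <- sweep(mat, 2, sf, "/")
  strata <- interaction(pb$samples$batch, pb$samples$age_group, drop = TRUE)
  m <- rowMeans(norm)
  groups <- split(seq_len(ncol(norm)), strata)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  if (length(groups) == 0 || sum(vapply(groups, length, integer(1))) -
      length(groups) < 1) {
    s2 <- row_vars(norm)
  } else {
    ss <- 0
    df <- 0
    for (idx in groups) {
      gm <- rowMeans(norm[, idx, drop = FALSE])
      ss <- ss + rowSums((norm[, idx, drop = FALSE] - gm)^2)
      df <- df + length(idx) - 1L
    }
    s2 <- ss / df
  }
  raw <- pmax(cfg$dispersion_floor, (s2 - m) / pmax(m, 1e-12)^2)
  raw[m <= 0] <- cfg$dispersion_floor
  w <- cfg$shrink_weight
  med <- stats::median(raw)
  # shrink toward the median, then floor at it: at pseudobulk sample sizes a
  # below-typical gene-wise estimate is noise, and trusting it makes the LRT
  # anticonservative in the far tail
  alpha <- pmax(cfg$dispersion_floor, (1 - w) * raw + w * med, med)
  names(alpha) <- rownames(mat)
  attr(alpha, "flagged") <- rownames(mat)[m <= 0]
  alpha
}

# Newton/IRLS fit of an NB log-linear model with fixed dispersion alpha.
# ridge > 0 adds a small L2 stabilization to the solve (used on separation).
fit_nb_glm <- function(y, X, offset, alpha, ridge = 0, maxit = 100, tol = 1e-12) {
  p <- ncol(X)
  eta0 <- log(pmax(y, 0.5)) - offset
  beta <- tryCatch(stats::lm.fit(X, eta0)$coefficients,
                   error = function(e) rep(0, p))
  beta[is.na(beta)] <- 0
  loglik <- function(b) {
    mu <- exp(pmin(pmax(drop(X %*% b) + offset, -30), 30))
    sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  }
  ll <- loglik(beta)
  conv <- FALSE
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    wt <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    A <- crossprod(X, wt * X)
    if (ridge > 0) A <- A + diag(ridge, p)
    beta_new <- tryCatch(solve(A, crossprod(X, wt * z)),
                         error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new)))
      return(list(beta = beta, ll = ll, converged = FALSE, singular = TRUE))
    beta_new <- drop(beta_new)
    ll_new <- loglik(beta_new)
    if (is.finite(ll) && (!is.finite(ll_new) || ll_new < ll - 1e-10)) {
      dir <- beta_new - beta
      step <- 1
      repeat {
        step <- step / 2
        beta_new <- beta + step * dir
        ll_new <- loglik(beta_new)
        if (is.finite(ll_new) && ll_new >= ll - 1e-10) break
        if (step < 1e-6) break
      }
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (is.finite(ll_new) && abs(ll_new - ll) < tol && delta < 1e-8) {
      ll <- ll_new
      conv <- TRUE
      break
    }
    ll <- ll_new
  }
  list(beta = beta, ll = ll, converged = conv || maxit == 0, singular = FALSE)
}

#' Negative-binomial likelihood-ratio test for one cell type
#'
#' Per gene, fits `log mu = offset + b0 + b_batch + b_age` (full) and the same
#' model without the age term (reduced), with the dispersion fixed at the
#' gene's estimate; `lrt_stat = 2 (ll_full - ll_reduced)` is referred to
#' chi-square with 1 df and `log2fc = b_age / ln 2` (aged vs young, unshrunk).
#' Genes below the `min_total_count` prefilter get `pvalue = NA` and do not
#' count toward the BH multiplicity. Separation or a singular solve triggers a
#' ridge-stabilized refit (penalty 1e-6), flagged in the output.
#'
#' @param pb A `pseudobulk` object.
#' @param dispersions Per-gene dispersions from [estimate_dispersions()].
#' @param cfg A [deg_config()].
#' @return A `DegTable` data.frame: cell_type, gene, log2fc, lrt_stat, pvalue,
#'   fdr (NA until [call_degs()]), direction, mean_expr, flag.
#' @export
nb_lrt <- function(pb, dispersions, cfg = deg_config()) {
  mat <- pb$counts
  samp <- pb$samples
  age <- factor(samp$age_group, levels = c("YOUNG", "AGED"))
  if (length(unique(samp$age_group)) < 2)
    stop("contrast not estimable: age group is constant", call. = FALSE)
  sf <- compute_size_factors(mat)
  offset <- log(sf)
  has_batch <- length(unique(samp$batch)) > 1
  X_red <- if (has_batch) {
    stats::model.matrix(~batch, data.frame(batch = factor(samp$batch)))
  } else {
    matrix(1, ncol(mat), 1, dimnames = list(NULL, "(Intercept)"))
  }
  X_full <- cbind(X_red, ageAGED = as.numeric(age == "AGED"))
  if (qr(X_full)$rank < ncol(X_full))
    stop("contrast not estimable: age is confounded with batch", call. = FALSE)

  norm <- sweep(mat, 2, sf, "/")
  tested <- rowSums(mat) >= cfg$min_total_count
  n_genes <- nrow(mat)
  log2fc <- lrt <- pval <- rep(NA_real_, n_genes)
  flag <- character(n_genes)
  flag[!tested] <- "lowcount"
  k_age <- ncol(X_full)
  for (g in which(tested)) {
    y <- mat[g, ]
    a <- dispersions[[g]]
    sep <- all(y[age == "YOUNG"] == 0) || all(y[age == "AGED"] == 0)
    full <- fit_nb_glm(y, X_full, offset, a)
    red <- fit_nb_glm(y, X_red, offset, a)
    if (sep || full$singular || red$singular ||
        !is.finite(full$ll) || !is.finite(red$ll) ||
        max(abs(full$beta)) > 20) {
      full <- fit_nb_glm(y, X_full, offset, a, ridge = 1e-6)
      red <- fit_nb_glm(y, X_red, offset, a, ridge = 1e-6)
      flag[g] <- "ridge"
    }
    if (!full$converged || !red$converged) {
      flag[g] <- "nonconv"
      next
    }
    log2fc[g] <- full$beta[k_age] / log(2)
    lrt[g] <- max(0, 2 * (full$ll - red$ll))
    pval[g] <- stats::pchisq(lrt[g], df = 1, lower.tail = FALSE)
  }
  data.frame(
    cell_type = pb$cell_type, gene = rownames(mat),
    log2fc = log2fc, lrt_stat = lrt, pvalue = pval, fdr = NA_real_,
    direction = "ns", mean_expr = rowMeans(norm), flag = flag,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Benjamini-Hochberg adjustment with NA pass-through
#'
#' Step-up BH over the non-missing p-values; the multiplicity is the number of
#' tested (non-NA) hypotheses. NAs stay NA.
#'
#' @param pvalues Numeric vector in `[0, 1]` (NAs allowed).
#' @return Adjusted values, elementwise >= input and <= 1.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Call DEG direction at the FDR threshold
#'
#' BH-adjusts p-values within each cell type separately (each cell type is its
#' own testing family) and sets `direction` to `up`/`down` for genes with
#' `fdr < fdr_threshold` (strict) and positive/negative log2 fold change,
#' `ns` otherwise.
#'
#' @param table A `DegTable` from [nb_lrt()] (one or several cell types).
#' @param cfg A [deg_config()].
#' @return The table with `fdr` and `direction` populated; attribute
#'   `summary` holds per-cell-type up/down counts.
#' @export
call_degs <- function(table, cfg = deg_config()) {
  out <- do.call(rbind, lapply(split(table, table$cell_type), function(d) {
    d$fdr <- bh_adjust(d$pvalue)
    d$direction <- ifelse(
      !is.na(d$fdr) & d$fdr < cfg$fdr_threshold,
      ifelse(d$log2fc > 0, "up", ifelse(d$log2fc < 0, "down", "ns")),
      "ns"
    )
    d
  }))
  rownames(out) <- NULL
  tab <- table(out$cell_type, factor(out$direction, c("up", "down", "ns")))
  attr(out, "summary") <- as.data.frame.matrix(tab)
  out
}

#' Full pseudobulk DEG analysis
#'
#' Convenience driver: aggregate to pseudobulk, drop small/unbalanced cell
#' types, estimate dispersions, run the NB LRT per cell type, and call
#' directions at the FDR threshold.
#'
#' @param counts Genes x cells count matrix.
#' @param meta Per-cell metadata.
#' @param cfg A [deg_config()].
#' @return A `DegTable` covering all retained cell types.
#' @export
run_deg <- function(counts, meta, cfg = deg_config()) {
  pbs <- exclude_small_clusters(aggregate_pseudobulk(counts, meta), cfg)
  tabs <- lapply(pbs, function(pb) {
    nb_lrt(pb, estimate_dispersions(pb, cfg), cfg)
  })
  call_degs(do.call(rbind, tabs), cfg)
}
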