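# End-to-end pipeline driver: simulate (or load) -> QC -> pseudobulk DEG ->
# consensus signature -> module & senescence scores -> age-state classifier,
# writing one artifact per stage plus a machine-readable manifest.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations. Every stage seed is derived from the
#' global seed and the stage name via [stage_seed()], so one integer
#' reproduces the whole run.
#'
#' @param seed Global seed.
#' @param synth A [synth_config()] (used when simulating).
#' @param qc A [qc_config()].
#' @param deg A [deg_config()].
#' @param score A [score_config()].
#' @param split A [split_spec()].
#' @param cv Optional [cv_spec()] (`NULL` skips cross-validation).
#' @param min_celltypes Consensus signature support threshold (default 2).
#' @param n_trees Trees for the final forest (default 500).
#' @param senescence_sets Optional named list of gene sets to score.
#' @param train_batch Batch/dataset label to train the classifier on
#'   (`NULL` = the largest batch; forests are trained within one dataset to
#'   avoid pooling across chemistries).
#' @param stages Stages to run, in order.
#' @param run_id Identifier recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, synth = synth_config(),
                            qc = qc_config(), deg = deg_config(),
                            score = score_config(), split = split_spec(),
                            cv = NULL, min_celltypes = 2, n_trees = 500,
                            senescence_sets = NULL, train_batch = NULL,
                            stages = c("qc", "deg", "signature", "score", "classify"),
                            run_id = "lungage-run") {
  synth$seed <- stage_seed(seed, "simulate")
  score$seed <- stage_seed(seed, "score")
  split$seed <- stage_seed(seed, "split")
  if (!is.null(cv)) cv$seed <- stage_seed(seed, "cv")
  structure(list(seed = seed, synth = synth, qc = qc, deg = deg,
                 score = score, split = split, cv = cv,
                 min_celltypes = min_celltypes, n_trees = n_trees,
                 senescence_sets = senescence_sets, train_batch = train_batch,
                 stages = stages, run_id = run_id),
            class = "pipeline_config")
}

log_stage <- function(manifest, stage, info) {
  line <- jsonlite::toJSON(c(list(stage = stage), info), auto_unbox = TRUE,
                           digits = NA)
  cat(line, "\n", file = manifest, append = TRUE, sep = "")
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order, writing each stage's artifact
#' (TSV/GMT/JSON/MTX) under `out_dir` and appending one JSON line per stage
#' to `manifest.jsonl`. Re-running with the same configuration and seed
#' reproduces identical outputs.
#'
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param input_dir Optional MTX bundle to analyze instead of simulating.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(), input_dir = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(out_dir, "manifest.jsonl")
  if (file.exists(manifest)) file.remove(manifest)
  res <- list(config = config)

  if (is.null(input_dir)) {
    d <- generate_dataset(config$synth)
    write_mtx_bundle(d$counts, d$meta, file.path(out_dir, "simulated"), d$truth)
    log_stage(manifest, "simulate", list(seed = config$synth$seed,
                                         n_genes = nrow(d$counts),
                                         n_cells = ncol(d$counts)))
  } else {
    d <- read_mtx_bundle(input_dir)
    log_stage(manifest, "load", list(dir = input_dir, n_genes = nrow(d$counts),
                                     n_cells = ncol(d$counts),
                                     n_unmatched = length(d$unmatched)))
  }
  res$data <- d

  if ("qc" %in% config$stages) {
    f <- filter_cells(d$counts, d$meta, config$qc)
    jsonlite::write_json(f$report, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage(manifest, "qc", f$report[c("n_input", "n_kept")])
    d <- f[c("counts", "meta")]
    res$qc <- f$report
  }
  lognorm <- lognormalize(d$counts, config$qc$lognorm_scale)
  res$lognorm <- lognorm
  res$meta <- d$meta

  degs <- NULL
  if ("deg" %in% config$stages) {
    degs <- run_deg(d$counts, d$meta, config$deg)
    utils::write.table(degs, file.path(out_dir, "deg_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    n_sig <- sum(degs$direction != "ns")
    log_stage(manifest, "deg", list(n_celltypes = length(unique(degs$cell_type)),
                                    n_significant = n_sig))
    res$degs <- degs
  }

  signature <- NULL
  if ("signature" %in% config$stages && !is.null(degs)) {
    mem_up <- build_membership(degs, "up")
    mem_down <- build_membership(degs, "down")
    signature <- consensus_signature(mem_up, mem_down, config$min_celltypes)
    write_signature_gmt(signature, file.path(out_dir, "signature.gmt"))
    upset <- list(up = mem_up$patterns, down = mem_down$patterns,
                  max_sharing_up = max_sharing(mem_up),
                  max_sharing_down = max_sharing(mem_down))
    jsonlite::write_json(upset, file.path(out_dir, "upset_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage(manifest, "signature",
              list(n_up = length(signature$up_genes),
                   n_down = length(signature$down_genes),
                   n_conflicts = length(signature$conflicts)))
    res$signature <- signature
  }

  if ("score" %in% config$stages && !is.null(signature)) {
    sets <- list(aging_up = signature$up_genes, aging_down = signature$down_genes)
    sets <- sets[lengths(sets) >= config$score$min_set_genes_present]
    scores <- do.call(rbind, lapply(names(sets), function(nm) {
      module_score(lognorm, sets[[nm]], config$score, set_name = nm)
    }))
    if (!is.null(config$senescence_sets)) {
      scores <- rbind(scores, senescence_scores(lognorm, config$senescence_sets,
                                                config$score))
    }
    comp <- compare_groups(scores, d$meta, by_celltype = TRUE)
    utils::write.table(scores, file.path(out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(comp, file.path(out_dir, "score_comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage(manifest, "score", list(n_sets = length(unique(scores$set))))
    res$scores <- scores
    res$comparisons <- comp
  }

  if ("classify" %in% config$stages && !is.null(signature) &&
      length(union(signature$up_genes, signature$down_genes)) > 0) {
    meta <- d$meta
    batch <- config$train_batch
    if (is.null(batch)) batch <- names(which.max(table(meta$batch)))
    meta <- meta[meta$batch == batch, , drop = FALSE]
    x <- make_features(lognorm[, meta$cell, drop = FALSE], signature, "all")
    labels <- stats::setNames(meta$age_group, meta$cell)
    sp <- stratified_split(meta, config$split)
    fit <- train_rf(x[sp$train, , drop = FALSE], labels[sp$train],
                    cv = config$cv, n_trees = config$n_trees,
                    seed = stage_seed(config$seed, "rf"))
    report <- evaluate_classifier(
      fit, x[sp$test, , drop = FALSE], labels[sp$test],
      cell_type = meta$cell_type[match(sp$test, meta$cell)])
    imp <- variable_importance(fit, top_k = 20, degs = degs)
    utils::write.table(imp, file.path(out_dir, "importance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(train_batch = batch, auroc = report$auroc,
           accuracy = report$accuracy, cv_auroc_mean = fit$cv_auroc_mean,
           cv_auroc_sd = fit$cv_auroc_sd, n_train = length(sp$train),
           n_test = length(sp$test)),
      file.path(out_dir, "classifier_report.json"),
      auto_unbox = TRUE, digits = NA)
    log_stage(manifest, "classify",
              list(train_batch = batch, auroc = report$auroc,
                   accuracy = report$accuracy))
    res$classifier <- list(fit = fit, report = report, importance = imp,
                           split = sp, train_batch = batch)
  }
  invisible(res)
}
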