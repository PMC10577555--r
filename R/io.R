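# Readers/writers for the 10x-style MTX triplet (MatrixMarket + features +
# barcodes + metadata TSV) and GMT gene sets. MatrixMarket files are 1-based
# on disk per convention; matrices are ordinary R objects in memory.

find_file <- function(dir, base) {
  for (f in c(file.path(dir, base), file.path(dir, paste0(base, ".gz"))))
    if (file.exists(f)) return(f)
  stop(sprintf("missing '%s' (or .gz) in %s", base, dir), call. = FALSE)
}

#' Read a 10x-style MTX bundle with per-cell metadata
#'
#' Expects `matrix.mtx`, `features.tsv`, `barcodes.tsv` (gzipped variants
#' accepted; tab-separated, no header) and a metadata TSV with header
#' `cell, sample, cell_type, age_group, batch, n_features, mito_fraction`.
#' Duplicate feature identifiers are disambiguated by suffixing; gene
#' matching elsewhere in the package is exact and case-sensitive.
#'
#' @param dir Directory containing the bundle.
#' @param metadata Metadata file name (default `"metadata.tsv"`).
#' @return List with `counts` (sparse genes x cells), `meta` (aligned to
#'   columns), and `unmatched` (barcodes absent from the metadata).
#' @export
read_mtx_bundle <- function(dir, metadata = "metadata.tsv") {
  counts <- methods::as(Matrix::readMM(find_file(dir, "matrix.mtx")),
                        "CsparseMatrix")
  feats <- utils::read.delim(find_file(dir, "features.tsv"), header = FALSE,
                             stringsAsFactors = FALSE)
  barcodes <- utils::read.delim(find_file(dir, "barcodes.tsv"), header = FALSE,
                                stringsAsFactors = FALSE)[, 1]
  if (nrow(feats) != nrow(counts) || length(barcodes) != ncol(counts))
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but %d features / %d barcodes",
      nrow(counts), ncol(counts), nrow(feats), length(barcodes)), call. = FALSE)
  ids <- feats[, 1]
  if (anyDuplicated(ids)) {
    message(sum(duplicated(ids)), " duplicate feature ID(s) suffixed")
    ids <- make.unique(ids)
  }
  dimnames(counts) <- list(ids, barcodes)
  meta <- utils::read.delim(find_file(dir, metadata), stringsAsFactors = FALSE)
  if (!all(meta$age_group %in% AGE_LEVELS))
    stop(sprintf("unknown age-group token(s): %s",
                 paste(setdiff(unique(meta$age_group), AGE_LEVELS), collapse = ", ")),
         call. = FALSE)
  unmatched <- setdiff(barcodes, meta$cell)
  if (length(unmatched) > 0) {
    counts <- counts[, colnames(counts) %in% meta$cell, drop = FALSE]
  }
  meta <- meta[match(colnames(counts), meta$cell), , drop = FALSE]
  rownames(meta) <- NULL
  list(counts = counts, meta = meta, unmatched = unmatched)
}

#' Write a 10x-style MTX bundle
#'
#' @param counts Genes x cells count matrix (sparse).
#' @param meta Per-cell metadata.
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth list, written as `ground_truth.json`.
#' @return `dir`, invisibly.
#' @export
write_mtx_bundle <- function(counts, meta, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(rownames(counts), rownames(counts)),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate genes within a set are removed (order-preserving) with a
#' warning; a line with fewer than three fields is an error naming the line.
#'
#' @param path GMT file.
#' @return Named list of character vectors; attribute `descriptions` keeps
#'   the second field per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate gene(s) in set '%s' removed", f[1]))
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @param descriptions Optional named descriptions (default the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(!is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && !is.na(descriptions[nm])) descriptions[nm] else nm
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a signature set as GMT
#'
#' @param signature A `signature_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_signature_gmt <- function(signature, path) {
  write_gmt(
    stats::setNames(
      list(signature$up_genes, signature$down_genes),
      paste0(signature$name, c("_up", "_down"))
    ),
    path,
    descriptions = stats::setNames(
      sprintf("genes %sregulated with age in >= %d cell types", c("up", "down"),
              signature$min_celltypes),
      paste0(signature$name, c("_up", "_down"))
    )
  )
}
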