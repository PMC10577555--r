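# Consensus aging signatures: genes differentially expressed in the same
# direction in at least `min_celltypes` cell types, with upset-style
# intersection accounting over the gene x cell-type membership matrix.

#' Build a gene x cell-type membership matrix for one DEG direction
#'
#' Rows are genes significant in at least one cell type in the given
#' direction; intersection sets are computed by full membership pattern, so
#' each gene contributes to exactly the pattern matching the cell types it is
#' significant in (the columns of an upset plot).
#'
#' @param degs A `DegTable` with directions called ([call_degs()]).
#' @param direction `"up"` or `"down"`.
#' @return A `membership_matrix`: list with logical `matrix` (genes x cell
#'   types), `patterns` data.frame (pattern, size, n_celltypes), `direction`.
#' @export
build_membership <- function(degs, direction = c("up", "down")) {
  direction <- match.arg(direction)
  sig <- degs[degs$direction == direction, , drop = FALSE]
  cts <- sort(unique(degs$cell_type))
  if (nrow(sig) == 0) {
    warning(sprintf("no significant '%s' genes in any cell type", direction))
    m <- matrix(FALSE, 0, length(cts), dimnames = list(character(0), cts))
    patterns <- data.frame(pattern = character(0), size = integer(0),
                           n_celltypes = integer(0), stringsAsFactors = FALSE)
    return(structure(list(matrix = m, patterns = patterns, direction = direction),
                     class = "membership_matrix"))
  }
  genes <- sort(unique(sig$gene))
  m <- matrix(FALSE, length(genes), length(cts), dimnames = list(genes, cts))
  m[cbind(match(sig$gene, genes), match(sig$cell_type, cts))] <- TRUE
  key <- apply(m, 1, function(r) paste(cts[r], collapse = "&"))
  patterns <- data.frame(
    pattern = names(sort(table(key), decreasing = TRUE)),
    stringsAsFactors = FALSE
  )
  patterns$size <- as.integer(table(key)[patterns$pattern])
  patterns$n_celltypes <- lengths(strsplit(patterns$pattern, "&", fixed = TRUE))
  patterns <- patterns[order(-patterns$size, patterns$pattern), , drop = FALSE]
  rownames(patterns) <- NULL
  structure(list(matrix = m, patterns = patterns, direction = direction),
            class = "membership_matrix")
}

#' Extract the consensus up/down aging signature
#'
#' A gene joins the up (down) signature when it is up- (down-) regulated in at
#' least `min_celltypes` cell types. Genes qualifying in both directions (up
#' in some cell types, down in others) are dropped from both lists and
#' reported in `conflicts`. Genes are ordered by descending number of
#' supporting cell types, then lexicographically.
#'
#' @param membership_up,membership_down `membership_matrix` objects.
#' @param min_celltypes Minimum number of supporting cell types (default 2).
#' @param name Signature name.
#' @return A `signature_set`: list with `name`, `up_genes`, `down_genes`,
#'   `min_celltypes`, `conflicts`, `support_up`, `support_down`.
#' @export
consensus_signature <- function(membership_up, membership_down,
                                min_celltypes = 2, name = "LungAge") {
  stopifnot(min_celltypes >= 1)
  pick <- function(mem) {
    if (nrow(mem$matrix) == 0) return(integer(0))
    support <- rowSums(mem$matrix)
    support[support >= min_celltypes]
  }
  sup_up <- pick(membership_up)
  sup_down <- pick(membership_down)
  conflicts <- intersect(names(sup_up), names(sup_down))
  sup_up <- sup_up[setdiff(names(sup_up), conflicts)]
  sup_down <- sup_down[setdiff(names(sup_down), conflicts)]
  order_genes <- function(sup) names(sup)[order(-sup, names(sup))]
  structure(list(
    name = name,
    up_genes = order_genes(sup_up),
    down_genes = order_genes(sup_down),
    min_celltypes = min_celltypes,
    conflicts = sort(conflicts),
    support_up = sup_up[order(-sup_up, names(sup_up))],
    support_down = sup_down[order(-sup_down, names(sup_down))]
  ), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("Signature '%s' (>= %d cell types): %d up, %d down, %d conflicting\n",
              x$name, x$min_celltypes, length(x$up_genes), length(x$down_genes),
              length(x$conflicts)))
  invisible(x)
}

#' Maximum cross-cell-type sharing of a membership matrix
#'
#' The largest number of cell types any single gene is significant in
#' (the reddest column of an upset plot); 0 for an empty matrix.
#'
#' @param membership A `membership_matrix`.
#' @return Integer.
#' @export
max_sharing <- function(membership) {
  if (nrow(membership$matrix) == 0) return(0L)
  as.integer(max(rowSums(membership$matrix)))
}
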