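# shared internal helpers

AGE_LEVELS <- c("YOUNG", "MIDDLE", "AGED")

#' Derive a stage-specific seed from a global seed
#'
#' Splits one global integer seed into reproducible per-stage substreams by
#' hashing the stage name into the seed. Every randomized step in the package
#' (simulation, control-gene sampling, data splits, forest training) draws its
#' seed this way, so a single pipeline seed determines the whole run while
#' stages stay independently reproducible.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name, e.g. `"simulate"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stage_seed(1, "simulate")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stage), length(stage) == 1L)
  h <- abs(seed) %% 2147483647
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# meta rows must match count matrix columns; returns meta reordered to columns
align_meta <- function(counts, meta) {
  if (is.null(colnames(counts)) || is.null(meta$cell) ||
      !setequal(colnames(counts), meta$cell) || anyDuplicated(meta$cell)) {
    stop("cell metadata does not match count matrix columns", call. = FALSE)
  }
  meta[match(colnames(counts), meta$cell), , drop = FALSE]
}

row_vars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / max(1L, ncol(x) - 1L)
}
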