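#' Paired multiome dataset for one homogeneous cell population
#'
#' Container for a matched scATAC-seq cell-by-peak count matrix and
#' scRNA-seq cell-by-gene count matrix, together with peak intervals and
#' gene annotations. Both matrices share the same cells in the same order.
#'
#' @param X sparse non-negative integer matrix, cells x peaks (ATAC counts).
#' @param Y sparse non-negative integer matrix, cells x genes (RNA counts).
#' @param cell_ids character vector of cell barcodes, length `nrow(X)`.
#' @param peaks tibble with columns `peak_id`, `chrom`, `start`, `end`
#'   (0-based half-open, BED convention), one row per column of `X`.
#' @param genes tibble with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand`, one row per column of `Y`.
#'
#' @return An object of class `multiome_dataset`: a list with elements
#'   `X`, `Y`, `cell_ids`, `peaks`, `genes`.
#' @export
#' @examples
#' sim <- simulate_multiome(synthetic_config(n_cells = 40, n_peaks = 30,
#'                                           n_genes = 8, seed = 1))
#' ds <- sim$dataset
#' dim(ds$X)
multiome_dataset <- function(X, Y, cell_ids, peaks, genes) {
  X <- as_dgc(X)
  Y <- as_dgc(Y)
  peaks <- tibble::as_tibble(peaks)
  genes <- tibble::as_tibble(genes)
  ds <- structure(
    list(X = X, Y = Y, cell_ids = as.character(cell_ids),
         peaks = peaks, genes = genes),
    class = "multiome_dataset"
  )
  validate_multiome_dataset(ds)
}

validate_multiome_dataset <- function(ds) {
  assert_that(nrow(ds$X) == nrow(ds$Y),
              "X and Y must have the same number of cells (%d vs %d)",
              nrow(ds$X), nrow(ds$Y))
  assert_that(nrow(ds$X) == length(ds$cell_ids),
              "cell_ids length (%d) must match cell count (%d)",
              length(ds$cell_ids), nrow(ds$X))
  assert_that(ncol(ds$X) == nrow(ds$peaks),
              "peaks table (%d rows) must match ncol(X) = %d",
              nrow(ds$peaks), ncol(ds$X))
  assert_that(ncol(ds$Y) == nrow(ds$genes),
              "genes table (%d rows) must match ncol(Y) = %d",
              nrow(ds$genes), ncol(ds$Y))
  assert_that(all(c("peak_id", "chrom", "start", "end") %in% names(ds$peaks)),
              "peaks must have columns peak_id, chrom, start, end")
  assert_that(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                    names(ds$genes)),
              "genes must have columns gene_id, chrom, start, end, strand")
  assert_that(is_nonneg(ds$X) && is_nonneg(ds$Y),
              "count matrices must be non-negative")
  assert_that(all(ds$peaks$start < ds$peaks$end),
              "peak intervals must satisfy start < end")
  assert_that(all(ds$genes$start < ds$genes$end),
              "gene intervals must satisfy start < end")
  assert_that(all(ds$genes$strand %in% c("+", "-")),
              "gene strand must be '+' or '-'")
  assert_that(!anyDuplicated(ds$peaks$peak_id) && !anyDuplicated(ds$genes$gene_id),
              "feature ids must be unique")
  key <- paste(ds$peaks$chrom, ds$peaks$start, ds$peaks$end)
  assert_that(!anyDuplicated(key), "duplicate peak intervals are not allowed")
  colnames(ds$X) <- ds$peaks$peak_id
  colnames(ds$Y) <- ds$genes$gene_id
  rownames(ds$X) <- rownames(ds$Y) <- ds$cell_ids
  ds
}

#' @method print multiome_dataset
#' @export
print.multiome_dataset <- function(x, ...) {
  cat(sprintf(
    "multiome_dataset: %d cells, %d peaks (ATAC), %d genes (RNA)\n",
    nrow(x$X), ncol(x$X), ncol(x$Y)))
  cat(sprintf("  ATAC nonzero fraction: %.3f; RNA nonzero fraction: %.3f\n",
              length(x$X@x) / prod(dim(x$X)),
              length(x$Y@x) / prod(dim(x$Y))))
  invisible(x)
}

#' @export
dim.multiome_dataset <- function(x) {
  c(cells = nrow(x$X), peaks = ncol(x$X), genes = ncol(x$Y))
}

## subset cells (integer/logical index), keeping both modalities aligned
subset_cells <- function(ds, idx) {
  if (is.logical(idx)) idx <- which(idx)
  assert_that(length(idx) > 0, "all cells removed: empty dataset")
  multiome_dataset(ds$X[idx, , drop = FALSE], ds$Y[idx, , drop = FALSE],
                   ds$cell_ids[idx], ds$peaks, ds$genes)
}

## subset features, keeping annotation tables aligned
subset_features <- function(ds, peak_idx = NULL, gene_idx = NULL) {
  if (is.null(peak_idx)) peak_idx <- seq_len(ncol(ds$X))
  if (is.null(gene_idx)) gene_idx <- seq_len(ncol(ds$Y))
  if (is.logical(peak_idx)) peak_idx <- which(peak_idx)
  if (is.logical(gene_idx)) gene_idx <- which(gene_idx)
  assert_that(length(peak_idx) > 0, "all peaks removed: empty dataset")
  assert_that(length(gene_idx) > 0, "all genes removed: empty dataset")
  multiome_dataset(ds$X[, peak_idx, drop = FALSE],
                   ds$Y[, gene_idx, drop = FALSE],
                   ds$cell_ids,
                   ds$peaks[peak_idx, , drop = FALSE],
                   ds$genes[gene_idx, , drop = FALSE])
}
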