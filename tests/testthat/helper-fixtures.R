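## shared fixtures and small utilities for the test suite

## tiny paired dataset built directly (no generator), 6 cells x 4 peaks x 3 genes
tiny_dataset <- function() {
  X <- Matrix::Matrix(matrix(c(
    1, 0, 2, 1,
    0, 1, 1, 0,
    2, 1, 0, 1,
    1, 2, 1, 0,
    0, 1, 0, 2,
    1, 0, 1, 1), 6, 4, byrow = TRUE), sparse = TRUE)
  Y <- Matrix::Matrix(matrix(c(
    3, 1, 0,
    2, 0, 1,
    5, 2, 1,
    1, 1, 2,
    2, 3, 0,
    4, 1, 1), 6, 3, byrow = TRUE), sparse = TRUE)
  peaks <- tibble::tibble(
    peak_id = paste0("p", 1:4), chrom = "chr1",
    start = c(1000, 5000, 9000, 13000), end = c(1500, 5500, 9500, 13500))
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:3), symbol = paste0("G", 1:3), chrom = "chr1",
    start = c(2000, 6000, 10000), end = c(4000, 8000, 12000),
    strand = c("+", "-", "+"))
  multiome_dataset(X, Y, paste0("c", 1:6), peaks, genes)
}

## small simulated dataset for stage tests (fast)
small_sim <- function(seed = 1, ...) {
  simulate_multiome(synthetic_config(
    n_cells = 150L, n_peaks = 60L, n_genes = 12L, n_linked_genes = 6L,
    n_modules = 3L, peak_block_size = 6L, chrom_count = 2L,
    genome_length = 3e5, seed = seed, ...))
}

## rank-based AUROC without external dependencies
auroc <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## all (gene, peak) pairs inside the cis windows of a dataset
window_pairs <- function(ds, window_bp = 1e5) {
  dplyr::bind_rows(lapply(seq_len(nrow(ds$genes)), function(j) {
    idx <- candidate_peaks(ds$genes[j, ], ds$peaks, window_bp)
    if (length(idx) == 0) return(NULL)
    tibble::tibble(gene_id = ds$genes$gene_id[j],
                   peak_id = ds$peaks$peak_id[idx])
  }))
}

## planted-vs-decoy AUROC of a pipeline result within the cis windows
planted_auroc <- function(res, truth, window_bp = 1e5) {
  ds <- res$prep$dataset
  wins <- window_pairs(ds, window_bp)
  key <- paste(wins$gene_id, wins$peak_id)
  lab <- key %in% paste(truth$links$gene_id, truth$links$peak_id)
  d <- res$ranking$distance[match(key, paste(res$ranking$gene_id,
                                             res$ranking$peak_id))]
  list(auroc = auroc(lab, -d),
       gap = mean(d[!lab]) - mean(d[lab]))
}

## small hand-built transition set over 3 peaks and 2 genes, no dead rows
toy_transitions <- function() {
  Wpp <- Matrix::Matrix(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3),
                        sparse = TRUE)
  Wgg <- Matrix::Matrix(matrix(c(0, 3, 3, 0), 2, 2), sparse = TRUE)
  Wpg <- Matrix::Matrix(matrix(c(1, 0, 2, 1, 1, 3), 3, 2), sparse = TRUE)
  net <- joint_network(Wpp, Wgg,
                       list(lasso = Wpg, rf = Wpg, xgboost = Wpg),
                       paste0("p", 1:3), paste0("g", 1:2))
  build_transition_set(net)
}
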