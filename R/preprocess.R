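#' QC parameter set
#'
#' Thresholds for cell- and feature-level quality control. Count-range
#' thresholds left `NULL` default to the 1st and 99th percentiles of the
#' per-cell totals of the dataset being filtered.
#'
#' @param min_rna_counts,max_rna_counts per-cell RNA count bounds.
#' @param min_atac_counts,max_atac_counts per-cell ATAC count bounds.
#' @param max_mito_fraction cells above this mitochondrial read fraction
#'   are removed (default 0.20).
#' @param min_cells_peak peaks detected in fewer cells are removed
#'   (default 5).
#' @param min_frac_gene genes detected in a smaller fraction of cells are
#'   removed (default 0.01).
#' @param n_hvg number of highly variable genes to retain (default 3000;
#'   capped at the number of genes present).
#' @param blacklist optional tibble of intervals (`chrom`, `start`, `end`,
#'   0-based half-open); features overlapping any are removed. Empty by
#'   default so synthetic data needs no genome files.
#' @return list of class `qc_params`.
#' @export
qc_params <- function(min_rna_counts = NULL, max_rna_counts = NULL,
                      min_atac_counts = NULL, max_atac_counts = NULL,
                      max_mito_fraction = 0.20, min_cells_peak = 5L,
                      min_frac_gene = 0.01, n_hvg = 3000L,
                      blacklist = NULL) {
  assert_that(max_mito_fraction >= 0 && max_mito_fraction <= 1,
              "max_mito_fraction must lie in [0, 1]")
  assert_that(min_cells_peak >= 0 && min_frac_gene >= 0 && n_hvg > 0,
              "QC thresholds must be non-negative")
  structure(as.list(environment()), class = "qc_params")
}

## standard chromosomes kept after filtering: autosomes only (X, Y and
## mitochondrial features are explicitly dropped)
is_standard_autosome <- function(chrom) {
  grepl("^(chr)?[0-9]+$", chrom)
}

#' Cell-level quality control
#'
#' Removes cells whose RNA or ATAC totals fall outside the configured
#' range, and cells whose mitochondrial read fraction exceeds the cutoff.
#'
#' @param ds a [multiome_dataset()].
#' @param mito_fraction numeric vector in `[0, 1]`, one value per cell;
#'   defaults to all zeros (no mitochondrial information).
#' @param qc a [qc_params()].
#' @param verbose log removal counts.
#' @return the filtered [multiome_dataset()].
#' @export
filter_cells <- function(ds, mito_fraction = NULL, qc = qc_params(),
                         verbose = FALSE) {
  n <- nrow(ds$X)
  mito_fraction <- mito_fraction %||% numeric(n)
  assert_that(length(mito_fraction) == n,
              "mito_fraction has length %d but there are %d cells",
              length(mito_fraction), n)
  assert_that(all(mito_fraction >= 0 & mito_fraction <= 1),
              "mito_fraction values must lie in [0, 1]")
  rna_tot <- Matrix::rowSums(ds$Y)
  atac_tot <- Matrix::rowSums(ds$X)
  bounds <- function(tot, lo, hi) {
    c(lo %||% unname(quantile(tot, 0.01)), hi %||% unname(quantile(tot, 0.99)))
  }
  br <- bounds(rna_tot, qc$min_rna_counts, qc$max_rna_counts)
  ba <- bounds(atac_tot, qc$min_atac_counts, qc$max_atac_counts)
  keep <- rna_tot >= br[1] & rna_tot <= br[2] &
    atac_tot >= ba[1] & atac_tot <= ba[2] &
    mito_fraction <= qc$max_mito_fraction
  if (verbose)
    message(sprintf("filter_cells: removed %d of %d cells", sum(!keep), n))
  assert_that(any(keep), "all cells removed by cell-level QC")
  if (all(keep)) return(ds)
  subset_cells(ds, keep)
}

## TRUE for features overlapping any blacklist interval (half-open)
in_blacklist <- function(chrom, start, end, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0)
    return(logical(length(chrom)))
  hit <- logical(length(chrom))
  for (r in seq_len(nrow(blacklist))) {
    hit <- hit | (chrom == blacklist$chrom[r] &
                    intervals_overlap(start, end,
                                      blacklist$start[r], blacklist$end[r]))
  }
  hit
}

#' Feature-level quality control
#'
#' Removes peaks and genes on sex or mitochondrial chromosomes or any
#' nonstandard contig, features overlapping blacklist intervals, peaks
#' detected in fewer than `min_cells_peak` cells, and genes detected in
#' fewer than `min_frac_gene` of cells.
#'
#' @inheritParams filter_cells
#' @return the filtered [multiome_dataset()].
#' @export
filter_features <- function(ds, qc = qc_params(), verbose = FALSE) {
  assert_that(!anyNA(ds$peaks$chrom) && !anyNA(ds$genes$chrom),
              "missing chromosome annotation")
  n <- nrow(ds$X)
  peak_det <- Matrix::colSums(ds$X > 0)
  gene_det <- Matrix::colSums(ds$Y > 0)
  keep_peak <- is_standard_autosome(ds$peaks$chrom) &
    !in_blacklist(ds$peaks$chrom, ds$peaks$start, ds$peaks$end, qc$blacklist) &
    peak_det >= qc$min_cells_peak
  keep_gene <- is_standard_autosome(ds$genes$chrom) &
    !in_blacklist(ds$genes$chrom, ds$genes$start, ds$genes$end, qc$blacklist) &
    gene_det >= qc$min_frac_gene * n
  if (verbose)
    message(sprintf("filter_features: removed %d of %d peaks, %d of %d genes",
                    sum(!keep_peak), length(keep_peak),
                    sum(!keep_gene), length(keep_gene)))
  if (all(keep_peak) && all(keep_gene)) return(ds)
  subset_features(ds, keep_peak, keep_gene)
}

## standardized dispersion: var/mean dispersion of the log-normalized
## values, z-scored within 20 bins of the per-gene mean (mean-variance
## trend removal)
hvg_dispersion <- function(L, n_bins = 20L) {
  m <- colMeans(L)
  v <- apply(L, 2, var)
  disp <- ifelse(m > 0, v / m, 0)
  ## keep several genes per bin so the within-bin spread is estimable
  n_bins <- max(1L, min(n_bins, floor(length(m) / 5)))
  bins <- cut(m, breaks = unique(quantile(m, seq(0, 1, length.out = n_bins + 1))),
              include.lowest = TRUE)
  z <- numeric(length(disp))
  for (b in levels(bins)) {
    idx <- which(bins == b)
    mu <- mean(disp[idx]); s <- sd(disp[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (disp[idx] - mu) / s
  }
  z
}

#' Library-size normalization, log transform, scaling and HVG selection
#'
#' Per-cell counts are scaled to a common target sum, log1p-transformed,
#' and the most variable genes are selected by a trend-standardized
#' dispersion statistic; the selected columns are then z-scaled per gene.
#'
#' @param Y cell-by-gene count matrix (sparse or dense, non-negative).
#' @param n_hvg number of highly variable genes to retain (capped at
#'   `ncol(Y)`).
#' @param target_sum per-cell total after library-size normalization.
#' @return list with `Y_norm` (dense cells x HVG matrix, per-gene mean 0 /
#'   sd 1 for non-constant genes), `hvg_index` (column indices into `Y`,
#'   ordered by decreasing standardized dispersion), and `stats` (tibble
#'   with per-gene mean, dispersion and standardized dispersion).
#' @export
normalize_rna <- function(Y, n_hvg = 3000L, target_sum = 1e4) {
  tot <- Matrix::rowSums(Y)
  assert_that(all(tot > 0), "cells with zero total RNA count present; run QC first")
  n_hvg <- min(n_hvg, ncol(Y))
  L <- as.matrix(Matrix::Diagonal(x = target_sum / tot) %*% Y)
  L <- log1p(L)
  z <- hvg_dispersion(L)
  ord <- order(z, decreasing = TRUE)
  hvg_index <- sort(ord[seq_len(n_hvg)])
  Ln <- L[, hvg_index, drop = FALSE]
  mu <- colMeans(Ln)
  sdv <- apply(Ln, 2, sd)
  sdv[sdv == 0] <- 1          # constant gene -> all-zero scaled column
  Y_norm <- sweep(sweep(Ln, 2, mu), 2, sdv, "/")
  colnames(Y_norm) <- colnames(Y)[hvg_index]
  list(Y_norm = Y_norm, hvg_index = hvg_index,
       stats = tibble::tibble(gene_index = seq_len(ncol(Y)),
                              mean = colMeans(L),
                              std_dispersion = z))
}

#' TF-IDF transform of the peak count matrix
#'
#' Term frequency is each count divided by its cell total; inverse document
#' frequency is `log(1 + n / (1 + n_cells_detected))` per peak. The
#' sparsity pattern is preserved.
#'
#' @param X cell-by-peak count matrix (sparse, non-negative, no all-zero
#'   cells).
#' @return sparse matrix of TF-IDF weights with the same dimensions.
#' @export
tfidf_transform <- function(X) {
  X <- as_dgc(X)
  tot <- Matrix::rowSums(X)
  assert_that(all(tot > 0), "cells with zero total ATAC count present; run QC first")
  n <- nrow(X)
  df <- Matrix::colSums(X > 0)
  idf <- log(1 + n / (1 + df))
  tf <- Matrix::Diagonal(x = 1 / tot) %*% X
  as_dgc(tf %*% Matrix::Diagonal(x = idf))
}

#' Full preprocessing of a paired multiome dataset
#'
#' Applies cell QC, feature QC, RNA normalization with HVG selection and
#' ATAC TF-IDF, returning everything the network stage needs.
#'
#' @inheritParams filter_cells
#' @return list of class `multiome_preprocessed` with elements `dataset`
#'   (filtered [multiome_dataset()] restricted to HVGs), `X_tfidf`,
#'   `Y_hvg` (dense normalized HVG matrix), `hvg_index`, and `qc`.
#' @export
preprocess_multiome <- function(ds, mito_fraction = NULL, qc = qc_params(),
                                verbose = FALSE) {
  ds <- filter_cells(ds, mito_fraction, qc, verbose = verbose)
  ds <- filter_features(ds, qc, verbose = verbose)
  ## drop cells emptied by feature filtering before normalization
  nonzero <- Matrix::rowSums(ds$Y) > 0 & Matrix::rowSums(ds$X) > 0
  if (!all(nonzero)) ds <- subset_cells(ds, nonzero)
  nr <- normalize_rna(ds$Y, qc$n_hvg)
  ds <- subset_features(ds, gene_idx = nr$hvg_index)
  structure(
    list(dataset = ds, X_tfidf = tfidf_transform(ds$X), Y_hvg = nr$Y_norm,
         hvg_index = nr$hvg_index, qc = qc),
    class = "multiome_preprocessed")
}

#' @method print multiome_preprocessed
#' @export
print.multiome_preprocessed <- function(x, ...) {
  cat(sprintf("multiome_preprocessed: %d cells, %d peaks, %d HVGs\n",
              nrow(x$X_tfidf), ncol(x$X_tfidf), ncol(x$Y_hvg)))
  invisible(x)
}
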