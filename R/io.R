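#' Read a paired multiome dataset from standard files
#'
#' Expects Matrix Market count matrices with matching barcode and feature
#' files: peaks as BED3/BED4 and genes as a GTF (gene records) or an
#' annotation TSV/BED6. Matrices stored features-by-cells (the common
#' convention) are transposed automatically.
#'
#' @param atac_mtx,rna_mtx paths to Matrix Market count files.
#' @param peaks_bed path to the peak BED file (0-based half-open).
#' @param genes_file path to a GTF (`.gtf`) or a TSV with columns
#'   `gene_id`, `symbol`, `chrom`, `start`, `end`, `strand`.
#' @param barcodes_tsv path to the cell barcode list (one per line).
#' @return a [multiome_dataset()].
#' @export
read_multiome <- function(atac_mtx, peaks_bed, rna_mtx, genes_file,
                          barcodes_tsv) {
  barcodes <- readr::read_tsv(barcodes_tsv, col_names = "barcode",
                              show_col_types = FALSE)$barcode
  peaks <- read_peaks_bed(peaks_bed)
  genes <- read_gene_annotation(genes_file)
  orient <- function(M, n_feat) {
    M <- as_dgc(M)
    if (nrow(M) == n_feat && ncol(M) == length(barcodes)) Matrix::t(M)
    else M
  }
  X <- orient(Matrix::readMM(atac_mtx), nrow(peaks))
  Y <- orient(Matrix::readMM(rna_mtx), nrow(genes))
  multiome_dataset(X, Y, barcodes, peaks, genes)
}

#' Read peak intervals from a BED file
#'
#' @param path BED3/BED4 file, 0-based half-open coordinates.
#' @return tibble (`peak_id`, `chrom`, `start`, `end`); ids default to
#'   `chrom:start-end` when the name column is absent.
#' @export
read_peaks_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE)
  assert_that(ncol(bed) >= 3, "BED file needs at least 3 columns")
  tibble::tibble(
    peak_id = if (ncol(bed) >= 4) as.character(bed[[4]])
              else sprintf("%s:%d-%d", bed[[1]], bed[[2]], bed[[3]]),
    chrom = as.character(bed[[1]]),
    start = as.integer(bed[[2]]), end = as.integer(bed[[3]]))
}

#' Read gene annotations from GTF or tabular files
#'
#' GTF `gene` records are parsed with rtracklayer and converted to
#' 0-based half-open coordinates; `.tsv` files must carry the annotation
#' columns directly; anything else is treated as BED6 (name = gene id).
#'
#' @param path annotation file path.
#' @return tibble (`gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `strand`).
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      abort_input("reading GTF requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    tibble::tibble(
      gene_id = gr$gene_id,
      symbol = if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # GTF is 1-based closed
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)))
  } else if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    tb <- readr::read_tsv(path, show_col_types = FALSE)
    assert_that(all(c("gene_id", "chrom", "start", "end", "strand") %in%
                      names(tb)), "gene TSV is missing annotation columns")
    if (is.null(tb$symbol)) tb$symbol <- tb$gene_id
    tibble::as_tibble(tb[, c("gene_id", "symbol", "chrom", "start", "end",
                             "strand")])
  } else {
    bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                           show_col_types = FALSE)
    assert_that(ncol(bed) >= 6, "BED gene annotation needs 6 columns")
    tibble::tibble(gene_id = as.character(bed[[4]]),
                   symbol = as.character(bed[[4]]),
                   chrom = as.character(bed[[1]]),
                   start = as.integer(bed[[2]]), end = as.integer(bed[[3]]),
                   strand = as.character(bed[[6]]))
  }
}

#' Write a paired multiome dataset to a directory
#'
#' Writes `atac.mtx` and `rna.mtx` (features by cells), `barcodes.tsv`,
#' `peaks.bed` and `genes.tsv` in the layout [read_multiome()] accepts.
#'
#' @param ds a [multiome_dataset()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_multiome <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(ds$X), file.path(dir, "atac.mtx"))
  Matrix::writeMM(Matrix::t(ds$Y), file.path(dir, "rna.mtx"))
  readr::write_tsv(tibble::tibble(barcode = ds$cell_ids),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(ds$peaks[, c("chrom", "start", "end", "peak_id")],
                   file.path(dir, "peaks.bed"), col_names = FALSE)
  readr::write_tsv(ds$genes, file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' Load a dataset written by [write_multiome()]
#'
#' @param dir the dataset directory.
#' @return a [multiome_dataset()].
#' @export
read_multiome_dir <- function(dir) {
  read_multiome(file.path(dir, "atac.mtx"), file.path(dir, "peaks.bed"),
                file.path(dir, "rna.mtx"), file.path(dir, "genes.tsv"),
                file.path(dir, "barcodes.tsv"))
}

#' Write the joint network as Matrix Market files plus node lists
#'
#' @param net a [joint_network()].
#' @param dir output directory.
#' @return the directory path, invisibly.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(net$Wpp, file.path(dir, "Wpp.mtx"))
  Matrix::writeMM(net$Wgg, file.path(dir, "Wgg.mtx"))
  for (m in names(net$Wpg))
    Matrix::writeMM(net$Wpg[[m]], file.path(dir, sprintf("Wpg_%s.mtx", m)))
  readr::write_tsv(tibble::tibble(peak_id = net$peak_ids),
                   file.path(dir, "peaks.tsv"))
  readr::write_tsv(tibble::tibble(gene_id = net$gene_ids),
                   file.path(dir, "genes.tsv"))
  invisible(dir)
}

#' Write training pairs and meta-path walks as TSV
#'
#' @param pairs a [generate_training_pairs()] result.
#' @param dir output directory.
#' @return the directory path, invisibly.
#' @export
write_training_pairs <- function(pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(pairs$E, file.path(dir, "pairs.tsv"))
  readr::write_tsv(pairs$Lpeak, file.path(dir, "walks_peak.tsv"))
  readr::write_tsv(pairs$Lgene, file.path(dir, "walks_gene.tsv"))
  invisible(dir)
}

#' Write an embedding as TSV
#'
#' One row per node: `node_id`, `type`, then the embedding coordinates.
#'
#' @param emb a [train_embedding()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_embedding <- function(emb, path) {
  readr::write_tsv(tidy(emb), path)
  invisible(path)
}
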