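#' Configuration for the synthetic paired-multiome generator
#'
#' Bundles the geometry, signal and noise parameters of the simulator.
#' Defaults describe the benchmark condition used throughout the package's
#' own validation: 500 cells, 200 peaks on two synthetic chromosomes,
#' 40 genes of which 20 carry one planted cis-regulatory peak each, strong
#' regulatory effect and mild dropout.
#'
#' @param n_cells number of cells.
#' @param n_peaks number of ATAC peaks, laid out uniformly along the genome.
#' @param n_genes number of RNA genes.
#' @param n_modules number of gene co-expression modules; each module is
#'   driven by one latent per-cell factor.
#' @param n_linked_genes number of genes that receive planted regulatory
#'   peaks (the remaining genes are nulls driven only by their module).
#' @param links_per_gene planted peaks per linked gene.
#' @param peak_block_size contiguous peaks per co-accessibility block; each
#'   block is tied to one module factor so block members open together.
#' @param chrom_count number of synthetic chromosomes.
#' @param genome_length length in bp of each synthetic chromosome.
#' @param peak_width width in bp of each peak interval.
#' @param gene_width width in bp of each gene body (kept short relative to
#'   the cis window so window logic is exercised).
#' @param window_bp cis window radius; planted links are guaranteed to lie
#'   within `gene body +/- window_bp`.
#' @param effect_size multiplier of the planted peak's latent accessibility
#'   signal on the log-mean expression of its target gene.
#' @param block_signal,peak_signal logit-scale weights of the shared block
#'   factor and the peak-specific factor on accessibility; the
#'   peak-specific part is what makes a planted peak identifiable among its
#'   block mates.
#' @param base_logit baseline accessibility log-odds.
#' @param module_signal weight of the module factor on gene log-expression.
#' @param log_mu0 baseline log mean RNA count.
#' @param noise_dispersion negative-binomial dispersion of RNA counts
#'   (variance = mu + dispersion * mu^2).
#' @param dropout_atac,dropout_rna probability that any single sequenced
#'   count unit is lost (binomial thinning), per modality.
#' @param seed integer seed; the generator is fully deterministic given it.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cells = 500L, n_peaks = 200L, n_genes = 40L,
                             n_modules = 4L, n_linked_genes = 20L,
                             links_per_gene = 1L, peak_block_size = 10L,
                             chrom_count = 2L, genome_length = 1e6,
                             peak_width = 500L, gene_width = 2000L,
                             window_bp = 1e5, effect_size = 3,
                             block_signal = 1.5, peak_signal = 1.5,
                             base_logit = -1.5, module_signal = 1,
                             log_mu0 = 0.5, noise_dispersion = 0.5,
                             dropout_atac = 0.1, dropout_rna = 0.1,
                             seed = 1L) {
  cfg <- as.list(environment())
  assert_that(all(unlist(cfg[c("n_cells", "n_peaks", "n_genes", "n_modules",
                               "links_per_gene", "peak_block_size",
                               "chrom_count")]) > 0),
              "all count parameters must be positive")
  assert_that(dropout_atac >= 0 && dropout_atac < 1 &&
                dropout_rna >= 0 && dropout_rna < 1,
              "dropout rates must lie in [0, 1)")
  assert_that(n_linked_genes <= n_genes,
              "n_linked_genes cannot exceed n_genes")
  structure(cfg, class = "synthetic_config")
}

#' Simulate a paired multiome dataset with planted ground truth
#'
#' Generates matched ATAC and RNA count matrices from a shared latent
#' per-cell state. Contiguous peak blocks open together (co-accessibility),
#' genes fall into co-expression modules, and each linked gene's expression
#' additionally follows the latent accessibility of its planted peaks, all
#' laid out so planted links respect the cis window and share it with decoy
#' peaks.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with elements `dataset` (a [multiome_dataset()]) and
#'   `truth` (list with tibble `links`, list `peak_blocks`, list
#'   `gene_modules`).
#' @export
#' @examples
#' sim <- simulate_multiome(synthetic_config(n_cells = 50, n_peaks = 40,
#'                                           n_genes = 10, seed = 7))
#' sim$truth$links
simulate_multiome <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)

  ## --- genome layout: uniformly spaced peaks over chrom_count chromosomes
  per_chrom <- ceiling(cfg$n_peaks / cfg$chrom_count)
  spacing <- floor(cfg$genome_length / (per_chrom + 1))
  assert_that(spacing > cfg$peak_width,
              "genome too short for the requested peak count")
  peak_chrom <- rep(paste0("chr", seq_len(cfg$chrom_count)),
                    each = per_chrom)[seq_len(cfg$n_peaks)]
  peak_start <- rep(spacing * seq_len(per_chrom),
                    times = cfg$chrom_count)[seq_len(cfg$n_peaks)]
  peaks <- tibble::tibble(
    peak_id = sprintf("peak_%03d", seq_len(cfg$n_peaks)),
    chrom = peak_chrom, start = peak_start,
    end = peak_start + cfg$peak_width)

  ## peak blocks: contiguous runs within a chromosome, each tied to a module
  block_of <- integer(cfg$n_peaks)
  b <- 0L
  for (ch in unique(peak_chrom)) {
    idx <- which(peak_chrom == ch)
    nb <- ceiling(length(idx) / cfg$peak_block_size)
    block_of[idx] <- b + rep(seq_len(nb),
                             each = cfg$peak_block_size)[seq_along(idx)]
    b <- b + nb
  }
  n_blocks <- max(block_of)

  ## --- gene layout: bodies centered on a planted peak neighborhood so the
  ## cis window always contains the planted peaks plus decoys
  gene_module <- rep_len(seq_len(cfg$n_modules), cfg$n_genes)
  linked <- seq_len(cfg$n_linked_genes)
  gene_chrom <- character(cfg$n_genes)
  gene_start <- numeric(cfg$n_genes)
  planted <- vector("list", cfg$n_genes)
  anchor_pool <- seq_len(cfg$n_peaks)
  for (j in seq_len(cfg$n_genes)) {
    anchor <- sample(anchor_pool, 1L)
    gene_chrom[j] <- peaks$chrom[anchor]
    gene_start[j] <- max(1, peaks$start[anchor] + sample(-5000:5000, 1L))
    if (j %in% linked) {
      win_lo <- gene_start[j] - cfg$window_bp
      win_hi <- gene_start[j] + cfg$gene_width + cfg$window_bp
      cand <- which(peaks$chrom == gene_chrom[j] &
                      intervals_overlap(peaks$start, peaks$end, win_lo, win_hi))
      assert_that(length(cand) >= cfg$links_per_gene,
                  "infeasible geometry: gene %d has %d candidate peaks but needs %d",
                  j, length(cand), cfg$links_per_gene)
      planted[[j]] <- sort(sample(cand, cfg$links_per_gene))
    } else {
      planted[[j]] <- integer(0)
    }
  }
  genes <- tibble::tibble(
    gene_id = sprintf("gene_%03d", seq_len(cfg$n_genes)),
    symbol = sprintf("Gene%d", seq_len(cfg$n_genes)),
    chrom = gene_chrom, start = gene_start,
    end = gene_start + cfg$gene_width,
    strand = rep_len(c("+", "-"), cfg$n_genes))

  ## --- latent state and accessibility: each co-accessibility block has its
  ## own per-cell factor (block-diagonal structure), genes their module
  ## factors, peaks an idiosyncratic component that makes a planted peak
  ## identifiable among its block mates
  n <- cfg$n_cells
  Z <- matrix(rnorm(n * cfg$n_modules), n, cfg$n_modules)  # gene modules
  Zb <- matrix(rnorm(n * n_blocks), n, n_blocks)           # peak blocks
  U <- matrix(rnorm(n * cfg$n_peaks), n, cfg$n_peaks)      # peak-specific
  eta <- cfg$base_logit +
    cfg$block_signal * Zb[, block_of, drop = FALSE] +
    cfg$peak_signal * U
  p_open <- stats::plogis(eta)
  X <- matrix(stats::rbinom(n * cfg$n_peaks, 2L, p_open), n, cfg$n_peaks)
  if (cfg$dropout_atac > 0)
    X <- matrix(stats::rbinom(length(X), X, 1 - cfg$dropout_atac), n)

  ## --- RNA: module baseline plus planted-peak latent signal
  log_mu <- matrix(cfg$log_mu0, n, cfg$n_genes) +
    cfg$module_signal * Z[, gene_module, drop = FALSE]
  for (j in linked) {
    sig <- rowMeans(eta[, planted[[j]], drop = FALSE])
    log_mu[, j] <- log_mu[, j] + cfg$effect_size * scale(sig)[, 1]
  }
  size <- 1 / cfg$noise_dispersion
  Y <- matrix(stats::rnbinom(n * cfg$n_genes, mu = exp(log_mu), size = size),
              n, cfg$n_genes)
  if (cfg$dropout_rna > 0)
    Y <- matrix(stats::rbinom(length(Y), Y, 1 - cfg$dropout_rna), n)

  ds <- multiome_dataset(
    X = Matrix::Matrix(X, sparse = TRUE), Y = Matrix::Matrix(Y, sparse = TRUE),
    cell_ids = sprintf("cell_%04d", seq_len(n)), peaks = peaks, genes = genes)

  links <- tibble::tibble(
    gene_id = rep(genes$gene_id, lengths(planted)),
    peak_id = peaks$peak_id[unlist(planted)])
  truth <- list(
    links = links,
    peak_blocks = split(seq_len(cfg$n_peaks), block_of),
    gene_modules = split(seq_len(cfg$n_genes), gene_module))
  list(dataset = ds, truth = truth)
}

#' Tiny hand-checkable worked example
#'
#' A fixed 20-cell, 12-peak, 4-gene instance on one chromosome, together
#' with hand-built network matrices whose every row has support, so the
#' derived transition set has no dead rows and the random-walk emission
#' count is exactly `T * (p + q) * 5`.
#'
#' @return list with `dataset`, `network` (a [joint_network()]) and
#'   `expected` (list with `n_nodes` and the function
#'   `n_pairs(T) = T * (p + q) * 5`).
#' @export
worked_example <- function() {
  set.seed(42)
  n <- 20L; p <- 12L; q <- 4L
  peaks <- tibble::tibble(
    peak_id = sprintf("wp_%02d", seq_len(p)), chrom = "chr1",
    start = 10000 * seq_len(p), end = 10000 * seq_len(p) + 500)
  genes <- tibble::tibble(
    gene_id = sprintf("wg_%d", seq_len(q)), symbol = sprintf("WG%d", seq_len(q)),
    chrom = "chr1", start = c(30000, 55000, 80000, 105000),
    end = c(32000, 57000, 82000, 107000), strand = c("+", "-", "+", "-"))
  X <- matrix(stats::rbinom(n * p, 2L, 0.4), n, p)
  Y <- matrix(stats::rpois(n * q, 3), n, q)
  ## guard against empty cells in so small a draw
  X[rowSums(X) == 0, 1] <- 1L
  Y[rowSums(Y) == 0, 1] <- 1L
  ds <- multiome_dataset(Matrix::Matrix(X, sparse = TRUE),
                         Matrix::Matrix(Y, sparse = TRUE),
                         sprintf("wc_%02d", seq_len(n)), peaks, genes)

  ## hand-built weights: peak chain, gene ring, and window-respecting Wpg
  Wpp <- Matrix::sparseMatrix(
    i = seq_len(p - 1), j = 2:p, x = seq_len(p - 1) / 2, dims = c(p, p),
    symmetric = FALSE)
  Wpp <- as_dgc(Wpp + Matrix::t(Wpp))
  Wgg <- Matrix::sparseMatrix(
    i = c(1, 2, 3, 4), j = c(2, 3, 4, 1), x = c(1, 2, 3, 4), dims = c(q, q))
  Wgg <- as_dgc(Wgg + Matrix::t(Wgg))
  ## all peaks lie within +/- 100 kb of every gene body here by layout
  wpg_of <- function(shift) {
    as_dgc(Matrix::sparseMatrix(
      i = seq_len(p), j = ((seq_len(p) + shift) %% q) + 1L,
      x = 1 + (seq_len(p) %% 3), dims = c(p, q)))
  }
  net <- joint_network(Wpp = Wpp, Wgg = Wgg,
                       Wpg = list(lasso = wpg_of(0), rf = wpg_of(1),
                                  xgboost = wpg_of(2)),
                       peak_ids = peaks$peak_id, gene_ids = genes$gene_id)
  list(dataset = ds, network = net,
       expected = list(n_nodes = p + q,
                       n_pairs = function(T) T * (p + q) * 5))
}
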