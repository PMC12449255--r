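#' Run the full co-embedding pipeline
#'
#' Chains preprocessing, joint-network construction, transition building,
#' meta-path walk generation and embedding training, returning every
#' intermediate alongside the final peak-gene ranking. All stages derive
#' their randomness from `seed`, so a fixed seed reproduces the result
#' byte for byte.
#'
#' @param ds a [multiome_dataset()].
#' @param mito_fraction optional per-cell mitochondrial fractions.
#' @param qc a [qc_params()].
#' @param methods peak-gene regression methods (default all three).
#' @param coaccess a [coaccess_params()].
#' @param window_bp cis window radius for the peak-gene stage.
#' @param K principal components of the gene-gene stage.
#' @param cfg a [train_config()]; `cfg$paths_per_node` sets the number of
#'   walks rooted at each node.
#' @param seed integer master seed.
#' @param verbose log progress.
#' @return list of class `scpoem_result` with elements `prep`, `network`,
#'   `transitions`, `pairs`, `embedding`, `ranking` and `seed`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_multiome(synthetic_config(n_cells = 120, n_peaks = 60,
#'                                           n_genes = 12, n_linked_genes = 6,
#'                                           seed = 1))
#' res <- scpoem_run(sim$dataset, cfg = train_config(d = 16, max_epochs = 20),
#'                   seed = 1)
#' head(res$ranking)
#' }
scpoem_run <- function(ds, mito_fraction = NULL, qc = qc_params(),
                       methods = c("lasso", "rf", "xgboost"),
                       coaccess = coaccess_params(), window_bp = 1e5,
                       K = 5L, cfg = train_config(), seed = 1L,
                       verbose = FALSE) {
  seeds <- derive_seeds(seed, 3L)
  prep <- preprocess_multiome(ds, mito_fraction, qc, verbose = verbose)
  if (verbose) message("building joint network ...")
  net <- build_joint_network(prep, methods = methods, coaccess = coaccess,
                             window_bp = window_bp, K = K, seed = seeds[1])
  ts <- build_transition_set(net)
  if (verbose) message("sampling meta-path walks ...")
  pairs <- generate_training_pairs(ts, T = cfg$paths_per_node,
                                   seed = seeds[2])
  if (verbose) message("training embedding ...")
  cfg$seed <- seeds[3]
  emb <- train_embedding(pairs, cfg = cfg, transitions = ts)
  ranking <- rank_peak_gene(emb)
  structure(list(prep = prep, network = net, transitions = ts,
                 pairs = pairs, embedding = emb, ranking = ranking,
                 seed = seed),
            class = "scpoem_result")
}

#' @method print scpoem_result
#' @export
print.scpoem_result <- function(x, ...) {
  d <- dim(x$prep$dataset)
  cat(sprintf("scpoem_result: %d cells, %d peaks, %d genes (seed %d)\n",
              d[1], d[2], d[3], x$seed))
  cat(sprintf("  %d training pairs, %d-dim embedding, %d epochs\n",
              nrow(x$pairs$E), ncol(x$embedding$F), nrow(x$embedding$log)))
  invisible(x)
}

#' Tidy the final ranking of a pipeline run
#'
#' @param x a `scpoem_result`.
#' @param ... unused.
#' @return the peak-gene ranking tibble, see [rank_peak_gene()].
#' @export
tidy.scpoem_result <- function(x, ...) x$ranking

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.scpoem_result
#' @return tibble of dataset sizes, pair counts and objective values.
#' @export
glance.scpoem_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_cells = nrow(x$prep$X_tfidf),
                   n_pairs = nrow(x$pairs$E),
                   n_truncated = x$pairs$n_truncated),
    glance(x$embedding))
}

#' Distance distributions of a peak-gene ranking
#'
#' Boxplot of embedded distances, optionally split by membership in a
#' reference pair set (e.g. planted ground-truth links).
#'
#' @param ranking a [rank_peak_gene()] tibble.
#' @param truth_pairs optional tibble (`gene_id`, `peak_id`).
#' @return a ggplot.
#' @export
plot_ranking_distances <- function(ranking, truth_pairs = NULL) {
  df <- ranking
  if (!is.null(truth_pairs)) {
    key <- paste(truth_pairs$gene_id, truth_pairs$peak_id)
    df <- dplyr::mutate(df, set = ifelse(
      paste(.data$gene_id, .data$peak_id) %in% key, "reference", "other"))
  } else {
    df <- dplyr::mutate(df, set = "all pairs")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set, y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::labs(x = NULL, y = "embedded distance") +
    ggplot2::theme_minimal()
}
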