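#' Training configuration for the co-embedding
#'
#' @param d embedding dimensionality (default 100).
#' @param batch_size minibatch size of the stochastic gradient ascent
#'   (default 32).
#' @param learning_rate initial learning rate (default 0.1).
#' @param lr_schedule `"linear"` (default) decays the rate linearly from
#'   `learning_rate` to `lr_min` over the epochs, the word2vec-family
#'   convention that damps late-iterate noise; `"constant"` keeps it
#'   fixed.
#' @param lr_min final learning rate under the linear schedule.
#' @param max_epochs training epoch cap (default 100).
#' @param M negative samples drawn per training pair (default 5).
#' @param paths_per_node meta-path walks rooted at each node per epoch
#'   (default 5).
#' @param resample_paths when training from a transition set, draw fresh
#'   meta-path walks every epoch (default) instead of reusing one static
#'   pair multiset; each epoch then sees `paths_per_node` fresh walks per
#'   node.
#' @param early_stop stop when the epoch objective plateaus.
#' @param tol,patience plateau definition: less than `tol` improvement for
#'   `patience` consecutive epochs.
#' @param init_scale embeddings initialize uniform in
#'   `[-init_scale, init_scale]`; default `0.5 / d`.
#' @param seed integer seed controlling initialization, walk draws,
#'   shuffling and negative draws.
#' @return list of class `train_config`.
#' @export
train_config <- function(d = 100L, batch_size = 32L, learning_rate = 0.1,
                         lr_schedule = c("linear", "constant"),
                         lr_min = 0.001, max_epochs = 100L, M = 5L,
                         paths_per_node = 5L, resample_paths = TRUE,
                         early_stop = FALSE, tol = 1e-4, patience = 5L,
                         init_scale = NULL, seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  assert_that(d > 0 && batch_size > 0 && learning_rate > 0 && lr_min > 0 &&
                max_epochs > 0 && M >= 1 && paths_per_node > 0,
              "all training hyperparameters must be positive")
  init_scale <- init_scale %||% (0.5 / d)
  structure(as.list(environment()), class = "train_config")
}

## per-epoch learning rates under the configured schedule
lr_sequence <- function(cfg) {
  n <- cfg$max_epochs
  if (cfg$lr_schedule == "constant" || n == 1) {
    rep(cfg$learning_rate, n)
  } else {
    cfg$learning_rate +
      (cfg$lr_min - cfg$learning_rate) * (seq_len(n) - 1) / (n - 1)
  }
}

## map pair ids onto 1-based indices into the node universe
pairs_to_index <- function(E, node_ids) {
  u <- match(E$u, node_ids); v <- match(E$v, node_ids)
  if (anyNA(u) || anyNA(v))
    abort_input("training pairs contain node ids missing from the universe")
  list(u = u, v = v, w = E$w)
}

#' Skip-gram negative-sampling objective
#'
#' Computes the weighted objective
#' `sum_r w_r (log sigma(F_vr . F_ur) + sum_m log sigma(-F_crm . F_ur))`
#' with a numerically stabilized log-sigmoid, for a fixed set of negative
#' draws.
#'
#' @param F numeric matrix of embeddings with rownames equal to node ids.
#' @param E tibble of training pairs (`u`, `v`, `w`).
#' @param negatives integer matrix, one row per pair, `M` columns of node
#'   row indices used as negatives.
#' @return the objective value (a scalar; larger is better).
#' @export
skipgram_objective <- function(F, E, negatives) {
  idx <- pairs_to_index(E, rownames(F))
  assert_that(nrow(negatives) == nrow(E),
              "negatives must have one row per training pair")
  objective_cpp(F, idx$u - 1L, idx$v - 1L, idx$w, negatives - 1L)
}

## reference R implementation of the objective gradient (dense, used by
## tests against finite differences and by no code path in training)
skipgram_gradient <- function(F, E, negatives) {
  idx <- pairs_to_index(E, rownames(F))
  G <- matrix(0, nrow(F), ncol(F), dimnames = dimnames(F))
  sig <- function(x) 1 / (1 + exp(-x))
  for (r in seq_along(idx$u)) {
    u <- idx$u[r]; v <- idx$v[r]; w <- idx$w[r]
    s <- 1 - sig(sum(F[v, ] * F[u, ]))
    G[u, ] <- G[u, ] + w * s * F[v, ]
    G[v, ] <- G[v, ] + w * s * F[u, ]
    for (c in negatives[r, ]) {
      sc <- sig(sum(F[c, ] * F[u, ]))
      G[u, ] <- G[u, ] - w * sc * F[c, ]
      G[c, ] <- G[c, ] - w * sc * F[u, ]
    }
  }
  G
}

#' Draw negative nodes for one training pair
#'
#' Uniform draws with replacement over the whole node universe, excluding
#' the pair's own endpoints.
#'
#' @param M number of negatives.
#' @param vocab_size number of nodes.
#' @param exclude integer indices never returned (the pair endpoints).
#' @return integer vector of length `M`.
#' @export
negative_sample <- function(M, vocab_size, exclude = integer(0)) {
  assert_that(vocab_size > length(unique(exclude)),
              "vocabulary must exceed the exclusion set")
  out <- integer(M)
  for (m in seq_len(M)) {
    repeat {
      c <- sample.int(vocab_size, 1L)
      if (!(c %in% exclude)) break
    }
    out[m] <- c
  }
  out
}

## fixed evaluation negatives for objective logging (deterministic per seed;
## vectorized rejection of collisions with the pair endpoints)
draw_eval_negatives <- function(u, v, M, vocab) {
  neg <- matrix(sample.int(vocab, length(u) * M, replace = TRUE),
                length(u), M)
  repeat {
    bad <- which(neg == u | neg == v)
    if (length(bad) == 0) break
    neg[bad] <- sample.int(vocab, length(bad), replace = TRUE)
  }
  neg
}

#' Train the shared peak-gene embedding
#'
#' Learns one d-dimensional row per node by minibatch stochastic gradient
#' ascent on the negative-sampling skip-gram objective, with fresh uniform
#' negatives for every pair at every epoch. When a transition set is
#' supplied and `cfg$resample_paths` is `TRUE` (the default), each epoch
#' draws fresh meta-path walks — `cfg$paths_per_node` per node — so the
#' pair stream approaches the expected transition statistics; otherwise a
#' single static pair multiset is reused. The epoch objective is logged on
#' a fixed evaluation pair set and fixed negatives so the training curve
#' is comparable across epochs.
#'
#' @param pairs a [generate_training_pairs()] result, or a tibble with
#'   columns `u`, `v`, `w`.
#' @param node_ids character vector of all node ids; defaults to the ids
#'   stored in `pairs`.
#' @param node_type `"peak"`/`"gene"` per node; defaults likewise.
#' @param cfg a [train_config()].
#' @param transitions optional [build_transition_set()] result enabling
#'   per-epoch walk resampling.
#' @return object of class `scpoem_embedding`: list with `F` (matrix,
#'   rownames = node ids), `node_type`, `log` (tibble epoch/objective),
#'   `cfg`.
#' @export
train_embedding <- function(pairs, node_ids = NULL, node_type = NULL,
                            cfg = train_config(), transitions = NULL) {
  if (inherits(pairs, "training_pairs")) {
    node_ids <- node_ids %||% c(pairs$peak_ids, pairs$gene_ids)
    node_type <- node_type %||% rep(c("peak", "gene"),
                                    c(length(pairs$peak_ids),
                                      length(pairs$gene_ids)))
    E <- pairs$E
  } else {
    E <- tibble::as_tibble(pairs)
    assert_that(!is.null(node_ids), "node_ids required for a bare pair table")
    node_type <- node_type %||% rep("node", length(node_ids))
  }
  assert_that(nrow(E) > 0, "no training pairs")
  idx <- pairs_to_index(E, node_ids)
  vocab <- length(node_ids)
  resample <- !is.null(transitions) && isTRUE(cfg$resample_paths)
  walk_seeds <- if (resample) derive_seeds(cfg$seed, cfg$max_epochs)

  set.seed(cfg$seed)
  F <- matrix(runif(vocab * cfg$d, -cfg$init_scale, cfg$init_scale),
              vocab, cfg$d, dimnames = list(node_ids, NULL))
  eval_neg <- draw_eval_negatives(idx$u, idx$v, cfg$M, vocab)
  lrs <- lr_sequence(cfg)
  log_obj <- numeric(0)
  best <- -Inf; stall <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    if (resample && epoch > 1) {
      Ee <- generate_training_pairs(transitions, T = cfg$paths_per_node,
                                    seed = walk_seeds[epoch])$E
      ide <- pairs_to_index(Ee, node_ids)
      nege <- draw_eval_negatives(ide$u, ide$v, cfg$M, vocab)
    } else {
      ide <- idx
      nege <- eval_neg
    }
    fit <- sgd_train_cpp(F, ide$u - 1L, ide$v - 1L, ide$w, vocab, cfg$M,
                         cfg$batch_size, lrs[epoch], 1L, FALSE, cfg$tol,
                         cfg$patience, nege - 1L)
    F <- fit$F
    ## log on the fixed evaluation pair set for a comparable curve
    obj <- objective_cpp(F, idx$u - 1L, idx$v - 1L, idx$w, eval_neg - 1L)
    log_obj <- c(log_obj, obj)
    if (cfg$early_stop) {
      if (obj > best + cfg$tol) {
        best <- obj; stall <- 0L
      } else if ((stall <- stall + 1L) >= cfg$patience) break
    }
  }
  structure(
    list(F = F, node_type = setNames(node_type, node_ids),
         log = tibble::tibble(epoch = seq_along(log_obj),
                              objective = log_obj),
         cfg = cfg, eval_negatives = eval_neg, E = E),
    class = "scpoem_embedding")
}

#' @method print scpoem_embedding
#' @export
print.scpoem_embedding <- function(x, ...) {
  cat(sprintf("scpoem_embedding: %d nodes (%d peaks, %d genes), d = %d\n",
              nrow(x$F), sum(x$node_type == "peak"),
              sum(x$node_type == "gene"), ncol(x$F)))
  cat(sprintf("  trained %d epoch(s); final objective %.4f\n",
              nrow(x$log), x$log$objective[nrow(x$log)]))
  invisible(x)
}

#' Euclidean distance between two embedded nodes
#'
#' @param emb a [train_embedding()] result.
#' @param u,v node ids.
#' @return `||F_u - F_v||_2`.
#' @export
pairwise_distance <- function(emb, u, v) {
  F <- emb$F
  assert_that(u %in% rownames(F) && v %in% rownames(F),
              "unknown node id '%s'", if (u %in% rownames(F)) v else u)
  sqrt(sum((F[u, ] - F[v, ])^2))
}

## distances from one row to a matrix of rows
dist_to_rows <- function(x, Mrows) {
  sqrt(pmax(rowSums(sweep(Mrows, 2, x)^2), 0))
}

#' K nearest peaks of a gene in the embedding
#'
#' @param emb a [train_embedding()] result.
#' @param gene gene node id.
#' @param K number of peaks (at most the number of embedded peaks).
#' @return tibble (`peak_id`, `distance`), ascending distance, ties broken
#'   by peak order for determinism.
#' @export
nearest_peaks <- function(emb, gene, K = 5L) {
  peaks <- names(emb$node_type)[emb$node_type == "peak"]
  assert_that(K <= length(peaks), "K exceeds the number of peaks")
  assert_that(gene %in% rownames(emb$F), "unknown gene id '%s'", gene)
  d <- dist_to_rows(emb$F[gene, ], emb$F[peaks, , drop = FALSE])
  ord <- order(d, seq_along(d))[seq_len(K)]
  tibble::tibble(peak_id = peaks[ord], distance = d[ord])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an embedding into one row per node
#'
#' @param x a `scpoem_embedding`.
#' @param ... unused.
#' @return tibble with `node_id`, `type`, and `dim_1 ... dim_d`.
#' @export
tidy.scpoem_embedding <- function(x, ...) {
  Fd <- as.data.frame(x$F)
  names(Fd) <- paste0("dim_", seq_len(ncol(Fd)))
  dplyr::bind_cols(
    tibble::tibble(node_id = rownames(x$F),
                   type = unname(x$node_type[rownames(x$F)])),
    tibble::as_tibble(Fd))
}

#' One-row summary of an embedding fit
#'
#' @inheritParams tidy.scpoem_embedding
#' @return tibble with node counts, dimensionality, epochs trained and
#'   initial/final objective.
#' @export
glance.scpoem_embedding <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$F),
    n_peaks = sum(x$node_type == "peak"),
    n_genes = sum(x$node_type == "gene"),
    d = ncol(x$F),
    epochs = nrow(x$log),
    objective_first = x$log$objective[1],
    objective_final = x$log$objective[nrow(x$log)])
}

#' Training-curve plot of an embedding fit
#'
#' @param object a `scpoem_embedding`.
#' @param ... unused.
#' @return a ggplot of the epoch objective.
#' @export
autoplot.scpoem_embedding <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch,
                                           y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "skip-gram objective",
                  title = "Embedding training curve") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
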