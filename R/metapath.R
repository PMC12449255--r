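#' Winsorize the nonzero entries of a weight matrix at quantiles
#'
#' Quantiles are computed over the nonzero entries only (linear
#' interpolation); nonzero values are clamped into `[q_lo, q_hi]`; zeros
#' and the sparsity pattern are untouched.
#'
#' @param W sparse non-negative matrix.
#' @param lo,hi quantile probabilities (defaults 0.10 and 0.90).
#' @return matrix of the same class and sparsity pattern.
#' @export
clip_quantiles <- function(W, lo = 0.10, hi = 0.90) {
  W <- as_dgc(W)
  assert_that(all(W@x >= 0), "weights must be non-negative")
  if (length(W@x) == 0) {
    warning("clip_quantiles: all-zero matrix returned unchanged", call. = FALSE)
    return(W)
  }
  qs <- quantile(W@x, c(lo, hi), names = FALSE)  # type 7, linear interpolation
  W@x <- pmin(pmax(W@x, qs[1]), qs[2])
  W
}

#' Row-normalize a non-negative matrix to a transition matrix
#'
#' Each nonzero row is divided by its sum; all-zero rows are left zero and
#' reported as dead rows.
#'
#' @param W non-negative matrix (sparse or dense).
#' @return list with `P` (row-stochastic sparse matrix) and `dead_rows`
#'   (integer indices of all-zero rows).
#' @export
row_normalize <- function(W) {
  W <- as_dgc(W)
  assert_that(all(W@x >= 0), "negative entries are not allowed")
  rs <- Matrix::rowSums(W)
  dead <- which(rs == 0)
  scale <- ifelse(rs > 0, 1 / rs, 0)
  P <- as_dgc(Matrix::Diagonal(x = scale) %*% W)
  list(P = P, dead_rows = dead)
}

#' Ensemble of method-specific transition matrices
#'
#' Elementwise mean of three row-stochastic matrices. A row is dead only
#' if it is dead in all three inputs; rows that are dead in a strict
#' subset of the inputs are renormalized so every live row sums to one.
#'
#' @param P_list list of three `row_normalize()` results (elements `P`,
#'   `dead_rows`) of identical shape.
#' @return list with `P` and `dead_rows` as in [row_normalize()].
#' @export
ensemble_transition <- function(P_list) {
  assert_that(length(P_list) >= 2, "need at least two transition matrices")
  dims <- lapply(P_list, function(z) dim(z$P))
  assert_that(all(vapply(dims, identical, logical(1), dims[[1]])),
              "transition matrices must share a shape")
  P <- Reduce(`+`, lapply(P_list, `[[`, "P")) / length(P_list)
  rn <- row_normalize(P)
  all_dead <- Reduce(intersect, lapply(P_list, `[[`, "dead_rows"))
  assert_that(setequal(rn$dead_rows, all_dead),
              "internal: ensemble dead rows inconsistent")
  rn
}

#' Transition set of the heterogeneous random walk
#'
#' Clips every weight matrix at its 10th/90th nonzero percentiles, row
#' normalizes, and ensembles the per-method peak-gene matrices into the
#' four transition matrices `Ppp`, `Pgg`, `Ppg` and `Pgp`.
#'
#' @param net a [joint_network()].
#' @param clip_lo,clip_hi clipping quantiles (defaults 0.10, 0.90).
#' @return list of class `transition_set` with row-stochastic sparse
#'   matrices `Ppp`, `Pgg`, `Ppg`, `Pgp`, per-matrix `dead` row index
#'   lists, and the node id vectors.
#' @export
build_transition_set <- function(net, clip_lo = 0.10, clip_hi = 0.90) {
  stopifnot(inherits(net, "joint_network"))
  npp <- row_normalize(clip_quantiles(net$Wpp, clip_lo, clip_hi))
  ngg <- row_normalize(clip_quantiles(net$Wgg, clip_lo, clip_hi))
  clipped <- lapply(net$Wpg, clip_quantiles, lo = clip_lo, hi = clip_hi)
  pg <- ensemble_transition(lapply(clipped, row_normalize))
  gp <- ensemble_transition(lapply(clipped, function(W)
    row_normalize(Matrix::t(W))))
  structure(
    list(Ppp = npp$P, Pgg = ngg$P, Ppg = pg$P, Pgp = gp$P,
         dead = list(Ppp = npp$dead_rows, Pgg = ngg$dead_rows,
                     Ppg = pg$dead_rows, Pgp = gp$dead_rows),
         peak_ids = net$peak_ids, gene_ids = net$gene_ids),
    class = "transition_set")
}

#' @method print transition_set
#' @export
print.transition_set <- function(x, ...) {
  cat(sprintf("transition_set: %d peaks, %d genes\n",
              length(x$peak_ids), length(x$gene_ids)))
  for (m in names(x$dead))
    cat(sprintf("  %s: %d dead row(s)\n", m, length(x$dead[[m]])))
  invisible(x)
}

## decompose a sparse row-stochastic matrix into per-row (cols, probs)
row_list <- function(P) {
  Pt <- Matrix::t(P)                 # column access is fast in CsparseMatrix
  n <- ncol(Pt)
  lapply(seq_len(n), function(i) {
    rng <- (Pt@p[i] + 1):Pt@p[i + 1]
    if (Pt@p[i] == Pt@p[i + 1]) return(NULL)
    list(j = Pt@i[rng] + 1L, p = Pt@x[rng])
  })
}

#' Sample the next node of a walk
#'
#' Draws column `j` with probability `P[i, j]`. A dead (all-zero) row
#' raises an error of class `scpoem_dead_end`.
#'
#' @param i row index of the current node.
#' @param P row-stochastic matrix.
#' @return sampled column index.
#' @export
sample_node <- function(i, P) {
  row <- P[i, ]
  s <- sum(row)
  if (s == 0)
    stop(structure(class = c("scpoem_dead_end", "error", "condition"),
                   list(message = sprintf("dead row %d", i), call = NULL)))
  sample.int(length(row), 1L, prob = row)
}

## internal sampler over a row_list; returns NA for dead rows
sample_rl <- function(rl, i) {
  e <- rl[[i]]
  if (is.null(e)) return(NA_integer_)
  if (length(e$j) == 1L) return(e$j)
  e$j[sample.int(length(e$j), 1L, prob = e$p)]
}

#' Generate weighted training node pairs by meta-path random walks
#'
#' Implements the meta-path walk over the scheme P3-P2-P1-G1-G2-G3: in
#' each of `T` loops, every peak roots one walk (gene branch
#' `G1 ~ Ppg`, `G2, G3 ~ Pgg`; peak branch `P2, P3 ~ Ppp`) and every gene
#' roots the symmetric walk. Each realized walk contributes five node
#' pairs per root with weight `exp(-0.1 k)`, `k` being the number of
#' intermediate nodes separating the pair in the path. Walks hitting a
#' dead transition row are truncated: only pairs whose far node was
#' realized are emitted.
#'
#' @param ts a [build_transition_set()] result.
#' @param T number of loops (meta-paths sampled per node).
#' @param seed integer seed.
#' @return list of class `training_pairs` with `E` (tibble `u`, `v`, `w`;
#'   `u` is the root of each pair), `Lpeak` and `Lgene` (tibbles of walks,
#'   `NA` where truncated), and counts of truncated emissions.
#' @export
generate_training_pairs <- function(ts, T = 5L, seed = 1L) {
  stopifnot(inherits(ts, "transition_set"))
  assert_that(T >= 1, "T must be at least 1")
  set.seed(seed)
  p <- length(ts$peak_ids); q <- length(ts$gene_ids)
  rl_pp <- row_list(ts$Ppp); rl_gg <- row_list(ts$Pgg)
  rl_pg <- row_list(ts$Ppg); rl_gp <- row_list(ts$Pgp)
  w_k <- exp(-0.1 * 0:2)
  id_of <- c(ts$peak_ids, ts$gene_ids)   # genes offset by p

  n_slots <- T * (p + q) * 5L
  u <- integer(n_slots); v <- integer(n_slots); w <- numeric(n_slots)
  walks <- matrix(NA_integer_, T * (p + q), 6L)
  r <- 0L; wr <- 0L
  emit <- function(ui, vi, wt) {
    r <<- r + 1L
    u[r] <<- ui; v[r] <<- vi; w[r] <<- wt
  }
  for (loop in seq_len(T)) {
    for (P1 in seq_len(p)) {
      G1 <- sample_rl(rl_pg, P1)
      G2 <- if (!is.na(G1)) sample_rl(rl_gg, G1) else NA_integer_
      G3 <- if (!is.na(G2)) sample_rl(rl_gg, G2) else NA_integer_
      P2 <- sample_rl(rl_pp, P1)
      P3 <- if (!is.na(P2)) sample_rl(rl_pp, P2) else NA_integer_
      wr <- wr + 1L
      walks[wr, ] <- c(P3, P2, P1, G1 + p, G2 + p, G3 + p)
      if (!is.na(G1)) emit(P1, G1 + p, w_k[1])
      if (!is.na(P2)) emit(P1, P2, w_k[1])
      if (!is.na(G2)) emit(P1, G2 + p, w_k[2])
      if (!is.na(P3)) emit(P1, P3, w_k[2])
      if (!is.na(G3)) emit(P1, G3 + p, w_k[3])
    }
    for (G1 in seq_len(q)) {
      G2 <- sample_rl(rl_gg, G1)
      G3 <- if (!is.na(G2)) sample_rl(rl_gg, G2) else NA_integer_
      P1 <- sample_rl(rl_gp, G1)
      P2 <- if (!is.na(P1)) sample_rl(rl_pp, P1) else NA_integer_
      P3 <- if (!is.na(P2)) sample_rl(rl_pp, P2) else NA_integer_
      wr <- wr + 1L
      walks[wr, ] <- c(P3, P2, P1, G1 + p, G2 + p, G3 + p)
      if (!is.na(P1)) emit(G1 + p, P1, w_k[1])
      if (!is.na(G2)) emit(G1 + p, G2 + p, w_k[1])
      if (!is.na(P2)) emit(G1 + p, P2, w_k[2])
      if (!is.na(G3)) emit(G1 + p, G3 + p, w_k[2])
      if (!is.na(P3)) emit(G1 + p, P3, w_k[3])
    }
  }
  keep <- seq_len(r)
  E <- tibble::tibble(u = id_of[u[keep]], v = id_of[v[keep]], w = w[keep])
  is_peak_walk <- rep(rep(c(TRUE, FALSE), c(p, q)), T)
  to_tbl <- function(m) {
    tibble::as_tibble(stats::setNames(
      as.data.frame(matrix(id_of[m], nrow(m), 6L)),
      c("P3", "P2", "P1", "G1", "G2", "G3")))
  }
  structure(
    list(E = E, Lpeak = to_tbl(walks[is_peak_walk, , drop = FALSE]),
         Lgene = to_tbl(walks[!is_peak_walk, , drop = FALSE]),
         n_truncated = n_slots - r,
         peak_ids = ts$peak_ids, gene_ids = ts$gene_ids),
    class = "training_pairs")
}

#' @method print training_pairs
#' @export
print.training_pairs <- function(x, ...) {
  cat(sprintf("training_pairs: %d pairs (%d truncated), %d peak walks, %d gene walks\n",
              nrow(x$E), x$n_truncated, nrow(x$Lpeak), nrow(x$Lgene)))
  invisible(x)
}
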