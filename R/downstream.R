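#' Importance score of a peak-gene pair
#'
#' Monotone transform of the embedded distance onto `(0, 1]`:
#' `exp(-distance)`.
#'
#' @param distance non-negative Euclidean distance(s).
#' @return `exp(-distance)`.
#' @export
importance_score <- function(distance) {
  assert_that(all(distance >= 0), "distances must be non-negative")
  exp(-distance)
}

#' Rank peak-gene pairs by embedded distance
#'
#' Computes the Euclidean distance from every gene to every peak (or only
#' to peaks in each gene's cis window when annotations are supplied) and
#' returns the pairs with importance scores and within-gene ranks.
#'
#' @param emb a [train_embedding()] result.
#' @param peaks,genes optional annotation tibbles; when both are given,
#'   pairs are restricted to each gene's `window_bp` cis window.
#' @param window_bp cis window radius used with annotations.
#' @return tibble (`gene_id`, `peak_id`, `distance`,
#'   `importance = exp(-distance)`, `rank` within gene by ascending
#'   distance).
#' @export
rank_peak_gene <- function(emb, peaks = NULL, genes = NULL, window_bp = 1e5) {
  peak_ids <- names(emb$node_type)[emb$node_type == "peak"]
  gene_ids <- names(emb$node_type)[emb$node_type == "gene"]
  Fp <- emb$F[peak_ids, , drop = FALSE]
  restrict <- !is.null(peaks) && !is.null(genes)
  out <- lapply(gene_ids, function(g) {
    cand <- peak_ids
    if (restrict) {
      grow <- genes[genes$gene_id == g, ]
      if (nrow(grow) == 1) {
        idx <- candidate_peaks(grow, peaks, window_bp)
        cand <- intersect(peaks$peak_id[idx], peak_ids)
      }
    }
    if (length(cand) == 0) return(NULL)
    d <- dist_to_rows(emb$F[g, ], Fp[cand, , drop = FALSE])
    ord <- order(d, seq_along(d))
    tibble::tibble(gene_id = g, peak_id = cand[ord], distance = d[ord],
                   importance = importance_score(d[ord]),
                   rank = seq_along(ord))
  })
  dplyr::bind_rows(out)
}

#' Size-constrained clustering of gene embeddings
#'
#' K-means on the gene rows followed by a greedy repair pass that moves
#' members out of oversized clusters into their nearest cluster with
#' capacity and pulls nearest outside genes into undersized clusters,
#' yielding exactly `n_groups` subgroups whose sizes lie in
#' `[size_min, size_max]`.
#'
#' @param emb a [train_embedding()] result (gene rows are used), or a
#'   numeric matrix with gene ids as rownames.
#' @param n_groups number of subgroups.
#' @param size_min,size_max inclusive size bounds (defaults 10 and 50).
#' @param seed integer seed for k-means initialization.
#' @return tibble (`subgroup`, `gene_id`), a partition of the gene set.
#' @export
cluster_genes <- function(emb, n_groups, size_min = 10L, size_max = 50L,
                          seed = 1L) {
  Fg <- if (inherits(emb, "scpoem_embedding")) {
    emb$F[names(emb$node_type)[emb$node_type == "gene"], , drop = FALSE]
  } else emb
  q <- nrow(Fg)
  assert_that(n_groups * size_min <= q && q <= n_groups * size_max,
              "infeasible size constraints: %d genes cannot form %d groups of %d-%d",
              q, n_groups, size_min, size_max)
  set.seed(seed)
  assign <- tryCatch(
    kmeans(Fg, centers = n_groups, nstart = 5L, iter.max = 100L)$cluster,
    error = function(e) rep_len(seq_len(n_groups), q))  # degenerate input
  centers <- function(a) {
    t(vapply(seq_len(n_groups),
             function(g) colMeans(Fg[a == g, , drop = FALSE]),
             numeric(ncol(Fg))))
  }
  ## repair oversized clusters
  repeat {
    sizes <- tabulate(assign, n_groups)
    over <- which(sizes > size_max)
    if (length(over) == 0) break
    ctr <- centers(assign)
    g <- over[1]
    members <- which(assign == g)
    open <- which(sizes < size_max)
    open <- setdiff(open, g)
    ## move the member closest to some open cluster's center
    dmat <- as.matrix(stats::dist(rbind(ctr[open, , drop = FALSE],
                                        Fg[members, , drop = FALSE])))
    k <- length(open)
    dsub <- dmat[seq_len(k), k + seq_along(members), drop = FALSE]
    best <- arrayInd(which.min(dsub), dim(dsub))
    assign[members[best[2]]] <- open[best[1]]
  }
  ## repair undersized clusters
  repeat {
    sizes <- tabulate(assign, n_groups)
    under <- which(sizes < size_min)
    if (length(under) == 0) break
    ctr <- centers(assign)
    g <- under[1]
    donors <- which(assign != g & sizes[assign] > size_min)
    if (length(donors) == 0)
      abort_input("size repair failed: no donor genes available")
    d <- dist_to_rows(ctr[g, ], Fg[donors, , drop = FALSE])
    assign[donors[which.min(d)]] <- g
  }
  tibble::tibble(subgroup = assign, gene_id = rownames(Fg)) |>
    dplyr::arrange(.data$subgroup, .data$gene_id)
}

#' Assign a peak set to a gene subgroup
#'
#' `knn_union` takes the union over member genes of each gene's `K`
#' nearest peaks; `radius` takes all peaks within distance `r` of the
#' subgroup centroid. Both are deterministic given the embedding.
#'
#' @param emb a [train_embedding()] result.
#' @param gene_ids member genes of the subgroup.
#' @param rule `"knn_union"` (default) or `"radius"`.
#' @param K nearest peaks per gene for `knn_union`.
#' @param r radius for `radius`.
#' @return character vector of assigned peak ids.
#' @export
assign_peaks <- function(emb, gene_ids, rule = c("knn_union", "radius"),
                         K = 5L, r = NULL) {
  rule <- match.arg(rule)
  if (rule == "knn_union") {
    sort(unique(unlist(lapply(gene_ids, function(g)
      nearest_peaks(emb, g, K)$peak_id))))
  } else {
    assert_that(!is.null(r) && r > 0, "radius rule requires r > 0")
    peak_ids <- names(emb$node_type)[emb$node_type == "peak"]
    ctr <- colMeans(emb$F[gene_ids, , drop = FALSE])
    d <- dist_to_rows(ctr, emb$F[peak_ids, , drop = FALSE])
    sort(peak_ids[d <= r])
  }
}

## cosine-similarity KNN graph on embedding rows; negative similarities
## are clamped to zero, edges symmetrized by maximum
cosine_knn_graph <- function(F, k = 20L) {
  nrm <- sqrt(rowSums(F^2))
  nrm[nrm == 0] <- 1
  C <- tcrossprod(F / nrm)
  diag(C) <- -Inf
  n <- nrow(F)
  k <- min(k, n - 1L)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    top <- order(C[i, ], decreasing = TRUE)[seq_len(k)]
    W[i, top] <- pmax(C[i, top], 0)
  }
  W <- pmax(W, t(W))
  diag(W) <- 0
  W
}

## joint-Laplacian manifold alignment with same-gene anchors; returns the
## aligned coordinates of both copies (rows 1..q = A, q+1..2q = B)
align_manifolds <- function(W_A, W_B, d_align, anchor_weight = NULL) {
  q <- nrow(W_A)
  lam <- anchor_weight %||% max(c(rowSums(W_A), rowSums(W_B), 1))
  W <- rbind(cbind(W_A, diag(lam, q)), cbind(diag(lam, q), W_B))
  L <- diag(rowSums(W)) - W
  ee <- eigen(L, symmetric = TRUE)
  vals <- rev(ee$values); vecs <- ee$vectors[, rev(seq_len(2 * q))]
  nontrivial <- which(vals > max(vals) * 1e-9 + 1e-12)
  take <- nontrivial[seq_len(min(d_align, length(nontrivial)))]
  vecs[, take, drop = FALSE]
}

#' Differential-regulation score between two conditions
#'
#' Builds a cosine-similarity KNN gene graph per condition from the gene
#' embedding rows, jointly embeds both graphs by a joint-Laplacian
#' manifold alignment with same-gene anchors, and scores every shared
#' gene by the Euclidean displacement between its two aligned
#' representations. Optional permutation p-values shuffle the gene
#' correspondence between conditions.
#'
#' @param emb_A,emb_B [train_embedding()] results (or matrices with gene
#'   ids as rownames) for the two conditions.
#' @param shared_genes gene ids present in both; defaults to the
#'   intersection.
#' @param k KNN neighbors of the per-condition gene graphs (default 20).
#' @param d_align dimensionality of the aligned space (default 5).
#' @param anchor_weight weight of the same-gene anchor edges; defaults to
#'   the maximum graph degree, which keeps the leading aligned dimensions
#'   anchor-consistent.
#' @param n_perm permutations for p-values (0 skips them).
#' @param seed integer seed for the permutations.
#' @return tibble (`gene_id`, `score`, `rank`, and `p_value` when
#'   permuted), ranked by decreasing displacement.
#' @export
differential_regulation <- function(emb_A, emb_B, shared_genes = NULL,
                                    k = 20L, d_align = 5L,
                                    anchor_weight = NULL, n_perm = 0L,
                                    seed = 1L) {
  gene_rows <- function(e) {
    if (inherits(e, "scpoem_embedding"))
      e$F[names(e$node_type)[e$node_type == "gene"], , drop = FALSE]
    else e
  }
  FA <- gene_rows(emb_A); FB <- gene_rows(emb_B)
  shared_genes <- shared_genes %||% intersect(rownames(FA), rownames(FB))
  assert_that(length(shared_genes) > 1, "need at least two shared genes")
  FA <- FA[shared_genes, , drop = FALSE]
  FB <- FB[shared_genes, , drop = FALSE]
  q <- length(shared_genes)
  W_A <- cosine_knn_graph(FA, k); W_B <- cosine_knn_graph(FB, k)
  score_of <- function(W_B_use) {
    V <- align_manifolds(W_A, W_B_use, d_align, anchor_weight)
    sqrt(rowSums((V[seq_len(q), , drop = FALSE] -
                    V[q + seq_len(q), , drop = FALSE])^2))
  }
  score <- score_of(W_B)
  out <- tibble::tibble(gene_id = shared_genes, score = score) |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    dplyr::mutate(rank = dplyr::row_number())
  if (n_perm > 0) {
    set.seed(seed)
    null_scores <- matrix(0, q, n_perm)
    for (b in seq_len(n_perm)) {
      perm <- sample.int(q)
      null_scores[, b] <- score_of(W_B[perm, perm])
    }
    pv <- vapply(seq_len(q), function(j)
      (1 + sum(null_scores[j, ] >= score[j])) / (n_perm + 1), numeric(1))
    out <- dplyr::left_join(
      out, tibble::tibble(gene_id = shared_genes, p_value = pv),
      by = "gene_id")
  }
  out
}

#' Precision and recall of a ranking against known pairs
#'
#' Truth can be explicit peak-gene pairs or genomic intervals per gene (a
#' ranked peak counts as positive when it overlaps a truth interval of its
#' gene, half-open).
#'
#' @param ranking a [rank_peak_gene()] tibble.
#' @param truth_pairs tibble (`gene_id`, `peak_id`) of true links.
#' @param truth_intervals tibble (`gene_id`, `chrom`, `start`, `end`);
#'   requires `peaks`.
#' @param peaks peak annotation tibble, needed with `truth_intervals`.
#' @param top_fraction fraction of the ranking (by ascending distance,
#'   globally) treated as predicted positives.
#' @return tibble with `precision`, `recall`, `overlap` (TP count),
#'   `n_top` and `n_truth`.
#' @export
overlap_eval <- function(ranking, truth_pairs = NULL, truth_intervals = NULL,
                         peaks = NULL, top_fraction = 0.1) {
  assert_that(top_fraction > 0 && top_fraction <= 1,
              "top_fraction must lie in (0, 1]")
  if (is.null(truth_pairs)) {
    assert_that(!is.null(truth_intervals) && !is.null(peaks),
                "supply truth_pairs, or truth_intervals plus peaks")
    assert_that(nrow(truth_intervals) > 0, "empty truth set")
    hits <- lapply(seq_len(nrow(truth_intervals)), function(r) {
      tr <- truth_intervals[r, ]
      ov <- peaks$chrom == tr$chrom &
        intervals_overlap(peaks$start, peaks$end, tr$start, tr$end)
      if (!any(ov)) return(NULL)
      tibble::tibble(gene_id = tr$gene_id, peak_id = peaks$peak_id[ov])
    })
    truth_pairs <- dplyr::distinct(dplyr::bind_rows(hits))
  }
  assert_that(nrow(truth_pairs) > 0, "empty truth set")
  ranked <- dplyr::arrange(ranking, .data$distance)
  n_top <- ceiling(top_fraction * nrow(ranked))
  top <- ranked[seq_len(n_top), ]
  key <- function(d) paste(d$gene_id, d$peak_id)
  tp <- sum(key(top) %in% key(truth_pairs))
  tibble::tibble(precision = tp / n_top, recall = tp / nrow(truth_pairs),
                 overlap = tp, n_top = n_top, n_truth = nrow(truth_pairs))
}

#' Subsample stability of the peak rankings
#'
#' Runs the full pipeline on `n_rep` random cell subsamples and, for every
#' gene retained in all runs, computes the Spearman correlation of its
#' peak distance ranks between the first two runs.
#'
#' @param ds a [multiome_dataset()].
#' @param fraction of cells kept per subsample (default 0.9).
#' @param n_rep number of replicates (default 2).
#' @param seed integer seed; replicate subsamples and pipelines derive
#'   child seeds from it.
#' @param ... passed to [scpoem_run()] (e.g. `qc`, `cfg`, `methods`).
#' @param shuffled_control also compute a control in which the gene
#'   correspondence between the two runs is permuted (a derangement), so
#'   the observed stability can be compared against chance pairing.
#' @return list with `per_gene` (tibble `gene_id`, `spearman`) and
#'   `median`; with the control, also `control_per_gene` and
#'   `control_median`.
#' @export
subsample_stability <- function(ds, fraction = 0.9, n_rep = 2L, seed = 1L,
                                shuffled_control = FALSE, ...) {
  assert_that(fraction > 0 && fraction <= 1, "fraction must lie in (0, 1]")
  seeds <- derive_seeds(seed, 2L * n_rep + 1L)
  n <- nrow(ds$X)
  runs <- lapply(seq_len(n_rep), function(rep_id) {
    set.seed(seeds[rep_id])
    idx <- sort(sample.int(n, round(fraction * n)))
    sub <- subset_cells(ds, idx)
    tryCatch(scpoem_run(sub, seed = seeds[n_rep + rep_id], ...),
             error = function(e) abort_input(
               "pipeline failed in replicate %d: %s", rep_id,
               conditionMessage(e)))
  })
  stability_from_runs(runs[[1]], runs[[2]],
                      control_seed = if (shuffled_control)
                        seeds[2L * n_rep + 1L])
}

## derangement: permutation with no fixed point (seeded)
derange <- function(n) {
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n)) || n == 1) return(p)
  }
}

#' Spearman stability of peak rankings between two pipeline runs
#'
#' For every gene present in both runs, correlates the distances to the
#' shared peaks (Spearman). With `control_seed`, also evaluates a
#' label-shuffled control that pairs each gene of the first run with a
#' different gene of the second.
#'
#' @param res_A,res_B two [scpoem_run()] results.
#' @param control_seed optional seed for the shuffled-control derangement.
#' @return list with `per_gene`, `median`, and optionally
#'   `control_per_gene`, `control_median`.
#' @export
stability_from_runs <- function(res_A, res_B, control_seed = NULL) {
  rk_A <- rank_peak_gene(res_A$embedding)
  rk_B <- rank_peak_gene(res_B$embedding)
  genes <- intersect(unique(rk_A$gene_id), unique(rk_B$gene_id))
  peaks <- sort(intersect(unique(rk_A$peak_id), unique(rk_B$peak_id)))
  dist_mat <- function(rk) {
    sub <- rk[rk$gene_id %in% genes & rk$peak_id %in% peaks, ]
    m <- matrix(NA_real_, length(peaks), length(genes),
                dimnames = list(peaks, genes))
    m[cbind(match(sub$peak_id, peaks), match(sub$gene_id, genes))] <-
      sub$distance
    m
  }
  A <- dist_mat(rk_A); B <- dist_mat(rk_B)
  sp <- function(a, b) cor(a, b, method = "spearman", use = "complete.obs")
  per_gene <- vapply(seq_along(genes), function(j) sp(A[, j], B[, j]),
                     numeric(1))
  out <- list(per_gene = tibble::tibble(gene_id = genes,
                                        spearman = per_gene),
              median = stats::median(per_gene, na.rm = TRUE))
  if (!is.null(control_seed)) {
    set.seed(control_seed)
    perm <- derange(length(genes))
    ctrl <- vapply(seq_along(genes), function(j) sp(A[, j], B[, perm[j]]),
                   numeric(1))
    out$control_per_gene <- tibble::tibble(gene_id = genes, spearman = ctrl)
    out$control_median <- stats::median(ctrl, na.rm = TRUE)
  }
  out
}
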