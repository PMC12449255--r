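#' Joint heterogeneous peak-gene network
#'
#' Bundles the three parts of the joint network: symmetric peak-peak
#' co-accessibility weights `Wpp`, symmetric gene-gene regression weights
#' `Wgg`, and one bipartite peak-gene weight matrix per regression method.
#'
#' @param Wpp sparse symmetric non-negative p x p matrix, zero diagonal.
#' @param Wgg sparse symmetric non-negative q x q matrix, zero diagonal.
#' @param Wpg named list of sparse non-negative p x q matrices (one per
#'   method, e.g. `lasso`, `rf`, `xgboost`).
#' @param peak_ids,gene_ids node identifiers.
#' @return list of class `joint_network`.
#' @export
joint_network <- function(Wpp, Wgg, Wpg, peak_ids, gene_ids) {
  Wpp <- as_dgc(Wpp); Wgg <- as_dgc(Wgg)
  Wpg <- lapply(Wpg, as_dgc)
  p <- length(peak_ids); q <- length(gene_ids)
  assert_that(all(dim(Wpp) == p) && all(dim(Wgg) == q),
              "Wpp/Wgg dimensions must match node counts")
  for (m in names(Wpg))
    assert_that(all(dim(Wpg[[m]]) == c(p, q)),
                "Wpg[[%s]] must be p x q", m)
  assert_that(max(abs(Wpp - Matrix::t(Wpp))) < 1e-12 &&
                max(abs(Wgg - Matrix::t(Wgg))) < 1e-12,
              "Wpp and Wgg must be symmetric")
  assert_that(all(Matrix::diag(Wpp) == 0) && all(Matrix::diag(Wgg) == 0),
              "Wpp and Wgg must have zero diagonals")
  assert_that(is_nonneg(Wpp) && is_nonneg(Wgg) &&
                all(vapply(Wpg, is_nonneg, logical(1))),
              "network weights must be non-negative")
  structure(list(Wpp = Wpp, Wgg = Wgg, Wpg = Wpg,
                 peak_ids = as.character(peak_ids),
                 gene_ids = as.character(gene_ids)),
            class = "joint_network")
}

#' @method print joint_network
#' @export
print.joint_network <- function(x, ...) {
  cat(sprintf("joint_network: %d peaks, %d genes\n",
              length(x$peak_ids), length(x$gene_ids)))
  cat(sprintf("  Wpp edges: %d; Wgg edges: %d\n",
              length(x$Wpp@x) / 2, length(x$Wgg@x) / 2))
  for (m in names(x$Wpg))
    cat(sprintf("  Wpg[%s] nonzeros: %d\n", m, length(x$Wpg[[m]]@x)))
  invisible(x)
}

#' Parameters of the peak-peak co-accessibility stage
#'
#' @param n_embed_dims dimensionality of the cell embedding used to find
#'   neighbors for metacell aggregation.
#' @param knn_k neighbors aggregated into each metacell profile.
#' @param glasso_penalty L1 penalty of the windowed graphical lasso.
#' @param window_bp genomic window width for the per-window fits
#'   (default 500 kb); windows overlap by half their width.
#' @param binarize binarize counts before embedding and aggregation.
#' @param embed_method `"svd"` (deterministic truncated SVD of the TF-IDF
#'   binary matrix) or `"umap"` (requires the uwot package).
#' @return list of class `coaccess_params`.
#' @export
coaccess_params <- function(n_embed_dims = 10L, knn_k = 50L,
                            glasso_penalty = 0.2, window_bp = 5e5,
                            binarize = TRUE, embed_method = c("svd", "umap")) {
  embed_method <- match.arg(embed_method)
  assert_that(n_embed_dims > 0 && knn_k > 0 && glasso_penalty > 0 &&
                window_bp > 0, "co-accessibility parameters must be positive")
  structure(as.list(environment()), class = "coaccess_params")
}

## deterministic truncated SVD embedding of cells
embed_cells <- function(B, k, method = "svd", seed = 1L) {
  n <- nrow(B)
  tot <- pmax(Matrix::rowSums(B), 1)
  idf <- log(1 + n / (1 + Matrix::colSums(B > 0)))
  Tm <- as.matrix(Matrix::Diagonal(x = 1 / tot) %*% B %*%
                    Matrix::Diagonal(x = idf))
  k <- min(k, n - 1L, ncol(Tm) - 1L)
  sv <- svd(scale(Tm, center = TRUE, scale = FALSE), nu = k, nv = 0)
  emb <- sv$u %*% diag(sv$d[seq_len(k)], k)
  if (method == "umap") {
    if (!requireNamespace("uwot", quietly = TRUE))
      abort_input("embed_method = 'umap' requires the uwot package")
    set.seed(seed)
    emb <- uwot::umap(emb, n_components = min(k, 10L),
                      n_threads = 1, n_sgd_threads = 1)
  }
  emb
}

## k-nearest-neighbor index (self included), small-n exact search
knn_index <- function(emb, k) {
  d <- as.matrix(stats::dist(emb))
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

## tile peaks (by interval midpoint) into overlapping windows per chromosome
peak_windows <- function(peaks, window_bp) {
  mid <- (peaks$start + peaks$end) / 2
  out <- list()
  for (ch in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == ch)
    lo <- min(mid[idx]); hi <- max(mid[idx])
    starts <- seq(lo - window_bp / 2, hi, by = window_bp / 2)
    for (ws in starts) {
      members <- idx[mid[idx] >= ws & mid[idx] < ws + window_bp]
      if (length(members) >= 2) out[[length(out) + 1]] <- members
    }
  }
  unique(out)
}

#' Peak-peak co-accessibility network
#'
#' Reimplements the standard co-accessibility workflow natively: binarize
#' the peak counts, embed cells in a low-dimensional space, aggregate each
#' cell's K nearest neighbors into a metacell profile, then fit a graphical
#' lasso within overlapping genomic windows and average the absolute
#' partial correlations of each peak pair over the windows containing it.
#' Peaks on different chromosomes never share a window, so cross-chromosome
#' entries are exactly zero.
#'
#' @param X cell-by-peak count matrix (post-QC).
#' @param peaks tibble of peak intervals, rows matching columns of `X`.
#' @param params a [coaccess_params()].
#' @param seed integer seed (used only by the optional UMAP embedding).
#' @return sparse symmetric non-negative p x p matrix with zero diagonal.
#' @export
build_peak_peak <- function(X, peaks, params = coaccess_params(), seed = 1L) {
  p <- ncol(X)
  B <- if (params$binarize) as_dgc(X > 0) else as_dgc(X)
  emb <- embed_cells(B, params$n_embed_dims, params$embed_method, seed)
  k <- min(params$knn_k, nrow(B))
  nn <- knn_index(emb, k)
  ## metacell profiles: neighborhood sums of the binary matrix
  A <- Matrix::sparseMatrix(i = rep(seq_len(nrow(B)), k), j = as.vector(nn),
                            x = 1, dims = c(nrow(B), nrow(B)))
  M <- as.matrix(A %*% B)

  wins <- peak_windows(peaks, params$window_bp)
  acc <- matrix(0, p, p); cnt <- matrix(0, p, p)
  n_ridged <- 0L
  for (members in wins) {
    sub <- M[, members, drop = FALSE]
    keep <- apply(sub, 2, sd) > 0
    if (sum(keep) < 2) next
    members <- members[keep]
    C <- cor(sub[, keep, drop = FALSE])
    fit <- graphical_lasso(C, params$glasso_penalty)
    if (fit$ridged) n_ridged <- n_ridged + 1L
    pc <- precision_to_parcor(fit$theta)
    acc[members, members] <- acc[members, members] + pc
    cnt[members, members] <- cnt[members, members] + 1
  }
  if (n_ridged > 0)
    message(sprintf("build_peak_peak: %d window(s) ridge-stabilized", n_ridged))
  W <- abs(ifelse(cnt > 0, acc / pmax(cnt, 1), 0))
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W[W < 1e-10] <- 0
  as_dgc(Matrix::Matrix(W, sparse = TRUE))
}

#' Principal-component regression of one gene on all others
#'
#' Regresses gene `j` on the leading principal components of the remaining
#' genes and maps the fitted coefficients back to the gene space:
#' `U = Y[, -j] V`, `alpha = (U'U)^-1 U' Y[, j]`, `beta = V alpha`.
#'
#' @param Y_hvg dense cells x genes matrix (normalized HVG expression).
#' @param j gene column index.
#' @param K number of leading principal components (default 5; capped at
#'   `min(K, q - 1, n - 1)`).
#' @return list with `U`, `V`, `alpha_hat`, `beta_hat` (length q - 1, in
#'   the order of the remaining columns), and `K_used`.
#' @export
pc_regress_gene <- function(Y_hvg, j, K = 5L) {
  n <- nrow(Y_hvg); q <- ncol(Y_hvg)
  assert_that(q >= 2, "need at least two genes")
  assert_that(j >= 1 && j <= q, "gene index %d out of range", j)
  Yc <- scale(Y_hvg, center = TRUE, scale = FALSE)
  Ymj <- Yc[, -j, drop = FALSE]
  Ks <- min(K, q - 1L, n - 1L)
  sv <- svd(Ymj, nu = 0, nv = Ks)
  V <- sv$v[, seq_len(Ks), drop = FALSE]
  U <- Ymj %*% V
  G <- crossprod(U)
  if (rcond(G) < 1e-12)
    abort_input("singular PC score matrix for gene %d", j)
  alpha <- solve(G, crossprod(U, Yc[, j]))
  list(U = U, V = V, alpha_hat = drop(alpha),
       beta_hat = drop(V %*% alpha), K_used = Ks)
}

#' Gene-gene network by principal-component regression
#'
#' Assembles the per-gene regression coefficients into a q x q matrix,
#' takes absolute values, symmetrizes by elementwise maximum, and keeps
#' only entries strictly above the 95th percentile of the off-diagonal
#' values.
#'
#' @inheritParams pc_regress_gene
#' @param percentile quantile above which edges are retained (default
#'   0.95).
#' @param percentile_population `"all"` computes the quantile over every
#'   off-diagonal entry (zeros included); `"nonzero"` restricts to nonzero
#'   entries.
#' @return sparse symmetric non-negative q x q matrix with zero diagonal.
#' @export
build_gene_gene <- function(Y_hvg, K = 5L, percentile = 0.95,
                            percentile_population = c("all", "nonzero")) {
  percentile_population <- match.arg(percentile_population)
  q <- ncol(Y_hvg)
  W <- matrix(0, q, q)
  for (j in seq_len(q)) {
    fit <- tryCatch(pc_regress_gene(Y_hvg, j, K),
                    error = function(e) abort_input(
                      "gene-gene network failed at gene %d: %s", j,
                      conditionMessage(e)))
    W[-j, j] <- fit$beta_hat
  }
  W <- abs(W)
  W <- pmax(W, t(W))
  off <- W[row(W) != col(W)]
  if (percentile_population == "nonzero") off <- off[off > 0]
  thr <- unname(quantile(off, percentile))
  W[W <= thr] <- 0
  diag(W) <- 0
  as_dgc(Matrix::Matrix(W, sparse = TRUE))
}

#' Candidate peaks within a gene's cis window
#'
#' Indices of peaks overlapping `[start - window_bp, end + window_bp)` of
#' the gene (half-open overlap on the gene's chromosome). With
#' `anchor = "tss"` the window is centered on the transcription start site
#' instead of spanning the gene body.
#'
#' @param gene one-row data frame (or list) with `chrom`, `start`, `end`,
#'   `strand`.
#' @param peaks tibble of peak intervals.
#' @param window_bp window radius in bp (default 100 kb).
#' @param anchor `"body"` (default) or `"tss"`.
#' @return integer vector of peak indices (possibly empty).
#' @export
candidate_peaks <- function(gene, peaks, window_bp = 1e5,
                            anchor = c("body", "tss")) {
  anchor <- match.arg(anchor)
  if (anchor == "body") {
    lo <- gene$start - window_bp; hi <- gene$end + window_bp
  } else {
    tss <- if (gene$strand == "+") gene$start else gene$end
    lo <- tss - window_bp; hi <- tss + window_bp
  }
  which(peaks$chrom == gene$chrom &
          intervals_overlap(peaks$start, peaks$end, lo, hi))
}

## per-gene regression dispatch; returns non-negative per-peak scores
peak_gene_scores <- function(x, y, method, seed, hyper) {
  k <- ncol(x)
  if (method == "lasso") {
    if (k >= 2) {
      set.seed(seed)
      fit <- glmnet::cv.glmnet(x, y, alpha = 1,
                               nfolds = hyper$lasso_nfolds)
      ## parsimonious CV penalty: weak decoy peaks get exact zeros, so the
      ## bipartite support carries signal even after quantile clipping
      abs(as.numeric(coef(fit, s = hyper$lasso_s))[-1])
    } else {
      abs(unname(coef(stats::lm(y ~ x))[2]))
    }
  } else if (method == "rf") {
    ## debiased impurity importance; uninformative peaks score <= 0 and are
    ## clamped to zero rather than accumulating spurious transition mass
    fit <- ranger::ranger(
      x = as.data.frame(x), y = y, num.trees = hyper$n_trees,
      importance = hyper$rf_importance, seed = seed, num.threads = 1)
    pmax(unname(fit$variable.importance), 0)
  } else if (method == "xgboost") {
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    fit <- xgboost::xgb.train(
      params = list(max_depth = hyper$max_depth, eta = hyper$eta,
                    nthread = 1, seed = seed, objective = "reg:squarederror"),
      data = dtrain, nrounds = hyper$n_rounds, verbose = 0)
    imp <- xgboost::xgb.importance(model = fit)
    out <- setNames(numeric(k), colnames(x))
    out[imp$Feature] <- imp$Gain
    unname(out)
  } else {
    abort_input("unknown method '%s'", method)
  }
}

#' Peak-gene bipartite network under one regression method
#'
#' For each gene, its normalized expression is regressed on the TF-IDF
#' profiles of the peaks in its cis window; the per-peak scores (absolute
#' lasso coefficients, random-forest impurity importances, or XGBoost gain
#' importances) form the gene's column. Genes without candidate peaks get
#' zero columns; a regressor failure on one gene yields a zero column with
#' a warning rather than aborting.
#'
#' @param X_tfidf sparse cell-by-peak TF-IDF matrix.
#' @param Y_hvg dense cell-by-gene normalized expression matrix.
#' @param genes,peaks annotation tibbles matching the matrix columns.
#' @param method one of `"lasso"`, `"rf"`, `"xgboost"`.
#' @param window_bp cis window radius (default 100 kb).
#' @param anchor window anchor, see [candidate_peaks()].
#' @param seed integer seed (each gene derives its own child seed).
#' @param hyper list of regressor hyperparameters; defaults: 5-fold CV for
#'   the lasso penalty, 100 trees of depth 6 (XGBoost `eta` 0.3).
#' @return sparse non-negative p x q matrix whose column support respects
#'   the cis windows.
#' @export
build_peak_gene <- function(X_tfidf, Y_hvg, genes, peaks,
                            method = c("lasso", "rf", "xgboost"),
                            window_bp = 1e5, anchor = "body", seed = 1L,
                            hyper = list()) {
  method <- match.arg(method)
  hyper <- utils::modifyList(
    list(lasso_nfolds = 5L, lasso_s = "lambda.1se",
         rf_importance = "impurity_corrected", n_trees = 100L,
         n_rounds = 100L, max_depth = 6L, eta = 0.3), hyper)
  p <- nrow(peaks); q <- nrow(genes)
  Xd <- as.matrix(X_tfidf)
  colnames(Xd) <- paste0("pk", seq_len(p))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  gene_seeds <- derive_seeds(seed, q)
  for (j in seq_len(q)) {
    cand <- candidate_peaks(genes[j, ], peaks, window_bp, anchor)
    if (length(cand) == 0) next
    scores <- tryCatch(
      peak_gene_scores(Xd[, cand, drop = FALSE], Y_hvg[, j], method,
                       gene_seeds[j], hyper),
      error = function(e) {
        warning(sprintf("peak-gene regression failed for gene %d (%s): %s",
                        j, method, conditionMessage(e)), call. = FALSE)
        numeric(length(cand))
      })
    nz <- which(scores > 0)
    ii <- c(ii, cand[nz]); jj <- c(jj, rep(j, length(nz)))
    xx <- c(xx, scores[nz])
  }
  as_dgc(Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(p, q)))
}

#' Build the full joint network from a preprocessed dataset
#'
#' @param prep a [preprocess_multiome()] result.
#' @param methods peak-gene regression methods to run.
#' @param coaccess a [coaccess_params()].
#' @param window_bp cis window radius for the peak-gene stage.
#' @param K number of principal components for the gene-gene stage.
#' @param seed integer seed.
#' @return a [joint_network()].
#' @export
build_joint_network <- function(prep, methods = c("lasso", "rf", "xgboost"),
                                coaccess = coaccess_params(),
                                window_bp = 1e5, K = 5L, seed = 1L) {
  ds <- prep$dataset
  seeds <- derive_seeds(seed, length(methods) + 1L)
  Wpp <- build_peak_peak(ds$X, ds$peaks, coaccess, seed = seeds[1])
  Wgg <- build_gene_gene(prep$Y_hvg, K = K)
  Wpg <- lapply(seq_along(methods), function(m) {
    build_peak_gene(prep$X_tfidf, prep$Y_hvg, ds$genes, ds$peaks,
                    method = methods[m], window_bp = window_bp,
                    seed = seeds[m + 1L])
  })
  names(Wpg) <- methods
  joint_network(Wpp, Wgg, Wpg, ds$peaks$peak_id, ds$genes$gene_id)
}
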