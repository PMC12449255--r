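test_that("importance scores round-trip with distances", {
  expect_equal(importance_score(0), 1)
  expect_equal(importance_score(log(2)), 0.5, tolerance = 1e-12)
  d <- seq(0, 5, by = 0.25)
  expect_true(all(diff(importance_score(d)) < 0))
  expect_lt(max(abs(-log(importance_score(d)) - d)), 1e-12)
  expect_error(importance_score(-0.1), "non-negative")
})

test_that("peak-gene rankings order by distance with importance in (0, 1]", {
  set.seed(51)
  ids <- c(paste0("p", 1:12), paste0("g", 1:3))
  F <- matrix(rnorm(15 * 4), 15, 4, dimnames = list(ids, NULL))
  emb <- structure(
    list(F = F, node_type = setNames(rep(c("peak", "gene"), c(12, 3)), ids)),
    class = "scpoem_embedding")
  rk <- rank_peak_gene(emb)
  expect_equal(nrow(rk), 36)
  expect_true(all(rk$importance > 0 & rk$importance <= 1))
  by_gene <- split(rk, rk$gene_id)
  for (b in by_gene) {
    expect_equal(b$rank, seq_len(nrow(b)))
    expect_true(all(diff(b$distance) >= 0))
  }
  expect_equal(rk$importance, exp(-rk$distance))
})

test_that("window-restricted rankings only contain cis pairs", {
  sim <- small_sim(seed = 52)
  prep <- preprocess_multiome(sim$dataset)
  ds <- prep$dataset
  ids <- c(ds$peaks$peak_id, ds$genes$gene_id)
  set.seed(1)
  F <- matrix(rnorm(length(ids) * 4), length(ids), 4,
              dimnames = list(ids, NULL))
  emb <- structure(
    list(F = F, node_type = setNames(
      rep(c("peak", "gene"), c(nrow(ds$peaks), nrow(ds$genes))), ids)),
    class = "scpoem_embedding")
  rk <- rank_peak_gene(emb, peaks = ds$peaks, genes = ds$genes,
                       window_bp = 1e5)
  wins <- window_pairs(ds, 1e5)
  expect_setequal(paste(rk$gene_id, rk$peak_id),
                  paste(wins$gene_id, wins$peak_id))
})

test_that("size-constrained clustering recovers planted blobs and respects bounds", {
  set.seed(53)
  Fg <- rbind(matrix(rnorm(100, 0), 25, 4), matrix(rnorm(100, 8), 25, 4),
              matrix(rnorm(100, -8), 25, 4), matrix(rnorm(100, 16), 25, 4))
  rownames(Fg) <- sprintf("g%03d", 1:100)
  cl <- cluster_genes(Fg, n_groups = 4, size_min = 10, size_max = 50,
                      seed = 2)
  expect_setequal(cl$gene_id, rownames(Fg))
  expect_equal(anyDuplicated(cl$gene_id), 0L)
  sizes <- table(cl$subgroup)
  expect_length(sizes, 4)
  expect_true(all(sizes >= 10 & sizes <= 50))
  ## blobs recovered exactly: each true blob maps to one subgroup
  truthcl <- rep(1:4, each = 25)
  tab <- table(cl$subgroup[match(rownames(Fg), cl$gene_id)], truthcl)
  expect_true(all(apply(tab, 2, max) == 25))
  ## degenerate input: identical embeddings still yield a valid partition
  F0 <- matrix(1, 40, 3, dimnames = list(sprintf("h%02d", 1:40), NULL))
  cl0 <- cluster_genes(F0, n_groups = 4, size_min = 5, size_max = 15,
                       seed = 3)
  s0 <- table(cl0$subgroup)
  expect_true(all(s0 >= 5 & s0 <= 15))
  expect_error(cluster_genes(F0, n_groups = 2, size_min = 25, size_max = 30),
               "infeasible")
})

test_that("size repair is honored over random embeddings (fuzz)", {
  for (s in 1:5) {
    set.seed(60 + s)
    q <- sample(40:80, 1)
    Fg <- matrix(rnorm(q * 3), q, 3,
                 dimnames = list(sprintf("g%03d", seq_len(q)), NULL))
    cl <- cluster_genes(Fg, n_groups = 4, size_min = 8, size_max = 25,
                        seed = s)
    sizes <- table(factor(cl$subgroup, levels = 1:4))
    expect_true(all(sizes >= 8 & sizes <= 25))
    expect_setequal(cl$gene_id, rownames(Fg))
  }
})

test_that("peak assignment rules are deterministic and monotone", {
  set.seed(54)
  ids <- c(paste0("p", 1:20), paste0("g", 1:4))
  F <- matrix(rnorm(24 * 4), 24, 4, dimnames = list(ids, NULL))
  emb <- structure(
    list(F = F, node_type = setNames(rep(c("peak", "gene"), c(20, 4)), ids)),
    class = "scpoem_embedding")
  ## single gene with K = 5 -> exactly its 5 nearest peaks
  expect_equal(sort(assign_peaks(emb, "g1", K = 5)),
               sort(nearest_peaks(emb, "g1", 5)$peak_id))
  ## enlarging K never shrinks the set
  prev <- character(0)
  for (K in c(2, 5, 9, 15)) {
    cur <- assign_peaks(emb, c("g1", "g2"), K = K)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  ## radius rule: grows with r, deterministic
  r1 <- assign_peaks(emb, c("g1", "g2"), rule = "radius", r = 1)
  r2 <- assign_peaks(emb, c("g1", "g2"), rule = "radius", r = 4)
  expect_true(all(r1 %in% r2))
  expect_identical(assign_peaks(emb, c("g1", "g2"), rule = "radius", r = 4),
                   r2)
  expect_error(assign_peaks(emb, "g1", rule = "radius"), "requires r")
})

test_that("subgroups of co-regulated genes are assigned their planted peaks", {
  ## peaks of one block embedded near their genes, the rest far away
  set.seed(55)
  ids <- c(paste0("p", 1:30), paste0("g", 1:6))
  F <- matrix(rnorm(36 * 3, sd = 0.4), 36, 3, dimnames = list(ids, NULL))
  F[c(1:5, 31:33), 1] <- F[c(1:5, 31:33), 1] + 10   # planted cluster
  emb <- structure(
    list(F = F, node_type = setNames(rep(c("peak", "gene"), c(30, 6)), ids)),
    class = "scpoem_embedding")
  got <- assign_peaks(emb, paste0("g", 1:3), K = 5)
  expect_gt(mean(paste0("p", 1:5) %in% got), 0.5)
})

test_that("differential regulation has a clean null, detects a planted perturbation, and is symmetric", {
  set.seed(56)
  q <- 50; d <- 12
  FA <- matrix(rnorm(q * d), q, d, dimnames = list(sprintf("g%02d", 1:q), NULL))
  null <- differential_regulation(FA, FA, d_align = 5)
  expect_true(all(null$score < 1e-6))
  expect_setequal(null$gene_id, rownames(FA))
  expect_equal(anyDuplicated(null$gene_id), 0L)
  ## planted perturbation of one gene's neighborhood
  FB <- FA; FB["g09", ] <- rnorm(d, sd = 5)
  sig <- differential_regulation(FA, FB, d_align = 5)
  expect_equal(sig$gene_id[sig$rank == 1], "g09")
  ## symmetric under swapping conditions
  swapped <- differential_regulation(FB, FA, d_align = 5)
  m <- dplyr::inner_join(sig, swapped, by = "gene_id")
  expect_lt(max(abs(m$score.x - m$score.y)), 1e-8)
  ## permutation p-values are well-formed
  pv <- differential_regulation(FA, FB, d_align = 5, n_perm = 10, seed = 3)
  expect_true(all(pv$p_value > 0 & pv$p_value <= 1))
})

test_that("overlap evaluation computes precision and recall against pair and interval truths", {
  rk <- tibble::tibble(
    gene_id = rep(c("g1", "g2"), each = 5),
    peak_id = rep(paste0("p", 1:5), 2),
    distance = c(0.1, 0.2, 0.9, 1.0, 1.1, 0.15, 0.25, 0.95, 1.05, 1.15))
  truth <- tibble::tibble(gene_id = c("g1", "g1", "g2", "g2"),
                          peak_id = c("p1", "p2", "p1", "p2"))
  ## truth pairs occupy exactly the 4 smallest distances
  ev <- overlap_eval(rk, truth_pairs = truth, top_fraction = 0.4)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$overlap, 4)
  ## full ranking recovers every truth pair
  ev_all <- overlap_eval(rk, truth_pairs = truth, top_fraction = 1)
  expect_equal(ev_all$recall, 1)
  expect_equal(ev_all$precision, 4 / 10)
  ## interval-based truth through peak coordinates (half-open overlap)
  peaks <- tibble::tibble(peak_id = paste0("p", 1:5), chrom = "chr1",
                          start = c(100, 300, 500, 700, 900),
                          end = c(200, 400, 600, 800, 1000))
  ti <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 150, end = 350)
  ev_i <- overlap_eval(rk, truth_intervals = ti, peaks = peaks,
                       top_fraction = 0.2)
  expect_equal(ev_i$n_truth, 2)   # p1 and p2 overlap the interval
  ## top 2 global pairs are (g1, p1) and (g2, p1); only the first is truth
  expect_equal(ev_i$precision, 0.5)
  expect_equal(ev_i$overlap, 1)
  expect_error(overlap_eval(rk, truth_pairs = truth[0, ]), "empty")
})

test_that("random rankings score near prevalence", {
  set.seed(57)
  genes <- paste0("g", 1:4); peaks <- paste0("p", 1:25)
  all_pairs <- expand.grid(gene_id = genes, peak_id = peaks,
                           stringsAsFactors = FALSE)
  truth <- all_pairs[sample(nrow(all_pairs), 10), ]
  prevalence <- 10 / nrow(all_pairs)
  precs <- replicate(100, {
    rk <- tibble::tibble(all_pairs, distance = runif(nrow(all_pairs)))
    overlap_eval(rk, truth_pairs = truth, top_fraction = 0.3)$precision
  })
  se <- sd(precs) / sqrt(length(precs))
  expect_lt(abs(mean(precs) - prevalence), 3 * max(se, 0.01))
})

test_that("identical runs give perfect stability and the helper handles controls", {
  sim <- small_sim(seed = 58)
  cfg <- train_config(d = 8, max_epochs = 10)
  res <- scpoem_run(sim$dataset, cfg = cfg, seed = 5)
  st <- stability_from_runs(res, res, control_seed = 1)
  expect_true(all(abs(st$per_gene$spearman - 1) < 1e-12))
  expect_equal(st$median, 1)
  expect_true(all(st$per_gene$spearman >= -1 & st$per_gene$spearman <= 1))
  ## shuffled control pairs different genes, so it is not identically 1
  expect_lt(st$control_median, 1)
})
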