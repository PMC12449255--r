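test_that("quantile clipping winsorizes nonzeros and matches a sort-based oracle", {
  W <- Matrix::sparseMatrix(i = 1:10, j = rep(1:2, 5), x = 1:10,
                            dims = c(10, 2))
  out <- clip_quantiles(W, 0.10, 0.90)
  ## oracle: linear-interpolation quantiles of the nonzero values, clamped
  ## elementwise in the matrix's own storage order
  Wc <- scpoem:::as_dgc(W)
  qs <- quantile(1:10, c(0.10, 0.90))
  expect_equal(out@x, unname(pmin(pmax(Wc@x, qs[1]), qs[2])))
  ## zeros untouched, pattern unchanged
  expect_equal(Matrix::which(out != 0), Matrix::which(W != 0))
  ## equal nonzeros -> unchanged
  W2 <- Matrix::sparseMatrix(i = 1:3, j = c(1, 2, 1), x = rep(4, 3),
                             dims = c(3, 2))
  expect_equal(clip_quantiles(W2)@x, rep(4, 3))
  expect_warning(clip_quantiles(Matrix::sparseMatrix(i = integer(0),
                                                     j = integer(0),
                                                     x = numeric(0),
                                                     dims = c(2, 2))),
                 "all-zero")
})

test_that("row normalization produces stochastic rows and reports dead rows", {
  rn <- row_normalize(matrix(c(2, 0, 2, 4), 2, 2))
  expect_equal(as.matrix(rn$P), matrix(c(0.5, 0, 0.5, 1), 2, 2),
               ignore_attr = TRUE)
  expect_length(rn$dead_rows, 0)
  rn2 <- row_normalize(matrix(c(0, 1, 0, 3), 2, 2))
  expect_equal(rn2$dead_rows, 1L)
  expect_equal(as.matrix(rn2$P)[2, ], c(0.25, 0.75), ignore_attr = TRUE)
  ## already stochastic -> unchanged
  P <- matrix(c(0.3, 0.6, 0.7, 0.4), 2, 2)
  expect_equal(as.matrix(row_normalize(P)$P), P, ignore_attr = TRUE)
  expect_error(row_normalize(matrix(c(-1, 1, 1, 1), 2, 2)), "negative|non-negative")
})

test_that("the transition ensemble averages methods and renormalizes partially dead rows", {
  A <- row_normalize(matrix(c(1, 0, 0, 1), 2, 2))
  B <- row_normalize(matrix(c(0, 0, 1, 1), 2, 2))
  C <- row_normalize(matrix(c(0, 0, 1, 1), 2, 2))
  out <- ensemble_transition(list(A, B, C))
  expect_equal(as.matrix(out$P)[1, ], c(1 / 3, 2 / 3), ignore_attr = TRUE)
  ## identical inputs -> identity
  same <- ensemble_transition(list(A, A, A))
  expect_equal(as.matrix(same$P), as.matrix(A$P))
  ## a row dead in one method but live in others still sums to one
  D <- row_normalize(matrix(c(0, 1, 0, 1), 2, 2))  # row 1 dead
  mix <- ensemble_transition(list(A, A, D))
  expect_equal(Matrix::rowSums(mix$P), c(1, 1), ignore_attr = TRUE)
  ## a row dead everywhere stays dead
  E2 <- row_normalize(matrix(c(0, 1, 0, 1), 2, 2))
  alldead <- ensemble_transition(list(D, E2, D))
  expect_equal(alldead$dead_rows, 1L)
  expect_error(ensemble_transition(list(A)), "at least two")
})

test_that("hand-built 4x3 ensemble matches a by-hand oracle", {
  m1 <- matrix(c(2, 0, 1, 0, 0, 2, 0, 4, 0, 2, 1, 0), 4, 3)
  m2 <- matrix(c(1, 1, 0, 0, 1, 0, 3, 0, 0, 0, 1, 4), 4, 3)
  m3 <- matrix(c(0, 2, 2, 1, 2, 0, 0, 1, 2, 2, 2, 1), 4, 3)
  rn <- lapply(list(m1, m2, m3), row_normalize)
  out <- ensemble_transition(rn)
  oracle <- (as.matrix(rn[[1]]$P) + as.matrix(rn[[2]]$P) +
               as.matrix(rn[[3]]$P)) / 3
  oracle <- sweep(oracle, 1, rowSums(oracle), "/")
  expect_equal(as.matrix(out$P), oracle, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_true(all(abs(Matrix::rowSums(out$P) - 1) < 1e-9))
})

test_that("clip-then-normalize is invariant to positive rescaling", {
  set.seed(31)
  W <- Matrix::rsparsematrix(20, 20, 0.3, rand.x = function(n) runif(n, 0, 5))
  W <- abs(W)
  for (c_scale in c(0.01, 7, 1e4)) {
    a <- row_normalize(clip_quantiles(W))
    b <- row_normalize(clip_quantiles(W * c_scale))
    expect_equal(as.matrix(a$P), as.matrix(b$P), tolerance = 1e-12)
  }
})

test_that("node sampling follows the transition row", {
  P <- rbind(c(0, 1, 0, 0), c(0, 0, 0, 0), c(0.2, 0, 0, 0.8))
  ## one-hot row always returns its column
  set.seed(32)
  expect_true(all(replicate(20, sample_node(1, P)) == 2))
  ## frequencies within 3 sigma of the binomial expectation
  draws <- replicate(10000, sample_node(3, P))
  phat <- mean(draws == 4)
  expect_lt(abs(phat - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))
  expect_setequal(unique(draws), c(1, 4))
  expect_error(sample_node(2, P), class = "scpoem_dead_end")
})

test_that("first-hop frequencies match the transition row (chi-square GOF)", {
  ts <- toy_transitions()
  set.seed(33)
  draws <- replicate(10000, sample_node(3, as.matrix(ts$Ppg)))
  obs <- tabulate(draws, 2)
  p_row <- as.matrix(ts$Ppg)[3, ]
  gof <- suppressWarnings(stats::chisq.test(obs, p = p_row))
  expect_gt(gof$p.value, 0.01)
})

test_that("the walk emits the exact pair counts and weights of the meta-path scheme", {
  ts <- toy_transitions()
  p <- 3; q <- 2
  pairs <- generate_training_pairs(ts, T = 4, seed = 34)
  expect_equal(nrow(pairs$E), 4 * (p + q) * 5)
  expect_equal(pairs$n_truncated, 0L)
  expect_equal(nrow(pairs$Lpeak), 4 * p)
  expect_equal(nrow(pairs$Lgene), 4 * q)
  w_ref <- exp(-0.1 * 0:2)
  expect_true(all(vapply(pairs$E$w, function(w)
    any(abs(w - w_ref) < 1e-12), logical(1))))
  expect_error(generate_training_pairs(ts, T = 0), "at least 1")
})

test_that("pair weights obey the separation law when replaying stored walks", {
  ts <- toy_transitions()
  pairs <- generate_training_pairs(ts, T = 3, seed = 35)
  w_k <- exp(-0.1 * 0:2)
  ## reconstruct E from the stored walks in emission order
  rebuild <- function(Lpeak, Lgene) {
    out <- list()
    for (i in seq_len(nrow(Lpeak))) {
      w <- Lpeak[i, ]
      out[[length(out) + 1]] <- tibble::tibble(
        u = rep(w$P1, 5), v = c(w$G1, w$P2, w$G2, w$P3, w$G3),
        w = w_k[c(1, 1, 2, 2, 3)])
    }
    for (i in seq_len(nrow(Lgene))) {
      w <- Lgene[i, ]
      out[[length(out) + 1]] <- tibble::tibble(
        u = rep(w$G1, 5), v = c(w$P1, w$G2, w$P2, w$G3, w$P3),
        w = w_k[c(1, 1, 2, 2, 3)])
    }
    E <- dplyr::bind_rows(out)
    E[!is.na(E$v), ]
  }
  ## walks are stored loop-major in the same order pairs were emitted
  T <- 3
  per_loop_p <- nrow(pairs$Lpeak) / T
  per_loop_g <- nrow(pairs$Lgene) / T
  Es <- dplyr::bind_rows(lapply(seq_len(T), function(l) {
    rebuild(pairs$Lpeak[(l - 1) * per_loop_p + seq_len(per_loop_p), ],
            pairs$Lgene[(l - 1) * per_loop_g + seq_len(per_loop_g), ])
  }))
  expect_equal(as.data.frame(pairs$E), as.data.frame(Es),
               ignore_attr = TRUE)
})

test_that("walks truncate at dead rows and emit only realized pairs", {
  ## peak 2 has no outgoing peak-gene weight in any method
  Wpp <- Matrix::Matrix(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3),
                        sparse = TRUE)
  Wgg <- Matrix::Matrix(matrix(c(0, 1, 1, 0), 2, 2), sparse = TRUE)
  Wpg <- Matrix::Matrix(matrix(c(1, 0, 1, 0, 0, 1), 3, 2), sparse = TRUE)
  net <- joint_network(Wpp, Wgg, list(lasso = Wpg, rf = Wpg, xgboost = Wpg),
                       paste0("p", 1:3), paste0("g", 1:2))
  ts <- build_transition_set(net)
  expect_equal(ts$dead$Ppg, 2L)
  pairs <- generate_training_pairs(ts, T = 2, seed = 36)
  ## peak 2 walks lose the three gene-branch pairs each
  expect_equal(pairs$n_truncated, 2L * 3L)
  expect_false(any(is.na(pairs$E$v)))
  ## truncated walks recorded with NA gene branch
  p2 <- pairs$Lpeak[pairs$Lpeak$P1 == "p2", ]
  expect_true(all(is.na(p2$G1)))
})

test_that("walk generation is byte-identical under a fixed seed", {
  ts <- toy_transitions()
  a <- generate_training_pairs(ts, T = 5, seed = 37)
  b <- generate_training_pairs(ts, T = 5, seed = 37)
  expect_identical(a, b)
  c <- generate_training_pairs(ts, T = 5, seed = 38)
  expect_false(identical(a$E, c$E))
})

test_that("transition sets built from a real joint network are row-stochastic", {
  sim <- small_sim(seed = 39)
  prep <- preprocess_multiome(sim$dataset)
  net <- build_joint_network(prep, seed = 5)
  ts <- build_transition_set(net)
  for (nm in c("Ppp", "Pgg", "Ppg", "Pgp")) {
    P <- ts[[nm]]
    rs <- Matrix::rowSums(P)
    live <- setdiff(seq_len(nrow(P)), ts$dead[[nm]])
    expect_true(all(abs(rs[live] - 1) < 1e-9), label = nm)
    expect_true(all(rs[ts$dead[[nm]]] == 0), label = paste(nm, "dead"))
    expect_true(all(P@x >= 0), label = nm)
  }
})
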